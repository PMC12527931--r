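# Curated one-transcript-per-gene protein-coding reference.
#
# All coordinates are 0-based, half-open, in transcript space: cds_start is
# the offset of the first nucleotide of the start codon, cds_end_exclusive
# the offset one past the last nucleotide of the stop codon.

STOP_CODONS <- c("TAG", "TAA", "TGA")

#' Construct a curated reference object
#'
#' Bundles a transcript table with the matching transcript sequences. Normally
#' produced by [build_reference()] or [simulate_reference()]; exposed so that
#' hand-built fixtures and readers can create one directly.
#'
#' @param transcripts Data frame with columns `transcript_id`, `gene_id`,
#'   `cds_start`, `cds_end_exclusive` (0-based, half-open, transcript space).
#' @param sequences Named character vector (or `DNAStringSet`) of transcript
#'   sequences; names must cover every `transcript_id`.
#' @return An object of class `ribo_reference`: a list with elements
#'   `transcripts` (data frame, one row per transcript, with derived columns
#'   `n_codons`, `utr5_length`, `utr3_length`) and `sequences` (named
#'   character, uppercase DNA).
#' @export
ribo_reference <- function(transcripts, sequences) {
  stopifnot(is.data.frame(transcripts))
  req <- c("transcript_id", "gene_id", "cds_start", "cds_end_exclusive")
  missing <- setdiff(req, names(transcripts))
  if (length(missing)) {
    stop("transcripts is missing column(s): ", paste(missing, collapse = ", "))
  }
  nm <- names(sequences)  # names() works on both XStringSet and character
  sequences <- as_dna(as.character(sequences))
  names(sequences) <- nm
  if (is.null(names(sequences))) stop("sequences must be named")
  absent <- setdiff(transcripts$transcript_id, names(sequences))
  if (length(absent)) {
    stop("no sequence for transcript(s): ", paste(head(absent, 5), collapse = ", "))
  }
  if (anyDuplicated(transcripts$transcript_id)) {
    stop("duplicate transcript_id in reference table")
  }
  tl <- nchar(sequences[transcripts$transcript_id])
  bad <- transcripts$cds_start < 0 | transcripts$cds_end_exclusive > tl |
    transcripts$cds_start >= transcripts$cds_end_exclusive
  if (any(bad)) {
    stop("CDS coordinates out of bounds for: ",
         paste(head(transcripts$transcript_id[bad], 5), collapse = ", "))
  }
  transcripts$n_codons <- (transcripts$cds_end_exclusive - transcripts$cds_start) / 3
  transcripts$utr5_length <- transcripts$cds_start
  transcripts$utr3_length <- tl - transcripts$cds_end_exclusive
  rownames(transcripts) <- NULL
  structure(
    list(transcripts = transcripts,
         sequences = sequences[transcripts$transcript_id]),
    class = "ribo_reference"
  )
}

#' @export
print.ribo_reference <- function(x, ...) {
  cat("ribo_reference with", nrow(x$transcripts), "transcripts (",
      length(unique(x$transcripts$gene_id)), "genes )\n")
  cat("  median CDS length:",
      stats::median(x$transcripts$n_codons), "codons\n")
  invisible(x)
}

# Internal: fetch one transcript row (stops on unknown id).
ref_row <- function(reference, transcript_id) {
  i <- match(transcript_id, reference$transcripts$transcript_id)
  if (anyNA(i)) {
    stop("unknown transcript_id: ",
         paste(head(transcript_id[is.na(i)], 5), collapse = ", "))
  }
  reference$transcripts[i, , drop = FALSE]
}

#' Validate a coding region
#'
#' Applies the three CDS validity rules used when curating the reference:
#' the CDS must have three-base periodicity (length divisible by 3), end in a
#' canonical stop codon (TAG/TAA/TGA; UAG/UAA/UGA on the RNA alphabet), and
#' contain no ambiguous bases (characters outside ACGT/U). The reported
#' `reason` is the first rule violated, in that order. Non-AUG start codons
#' and internal UGA (selenocysteine recoding) are deliberately accepted.
#'
#' @param sequence Transcript sequence (character scalar, DNA or RNA).
#' @param cds_start,cds_end_exclusive 0-based half-open CDS coordinates.
#' @return List with `accepted` (logical) and `reason` (one of `"ok"`,
#'   `"not_periodic"`, `"bad_stop"`, `"ambiguous_base"`).
#' @export
#' @examples
#' validate_cds("ATGGGCTAA", 0, 9)
#' validate_cds("ATGGNCTAA", 0, 9)
validate_cds <- function(sequence, cds_start, cds_end_exclusive) {
  sequence <- as_dna(sequence)
  if (cds_start < 0 || cds_end_exclusive > nchar(sequence) ||
      cds_start >= cds_end_exclusive) {
    stop("CDS coordinates out of bounds")
  }
  cds <- substr(sequence, cds_start + 1L, cds_end_exclusive)
  if (nchar(cds) %% 3L != 0L) {
    return(list(accepted = FALSE, reason = "not_periodic"))
  }
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  if (!last %in% STOP_CODONS) {
    return(list(accepted = FALSE, reason = "bad_stop"))
  }
  if (grepl("[^ACGT]", cds)) {
    return(list(accepted = FALSE, reason = "ambiguous_base"))
  }
  list(accepted = TRUE, reason = "ok")
}

#' Select the principal transcript of a gene
#'
#' Chooses one transcript per gene following the MANE/APPRIS precedence: the
#' MANE transcript when one exists; otherwise all candidates tied at the best
#' APPRIS rank are considered, the longest is taken, and equal-length ties are
#' broken uniformly at random (reproducibly under `seed`). If several
#' candidates are flagged MANE the same longest-then-random rule is applied
#' within the MANE set.
#'
#' @param candidates Data frame of one gene's candidate transcripts with
#'   columns `transcript_id`, `is_mane` (logical), `appris_rank` (integer,
#'   smaller is better, `NA` = unranked) and `transcript_length` (nt).
#' @param seed Integer seed for reproducible tie-breaking.
#' @return The selected `transcript_id` (character scalar).
#' @export
select_principal_transcript <- function(candidates, seed = 1L) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    stop("no candidates for gene")
  }
  pool <- candidates
  if (any(pool$is_mane)) {
    pool <- pool[pool$is_mane, , drop = FALSE]
  } else {
    rank <- pool$appris_rank
    rank[is.na(rank)] <- Inf
    pool <- pool[rank == min(rank), , drop = FALSE]
  }
  pool <- pool[pool$transcript_length == max(pool$transcript_length), , drop = FALSE]
  if (nrow(pool) == 1L) {
    return(pool$transcript_id[1])
  }
  # deterministic tie-break; order candidates by id first so row order in the
  # input cannot change the outcome
  pool <- pool[order(pool$transcript_id), , drop = FALSE]
  with_seed(seed, pool$transcript_id[sample.int(nrow(pool), 1L)])
}

#' Build the curated reference
#'
#' Runs principal-transcript selection for every gene, validates the chosen
#' CDS with [validate_cds()], and drops genes whose selected transcript fails
#' validation (the runner-up isoform is *not* promoted). Genes on the
#' exclusion list are removed before selection.
#'
#' @param candidates Data frame with columns `gene_id`, `transcript_id`,
#'   `is_mane`, `appris_rank`, `cds_start`, `cds_end_exclusive` (one row per
#'   candidate transcript).
#' @param sequences Named character vector / `DNAStringSet` of transcript
#'   sequences.
#' @param exclude Character vector of gene_ids to drop (e.g. manually
#'   identified misannotations or pseudoautosomal duplicates).
#' @param seed Integer seed for equal-length tie-breaking.
#' @return A `ribo_reference`. Genes dropped during validation are recorded in
#'   `attr(, "dropped")` (data frame: gene_id, transcript_id, reason).
#' @export
build_reference <- function(candidates, sequences, exclude = character(),
                            seed = 1L) {
  stopifnot(is.data.frame(candidates))
  if (anyDuplicated(candidates$transcript_id)) {
    stop("duplicate transcript_id across candidate records")
  }
  nm <- names(sequences)
  sequences <- as_dna(as.character(sequences))
  names(sequences) <- nm
  absent <- setdiff(candidates$transcript_id, names(sequences))
  if (length(absent)) {
    stop("no sequence for candidate transcript(s): ",
         paste(head(absent, 5), collapse = ", "))
  }
  candidates$transcript_length <- nchar(sequences[candidates$transcript_id])
  genes <- unique(candidates$gene_id)
  genes <- setdiff(genes, exclude)

  rows <- vector("list", length(genes))
  dropped <- list()
  for (k in seq_along(genes)) {
    g <- genes[k]
    cand <- candidates[candidates$gene_id == g, , drop = FALSE]
    tid <- select_principal_transcript(cand, seed = seed)
    row <- cand[cand$transcript_id == tid, , drop = FALSE]
    v <- validate_cds(sequences[[tid]], row$cds_start, row$cds_end_exclusive)
    if (!v$accepted) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(gene_id = g, transcript_id = tid, reason = v$reason,
                   stringsAsFactors = FALSE)
      next
    }
    rows[[k]] <- data.frame(
      transcript_id = tid, gene_id = g,
      cds_start = row$cds_start, cds_end_exclusive = row$cds_end_exclusive,
      stringsAsFactors = FALSE
    )
  }
  tbl <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tbl)) {
    tbl <- data.frame(transcript_id = character(), gene_id = character(),
                      cds_start = integer(), cds_end_exclusive = integer(),
                      stringsAsFactors = FALSE)
  }
  ref <- ribo_reference(tbl, sequences[tbl$transcript_id])
  attr(ref, "dropped") <- if (length(dropped)) {
    do.call(rbind, dropped)
  } else {
    data.frame(gene_id = character(), transcript_id = character(),
               reason = character(), stringsAsFactors = FALSE)
  }
  ref
}

#' Write a curated reference to FASTA + table
#'
#' @param reference A `ribo_reference`.
#' @param prefix Output path prefix; writes `<prefix>.fa` and
#'   `<prefix>.transcripts.tsv` (transcript_id, gene_id, cds_start,
#'   cds_end_exclusive, n_codons).
#' @return Invisibly, the two file paths.
#' @export
write_reference <- function(reference, prefix) {
  fa <- paste0(prefix, ".fa")
  tsv <- paste0(prefix, ".transcripts.tsv")
  writeXStringSet(DNAStringSet(reference$sequences), fa)
  cols <- c("transcript_id", "gene_id", "cds_start", "cds_end_exclusive",
            "n_codons")
  write.table(reference$transcripts[, cols], tsv, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, table = tsv))
}

#' Read a curated reference written by [write_reference()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `ribo_reference`.
#' @export
read_reference <- function(prefix) {
  tbl <- read.delim(paste0(prefix, ".transcripts.tsv"),
                    stringsAsFactors = FALSE)
  seqs <- readDNAStringSet(paste0(prefix, ".fa"))
  sq <- as.character(seqs)
  names(sq) <- sub("\\s.*$", "", names(seqs))
  ribo_reference(tbl, sq)
}

#' Read candidate transcripts from a transcript-space GTF
#'
#' Minimal reader for annotation where `seqnames` are transcript ids and CDS
#' features carry `gene_id`/`transcript_id` attributes, plus optionally a
#' `tag` attribute marking the MANE transcript and an `appris_rank`
#' attribute. Requires the rtracklayer package. Exon-aware genome-space
#' arithmetic is out of scope: coordinates must already be transcript-space.
#'
#' @param gtf Path to the GTF file.
#' @param mane_tag Attribute value in `tag` that marks a MANE transcript.
#' @return Candidate data frame suitable for [build_reference()].
#' @export
read_candidates_gtf <- function(gtf, mane_tag = "MANE_Select") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_candidates_gtf requires the rtracklayer package")
  }
  gr <- rtracklayer::import(gtf, format = "gtf")
  gr <- gr[gr$type == "CDS"]
  if (!length(gr)) stop("no CDS features in ", gtf)
  md <- as.data.frame(gr)
  tag <- if ("tag" %in% names(md)) as.character(md$tag) else NA_character_
  rank <- if ("appris_rank" %in% names(md)) {
    suppressWarnings(as.integer(as.character(md$appris_rank)))
  } else {
    NA_integer_
  }
  cand <- data.frame(
    gene_id = as.character(md$gene_id),
    transcript_id = as.character(md$transcript_id),
    is_mane = !is.na(tag) & tag == mane_tag,
    appris_rank = rank,
    cds_start = md$start - 1L,  # GTF is 1-based inclusive
    cds_end_exclusive = md$end,
    stringsAsFactors = FALSE
  )
  # one CDS feature per transcript expected; collapse defensively
  cand <- do.call(rbind, lapply(split(cand, cand$transcript_id), function(d) {
    d$cds_start <- min(d$cds_start)
    d$cds_end_exclusive <- max(d$cds_end_exclusive)
    d[1, , drop = FALSE]
  }))
  rownames(cand) <- NULL
  cand
}
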