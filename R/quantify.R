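# Footprint reads -> codon-level A-site count matrices.
#
# Reads are tabular records (transcript_id, five_prime_pos, length) with
# optional condition/replicate columns. five_prime_pos is the 0-based
# transcript coordinate of the read 5' end.

#' Default A-site offset table
#'
#' Maps admitted monosome read lengths to the distance (nt) from the read 5'
#' end to the first nucleotide of the A-site codon. The default uses the
#' canonical mammalian +15 nt offset for full-length (29-32 nt) footprints
#' and anchors short (20-22 nt, vacant-A-site) footprints by their 5' end
#' with the same offset. Fully overridable per length.
#'
#' @param lengths Integer vector of admitted read lengths.
#' @param offset Offset(s) in nt, recycled over `lengths`.
#' @return Named integer vector mapping length -> offset.
#' @export
#' @examples
#' default_offsets()
default_offsets <- function(lengths = c(20:22, 29:32), offset = 15L) {
  offs <- as.integer(rep_len(offset, length(lengths)))
  if (any(offs <= 0L)) stop("offsets must be positive")
  stats::setNames(offs, as.character(lengths))
}

#' Filter reads by footprint length classes
#'
#' Retains exactly the reads whose length falls in any admitted inclusive
#' range (e.g. 20-22 nt vacant-A-site and 29-32 nt occupied-A-site monosome
#' footprints), preserving input order.
#'
#' @param reads Data frame with a `length` column.
#' @param classes Length classes, e.g. `"20-22,29-32"` or
#'   `list(c(20, 22), c(29, 32))`.
#' @return The filtered data frame.
#' @export
filter_reads_by_length <- function(reads, classes = "20-22,29-32") {
  classes <- parse_length_classes(classes)
  keep <- Reduce(`|`, lapply(classes, function(r) in_range(reads$length, r)))
  reads[keep, , drop = FALSE]
}

#' Assign A-site codons to footprint reads
#'
#' The A-site nucleotide of a read is `five_prime_pos + offset(length)`; its
#' codon index is `floor((a_site - cds_start) / 3)` (0-based). Reads whose
#' A-site falls outside the CDS get `NA` (they are excluded from CDS count
#' matrices but logged by [build_codon_matrix()]).
#'
#' @param reads Data frame with `transcript_id`, `five_prime_pos`, `length`.
#' @param reference A `ribo_reference`.
#' @param offsets Named offset table from [default_offsets()].
#' @return `reads` with added columns `a_site` (nt) and `codon` (0-based
#'   index, `NA` outside the CDS).
#' @export
assign_a_site <- function(reads, reference, offsets = default_offsets()) {
  lens <- as.character(reads$length)
  miss <- setdiff(unique(lens), names(offsets))
  if (length(miss)) {
    stop("no A-site offset for read length(s): ", paste(miss, collapse = ", "))
  }
  rows <- ref_row(reference, reads$transcript_id)
  a <- reads$five_prime_pos + unname(offsets[lens])
  codon <- floor((a - rows$cds_start) / 3)
  codon[a < rows$cds_start | a >= rows$cds_end_exclusive] <- NA_integer_
  reads$a_site <- a
  reads$codon <- as.integer(codon)
  reads
}

#' Build codon-level count matrices
#'
#' Admits reads by length class, assigns A-site codons, and tabulates in-CDS
#' reads per codon for every (condition, replicate) sample. Reads mapping
#' outside the CDS are counted separately and reported in the attached log
#' summary, so that in-CDS + outside = admitted for every sample.
#'
#' @param reads Data frame with `transcript_id`, `five_prime_pos`, `length`
#'   and optional `condition`/`replicate` columns (defaulted to a single
#'   sample when absent).
#' @param reference A `ribo_reference`.
#' @param offsets Offset table; see [default_offsets()].
#' @param classes Admitted length classes (see [filter_reads_by_length()]).
#' @return A `codon_counts` object: nested list `counts[[transcript]][[condition]]`
#'   of integer matrices (n_codons x replicates), with `conditions`,
#'   `replicates` and `n_codons` elements and an `attr(, "outside")` data
#'   frame logging per-sample admitted / in-CDS / outside-CDS read counts.
#' @export
build_codon_matrix <- function(reads, reference, offsets = default_offsets(),
                               classes = "20-22,29-32") {
  if (is.null(reads$condition)) reads$condition <- "sample"
  if (is.null(reads$replicate)) reads$replicate <- "rep1"
  reads <- filter_reads_by_length(reads, classes)
  reads <- assign_a_site(reads, reference, offsets)

  conditions <- unique(reads$condition)
  replicates <- sort(unique(reads$replicate))
  tx <- reference$transcripts
  n_codons <- stats::setNames(tx$n_codons, tx$transcript_id)

  counts <- lapply(tx$transcript_id, function(t) {
    lapply(stats::setNames(conditions, conditions), function(cond) {
      matrix(0L, nrow = n_codons[[t]], ncol = length(replicates),
             dimnames = list(NULL, replicates))
    })
  })
  names(counts) <- tx$transcript_id

  ok <- !is.na(reads$codon)
  inside <- reads[ok, , drop = FALSE]
  key <- split(seq_len(nrow(inside)),
               list(inside$transcript_id, inside$condition, inside$replicate),
               drop = TRUE)
  for (k in names(key)) {
    idx <- key[[k]]
    t <- inside$transcript_id[idx[1]]
    cond <- inside$condition[idx[1]]
    rep <- inside$replicate[idx[1]]
    counts[[t]][[cond]][, rep] <-
      counts[[t]][[cond]][, rep] +
      tabulate(inside$codon[idx] + 1L, nbins = n_codons[[t]])
  }

  log <- do.call(rbind, lapply(conditions, function(cond) {
    do.call(rbind, lapply(replicates, function(rep) {
      sel <- reads$condition == cond & reads$replicate == rep
      data.frame(condition = cond, replicate = rep,
                 n_admitted = sum(sel),
                 n_in_cds = sum(sel & ok),
                 n_outside = sum(sel & !ok),
                 stringsAsFactors = FALSE)
    }))
  }))

  obj <- structure(
    list(counts = counts, conditions = conditions, replicates = replicates,
         n_codons = n_codons),
    class = "codon_counts"
  )
  attr(obj, "outside") <- log
  obj
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("codon_counts:", length(x$counts), "transcripts,",
      "conditions:", paste(x$conditions, collapse = ", "),
      "| replicates:", paste(x$replicates, collapse = ", "), "\n")
  invisible(x)
}

#' Apply the transcript coverage filter
#'
#' A transcript is retained iff in *every* replicate of *both* compared
#' conditions its mean footprint count per codon is at least `min_mean`
#' (default 0.5 reads/codon; the threshold is inclusive).
#'
#' @param counts A `codon_counts` object.
#' @param conditions Character vector of the two compared conditions
#'   (defaults to all conditions present).
#' @param min_mean Minimum mean reads per codon.
#' @return Character vector of retained transcript_ids.
#' @export
coverage_filter <- function(counts, conditions = counts$conditions,
                            min_mean = 0.5) {
  txs <- names(counts$counts)
  if (is.null(txs)) return(character(0))
  keep <- vapply(txs, function(t) {
    all(vapply(conditions, function(cond) {
      m <- counts$counts[[t]][[cond]]
      if (is.null(m)) return(FALSE)
      all(colSums(m) / nrow(m) >= min_mean)
    }, logical(1)))
  }, logical(1))
  txs[keep]
}

#' Export codon counts as a tidy table
#'
#' @param counts A `codon_counts` object.
#' @return Data frame (transcript_id, codon, condition, replicate, count).
#' @export
counts_to_table <- function(counts) {
  do.call(rbind, lapply(names(counts$counts), function(t) {
    do.call(rbind, lapply(counts$conditions, function(cond) {
      m <- counts$counts[[t]][[cond]]
      do.call(rbind, lapply(colnames(m), function(rep) {
        data.frame(transcript_id = t, codon = seq_len(nrow(m)) - 1L,
                   condition = cond, replicate = rep, count = m[, rep],
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
}

#' Read a footprint read table
#'
#' Tab-separated with columns `transcript_id`, `five_prime_pos`, `length`
#' and optional `condition`, `replicate`.
#'
#' @param path File path.
#' @return Data frame of reads.
#' @export
read_footprint_table <- function(path) {
  reads <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("transcript_id", "five_prime_pos", "length")
  missing <- setdiff(req, names(reads))
  if (length(missing)) {
    stop("read table is missing column(s): ", paste(missing, collapse = ", "))
  }
  reads
}

#' Read footprints from a transcript-space BAM file
#'
#' Extracts (transcript_id, five_prime_pos, length) from alignments whose
#' reference sequences are transcripts (e.g. a transcriptome-space BAM).
#' Read length is taken as the aligned query width; the 5' end as the
#' leftmost aligned position. Requires the Rsamtools package.
#'
#' @param path BAM file path.
#' @return Data frame of reads.
#' @export
read_footprint_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("read_footprint_bam requires the Rsamtools package")
  }
  p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "qwidth"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  ok <- !is.na(b$pos)
  data.frame(transcript_id = as.character(b$rname)[ok],
             five_prime_pos = b$pos[ok] - 1L,  # BAM pos is 1-based
             length = b$qwidth[ok],
             stringsAsFactors = FALSE)
}
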