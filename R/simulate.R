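# Seed-deterministic synthetic-data generators. Every generator emits the
# ground truth needed for recovery tests alongside the data, and its outputs
# satisfy the consuming modules' preconditions by construction.

SENSE_CODONS <- setdiff(
  as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"), paste0),
                  c("T", "C", "A", "G"), paste0)),
  STOP_CODONS
)

#' Simulate a curated reference
#'
#' Generates random transcripts that satisfy every curated-reference
#' invariant by construction: AUG start codon, in-frame stop codon only at
#' the CDS end (internal codons drawn from the 61 sense codons), no
#' ambiguous bases, UTRs of random sequence.
#'
#' @param n_transcripts Number of transcripts (one per gene).
#' @param cds_codons Inclusive range of CDS lengths in codons (including the
#'   stop codon), default `c(150, 450)`.
#' @param utr5 Inclusive range of 5'UTR lengths (nt), default `c(20, 150)`.
#' @param utr3 Inclusive range of 3'UTR lengths (nt), default `c(20, 150)`.
#' @param seed Integer seed.
#' @return A `ribo_reference`; the transcript table doubles as the ground
#'   truth.
#' @export
simulate_reference <- function(n_transcripts, cds_codons = c(150L, 450L),
                               utr5 = c(20L, 150L), utr3 = c(20L, 150L),
                               seed = 1L) {
  with_seed(seed, {
    ids <- sprintf("tx%04d", seq_len(n_transcripts))
    seqs <- character(n_transcripts)
    cds_start <- integer(n_transcripts)
    cds_end <- integer(n_transcripts)
    pick <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
    for (i in seq_len(n_transcripts)) {
      nc <- pick(cds_codons)
      u5 <- pick(utr5)
      u3 <- pick(utr3)
      cds <- paste0(
        "ATG",
        paste(sample(SENSE_CODONS, nc - 2L, replace = TRUE), collapse = ""),
        sample(STOP_CODONS, 1L)
      )
      seqs[i] <- paste0(
        paste(sample(c("A", "C", "G", "T"), u5, replace = TRUE), collapse = ""),
        cds,
        paste(sample(c("A", "C", "G", "T"), u3, replace = TRUE), collapse = "")
      )
      cds_start[i] <- u5
      cds_end[i] <- u5 + 3L * nc
    }
    ribo_reference(
      data.frame(transcript_id = ids,
                 gene_id = sub("^tx", "gene", ids),
                 cds_start = cds_start, cds_end_exclusive = cds_end,
                 stringsAsFactors = FALSE),
      stats::setNames(seqs, ids)
    )
  })
}

#' Simulate codon-level footprint counts
#'
#' Draws per-codon counts from a negative binomial (mean = `coverage`,
#' dispersion `size = dispersion`; `Inf` degenerates to Poisson) for every
#' transcript, condition and replicate. Pause sites are injected as
#' multiplicative rate factors at chosen codons in chosen conditions.
#' Ribosome-profiling codon counts are overdispersed relative to Poisson,
#' hence the negative-binomial default.
#'
#' @param reference A `ribo_reference`.
#' @param coverage Baseline mean reads per codon (default 2).
#' @param dispersion Negative-binomial size parameter (default 10; `Inf` =
#'   Poisson).
#' @param pauses `NULL` or a data frame (transcript_id, codon \[0-based\],
#'   fold, condition) where `condition` names one condition or `"all"`.
#' @param n_replicates Replicates per condition (default 2).
#' @param conditions Condition names (default `c("test", "ctrl")`).
#' @param seed Integer seed.
#' @return A `codon_counts` object; the injected pause table is attached as
#'   `attr(, "truth")`.
#' @export
simulate_codon_counts <- function(reference, coverage = 2, dispersion = 10,
                                  pauses = NULL, n_replicates = 2L,
                                  conditions = c("test", "ctrl"), seed = 1L) {
  stopifnot(coverage > 0)
  tx <- reference$transcripts
  replicates <- paste0("rep", seq_len(n_replicates))
  if (!is.null(pauses)) {
    bad <- !pauses$transcript_id %in% tx$transcript_id
    if (any(bad)) stop("pause spec references unknown transcripts")
    if (any(pauses$fold <= 0)) stop("pause folds must be positive")
  }
  draw <- function(mu) {
    if (is.infinite(dispersion)) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = dispersion)
  }
  with_seed(seed, {
    counts <- lapply(tx$transcript_id, function(t) {
      nc <- tx$n_codons[tx$transcript_id == t]
      lapply(stats::setNames(conditions, conditions), function(cond) {
        rate <- rep(coverage, nc)
        if (!is.null(pauses)) {
          sel <- pauses$transcript_id == t &
            (pauses$condition == cond | pauses$condition == "all")
          if (any(sel)) {
            idx <- pauses$codon[sel] + 1L
            if (any(idx < 1L | idx > nc)) stop("pause codon outside CDS")
            rate[idx] <- rate[idx] * pauses$fold[sel]
          }
        }
        m <- matrix(draw(rep(rate, n_replicates)), nrow = nc,
                    dimnames = list(NULL, replicates))
        storage.mode(m) <- "integer"
        m
      })
    })
    names(counts) <- tx$transcript_id
    obj <- structure(
      list(counts = counts, conditions = conditions, replicates = replicates,
           n_codons = stats::setNames(tx$n_codons, tx$transcript_id)),
      class = "codon_counts"
    )
    attr(obj, "truth") <- pauses
    obj
  })
}

#' Simulate long (collision-class) footprint reads
#'
#' For each collision class, reads are sampled uniformly over the class's
#' defining length x 5'-offset rectangle on transcripts that can host it;
#' background `other` reads are monosome-length footprints placed uniformly
#' over CDSs. Labels are retained for classifier recovery tests.
#'
#' @param reference A `ribo_reference`.
#' @param n_per_class Named integer vector of read counts per class
#'   (`start_40S_80S`, `start_80S_80S`, `termination_disome`, `other`);
#'   classes with zero counts are absent from the output.
#' @param rectangles Class gates (defaults mirror
#'   [collision_rectangles()], so the classifier recovers labels exactly).
#' @param monosome_lengths Lengths for background reads (default 29-32 nt).
#' @param seed Integer seed.
#' @return Data frame (transcript_id, five_prime_pos, length, label).
#' @export
simulate_long_reads <- function(reference,
                                n_per_class = c(start_40S_80S = 500L,
                                                start_80S_80S = 500L,
                                                termination_disome = 500L,
                                                other = 2000L),
                                rectangles = collision_rectangles(),
                                monosome_lengths = 29:32,
                                seed = 1L) {
  tx <- reference$transcripts
  tlen <- nchar(reference$sequences)[tx$transcript_id]
  with_seed(seed, {
    out <- list()
    for (cls in names(n_per_class)) {
      n <- n_per_class[[cls]]
      if (n == 0L) next
      if (cls == "other") {
        i <- sample.int(nrow(tx), n, replace = TRUE)
        len <- sample(monosome_lengths, n, replace = TRUE)
        # uniform 5' position over the CDS, kept inside the transcript
        lo <- tx$cds_start[i]
        hi <- pmin(tx$cds_end_exclusive[i] - 1L, tlen[i] - len)
        pos <- lo + floor(runif(n) * (hi - lo + 1L))
        out[[cls]] <- data.frame(transcript_id = tx$transcript_id[i],
                                 five_prime_pos = as.integer(pos),
                                 length = as.integer(len), label = cls,
                                 stringsAsFactors = FALSE)
        next
      }
      r <- rectangles[[cls]]
      anchor <- if (r$anchor == "start") tx$cds_start else tx$cds_end_exclusive - 3L
      # transcripts able to host the whole rectangle
      ok <- anchor + r$d[1] >= 0L & anchor + r$d[2] + r$length[2] <= tlen
      if (!any(ok)) stop("rectangle for class ", cls,
                         " is not placeable on any transcript")
      i <- sample(which(ok), n, replace = TRUE)
      len <- sample(r$length[1]:r$length[2], n, replace = TRUE)
      d <- sample(r$d[1]:r$d[2], n, replace = TRUE)
      out[[cls]] <- data.frame(transcript_id = tx$transcript_id[i],
                               five_prime_pos = as.integer(anchor[i] + d),
                               length = as.integer(len), label = cls,
                               stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, out)
    rownames(reads) <- NULL
    reads
  })
}

#' Simulate an inducible CRISPRi screen count table
#'
#' Each sgRNA's true log2 enrichment is its gene's effect plus
#' `Normal(0, sgrna_sd)` noise (non-targeting controls have gene effect 0
#' and the same sgRNA-level noise, making them exchangeable with
#' null-effect genes). Uninduced sample counts are multinomial over a
#' uniform abundance vector at the stated depth; induced abundances are
#' tilted by `2^e`. Replicates are independent draws around the same true
#' enrichments.
#'
#' @param gene_effects Named numeric vector of true per-gene log2 effects
#'   (names become targets).
#' @param sgrnas_per_gene sgRNAs per gene TSS (default 9, the screen design).
#' @param n_ntc Number of non-targeting controls; default sizes the library
#'   so NTCs are `ntc_fraction` of it.
#' @param ntc_fraction NTC fraction of the library when `n_ntc` is `NULL`
#'   (default 0.10).
#' @param sgrna_sd sgRNA-level standard deviation of true enrichment
#'   (default 0.5).
#' @param depth Mean reads per sgRNA per sample (default 1000).
#' @param n_replicates Replicates (default 2).
#' @param seed Integer seed.
#' @return List: `counts` (sgRNA_id, target, one column per sample),
#'   `samples` (sample sheet), `truth` (per-sgRNA true enrichments and gene
#'   effects).
#' @export
simulate_screen <- function(gene_effects, sgrnas_per_gene = 9L, n_ntc = NULL,
                            ntc_fraction = 0.10, sgrna_sd = 0.5,
                            depth = 1000L, n_replicates = 2L, seed = 1L) {
  stopifnot(depth > 0, ntc_fraction >= 0, ntc_fraction < 1)
  if (is.null(names(gene_effects))) {
    names(gene_effects) <- sprintf("gene%03d", seq_along(gene_effects))
  }
  n_target <- length(gene_effects) * sgrnas_per_gene
  if (is.null(n_ntc)) {
    n_ntc <- round(n_target * ntc_fraction / (1 - ntc_fraction))
  }
  with_seed(seed, {
    target <- c(rep(names(gene_effects), each = sgrnas_per_gene),
                rep(NTC_LABEL, n_ntc))
    sgRNA_id <- c(
      paste0(rep(names(gene_effects), each = sgrnas_per_gene), "_sg",
             rep(seq_len(sgrnas_per_gene), length(gene_effects))),
      sprintf("NTC_sg%04d", seq_len(n_ntc))
    )
    effect <- c(rep(unname(gene_effects), each = sgrnas_per_gene),
                rep(0, n_ntc))
    e_true <- effect + rnorm(length(effect), 0, sgrna_sd)

    n_sg <- length(sgRNA_id)
    total <- as.integer(depth) * n_sg
    base <- rep(1 / n_sg, n_sg)
    tilted <- base * 2^e_true
    tilted <- tilted / sum(tilted)

    counts <- data.frame(sgRNA_id = sgRNA_id, target = target,
                         stringsAsFactors = FALSE)
    samples <- list()
    for (r in seq_len(n_replicates)) {
      u <- paste0("uninduced_rep", r)
      i <- paste0("induced_rep", r)
      counts[[u]] <- as.integer(rmultinom(1L, total, base))
      counts[[i]] <- as.integer(rmultinom(1L, total, tilted))
      samples[[length(samples) + 1L]] <-
        data.frame(sample = c(u, i), condition = c("uninduced", "induced"),
                   replicate = paste0("rep", r), stringsAsFactors = FALSE)
    }
    list(
      counts = counts,
      samples = do.call(rbind, samples),
      truth = data.frame(sgRNA_id = sgRNA_id, target = target,
                         gene_effect = effect, e_true = e_true,
                         stringsAsFactors = FALSE)
    )
  })
}
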