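# Pause-site calling and differential pausing between two conditions.

#' Average replicate profiles
#'
#' Per-codon arithmetic mean across replicates, rounded to the nearest
#' integer half-away-from-zero (2.5 -> 3). This integerised averaged profile
#' is the object used both for Z-scoring and for the Fisher contingency
#' tables downstream.
#'
#' @param replicates Numeric matrix (codons x replicates) or a vector for a
#'   single replicate.
#' @return Integer vector, one value per codon.
#' @export
average_profile <- function(replicates) {
  if (is.vector(replicates)) replicates <- matrix(replicates, ncol = 1L)
  as.integer(round_half_up(rowMeans(replicates)))
}

#' Z-score a codon coverage profile
#'
#' Standardises counts over all codons of the transcript using the population
#' standard deviation (divisor n). A zero-variance (uniform) profile has no
#' defined Z-scores and returns an all-`NA` vector as a sentinel: such
#' transcripts carry no pauses.
#'
#' @param counts Numeric vector of per-codon counts (length >= 2).
#' @return Numeric vector of Z-scores, or all-`NA` for a uniform profile.
#' @export
#' @examples
#' zscore_profile(c(1, 1, 1, 1, 16))
zscore_profile <- function(counts) {
  n <- length(counts)
  if (n < 2L) stop("profile must have at least 2 codons")
  m <- mean(counts)
  s <- sqrt(mean((counts - m)^2))
  if (s == 0) return(rep(NA_real_, n))
  (counts - m) / s
}

#' Call pause sites with replicate concordance
#'
#' A codon is a pause site iff its Z-score in the replicate-averaged profile
#' is `>= z_threshold` *and* every replicate has a Z-score `>= z_threshold`
#' at the same codon or at one of the `flank` codons on either side (flanks
#' truncated at CDS boundaries).
#'
#' @param avg Averaged profile (integer vector, from [average_profile()]).
#' @param replicates Matrix (codons x replicates) of per-replicate counts.
#' @param z_threshold Z-score threshold (default 5.0).
#' @param flank Concordance window half-width in codons (default 1).
#' @return Data frame (codon \[0-based\], z_avg, concordant) of retained
#'   sites; the per-replicate Z-score matrix is attached as
#'   `attr(, "z_rep")`.
#' @export
call_pauses <- function(avg, replicates, z_threshold = 5.0, flank = 1L) {
  if (is.vector(replicates)) replicates <- matrix(replicates, ncol = 1L)
  stopifnot(length(avg) == nrow(replicates))
  n <- length(avg)
  empty <- data.frame(codon = integer(), z_avg = numeric(),
                      concordant = logical())
  z_avg <- zscore_profile(avg)
  if (all(is.na(z_avg))) return(empty)
  cand <- which(z_avg >= z_threshold)
  if (!length(cand)) return(empty)

  z_rep <- apply(replicates, 2L, function(x) {
    z <- zscore_profile(x)
    if (all(is.na(z))) rep(-Inf, n) else z  # uniform replicate: no hits
  })
  hit <- z_rep >= z_threshold
  ok <- vapply(cand, function(c) {
    win <- max(1L, c - flank):min(n, c + flank)
    all(apply(hit[win, , drop = FALSE], 2L, any))
  }, logical(1))
  out <- data.frame(codon = cand[ok] - 1L, z_avg = z_avg[cand[ok]],
                    concordant = rep(TRUE, sum(ok)))
  attr(out, "z_rep") <- z_rep
  out
}

#' Pause scores along a profile
#'
#' The pause score of a codon is its footprint count divided by the mean
#' count over the CDS excluding the first five and last five codons (those
#' positions carry initiation/termination occupancy effects). Transcripts
#' with 10 or fewer codons, or with an all-zero interior window, have no
#' defined scores and return all-`NA` (they are skipped for differential
#' testing).
#'
#' @param counts Per-codon counts (averaged profile).
#' @return Numeric vector of pause scores (`NA` where undefined).
#' @export
pause_scores <- function(counts) {
  n <- length(counts)
  if (n <= 10L) return(rep(NA_real_, n))
  denom <- mean(counts[6:(n - 5L)])
  if (denom == 0) return(rep(NA_real_, n))
  counts / denom
}

#' @rdname pause_scores
#' @param codon 0-based codon index.
#' @export
pause_score <- function(counts, codon) {
  if (codon < 0L || codon >= length(counts)) stop("codon out of range")
  pause_scores(counts)[codon + 1L]
}

#' Two-sided Fisher's exact p for 2x2 tables (vectorised)
#'
#' Computes the two-sided exact p-value for tables
#' `[[a, b], [c, d]]` by summing hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table (with the standard 1e-7 relative tolerance for floating
#' ties). Vectorised over table cells; designed for the tens of thousands of
#' per-codon tables a transcriptome-wide comparison produces.
#'
#' @param a,b,c,d Non-negative integer vectors of cell counts.
#' @return Numeric vector of two-sided p-values.
#' @export
#' @examples
#' fisher_test_2x2(3, 7, 0, 10)
fisher_test_2x2 <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  p <- numeric(length(a))
  for (i in seq_along(a)) {
    lo <- max(0L, k[i] - n2[i])
    hi <- min(k[i], m[i])
    supp <- lo:hi
    dens <- dhyper(supp, m[i], n2[i], k[i])
    dobs <- dhyper(a[i], m[i], n2[i], k[i])
    p[i] <- min(1, sum(dens[dens <= dobs * (1 + 1e-7)]))
  }
  p
}

#' Sample (cross-product) odds ratio with continuity correction
#'
#' `(a*d)/(b*c)`; when any cell of a table is zero, 0.5 is added to all four
#' cells of that table before forming the ratio.
#'
#' @inheritParams fisher_test_2x2
#' @return Numeric vector of odds ratios.
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  a <- a + 0.5 * zero
  b <- b + 0.5 * zero
  c <- c + 0.5 * zero
  d <- d + 0.5 * zero
  (a * d) / (b * c)
}

#' Pause sites for one condition across a count set
#'
#' Runs [call_pauses()] on every retained transcript of one condition.
#'
#' @param counts A `codon_counts` object.
#' @param condition Condition name.
#' @param z_threshold,flank See [call_pauses()].
#' @param retained Transcripts to analyse (default: all, i.e. apply
#'   [coverage_filter()] upstream as appropriate).
#' @return Data frame (transcript_id, codon, z_avg, concordant).
#' @export
pause_sites <- function(counts, condition, z_threshold = 5.0, flank = 1L,
                        retained = names(counts$counts)) {
  out <- lapply(retained, function(t) {
    m <- counts$counts[[t]][[condition]]
    ps <- call_pauses(average_profile(m), m, z_threshold, flank)
    if (!nrow(ps)) return(NULL)
    cbind(data.frame(transcript_id = t, stringsAsFactors = FALSE), ps)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(), codon = integer(),
                      z_avg = numeric(), concordant = logical())
  }
  rownames(out) <- NULL
  out
}

#' Differential ribosome pauses between two conditions
#'
#' For every codon of every transcript passing the coverage filter, builds a
#' 2x2 contingency table from the replicate-averaged (integerised) profiles
#' — reads at the codon vs reads at all other codons, test vs control — and
#' computes a two-sided Fisher's exact p, a continuity-corrected sample odds
#' ratio, and a BH-adjusted p across all tested codons. A codon is
#' *differential* when the averaged test profile has `Z >= z_threshold`
#' there, the odds ratio differs from 1, and `p_adj < alpha`; it is
#' classified `increased` when additionally `OR > 1` and the test pause
#' score exceeds the control pause score (`decreased` symmetrically;
#' `unchanged` otherwise). Codons with zero counts in both conditions are
#' uninformative and excluded from testing and from the BH family.
#' Transcripts with <= 10 codons or an undefined pause-score denominator are
#' skipped (recorded in `attr(, "skipped")`).
#'
#' @param counts A `codon_counts` object holding both conditions.
#' @param test,ctrl Names of the test (mutant/treated) and control
#'   conditions.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param z_threshold Z-score gate on the averaged test profile (default 5).
#' @param min_mean Coverage-filter threshold (reads/codon, default 0.5).
#' @param bh_scope `"global"` (one BH family across all tested codons of all
#'   transcripts; default) or `"transcript"` (per-transcript correction).
#' @return Data frame with one row per tested codon: transcript_id, codon,
#'   z_avg, pause_score_test, pause_score_ctrl, odds_ratio, p_raw, p_adj,
#'   differential, class, is_start_site (codon < 5).
#' @export
differential_pauses <- function(counts, test, ctrl, alpha = 0.05,
                                z_threshold = 5.0, min_mean = 0.5,
                                bh_scope = c("global", "transcript")) {
  bh_scope <- match.arg(bh_scope)
  if (!all(c(test, ctrl) %in% counts$conditions)) {
    stop("both conditions must be present in the count set")
  }
  retained <- coverage_filter(counts, conditions = c(test, ctrl),
                              min_mean = min_mean)
  skipped <- character()
  per_tx <- lapply(retained, function(t) {
    avg_t <- average_profile(counts$counts[[t]][[test]])
    avg_c <- average_profile(counts$counts[[t]][[ctrl]])
    ps_t <- pause_scores(avg_t)
    ps_c <- pause_scores(avg_c)
    if (all(is.na(ps_t)) || all(is.na(ps_c))) {
      skipped <<- c(skipped, t)
      return(NULL)
    }
    z <- zscore_profile(avg_t)
    tot_t <- sum(avg_t)
    tot_c <- sum(avg_c)
    keep <- which(avg_t + avg_c > 0L)
    if (!length(keep)) return(NULL)
    data.frame(
      transcript_id = t,
      codon = keep - 1L,
      z_avg = z[keep],
      pause_score_test = ps_t[keep],
      pause_score_ctrl = ps_c[keep],
      a = avg_t[keep], b = tot_t - avg_t[keep],
      c = avg_c[keep], d = tot_c - avg_c[keep],
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, per_tx[!vapply(per_tx, is.null, logical(1))])
  if (is.null(tab) || !nrow(tab)) {
    out <- data.frame(
      transcript_id = character(), codon = integer(), z_avg = numeric(),
      pause_score_test = numeric(), pause_score_ctrl = numeric(),
      odds_ratio = numeric(), p_raw = numeric(), p_adj = numeric(),
      differential = logical(), class = character(), is_start_site = logical(),
      stringsAsFactors = FALSE
    )
    attr(out, "skipped") <- skipped
    return(out)
  }

  tab$odds_ratio <- odds_ratio_2x2(tab$a, tab$b, tab$c, tab$d)
  tab$p_raw <- fisher_test_2x2(tab$a, tab$b, tab$c, tab$d)
  tab$p_adj <- if (bh_scope == "global") {
    p.adjust(tab$p_raw, method = "BH")
  } else {
    stats::ave(tab$p_raw, tab$transcript_id,
               FUN = function(p) p.adjust(p, method = "BH"))
  }

  z_ok <- !is.na(tab$z_avg) & tab$z_avg >= z_threshold
  tab$differential <- z_ok & tab$odds_ratio != 1 & tab$p_adj < alpha
  tab$class <- ifelse(
    tab$differential & tab$odds_ratio > 1 &
      tab$pause_score_test > tab$pause_score_ctrl, "increased",
    ifelse(tab$differential & tab$odds_ratio < 1 &
             tab$pause_score_test < tab$pause_score_ctrl, "decreased",
           "unchanged")
  )
  tab$is_start_site <- tab$codon < 5L
  tab <- tab[, c("transcript_id", "codon", "z_avg", "pause_score_test",
                 "pause_score_ctrl", "odds_ratio", "p_raw", "p_adj",
                 "differential", "class", "is_start_site")]
  rownames(tab) <- NULL
  attr(tab, "skipped") <- skipped
  tab
}

#' Summarise start-site pauses
#'
#' Counts increased differential pauses and the fraction lying within the
#' first five codons of their CDS (codon index < 5), the signature of
#' initiation-proximal pausing.
#'
#' @param pauses Output of [differential_pauses()].
#' @return List: n_increased, n_transcripts (distinct mRNAs carrying an
#'   increased pause), n_start_site, fraction (0 when there are no increased
#'   pauses).
#' @export
summarize_start_site_fraction <- function(pauses) {
  inc <- pauses[pauses$class == "increased", , drop = FALSE]
  n_inc <- nrow(inc)
  list(
    n_increased = n_inc,
    n_transcripts = length(unique(inc$transcript_id)),
    n_start_site = sum(inc$is_start_site),
    fraction = if (n_inc == 0) 0 else sum(inc$is_start_site) / n_inc
  )
}

#' Write pause tables and a JSON run summary
#'
#' @param pauses Output of [differential_pauses()].
#' @param prefix Output prefix; writes `<prefix>.pauses.tsv` and
#'   `<prefix>.summary.json` (counts per class plus the start-site summary).
#' @return Invisibly, the file paths.
#' @export
write_pause_results <- function(pauses, prefix) {
  tsv <- paste0(prefix, ".pauses.tsv")
  js <- paste0(prefix, ".summary.json")
  write.table(pauses, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- c(
    as.list(table(pauses$class)),
    summarize_start_site_fraction(pauses)
  )
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA)
  invisible(c(table = tsv, summary = js))
}
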