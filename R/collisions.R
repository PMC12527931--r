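# Long-footprint (collision) analysis: length x 5'-position densities around
# start/stop codons, collision-class calling, metagene profiles, and P-site
# assignment for 40-70 nt footprints.
#
# Offsets are nt distances of read 5' ends from the anchor: the first
# nucleotide of the start codon, or the first nucleotide of the stop codon.

#' Default collision class rectangles
#'
#' Length x 5'-offset gates defining the three collision footprint classes:
#' scanning-ribosome collisions with an initiating 80S (`start_40S_80S`,
#' 45-62 nt with 5' ends 25-40 nt upstream of the start codon), 80S-80S
#' collisions during early elongation (`start_80S_80S`, ~60 nt with 5' ends
#' around the start codon), and termination disomes (`termination_disome`,
#' ~60 nt with 5' ends ~50 nt upstream of the stop codon).
#'
#' @return Named list of lists with `length` and `d` (offset) ranges plus the
#'   anchor each `d` is measured from.
#' @export
collision_rectangles <- function() {
  list(
    start_40S_80S = list(length = c(45L, 62L), d = c(-40L, -25L), anchor = "start"),
    start_80S_80S = list(length = c(55L, 65L), d = c(-5L, 5L), anchor = "start"),
    termination_disome = list(length = c(55L, 65L), d = c(-55L, -45L), anchor = "stop")
  )
}

# Internal: 5'-end offsets of reads from the start / stop anchor.
anchor_offsets <- function(reads, reference, anchor = c("start", "stop")) {
  anchor <- match.arg(anchor)
  rows <- ref_row(reference, reads$transcript_id)
  a <- if (anchor == "start") rows$cds_start else rows$cds_end_exclusive - 3L
  reads$five_prime_pos - a
}

#' Length x 5'-position density around start or stop codons
#'
#' Bins every admitted read by footprint length and by the offset of its 5'
#' end from the anchor codon. The cell sum equals the number of admitted
#' reads, so the matrix conserves counts exactly (before optional
#' per-million scaling).
#'
#' @param reads Data frame (transcript_id, five_prime_pos, length).
#' @param reference A `ribo_reference`.
#' @param anchor `"start"` or `"stop"` (offset 0 = first nt of that codon).
#' @param window Inclusive nt offset range of 5' ends, default `c(-60, 30)`.
#' @param lengths Inclusive footprint length range, default `c(42, 68)`.
#' @param rpm Scale cells to reads-per-million of the input library size.
#' @return Numeric matrix (rows = lengths, cols = offsets) with
#'   `attr(, "n_reads")` = admitted read count.
#' @export
length_position_density <- function(reads, reference,
                                    anchor = c("start", "stop"),
                                    window = c(-60L, 30L),
                                    lengths = c(42L, 68L),
                                    rpm = FALSE) {
  anchor <- match.arg(anchor)
  stopifnot(window[1] <= window[2], lengths[1] <= lengths[2])
  library_size <- nrow(reads)
  d <- anchor_offsets(reads, reference, anchor)
  keep <- in_range(d, window) & in_range(reads$length, lengths)
  lv <- lengths[1]:lengths[2]
  dv <- window[1]:window[2]
  mat <- table(factor(reads$length[keep], levels = lv),
               factor(d[keep], levels = dv))
  mat <- matrix(as.numeric(mat), nrow = length(lv),
                dimnames = list(length = lv, offset = dv))
  attr(mat, "n_reads") <- sum(keep)
  if (rpm) {
    if (library_size == 0) stop("cannot RPM-scale an empty library")
    mat <- mat * 1e6 / library_size
    attr(mat, "n_reads") <- sum(keep)
  }
  mat
}

#' Classify collision-footprint reads
#'
#' Assigns each read to a collision class by its length and the offset of
#' its 5' end from the start codon (`d_start`) or the first nt of the stop
#' codon (`d_stop`), using the gates of [collision_rectangles()]. Classes are
#' mutually exclusive with precedence
#' `start_40S_80S > start_80S_80S > termination_disome`; everything else is
#' `other`.
#'
#' @param reads Data frame (transcript_id, five_prime_pos, length).
#' @param reference A `ribo_reference`.
#' @param rectangles Class gates, see [collision_rectangles()].
#' @return Character vector of class labels, one per read.
#' @export
classify_collision_read <- function(reads, reference,
                                    rectangles = collision_rectangles()) {
  d_start <- anchor_offsets(reads, reference, "start")
  d_stop <- anchor_offsets(reads, reference, "stop")
  cls <- rep("other", nrow(reads))
  for (name in rev(c("start_40S_80S", "start_80S_80S", "termination_disome"))) {
    r <- rectangles[[name]]
    d <- if (r$anchor == "start") d_start else d_stop
    hit <- in_range(reads$length, r$length) & in_range(d, r$d)
    cls[hit] <- name  # later (higher-precedence) assignments overwrite
  }
  cls
}

#' Metagene occupancy profile around start or stop codons
#'
#' Each transcript's codon occupancy over the window is divided by that
#' transcript's mean CDS occupancy (equal weight per transcript; zero-mean
#' transcripts are skipped), then averaged position-wise across the
#' transcripts that actually span each offset.
#'
#' @param profiles Named list of per-codon count vectors (e.g. averaged
#'   profiles of one condition; see [averaged_profiles()]).
#' @param anchor `"start"` (offset 0 = first codon) or `"stop"` (offset 0 =
#'   stop codon, negative offsets upstream).
#' @param window Inclusive codon-offset range; defaults to `c(0, 50)` for
#'   start and `c(-50, 0)` for stop.
#' @return Data frame (offset, occupancy, n) where `n` is the number of
#'   transcripts contributing at that offset.
#' @export
metagene_profile <- function(profiles, anchor = c("start", "stop"),
                             window = NULL) {
  anchor <- match.arg(anchor)
  if (is.null(window)) {
    window <- if (anchor == "start") c(0L, 50L) else c(-50L, 0L)
  }
  if (window[1] > window[2]) stop("empty metagene window")
  offsets <- window[1]:window[2]
  acc <- numeric(length(offsets))
  n <- integer(length(offsets))
  contributed <- FALSE
  for (counts in profiles) {
    m <- mean(counts)
    if (m == 0) next
    norm <- counts / m
    nc <- length(counts)
    idx <- if (anchor == "start") offsets else (nc - 1L) + offsets
    ok <- idx >= 0L & idx < nc
    acc[ok] <- acc[ok] + norm[idx[ok] + 1L]
    n[ok] <- n[ok] + 1L
    contributed <- contributed || any(ok)
  }
  if (!contributed) stop("no transcript spans the metagene window")
  data.frame(offset = offsets,
             occupancy = ifelse(n > 0, acc / pmax(n, 1L), 0),
             n = n)
}

#' Averaged per-transcript profiles for one condition
#'
#' @param counts A `codon_counts` object.
#' @param condition Condition name.
#' @param transcripts Transcripts to include (default all).
#' @return Named list of integer vectors (replicate-averaged profiles).
#' @export
averaged_profiles <- function(counts, condition,
                              transcripts = names(counts$counts)) {
  stats::setNames(
    lapply(transcripts,
           function(t) average_profile(counts$counts[[t]][[condition]])),
    transcripts
  )
}

#' P-site assignment for long (40-70 nt) footprints
#'
#' Calibrates one P-site offset per read length on reads whose 3' ends fall
#' within the second-to-last codon of a CDS (the last sense codon before the
#' stop): for each length the offset is the mode of (first nt of that codon
#' - read 5' end) over calibrating reads. Lengths with fewer than
#' `min_calibrating` such reads fall back to `length - fallback_from_3p` nt
#' (default anchors the P-site 47 nt upstream of the 3' end). Reads are then
#' annotated with their P-site nucleotide and codon.
#'
#' @param reads Data frame (transcript_id, five_prime_pos, length), already
#'   length-filtered to the admitted range.
#' @param reference A `ribo_reference`.
#' @param length_range Admitted length range, default `c(40, 70)`.
#' @param min_calibrating Minimum calibrating reads per length (default 10).
#' @param fallback_from_3p Fallback distance from the 3' end (default 47).
#' @return `reads` with columns `psite` (nt) and `psite_codon` (0-based, NA
#'   outside CDS); the per-length offset table is in `attr(, "offsets")`.
#' @export
psite_long_reads <- function(reads, reference, length_range = c(40L, 70L),
                             min_calibrating = 10L, fallback_from_3p = 47L) {
  reads <- reads[in_range(reads$length, length_range), , drop = FALSE]
  rows <- ref_row(reference, reads$transcript_id)
  target_first <- rows$cds_end_exclusive - 6L  # first nt, second-to-last codon
  three_prime <- reads$five_prime_pos + reads$length - 1L
  calib <- three_prime >= target_first & three_prime <= target_first + 2L

  offsets <- integer(0)
  for (len in sort(unique(reads$length))) {
    sel <- calib & reads$length == len
    if (sum(sel) >= min_calibrating) {
      off <- target_first[sel] - reads$five_prime_pos[sel]
      tab <- table(off)
      best <- as.integer(names(tab)[tab == max(tab)])
      mode <- min(best)  # ties broken toward the smallest offset
    } else {
      mode <- len - fallback_from_3p
    }
    offsets[as.character(len)] <- mode
  }
  reads$psite <- reads$five_prime_pos + unname(offsets[as.character(reads$length)])
  codon <- floor((reads$psite - rows$cds_start) / 3)
  codon[reads$psite < rows$cds_start |
          reads$psite >= rows$cds_end_exclusive] <- NA_integer_
  reads$psite_codon <- as.integer(codon)
  attr(reads, "offsets") <- offsets
  reads
}

#' Write a density matrix with axis headers
#'
#' @param density Matrix from [length_position_density()].
#' @param path Output TSV path (rows = lengths, columns = 5'-end offsets).
#' @return Invisibly, `path`.
#' @export
write_density <- function(density, path) {
  df <- data.frame(length = rownames(density), as.data.frame(density),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
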