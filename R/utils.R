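# Shared internal helpers.

#' Round half away from zero
#'
#' Rounds to the nearest integer with exact halves moving away from zero
#' (2.5 -> 3), unlike [base::round()]'s round-half-to-even. Replicate-averaged
#' codon counts are integerised with this rule so that tied averages never
#' silently deflate contingency tables.
#'
#' @param x Numeric vector.
#' @return Numeric vector of integers (as doubles).
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5, 2.4))
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Parse a length-class specification
#'
#' Converts a compact string such as `"20-22,29-32"` into a list of inclusive
#' `c(lo, hi)` ranges. Lists of numeric ranges pass through unchanged.
#'
#' @param classes Character scalar (`"lo-hi[,lo-hi...]"`) or list of length-2
#'   numeric vectors.
#' @return List of inclusive `c(lo, hi)` integer ranges.
#' @export
#' @examples
#' parse_length_classes("20-22,29-32")
parse_length_classes <- function(classes) {
  if (is.character(classes)) {
    parts <- strsplit(classes, ",", fixed = TRUE)[[1]]
    classes <- lapply(parts, function(p) {
      lohi <- as.integer(strsplit(trimws(p), "-", fixed = TRUE)[[1]])
      if (length(lohi) == 1L) lohi <- c(lohi, lohi)
      lohi
    })
  }
  if (!is.list(classes)) classes <- list(classes)
  lapply(classes, function(r) {
    r <- as.integer(r)
    if (length(r) != 2L || anyNA(r) || r[1] > r[2]) {
      stop("each length class must be an inclusive c(lo, hi) range")
    }
    r
  })
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive k reproducible sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Normalise nucleotide strings: uppercase, RNA U -> DNA T.
as_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

in_range <- function(x, range) x >= range[1] & x <= range[2]
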