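# Sequence context of pause sites: nucleotide / amino-acid windows around the
# P-site codon, frequency matrices, Kozak-context matching, and the uniform
# 1/20 amino-acid background for CDS-terminal pauses.
#
# Register convention: the pause codon is treated as the ribosomal P-site;
# the A-site is the codon immediately downstream (position P+1). An off-by-one
# here flips AUG-in-P-site enrichment into AUG-in-A-site, so the register is
# fixed package-wide and documented rather than configurable.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Translate a vector of DNA codons via the standard genetic code.
translate_codons <- function(codons) {
  aa <- unname(GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Extract sequence windows around pause sites
#'
#' For each pause, takes a nucleotide window centred on the first nucleotide
#' of the pause (P-site) codon and an amino-acid window of residues
#' P-aa_flank ... P+aa_flank from the translated CDS. Nucleotide positions
#' outside the transcript are masked with `N`; amino-acid positions outside
#' the CDS are masked with `X` (fillable by [terminal_background()] for
#' pauses near CDS ends). Stop codons translate to `*`.
#'
#' @param pauses Data frame with `transcript_id` and `codon` (0-based).
#' @param reference A `ribo_reference`.
#' @param nt_flank Nucleotides of context either side of the P-site first nt
#'   (default 15).
#' @param aa_flank Residues of context either side of the P-site (default 5).
#' @return Data frame (transcript_id, codon, nt_window, aa_window,
#'   is_terminal) where `is_terminal` flags pauses within the first or last
#'   five codons of their CDS.
#' @export
extract_windows <- function(pauses, reference, nt_flank = 15L, aa_flank = 5L) {
  rows <- ref_row(reference, pauses$transcript_id)
  if (any(pauses$codon < 0L | pauses$codon >= rows$n_codons)) {
    stop("pause codon outside CDS")
  }
  seqs <- reference$sequences[pauses$transcript_id]
  n <- nrow(pauses)
  nt_win <- character(n)
  aa_win <- character(n)
  for (i in seq_len(n)) {
    s <- seqs[[i]]
    p0 <- rows$cds_start[i] + 3L * pauses$codon[i]  # first nt of P-site codon
    pos <- (p0 - nt_flank):(p0 + nt_flank)
    chars <- rep("N", length(pos))
    ok <- pos >= 0L & pos < nchar(s)
    chars[ok] <- strsplit(substr(s, min(pos[ok]) + 1L, max(pos[ok]) + 1L), "")[[1]]
    nt_win[i] <- paste(chars, collapse = "")

    cod_idx <- (pauses$codon[i] - aa_flank):(pauses$codon[i] + aa_flank)
    aa <- rep("X", length(cod_idx))
    okc <- cod_idx >= 0L & cod_idx < rows$n_codons[i]
    starts <- rows$cds_start[i] + 3L * cod_idx[okc]
    codons <- substring(s, starts + 1L, starts + 3L)
    aa[okc] <- translate_codons(codons)
    aa_win[i] <- paste(aa, collapse = "")
  }
  data.frame(
    transcript_id = pauses$transcript_id,
    codon = pauses$codon,
    nt_window = nt_win,
    aa_window = aa_win,
    is_terminal = pauses$codon < 5L | pauses$codon >= rows$n_codons - 5L,
    stringsAsFactors = FALSE
  )
}

#' Fill terminal-pause amino-acid masks with a uniform background
#'
#' Replaces masked (`X`) amino-acid positions — those falling outside the CDS
#' for pauses near its ends — with residues drawn i.i.d. uniformly over the
#' 20 standard amino acids (probability 1/20 each), reproducibly under
#' `seed`. Windows without masked positions are returned unchanged.
#'
#' @param windows Data frame from [extract_windows()].
#' @param seed Integer seed.
#' @return `windows` with `aa_window` masks filled.
#' @export
terminal_background <- function(windows, seed = 1L) {
  with_seed(seed, {
    windows$aa_window <- vapply(windows$aa_window, function(w) {
      chars <- strsplit(w, "")[[1]]
      mask <- chars == "X"
      if (any(mask)) {
        chars[mask] <- sample(AA_ALPHABET, sum(mask), replace = TRUE)
      }
      paste(chars, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  windows
}

#' Position frequency matrix of aligned windows
#'
#' Per-position symbol frequencies over contributing (unmasked) symbols,
#' plus per-position information content in bits relative to a uniform
#' background over the alphabet (4 for nucleotides, 20 for amino acids).
#'
#' @param windows Character vector of equal-length windows (or a data frame
#'   from [extract_windows()], in which case `which` selects the window).
#' @param which `"nt"` or `"aa"` when a data frame is supplied.
#' @param mask_char Symbol treated as masked (default: `N` for nt, `X` for
#'   aa).
#' @return Object of class `frequency_matrix`: list with `freq` (position x
#'   symbol probability matrix), `ic` (bits per position), `n_contributing`
#'   (unmasked symbols per position), `n_sequences`, `alphabet_size`.
#' @export
frequency_matrix <- function(windows, which = c("nt", "aa"),
                             mask_char = NULL) {
  which <- match.arg(which)
  if (is.data.frame(windows)) {
    windows <- windows[[paste0(which, "_window")]]
  }
  if (!length(windows)) stop("at least one window required")
  lens <- nchar(windows)
  if (length(unique(lens)) != 1L) stop("windows have inconsistent lengths")
  if (is.null(mask_char)) mask_char <- if (which == "nt") "N" else "X"
  K <- if (which == "nt") 4L else 20L

  chars <- do.call(rbind, strsplit(windows, ""))
  symbols <- sort(setdiff(unique(as.vector(chars)), mask_char))
  L <- ncol(chars)
  freq <- matrix(0, nrow = L, ncol = length(symbols),
                 dimnames = list(position = seq_len(L) - 1L, symbol = symbols))
  n_contrib <- integer(L)
  ic <- numeric(L)
  for (j in seq_len(L)) {
    col <- chars[, j]
    col <- col[col != mask_char]
    n_contrib[j] <- length(col)
    if (!length(col)) next
    p <- table(factor(col, levels = symbols)) / length(col)
    freq[j, ] <- as.numeric(p)
    nz <- p[p > 0]
    ic[j] <- log2(K) + sum(nz * log2(nz))
  }
  structure(
    list(freq = freq, ic = ic, n_contributing = n_contrib,
         n_sequences = length(windows), alphabet_size = K),
    class = "frequency_matrix"
  )
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat("frequency_matrix:", nrow(x$freq), "positions x", ncol(x$freq),
      "symbols over", x$n_sequences, "sequences\n")
  cat("  information content (bits):",
      paste(sprintf("%.2f", x$ic), collapse = " "), "\n")
  invisible(x)
}

#' Kozak-context match at the start codon
#'
#' Tests whether the context around each annotated start codon matches the
#' Kozak-like consensus RCCAUGG (R = A/G), i.e. transcript positions
#' cds_start-3 ... cds_start+3 match `[AG]CCATGG` on the DNA alphabet.
#' Transcripts with fewer than 3 nt of 5'UTR (or a CDS too short to provide
#' the +4 position) cannot match.
#'
#' @param reference A `ribo_reference`.
#' @return Named logical vector, one entry per transcript.
#' @export
kozak_match <- function(reference) {
  tx <- reference$transcripts
  out <- vapply(seq_len(nrow(tx)), function(i) {
    s <- reference$sequences[[tx$transcript_id[i]]]
    cs <- tx$cds_start[i]
    if (cs < 3L || cs + 4L > nchar(s)) return(FALSE)
    win <- substr(s, cs - 2L, cs + 4L)  # 0-based cds_start-3 .. cds_start+3
    grepl("^[AG]CCATGG$", win)
  }, logical(1))
  stats::setNames(out, tx$transcript_id)
}

#' Write a frequency matrix in MEME minimal motif format
#'
#' @param fm A `frequency_matrix`.
#' @param path Output path.
#' @param name Motif name.
#' @return Invisibly, `path`.
#' @export
write_meme <- function(fm, path, name = "pause_context") {
  lines <- c(
    "MEME version 4", "",
    paste0("ALPHABET= ", paste(colnames(fm$freq), collapse = "")), "",
    paste0("MOTIF ", name),
    sprintf("letter-probability matrix: alength= %d w= %d nsites= %d",
            ncol(fm$freq), nrow(fm$freq), fm$n_sequences),
    apply(fm$freq, 1L, function(r) paste(sprintf("%.6f", r), collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Export pause windows as FASTA
#'
#' @param windows Data frame from [extract_windows()].
#' @param path Output FASTA path.
#' @param which `"nt"` or `"aa"` windows.
#' @return Invisibly, `path`.
#' @export
write_windows_fasta <- function(windows, path, which = c("nt", "aa")) {
  which <- match.arg(which)
  ids <- paste0(windows$transcript_id, "_codon", windows$codon)
  writeLines(
    as.vector(rbind(paste0(">", ids), windows[[paste0(which, "_window")]])),
    path
  )
  invisible(path)
}
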