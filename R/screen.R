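# Gene-level scoring of inducible CRISPRi screens from sgRNA count tables.
#
# Counts tables have one row per sgRNA (sgRNA_id, target) and one column per
# sequenced sample; the sample sheet maps samples to condition
# ("induced"/"uninduced") and replicate. Non-targeting controls carry
# target == "NTC" and provide the null distribution for all statistics.

NTC_LABEL <- "NTC"

#' Filter and normalise a screen count table
#'
#' Per replicate, pairs the induced and uninduced samples and (1) drops
#' sgRNAs with fewer than `min_reads` raw reads in either compared sample,
#' (2) replaces remaining zero counts with a pseudocount of 1 (zeros only;
#' non-zero counts are untouched), then (3) scales each sample to
#' reads-per-million over the surviving sgRNAs.
#'
#' @param counts Data frame with `sgRNA_id`, `target` and one column per
#'   sample.
#' @param samples Data frame with `sample`, `condition`
#'   (`"induced"`/`"uninduced"`) and `replicate`.
#' @param min_reads Minimum raw reads in each compared sample (default 50).
#' @return Long data frame (sgRNA_id, target, replicate, rpm_induced,
#'   rpm_uninduced), one row per surviving sgRNA per replicate.
#' @export
filter_and_normalize <- function(counts, samples, min_reads = 50L) {
  stopifnot(all(c("sgRNA_id", "target") %in% names(counts)))
  if (!any(counts$target == NTC_LABEL)) {
    stop("count table contains no non-targeting controls")
  }
  reps <- unique(samples$replicate)
  out <- lapply(reps, function(r) {
    ind <- samples$sample[samples$replicate == r & samples$condition == "induced"]
    uni <- samples$sample[samples$replicate == r & samples$condition == "uninduced"]
    if (length(ind) != 1L || length(uni) != 1L) {
      stop("replicate ", r, " must have exactly one induced and one uninduced sample")
    }
    ci <- counts[[ind]]
    cu <- counts[[uni]]
    if (is.null(ci) || is.null(cu)) stop("sample column missing from count table")
    if (sum(ci) == 0 || sum(cu) == 0) stop("sample with zero total counts")
    keep <- ci >= min_reads & cu >= min_reads
    ci <- ci[keep]
    cu <- cu[keep]
    ci[ci == 0] <- 1
    cu[cu == 0] <- 1
    data.frame(
      sgRNA_id = counts$sgRNA_id[keep],
      target = counts$target[keep],
      replicate = r,
      rpm_induced = 1e6 * ci / sum(ci),
      rpm_uninduced = 1e6 * cu / sum(cu),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (!any(out$target == NTC_LABEL)) stop("no non-targeting control survived filtering")
  rownames(out) <- NULL
  out
}

#' Per-sgRNA log2 enrichment, NTC-median centred
#'
#' `e = log2(RPM_induced / RPM_uninduced)` minus the median of the same
#' quantity over non-targeting controls of the same replicate, so the NTC
#' median of centred enrichments is 0 by construction.
#'
#' @param normalized Output of [filter_and_normalize()].
#' @return The input with an added `e` column.
#' @export
sgrna_enrichment <- function(normalized) {
  e_raw <- log2(normalized$rpm_induced / normalized$rpm_uninduced)
  out <- lapply(split(seq_len(nrow(normalized)), normalized$replicate),
                function(idx) {
    ntc <- normalized$target[idx] == NTC_LABEL
    if (!any(ntc)) stop("no surviving NTC in a replicate")
    cbind(normalized[idx, , drop = FALSE],
          e = e_raw[idx] - median(e_raw[idx][ntc]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Score one gene TSS
#'
#' Phenotype = mean enrichment of the (up to) three sgRNAs with the largest
#' absolute enrichment; significance = two-sided Mann-Whitney comparing all
#' surviving sgRNAs of the gene against all non-targeting controls
#' (exact for small untied samples, normal approximation with tie/continuity
#' correction otherwise, as in [stats::wilcox.test()]).
#'
#' @param e_gene Enrichments of the gene's surviving sgRNAs (>= 1).
#' @param e_ntc Enrichments of the NTC sgRNAs (>= 2).
#' @return List: phenotype, p, n_sgrnas_used.
#' @export
gene_score <- function(e_gene, e_ntc) {
  if (!length(e_gene)) stop("gene has no surviving sgRNAs")
  if (length(e_ntc) < 2L) stop("need at least 2 NTC enrichments")
  top <- head(e_gene[order(-abs(e_gene))], 3L)
  p <- suppressWarnings(
    wilcox.test(e_gene, e_ntc, alternative = "two.sided")$p.value
  )
  list(phenotype = mean(top), p = p, n_sgrnas_used = length(e_gene))
}

#' Gene-level scores for a whole screen
#'
#' Averages each sgRNA's enrichment across the replicates in which it
#' survived, then scores every targeted gene TSS with [gene_score()]
#' against the replicate-averaged NTC enrichments.
#'
#' @param enrichment Output of [sgrna_enrichment()].
#' @return Data frame (target, phenotype, p, n_sgrnas).
#' @export
screen_gene_scores <- function(enrichment) {
  by_sg <- split(enrichment$e, enrichment$sgRNA_id)
  e_mean <- vapply(by_sg, mean, numeric(1))
  target <- enrichment$target[match(names(by_sg), enrichment$sgRNA_id)]
  ntc_e <- e_mean[target == NTC_LABEL]
  genes <- setdiff(unique(target), NTC_LABEL)
  out <- do.call(rbind, lapply(genes, function(g) {
    gs <- gene_score(unname(e_mean[target == g]), unname(ntc_e))
    data.frame(target = g, phenotype = gs$phenotype, p = gs$p,
               n_sgrnas = gs$n_sgrnas_used, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Collapse alternative-TSS scores to one record per gene
#'
#' Genes screened at two alternative transcription start sites are collapsed
#' by keeping, among TSS records with Mann-Whitney `p <= alpha`, the one
#' with the strongest phenotype magnitude; when no record reaches `p <=
#' alpha` the strongest-magnitude record is reported and the gene is flagged
#' non-essential. `essential = (chosen p <= alpha)`.
#'
#' @param scores Data frame from [screen_gene_scores()].
#' @param gene Character vector mapping each row of `scores` to a gene
#'   (defaults to the target with any trailing `_TSS<k>` suffix removed).
#' @param alpha Significance threshold (default 0.1).
#' @return Data frame (gene, target, phenotype, p, essential).
#' @export
collapse_tss <- function(scores, gene = NULL, alpha = 0.1) {
  if (is.null(gene)) gene <- sub("_TSS\\d+$", "", scores$target)
  out <- do.call(rbind, lapply(split(seq_len(nrow(scores)), gene),
                               function(idx) {
    d <- scores[idx, , drop = FALSE]
    sig <- d$p <= alpha
    pool <- if (any(sig)) d[sig, , drop = FALSE] else d
    pick <- pool[which.max(abs(pool$phenotype)), , drop = FALSE]
    data.frame(gene = gene[idx][1], target = pick$target,
               phenotype = pick$phenotype, p = pick$p,
               essential = pick$p <= alpha, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Full screen-scoring pipeline
#'
#' [filter_and_normalize()] -> [sgrna_enrichment()] ->
#' [screen_gene_scores()] -> [collapse_tss()].
#'
#' @inheritParams filter_and_normalize
#' @param alpha Mann-Whitney threshold for essentiality (default 0.1).
#' @return List with `sgrna` (per-sgRNA enrichments), `tss` (per-TSS
#'   scores) and `genes` (collapsed gene calls).
#' @export
screen_score <- function(counts, samples, min_reads = 50L, alpha = 0.1) {
  norm <- filter_and_normalize(counts, samples, min_reads)
  enr <- sgrna_enrichment(norm)
  tss <- screen_gene_scores(enr)
  list(sgrna = enr, tss = tss, genes = collapse_tss(tss, alpha = alpha))
}
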