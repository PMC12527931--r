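test_that("length-class filtering retains exactly the admitted lengths", {
  reads <- data.frame(transcript_id = "tx1", five_prime_pos = 0L,
                      length = c(19L, 20L, 22L, 25L, 29L, 32L, 33L))
  expect_equal(filter_reads_by_length(reads, "20-22,29-32")$length,
               c(20L, 22L, 29L, 32L))
  expect_equal(nrow(filter_reads_by_length(reads[0, ], "20-22")), 0L)
  long <- data.frame(transcript_id = "tx1", five_prime_pos = 0L,
                     length = c(39L, 40L, 70L, 71L))
  expect_equal(filter_reads_by_length(long, list(c(40, 70)))$length,
               c(40L, 70L))
})

test_that("A-site assignment arithmetic and out-of-CDS sentinel", {
  ref <- toy_reference()  # tx1: cds_start 60; tx2: cds_start 0
  offs <- default_offsets()
  reads <- data.frame(
    transcript_id = c("tx1", "tx1", "tx2"),
    five_prime_pos = c(60L, 30L, 0L),
    length = c(30L, 21L, 30L)
  )
  out <- assign_a_site(reads, ref, offs)
  expect_equal(out$a_site, c(75L, 45L, 15L))
  expect_equal(out$codon, c(5L, NA_integer_, 5L))
  expect_error(assign_a_site(data.frame(transcript_id = "tx1",
                                        five_prime_pos = 0L, length = 27L),
                             ref, offs),
               "27")
})

test_that("codon matrices tabulate A-site reads and conserve counts", {
  ref <- toy_reference()
  # 3 reads all landing on codon 7 of tx1 (A-site nt = 60 + 21..23)
  reads <- data.frame(
    transcript_id = "tx1",
    five_prime_pos = c(66L, 67L, 68L),
    length = 30L
  )
  cc <- build_codon_matrix(reads, ref)
  m <- cc$counts[["tx1"]][["sample"]]
  expect_equal(unname(m[8, "rep1"]), 3L)
  expect_equal(sum(m), 3L)
  expect_equal(sum(cc$counts[["tx2"]][["sample"]]), 0L)

  # conservation: in-CDS + outside = admitted, per sample, on random reads
  set.seed(71)
  n <- 500
  rnd <- data.frame(
    transcript_id = sample(c("tx1", "tx2", "tx3"), n, replace = TRUE),
    five_prime_pos = sample(0:80, n, replace = TRUE),
    length = sample(c(19:23, 29:33), n, replace = TRUE),
    condition = sample(c("a", "b"), n, replace = TRUE),
    replicate = sample(c("rep1", "rep2"), n, replace = TRUE)
  )
  tlen <- nchar(ref$sequences)[rnd$transcript_id]
  rnd <- rnd[rnd$five_prime_pos + rnd$length <= tlen, ]
  cc2 <- build_codon_matrix(rnd, ref)
  log <- attr(cc2, "outside")
  admitted <- filter_reads_by_length(rnd, "20-22,29-32")
  for (i in seq_len(nrow(log))) {
    sel <- admitted$condition == log$condition[i] &
      admitted$replicate == log$replicate[i]
    expect_equal(log$n_admitted[i], sum(sel))
    in_cds <- sum(vapply(names(cc2$counts), function(t) {
      sum(cc2$counts[[t]][[log$condition[i]]][, log$replicate[i]])
    }, numeric(1)))
    expect_equal(in_cds, log$n_in_cds[i])
    expect_equal(log$n_in_cds[i] + log$n_outside[i], log$n_admitted[i])
  }
  expect_error(build_codon_matrix(data.frame(transcript_id = "nope",
                                             five_prime_pos = 0L, length = 30L),
                                  ref),
               "unknown transcript")
})

test_that("A-site assignment is equivariant under +3k frame-preserving shifts", {
  k <- 4L
  base_seq <- make_tx(strrep("A", 30), filler_cds(25), strrep("C", 20))
  ref1 <- ribo_reference(
    data.frame(transcript_id = "t", gene_id = "g", cds_start = 30L,
               cds_end_exclusive = 105L),
    c(t = base_seq)
  )
  ref2 <- ribo_reference(
    data.frame(transcript_id = "t", gene_id = "g", cds_start = 30L + 3L * k,
               cds_end_exclusive = 105L + 3L * k),
    c(t = paste0(strrep("G", 3L * k), base_seq))
  )
  reads <- data.frame(transcript_id = "t",
                      five_prime_pos = seq(20L, 60L, by = 1L), length = 30L)
  shifted <- transform(reads, five_prime_pos = five_prime_pos + 3L * k)
  expect_equal(assign_a_site(reads, ref1)$codon,
               assign_a_site(shifted, ref2)$codon)
})

test_that("coverage filter is inclusive at the boundary and monotone", {
  nc <- 100L
  mk <- function(sums) {
    # two conditions x two replicates with the given per-replicate totals
    counts <- list(t1 = list(
      condA = cbind(rep1 = c(sums[1], rep(0L, nc - 1L)),
                    rep2 = c(sums[2], rep(0L, nc - 1L))),
      condB = cbind(rep1 = c(sums[3], rep(0L, nc - 1L)),
                    rep2 = c(sums[4], rep(0L, nc - 1L)))
    ))
    structure(list(counts = counts, conditions = c("condA", "condB"),
                   replicates = c("rep1", "rep2"),
                   n_codons = c(t1 = nc)),
              class = "codon_counts")
  }
  expect_equal(coverage_filter(mk(c(60L, 55L, 70L, 49L))), character(0))
  expect_equal(coverage_filter(mk(c(50L, 50L, 50L, 50L))), "t1")
  # monotone: adding reads never removes a transcript
  expect_equal(coverage_filter(mk(c(50L, 50L, 50L, 51L))), "t1")
  empty <- structure(list(counts = list(), conditions = "condA",
                          replicates = "rep1", n_codons = numeric()),
                     class = "codon_counts")
  expect_equal(coverage_filter(empty, conditions = "condA"),
               character(0))
})

test_that("read tables and transcript-space BAM round through the readers", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "reads.tsv")
  reads <- data.frame(transcript_id = c("tx1", "tx2"),
                      five_prime_pos = c(5L, 7L), length = c(30L, 21L))
  write.table(reads, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_footprint_table(tsv), reads)
  expect_error(read_footprint_table({
    bad <- file.path(dir, "bad.tsv")
    write.table(data.frame(x = 1), bad, sep = "\t", row.names = FALSE)
    bad
  }), "missing column")

  skip_if_not_installed("Rsamtools")
  sam <- file.path(dir, "reads.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:tx1\tLN:150",
    paste0("r1\t0\ttx1\t6\t255\t30M\t*\t0\t0\t", strrep("A", 30), "\t*"),
    paste0("r2\t0\ttx1\t8\t255\t21M\t*\t0\t0\t", strrep("A", 21), "\t*")
  ), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE)
  got <- read_footprint_bam(bam)
  expect_equal(got$five_prime_pos, c(5L, 7L))
  expect_equal(got$length, c(30L, 21L))
  expect_equal(got$transcript_id, c("tx1", "tx1"))
})
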