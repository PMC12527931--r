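test_that("replicate averaging rounds half away from zero", {
  expect_equal(average_profile(cbind(c(2, 4), c(3, 4))), c(3L, 4L))
  expect_equal(average_profile(c(7, 0, 2)), c(7L, 0L, 2L))  # single replicate
  expect_equal(average_profile(cbind(c(1, 0), c(2, 1))), c(2L, 1L))
  expect_error(round_half_up("x"))
})

test_that("Z-scores use the population sd and flag uniform profiles", {
  z <- zscore_profile(c(1, 1, 1, 1, 16))
  expect_equal(z[5], 2.0)  # mean 4, population sd 6
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_true(all(is.na(zscore_profile(rep(3, 10)))))  # uniform sentinel
  x <- c(0, 5, 1, 9, 2, 2)
  expect_equal(zscore_profile(7 * x), zscore_profile(x))  # scale invariance
  expect_error(zscore_profile(3), "at least 2")
})

test_that("pause calling requires averaged-profile and per-replicate concordance", {
  n <- 201L
  base <- rep(1, n)
  spike <- function(at, height = 60) {
    x <- base
    x[at + 1L] <- height
    x
  }
  # replicate peaks at the same codon or one flank away: retained (both the
  # averaged-profile peaks at 100 and 101 satisfy the +-1 concordance rule)
  reps <- cbind(spike(100), spike(101))
  avg <- average_profile(reps)
  got <- call_pauses(avg, reps)
  expect_true(100L %in% got$codon)
  expect_true(all(got$codon %in% c(100L, 101L)))
  expect_true(all(got$concordant))
  # one replicate peaking 3 codons away: dropped
  reps2 <- cbind(spike(100), spike(103))
  got2 <- call_pauses(average_profile(reps2), reps2)
  expect_false(100L %in% got2$codon)
  # nothing above threshold: empty
  flat <- cbind(base + c(1, rep(0, n - 1L)), base)
  expect_equal(nrow(call_pauses(average_profile(flat), flat)), 0L)
  # uniform averaged profile: sentinel, no pauses
  uni <- cbind(rep(2, n), rep(2, n))
  expect_equal(nrow(call_pauses(average_profile(uni), uni)), 0L)
})

test_that("pause score uses the interior-CDS mean and flags degenerate cases", {
  counts <- c(3, 10, rep(0, 3), rep(2, 10), rep(0, 5))  # 20 codons, middle mean 2
  expect_equal(pause_score(counts, 1L), 5.0)
  expect_equal(pause_score(counts, 10L), 1.0)
  zeros <- c(rep(9, 5), rep(0, 10), rep(9, 5))
  expect_true(is.na(pause_score(zeros, 2L)))  # all-zero interior window
  expect_true(all(is.na(pause_scores(rep(1, 10)))))  # too short
  expect_error(pause_score(counts, 20L), "out of range")
})

test_that("vectorised Fisher p agrees with stats::fisher.test and enumeration", {
  expect_equal(fisher_test_2x2(3, 7, 0, 10), 4 / 19, tolerance = 1e-12)
  expect_equal(fisher_test_2x2(3, 7, 0, 10), oracle_fisher_p(3, 7, 0, 10),
               tolerance = 1e-12)
  set.seed(5)
  tabs <- matrix(rpois(400, 8), ncol = 4)
  p_pkg <- fisher_test_2x2(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4])
  p_ref <- apply(tabs, 1L, function(t) {
    stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value
  })
  expect_equal(p_pkg, p_ref, tolerance = 1e-8)
})

test_that("sample odds ratio uses the cross product with 0.5 zero-cell correction", {
  expect_equal(odds_ratio_2x2(5, 95, 1, 99), 495 / 95)
  expect_equal(odds_ratio_2x2(3, 7, 0, 10), (3.5 * 10.5) / (7.5 * 0.5))
  expect_equal(odds_ratio_2x2(c(2, 0), c(2, 1), c(1, 1), c(4, 1)),
               c(8 / 2, (0.5 * 1.5) / (1.5 * 1.5)))
})

test_that("identical conditions yield no differential pauses", {
  ref <- simulate_reference(10, cds_codons = c(60, 100), seed = 3L)
  cc <- simulate_codon_counts(ref, coverage = 3, seed = 8L)
  # duplicate one condition so test == ctrl exactly
  for (t in names(cc$counts)) cc$counts[[t]][["ctrl"]] <- cc$counts[[t]][["test"]]
  dp <- differential_pauses(cc, "test", "ctrl")
  expect_true(all(dp$odds_ratio == 1))
  expect_false(any(dp$differential))
  expect_true(all(dp$class == "unchanged"))
})

test_that("swapping conditions inverts odds ratios and mirrors classes", {
  ref <- simulate_reference(12, cds_codons = c(80, 120), seed = 21L)
  pauses <- data.frame(
    transcript_id = ref$transcripts$transcript_id[1:6],
    codon = c(10L, 20L, 30L, 40L, 50L, 60L),
    fold = 20, condition = rep(c("test", "ctrl"), 3)
  )
  cc <- simulate_codon_counts(ref, coverage = 3, pauses = pauses, seed = 9L)
  fwd <- differential_pauses(cc, "test", "ctrl")
  rev <- differential_pauses(cc, "ctrl", "test")
  key <- function(d) paste(d$transcript_id, d$codon)
  shared <- intersect(key(fwd), key(rev))
  f <- fwd[match(shared, key(fwd)), ]
  r <- rev[match(shared, key(rev)), ]
  expect_equal(f$odds_ratio, 1 / r$odds_ratio, tolerance = 1e-12)
  expect_equal(f$p_raw, r$p_raw, tolerance = 1e-12)
  # increased pauses whose reverse-direction z gate also fires become decreased
  inc <- f$class == "increased" & !is.na(r$z_avg) & r$z_avg >= 5
  expect_true(all(r$class[inc] == "decreased"))
})

test_that("injected condition-specific pauses are recovered as increased", {
  ref <- simulate_reference(20, cds_codons = c(250, 350), seed = 31L)
  pauses <- data.frame(
    transcript_id = ref$transcripts$transcript_id[1:10],
    codon = seq(10L, 100L, by = 10L),
    fold = 20, condition = "test"
  )
  cc <- simulate_codon_counts(ref, coverage = 2, pauses = pauses, seed = 32L)
  dp <- differential_pauses(cc, "test", "ctrl")
  hits <- merge(pauses, dp[dp$class == "increased", ],
                by = c("transcript_id", "codon"))
  expect_gte(nrow(hits), 9L)
  # BH adjustment matches the naive step-up oracle on the package's own p's
  expect_equal(dp$p_adj, oracle_bh(dp$p_raw), tolerance = 1e-12)
  # BH monotonicity: p_adj in [p_raw, 1], non-decreasing in p_raw rank
  expect_true(all(dp$p_adj >= dp$p_raw - 1e-15 & dp$p_adj <= 1))
  ord <- order(dp$p_raw)
  expect_true(all(diff(dp$p_adj[ord]) >= -1e-12))
})

test_that("start-site fraction summarises increased pauses", {
  dp <- data.frame(
    transcript_id = paste0("t", 1:10),
    codon = c(0:5, 40L, 50L, 2L, 3L),
    class = c(rep("increased", 10)),
    is_start_site = c(0:5, 40L, 50L, 2L, 3L) < 5L
  )
  dp$class[5] <- "unchanged"
  dp$class[6] <- "decreased"
  s <- summarize_start_site_fraction(dp)
  expect_equal(s$n_increased, 8L)
  expect_equal(s$n_start_site, 6L)
  expect_equal(s$fraction, 0.75)
  none <- summarize_start_site_fraction(dp[dp$class == "missing", ])
  expect_equal(none, list(n_increased = 0L, n_transcripts = 0L,
                          n_start_site = 0L, fraction = 0))
})

test_that("pause tables and JSON summaries are written", {
  ref <- simulate_reference(6, cds_codons = c(60, 80), seed = 41L)
  pauses <- data.frame(transcript_id = ref$transcripts$transcript_id[1],
                       codon = 1L, fold = 25, condition = "test")
  cc <- simulate_codon_counts(ref, coverage = 3, pauses = pauses, seed = 42L)
  dp <- differential_pauses(cc, "test", "ctrl")
  prefix <- file.path(withr::local_tempdir(), "run")
  paths <- write_pause_results(dp, prefix)
  tab <- read.delim(paths[["table"]])
  expect_equal(nrow(tab), nrow(dp))
  js <- jsonlite::read_json(paths[["summary"]])
  expect_equal(js$n_increased, sum(dp$class == "increased"))
})
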