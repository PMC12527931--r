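# In-code fixtures shared across test files.

# Assemble a transcript sequence from UTRs and a codon vector.
make_tx <- function(u5 = "", codons = c("ATG", "GGC", "TAA"), u3 = "") {
  paste0(u5, paste(codons, collapse = ""), u3)
}

# A valid CDS of n codons (start + glycine filler + stop).
filler_cds <- function(n_codons, stop = "TAA") {
  c("ATG", rep("GGC", n_codons - 2L), stop)
}

# Tiny 3-transcript reference with known coordinates, for quantification and
# window tests. tx1: 60-nt 5'UTR, 20 codons; tx2: no 5'UTR, 30 codons;
# tx3: 12-nt 5'UTR, 15 codons.
toy_reference <- function() {
  seqs <- c(
    tx1 = make_tx(strrep("A", 60), filler_cds(20), strrep("C", 30)),
    tx2 = make_tx("", filler_cds(30), strrep("C", 20)),
    tx3 = make_tx(strrep("G", 12), filler_cds(15), strrep("C", 15))
  )
  ribo_reference(
    data.frame(
      transcript_id = c("tx1", "tx2", "tx3"),
      gene_id = c("g1", "g2", "g3"),
      cds_start = c(60L, 0L, 12L),
      cds_end_exclusive = c(60L + 60L, 90L, 12L + 45L),
      stringsAsFactors = FALSE
    ),
    seqs
  )
}

# Hand-built 12-gene candidate fixture covering the selection and validity
# rules: MANE present/absent, APPRIS rank ties, equal-length ties, rank
# precedence over length, bad stop, non-periodic CDS, ambiguous base,
# exclusion list, selenocysteine-like internal TGA.
reference_fixture <- function() {
  cand <- function(gene, tx, mane, rank, cds_start, cds_end) {
    data.frame(gene_id = gene, transcript_id = tx, is_mane = mane,
               appris_rank = rank, cds_start = cds_start,
               cds_end_exclusive = cds_end, stringsAsFactors = FALSE)
  }
  seqs <- character()
  rows <- list()
  add <- function(gene, tx, mane, rank, seq, cds_start, cds_end) {
    seqs[[tx]] <<- seq
    rows[[length(rows) + 1L]] <<- cand(gene, tx, mane, rank, cds_start, cds_end)
  }

  # geneA: MANE among three candidates wins regardless of rank/length
  add("geneA", "A1", FALSE, 1L, make_tx("AA", filler_cds(12), strrep("T", 40)), 2L, 38L)
  add("geneA", "A2", TRUE, 2L, make_tx("AAA", filler_cds(10), "TT"), 3L, 33L)
  add("geneA", "A3", FALSE, 1L, make_tx("A", filler_cds(11), strrep("T", 60)), 1L, 34L)
  # geneB: no MANE, two rank-1 candidates of lengths 150 vs 180 -> longer
  add("geneB", "B1", FALSE, 1L, make_tx(strrep("A", 21), filler_cds(40), strrep("T", 9)), 21L, 141L)
  add("geneB", "B2", FALSE, 1L, make_tx(strrep("A", 30), filler_cds(48), strrep("T", 6)), 30L, 174L)
  add("geneB", "B3", FALSE, 2L, make_tx(strrep("A", 30), filler_cds(60), strrep("T", 30)), 30L, 210L)
  # geneC: no MANE, two rank-1 candidates of equal length -> seeded choice
  add("geneC", "C1", FALSE, 1L, make_tx(strrep("A", 10), filler_cds(20), strrep("T", 10)), 10L, 70L)
  add("geneC", "C2", FALSE, 1L, make_tx(strrep("G", 10), filler_cds(20), strrep("C", 10)), 10L, 70L)
  # geneD: MANE transcript has no stop codon -> gene dropped, runner-up NOT used
  add("geneD", "D1", TRUE, 1L, make_tx("AA", c("ATG", "GGC", "AAA"), "TT"), 2L, 11L)
  add("geneD", "D2", FALSE, 1L, make_tx("AA", filler_cds(10), "TT"), 2L, 32L)
  # geneE: selected CDS not divisible by 3 -> dropped
  add("geneE", "E1", TRUE, 1L, make_tx("A", c("ATG", "GGC", "TA"), "TT"), 1L, 9L)
  # geneF: ambiguous base in ORF -> dropped
  add("geneF", "F1", TRUE, 1L, make_tx("AA", c("ATG", "GNC", "TAA"), "TT"), 2L, 11L)
  # geneG: no MANE, no APPRIS ranks -> longest
  add("geneG", "G1", FALSE, NA, make_tx("A", filler_cds(10), "T"), 1L, 31L)
  add("geneG", "G2", FALSE, NA, make_tx(strrep("A", 6), filler_cds(12), strrep("T", 6)), 6L, 42L)
  # geneH: single candidate
  add("geneH", "H1", FALSE, 3L, make_tx("AAA", filler_cds(8), "TTT"), 3L, 27L)
  # geneI: MANE beats a better APPRIS rank elsewhere
  add("geneI", "I1", FALSE, 1L, make_tx(strrep("A", 9), filler_cds(30), strrep("T", 9)), 9L, 99L)
  add("geneI", "I2", TRUE, 5L, make_tx("AAA", filler_cds(9), "TTT"), 3L, 30L)
  # geneJ: unique best rank wins even though a worse-rank isoform is longer
  add("geneJ", "J1", FALSE, 1L, make_tx("AA", filler_cds(10), "TT"), 2L, 32L)
  add("geneJ", "J2", FALSE, 2L, make_tx(strrep("A", 30), filler_cds(40), strrep("T", 30)), 30L, 150L)
  # geneK: valid but on the exclusion list
  add("geneK", "K1", TRUE, 1L, make_tx("AA", filler_cds(10), "TT"), 2L, 32L)
  # geneL: internal TGA (selenocysteine-like) retained
  add("geneL", "L1", TRUE, 1L, make_tx("AA", c("ATG", "TGA", "GGC", "TAA"), "TT"), 2L, 14L)

  list(
    candidates = do.call(rbind, rows),
    sequences = seqs,
    exclude = "geneK",
    expected_selected = c(geneA = "A2", geneB = "B2", geneG = "G2",
                          geneH = "H1", geneI = "I2", geneJ = "J1",
                          geneL = "L1"),
    expected_dropped = c(geneD = "bad_stop", geneE = "not_periodic",
                         geneF = "ambiguous_base"),
    tie_gene = "geneC",
    tie_candidates = c("C1", "C2")
  )
}
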