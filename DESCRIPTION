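Package: ribopause
Title: Ribosome Pause-Site Detection, Collision Footprints and CRISPRi Screen Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for codon-resolution analysis of ribosome-profiling
    data: curation of a one-transcript-per-gene protein-coding reference,
    A-site assignment of monosome footprints into codon-level count matrices,
    Z-score pause-site calling with replicate concordance, Fisher's-exact
    differential pausing between conditions with Benjamini-Hochberg
    correction, long-footprint (disome/collision) classification around start
    and stop codons, pause sequence-context motif analysis, and gene-level
    scoring of inducible CRISPRi screens from sgRNA count tables. Includes
    seed-deterministic synthetic-data generators emitting ground truth for
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    Rsamtools,
    withr
Config/testthat/edition: 3
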