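---
title: "Methods: codon-level pause detection, collision footprints and screen scoring"
author: "ribopause"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-level pause detection, collision footprints and screen scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribopause)
```

# Overview

`ribopause` implements a codon-resolution analysis chain for ribosome
profiling together with a gene-scoring recipe for inducible CRISPRi screens:

1. **Reference curation** — one principal protein-coding transcript per gene,
   selected by MANE > APPRIS rank > length > seeded random tie-break, then
   filtered for CDS validity.
2. **Footprint quantification** — admitted monosome footprints (20–22 nt
   vacant-A-site and 29–32 nt occupied-A-site classes) are converted to
   per-codon A-site counts per condition and replicate.
3. **Pause calling and differential pausing** — Z-score pause sites with
   replicate concordance; per-codon Fisher's exact tests between two
   conditions with joint Benjamini–Hochberg correction.
4. **Collision footprints** — length × 5′-position densities of long
   footprints around start/stop codons, rectangle-gated collision classes,
   metagene profiles, and P-site assignment for 40–70-nt reads.
5. **Pause sequence context** — nucleotide and amino-acid windows around the
   pause (P-site) codon, frequency matrices, Kozak-context matching, and a
   uniform 1/20 amino-acid background for CDS-terminal pauses.
6. **Screen scoring** — sgRNA filtering/normalisation, NTC-centred log2
   enrichment, top-3-by-magnitude gene phenotypes, Mann–Whitney significance,
   and dual-TSS collapse.
7. **Synthetic data** — seed-deterministic generators for every input, each
   emitting machine-readable ground truth.

All coordinates are 0-based, half-open, in transcript space. Codon indices
are 0-based from the start codon.

# Reference curation

For each gene the principal transcript is the MANE transcript when one
exists; otherwise all candidates tied at the best APPRIS rank are taken, the
longest wins, and equal-length ties are broken uniformly at random under a
caller-supplied seed (candidates are ordered by id first, so input row order
cannot change the draw). The chosen CDS must then (i) have three-base
periodicity, (ii) end in UAG/UAA/UGA, and (iii) contain no base outside
ACGT/U; the reported failure reason is the first rule violated in that
order. A gene whose selected transcript fails validation is **dropped, not
replaced** — curation filters the selected set rather than falling back to a
runner-up isoform, which would quietly change which isoform represents the
gene. Non-AUG starts and internal UGA (selenocysteine recoding) are
accepted. Manually identified misannotations or pseudoautosomal duplicates
enter through a plain exclusion list (one gene id per line), not through any
heuristic.

# Footprint quantification

A read's A-site nucleotide is `five_prime_pos + offset(length)`. The default
offset table uses the canonical mammalian +15 nt for 29–32-nt footprints and
anchors the short 20–22-nt (vacant-A-site) class by its 5′ end with the same
offset; both are per-length overridable for users who calibrate offsets on
their own data. Both admitted length classes are pooled **after** A-site
assignment into a single codon count matrix per sample. Reads whose A-site
falls in a UTR are excluded from CDS matrices but logged, so the identity
*in-CDS + outside = admitted* holds per sample; metagene and collision
analyses use raw 5′ ends instead and are unaffected by the offset model.
Duplicate reads are counted as-is (no UMI logic).

The coverage filter retains a transcript only when **every** replicate of
**both** compared conditions has a mean of at least 0.5 reads per codon
(inclusive threshold). The filter is monotone: adding reads can only add
transcripts.

# Pause calling and differential pausing

Within each condition, replicate profiles are averaged per codon and rounded
to the nearest integer, half away from zero (2.5 → 3; round-half-to-even
would deflate tied averages in the downstream integer contingency tables).
Z-scores standardise a profile over all its codons using the population
standard deviation; a uniform profile has no defined Z-scores and carries no
pauses. A codon is a *pause site* when the averaged profile reaches Z ≥ 5
there and every replicate reaches Z ≥ 5 at that codon or an adjacent one
(±1 codon, truncated at CDS ends).

The *pause score* of a codon is its count divided by the mean over the CDS
interior (excluding the first and last five codons, which carry
initiation/termination occupancy). The exclusion applies only to this
denominator; Z-scores use all codons, because the interior-window rule is a
normalisation choice, not a detection one.

For two conditions, each codon of each retained transcript yields the table

```
[ test[c]   sum(test) − test[c] ]
[ ctrl[c]   sum(ctrl) − ctrl[c] ]
```

built from the rounded averaged profiles (the same object Z-scores use).
The two-sided Fisher exact p is computed by hypergeometric tail summation;
the odds ratio is the sample cross-product, with 0.5 added to all four cells
only when some cell is zero (the continuity-corrected OR is also what the
`OR ≠ 1` gate evaluates). Codons with zero counts in both conditions are
uninformative and are excluded from testing and from the multiple-testing
family. BH correction is applied jointly across all tested codons of all
retained transcripts by default — the conservative reading when the
correction family is otherwise unspecified — with a per-transcript option
(`bh_scope = "transcript"`).

A codon is **differential** when Z(test) ≥ 5, OR ≠ 1 and adjusted p < 0.05;
**increased** additionally requires OR > 1 and a larger test than control
pause score (decreased symmetrically). *Start-site pauses* are increased
pauses at codon index < 5.

`stats::fisher.test` is deliberately not used in the hot path: it computes
the conditional-MLE odds ratio rather than the sample OR used here, and is
orders of magnitude too slow for the ~3 × 10^4 tables a transcriptome-wide
comparison produces. The in-package tail summation is validated in the test
suite against both `stats::fisher.test` and an independent `choose()`-based
exhaustive enumeration over all 46,376 tables with total ≤ 30.

# Collision footprints

Long footprints are summarised by the offset of their 5′ end from the first
nucleotide of the start codon (`d_start`) or of the stop codon (`d_stop`).
Three rectangle gates define the collision classes:

| class | length (nt) | offset (nt) |
|---|---|---|
| `start_40S_80S` (scanning 43S against initiating 80S) | 45–62 | d_start ∈ [−40, −25] |
| `start_80S_80S` (80S–80S during early elongation) | 55–65 | d_start ∈ [−5, +5] |
| `termination_disome` | 55–65 | d_stop ∈ [−55, −45] |

with precedence `start_40S_80S` > `start_80S_80S` > `termination_disome`.
The admitted-length conventions differ by task and are separate
configuration values on purpose: 40–70 nt for P-site assignment I/O,
42–68 nt for heatmap axes, and the class rectangles above. The ~60-nt/±5
gates of `start_80S_80S` operationalise "around the start codon" and are
documented defaults rather than measured constants. The read 3′-end position
is redundant given 5′ end and length and is not used for classification.

Metagene profiles divide each transcript's windowed occupancy by its own
mean CDS occupancy before averaging across transcripts (equal weight per
transcript, zero-mean transcripts skipped; positions beyond a transcript's
bounds contribute nothing). This makes the profile invariant to scaling any
transcript's counts.

P-site assignment for 40–70-nt reads calibrates one offset per read length
as the mode of (first nt of the second-to-last CDS codon − read 5′ end)
over reads whose 3′ ends fall in that codon, breaking mode ties toward the
smaller offset; lengths with fewer than 10 calibrating reads fall back to
`length − 47` (anchoring the P-site 47 nt upstream of the 3′ end, the
second-to-last-codon geometry of a full-length footprint).

# Pause sequence context

The pause codon is treated as the ribosomal **P-site**; the A-site is the
next codon downstream. This register is fixed package-wide because an
off-by-one here silently converts P-site AUG enrichment into A-site
enrichment. Nucleotide windows are centred on the first nucleotide of the
pause codon (default ±15 nt) and are masked only where they extend beyond
the *transcript*: 5′UTR context is real sequence and is required for
Kozak-like patterns at start-site pauses to be visible. Amino-acid windows
(default ±5 residues) are masked where they extend beyond the *CDS*; for
pauses in the first or last five codons those masked residue positions can
be filled i.i.d. uniformly over the 20 standard amino acids (probability
1/20 each) so that terminal-pause logos have a defined, flat background.
Frequency matrices report per-position probabilities over contributing
symbols and information content in bits against a uniform background
(log2 4 for nucleotides, log2 20 for residues); no genome-composition
correction is applied. Kozak matching tests positions −3…+4 around the
start codon against `RCCAUGG` (R = A/G); transcripts with under 3 nt of
5′UTR cannot match.

# Screen scoring

Per replicate, the induced and uninduced samples are compared: sgRNAs below
50 raw reads in either sample are dropped, remaining zero counts receive a
pseudocount of 1 (zeros only, applied before scaling), and each sample is
scaled to reads-per-million over the surviving sgRNAs. Enrichment is
`log2(RPM_induced / RPM_uninduced)` minus the per-replicate median over
non-targeting controls, so NTC-median centring removes sequencing-depth and
global-growth terms. sgRNA enrichments are averaged across the replicates
in which the sgRNA survived; a gene TSS's phenotype is the mean of its (up
to) three largest-|e| sgRNAs and its p-value a two-sided Mann–Whitney of all
its surviving sgRNAs against all NTCs (`stats::wilcox.test`: exact for
small untied samples, normal approximation with tie correction otherwise).
Genes screened at two alternative TSSs are collapsed by keeping the
strongest-|phenotype| record among those with p ≤ 0.1, falling back to the
strongest-|phenotype| record flagged non-essential when none is significant.
No growth-generation scaling is applied to enrichments.

# Synthetic data: what it emulates, and what it does not

The generators reproduce the *structure* the statistics above assume, with
known ground truth:

* **Reference** — random transcripts satisfying every curation invariant by
  construction (AUG start, in-frame stops only terminal, ACGT-only CDS).
  Defaults: 150–450-codon CDSs, 20–150-nt UTRs, typical mammalian mRNA
  scales.
* **Codon counts** — negative-binomial counts (default dispersion 10,
  `Inf` degenerates to Poisson) around a uniform per-codon rate, because
  real codon counts are overdispersed; pauses are injected as multiplicative
  rate factors at chosen codons in chosen conditions. There is no
  sequence-dependent dwell-time model: pauses are positional, which is
  exactly the structure the Z-score/Fisher machinery tests.
* **Long reads** — uniform sampling inside each collision class rectangle
  plus uniform CDS background at monosome lengths (29–32 nt).
* **Screens** — per-sgRNA true enrichment = gene effect + Normal(0, sd);
  NTCs have gene effect 0 *and the same sgRNA-level noise*, making targeting
  and control sgRNAs exchangeable under the null — the property that makes
  the Mann–Whitney call rate nominal. Counts are multinomial at the stated
  depth over uniform uninduced abundances, with induced abundances tilted by
  2^e.

Passing recovery tests on these generators shows the statistical machinery
is correct and calibrated under its own assumptions. It does not show
robustness to features of real libraries the generators deliberately omit:
ligation and PCR bias, codon-specific dwell times, positional
autocorrelation, rRNA contamination, UMI structure, or mapping artefacts.

```{r example}
ref <- simulate_reference(30, cds_codons = c(150, 250), seed = 1)
pz <- data.frame(transcript_id = ref$transcripts$transcript_id[1:10],
                 codon = rep(0:4, 2), fold = 20, condition = "test")
cc <- simulate_codon_counts(ref, coverage = 2, pauses = pz, seed = 2)
dp <- differential_pauses(cc, "test", "ctrl")
summarize_start_site_fraction(dp)
```

# Numerical choices

* Rounding of averaged profiles: half away from zero.
* Fisher ties: tables whose probability is within a 1e-7 relative tolerance
  of the observed table's probability count toward the two-sided p (the
  standard guard against floating-point ties in hypergeometric enumeration).
* OR continuity correction: +0.5 to all four cells, only when a cell is 0.
* Degenerate inputs produce sentinels, not errors, wherever the quantity is
  merely undefined: uniform profiles (no Z-scores), all-zero interior
  windows (no pause scores; transcript skipped for differential testing),
  transcripts with ≤ 10 codons (no interior window), A-sites in UTRs
  (excluded, logged). Genuine contract violations (unknown transcript ids,
  out-of-bounds CDS coordinates, missing offset entries) are errors.
* Replicate-concordance flank hits: any one flanking hit per replicate
  suffices; no double counting.
* Mode ties in P-site calibration resolve to the smallest offset.

# Problem sizes used by the test suite and acceptance script

Simulation-based checks run at 100 transcripts × 300 codons × 2 conditions
× 2 replicates at 2 reads/codon for null calibration (8–20 seeds) and pause
recovery (5 seeds × 50 injected fold-20 pauses); 60 transcripts at 5
reads/codon for the start-site readout; 200 transcripts at 10 reads/codon
for the metagene ratio; and 50 seeds of 40 genes × 9 sgRNAs + 300 NTCs at
1000 reads/sgRNA for screen power and type-I. These sizes give
Monte-Carlo error comfortably inside the asserted bounds while keeping a
full run in tens of seconds on one CPU.

# Known limitations

* A-site offsets are declared, not learned; there is no periodicity-based
  offset calibration.
* Only two-condition comparisons; no GLM or dwell-time modelling.
* Genome-space (exon-aware) arithmetic is out of scope; all inputs are
  transcript-space.
* The screen module scores depletion/enrichment against NTCs only; no
  generation scaling, and no cell-type specificity scoring.
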