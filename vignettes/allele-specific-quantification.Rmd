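---
title: "Allele-specific TSHR transcription and isoform expression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific TSHR transcription and isoform expression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tshrasq)
```

## The scientific question

Graves' disease risk maps to SNPs in intron 1 of *TSHR*, and one proposed
mechanism is cis-regulatory: the protective G allele of rs179247 is
transcribed more strongly than the predisposing A allele in the thymus,
raising thymic TSHR dose and strengthening central tolerance. Because the
SNP is intronic, it can be read directly in pre-mRNA-derived cDNA from
heterozygous donors, and genomic DNA from the same donor provides a
built-in 1:1 control — every cell carries exactly one copy of each allele,
so any assay bias shows up as a gDNA ratio away from 1.

`tshrasq` implements the two quantitative arms of this design:

1. **Allele-specific quantification (ASQ)** from targeted amplicon
   deep-sequencing: align paired-end reads to the 233-bp amplimer,
   pile up the bases at the SNP, QC each sample, call genotypes from
   gDNA, keep heterozygotes, and summarise allelic imbalance per tissue.
2. **Isoform expression** from qPCR Ct triplicates: GAPDH-normalised
   expression of the full-length transcript (flTSHR) and the two
   truncated splice isoforms (ST4, ST5), their ratios and shares, and
   genotype-association models for a splicing effect.

A synthetic-data module generates amplicon read sets and qPCR cohorts
with known truth, so every stage is testable without any external data.
The study's published per-sample allele-count table also ships as a
plain-text fixture (`load_table1_fixture()`), and the headline cohort
statistics are recomputed from it at run time.

## ASQ model and conventions

For a sample with `count_alt` G reads and `count_ref` A reads at the SNP:

* **Frequency** is reported as `100 * count_alt / depth`, with total
  depth (including `count_other`) as the denominator. This matches the
  arithmetic of the published per-sample table, where the printed
  percentage equals G count over depth for every row.
* **Allelic ratio** is `count_alt / count_ref`, i.e. `f / (1 - f)` on
  the informative-read fraction `f`. The two definitions coincide for
  error-free data; both are exposed.
* **Balance** is the fraction of fragments sequenced from the forward
  primer. 0.5 means no strand bias; the QC band is [0.4, 0.6].

Coordinates are 0-based half-open internally and 1-based in
human-readable reports.

### Alignment

Reads are aligned semi-globally (read fully contained in the reference,
end-gap free), both orientations, higher score kept. The implementation
is a two-stage design suited to amplicon data, where substitution errors
dominate:

1. an ungapped scan scoring every candidate offset by Hamming distance,
   vectorised byte-wise across reads — exact for substitution-only
   errors and fast at depths in the thousands;
2. a gapped semi-global rescue (`Biostrings::pairwiseAlignment`,
   read-global/reference-local, match 1, mismatch −1, gap open 2,
   extend 1) only for reads that fail the identity threshold ungapped,
   which recovers indel-bearing reads.

Ties between orientations break toward forward; equal-best multi-offset
hits are discarded as ambiguous rather than placed arbitrarily. The
default identity threshold is 0.9.

### Pileup and QC

The base aligned to the SNP is classified as G, A, or other; bases below
Phred Q20 go to `other` regardless of identity, the standard pileup
guard. The bookkeeping invariants (`alt + ref + other = depth`,
`fwd + rev = depth`) are enforced by the `allele_count` constructor.

Thresholds the study did not publish are explicit, configurable
defaults chosen by assay logic:

* heterozygote band on gDNA informative fraction: [0.35, 0.65], closed
  at both ends, with a 500× minimum depth for a genotype call (a gDNA
  heterozygote should sit near 0.5; the band is wide enough to tolerate
  amplification bias, narrow enough to exclude homozygotes even with a
  few percent error);
* sample QC: minimum depth 100× and balance in [0.4, 0.6]. The
  published cohort retained a 342× cDNA sample, so the depth gate is
  deliberately permissive; depth enters the statistics only through the
  binomial precision of the frequency.

### Cohort statistics

Group summaries (n, mean, SD, min, max of frequency and ratio) are
computed per tissue × material. Two test families are reported, because
the study names both without resolving which produced the headline
contrast: Kruskal-Wallis with Dunn's post hoc across the four groups on
the G/A ratio, and a t test for the thymus-vs-thyroid cDNA contrast.
The t test is Welch's by default — only "t test" is stated in the
source, and the unequal-variance form is the safer default for groups
of 19 and 8.

## qPCR arm

Triplicate Ct values are averaged; the CV (sample SD over mean, on the
Ct scale) must stay below 15%. With GAPDH as both normaliser and
calibrator, the comparative-Ct quantity reduces to

```
expression = 2^(Ct_GAPDH − Ct_target) × 100,000   (copies per 100,000 GAPDH)
```

Amplification efficiency is fixed at 2.0 per cycle; it is an argument
(`efficiency`) for sensitivity analysis, but no standard-curve
correction is attempted. Isoform profiles carry the three ratios
(fl/ST4, fl/ST5, ST4/ST5) and the ST5 share of total transcripts; with
`st5 = 0` the ST5 ratios are flagged undefined while the share is still
computed.

Genotype association uses three inheritance models on four endpoints
(ST4, ST5, and their ratios to flTSHR): codominant (Kruskal-Wallis +
Dunn across the three genotypes), and dominant/recessive two-group
collapses by Mann-Whitney. The collapses are oriented by the risk
allele: A for rs179247 and T for rs12101255, matching the predisposing
genotypes; for the non-associated control SNP rs2288495 the orientation
is the caller's choice. Pediatric-vs-adult thymic involution is a Welch
t test between the 0–11 y and 40–80 y bands with mean ± SEM.

## Statistical conventions

* Mann-Whitney U: exact enumeration for tie-free samples with combined
  n ≤ 12; otherwise the normal approximation with tie and continuity
  corrections. Two-sided throughout.
* Kruskal-Wallis: tie-corrected H against chi-square with k − 1 df;
  an all-identical input returns H = 0, p = 1 instead of a 0/0 tie
  correction.
* Dunn's post hoc: pairwise z on mean ranks with pooled tie-corrected
  variance; p multiplied by the number of comparisons and capped at 1
  (the Prism-style "multiple comparison test"); Holm is available. For
  two groups, z² equals the tie-corrected H — an identity the tests
  verify numerically.
* Descriptives: sample SD (n − 1); type-7 (linear interpolation)
  quartiles; SIR = IQR/2. n = 1 groups omit SD/SEM with a flag.
* Degenerate t inputs: two constant equal groups give p = 1, two
  constant separated groups the p → 0 sentinel, both flagged.

## What the simulator emulates — and what it does not

`simulate_reads()` draws, per template fragment: the allele (Bernoulli
at `allele_fraction`), the sequencing orientation (Bernoulli at
`fwd_fraction`, defining balance), and independent per-base
substitutions at `error_rate`, each to a uniformly random different
base. Both mates then read the mutated fragment, so a pair is
internally consistent and the pair counts once in the pileup (read 1 is
the representative; with the default 2 × 233 full-amplimer layout the
mates overlap completely). A 1-bp indel process (`indel_rate`, default
0) exercises the gapped alignment path. Reads are written as 4-line
Phred+33 FASTQ at constant Q37.

This emulates the statistical structure the pipeline assumes — binomial
allele sampling at configurable depth, imbalance, error and primer
balance — and deliberately omits PCR-cycle error accumulation, chimera
formation, index hopping, quality-score decay along the read, and any
real sequence context (the true amplimer sequence is not public; a
seeded random sequence of matching length and GC stands in, labelled
synthetic). Passing tests therefore demonstrate correctness of the
counting and statistics under the assay's sampling model, not
robustness to every failure mode of real MiSeq data.

`simulate_qpcr_cohort()` draws true expression lognormally around the
published tissue × gene medians, with the spread matched to the
published IQRs via `sigma = asinh((IQR/median)/2) / qnorm(0.75)`,
multiplies in any configured genotype effect (default: none, the null),
converts to a target Ct with GAPDH at Ct 18, and adds Gaussian
triplicate noise (SD 0.15 cycles, comfortably inside the 15% CV gate).
Cohort structure follows the study: 49 thyroid donors (ages 15–71) and
39 thymus donors (31 pediatric 0–11 y, 8 adults 40–72 y). Genotype
frequencies are not printed for this cohort, so Hardy-Weinberg values at
typical European allele frequencies are fixed once as defaults. With
zero dispersion and zero noise the Ct construction inverts exactly,
which the round-trip tests exploit.

## Numerical choices and degenerate inputs

* Zero-depth pileups return depth 0 rather than erroring; frequency and
  ratio are then undefined and the per-sample row is QC-failed.
* `count_ref = 0` reports the ratio as `Inf` with a `ratio_undefined`
  flag; such rows are excluded from ratio summaries.
* RNG: every stochastic operation takes an explicit integer seed and
  runs under a save/restore wrapper, so fixed seeds give byte-identical
  output without disturbing the caller's RNG state.
* Report round-trip: the formatted per-sample table parses back to the
  exact integer counts; balance and frequency return at their printed
  2-decimal precision.

## Test problem sizes

The Monte-Carlo suite uses sizes chosen to make the binomial envelopes
tight while keeping the whole suite at desk scale: pileup-vs-oracle
equality on error-free reads across 100 seeds at depth 300;
allele-fraction recovery at the assay's cDNA depth of 9,000 for true
fractions {0.5, 0.55, 0.591, 0.65} × 50 seeds, requiring ≥ 99% of runs
inside 3 binomial SEs; and test-size calibration at 2,000 replicates per
test, where the empirical type-I error at α = 0.05 must fall in
[3.5%, 6.5%].

## Known limitations

* The synthetic amplimer cannot be sequence-validated against the real
  primers/coordinates, which were never published.
* Published flTSHR/ST5 and ST4/ST5 ratios (9.86/39.01 and 4.5/24.3) are
  medians of per-sample ratios of unpublished raw data; they are not
  recomputable from the printed group medians and are not asserted
  anywhere. The fl/ST4 ratios and ST5 shares, by contrast, are exact
  arithmetic on printed medians and are verified.
* The expression simulator treats genes independently within a sample;
  real isoform expressions are correlated through shared regulation, so
  simulated ratio dispersions are wider than real ones.
* No multi-plate Ct calibration, melt-curve QC, or standard-curve
  efficiency correction is modelled.
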