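# tshrasq

Allele-specific *TSHR* transcription and splice-isoform expression
analysis.

## What it is for

Graves' disease risk is associated with SNPs in intron 1 of *TSHR*, the
thyrotropin-receptor gene. One candidate mechanism is cis-regulatory:
in the thymus, the protective G allele of the intronic SNP rs179247 is
transcribed more strongly than the predisposing A allele, which would
raise thymic TSHR dose and strengthen central tolerance. Because the
SNP is intronic it can be read in pre-mRNA-derived cDNA of heterozygous
donors, and the donor's genomic DNA — exactly one copy of each allele
per cell — calibrates the assay: any gDNA allele ratio away from 1 is
assay bias, while a cDNA ratio away from 1 is transcriptional
imbalance.

`tshrasq` is for analysts working with this kind of design. It
implements:

* **Allele-specific quantification (ASQ)** from targeted amplicon
  deep-sequencing: semi-global read alignment to the 233-bp amplimer,
  allele pileup at the SNP with base-quality and strand-balance QC,
  genotype calling from gDNA, heterozygote selection, and tissue-level
  imbalance statistics. For a sample with `G` and `A` allele reads at
  total depth `d`, it reports the frequency `100·G/d` (%) and the
  allelic ratio `G/A = f/(1−f)` with `f = G/(G+A)`.
* **Isoform expression from qPCR**: triplicate Ct averaging with a CV
  gate, comparative-Ct normalisation
  `expression = 2^(Ct_GAPDH − Ct_target) × 10^5` (copies per 100,000
  GAPDH), ratios and shares of the full-length transcript (flTSHR) and
  the truncated splice isoforms ST4/ST5, genotype-association models
  (codominant, dominant, recessive), and age-band contrasts.
* **Statistics**: Mann-Whitney U (exact for small tie-free samples),
  tie-corrected Kruskal-Wallis, Dunn's post hoc on mean ranks with
  Bonferroni adjustment, Welch/Student t, and median/IQR/SIR
  descriptives, all returning a uniform result object.
* **A seedable synthetic-data generator** for paired-end amplicon read
  sets (configurable allelic imbalance, depth, substitution error,
  primer balance) with a truth table for oracle testing, and for qPCR
  Ct cohorts with tissue/genotype/age structure.

The published per-sample allele-count table of the motivating study (27
heterozygous donors: 8 thyroid, 19 thymus; one gDNA and one cDNA row
each) ships as a plain-text fixture and is consistency-checked on load.

## Worked example

Simulate a thymus-like cDNA sample (59.1% true G fraction, the assay's
typical cDNA depth of 9,000×, 0.5% substitution error), run it through
the full pipeline, and look at the published cohort:

```r
library(tshrasq)

ref <- make_amplicon_reference(seed = 42)           # synthetic 233-bp amplimer
cfg <- simulation_config(allele_fraction = 0.591, depth = 9000,
                         error_rate = 0.005, seed = 43)
rs  <- simulate_reads(ref, cfg)
ac  <- pileup_alleles(align_reads(rs$r1, ref), ref)
print(ac)
#> Allele count: depth 9000 (alt 5246 / ref 3729 / other 25), balance 0.51

st <- allele_stats(ac)
sprintf("frequency %.2f%%, G/A ratio %.3f", st$frequency_alt, st$ratio_ga)
#> "frequency 58.29%, G/A ratio 1.407"
```

The recovered frequency (58.29%) sits within binomial noise of the true
58.9% expected after error leakage, and the G/A ratio of 1.4 is the
thymus-like imbalance the simulation planted. The `other` count (25 of
9,000) is the expected 2/3 of the 0.5% substitution errors hitting the
SNP position. The published cohort statistics come straight from the
packaged table:

```r
print(reproduce_table1())
#> Headline allele-specific quantification quantities:
#>   Thymus cDNA (n=19): mean G frequency 59.1%, G/A ratio 1.5 +/- 0.2
#>   Thyroid cDNA (n=8): frequency range 45.1-54.9%, G/A ratio 1.1 +/- 0.1
#>   gDNA control: G/A ratios in [1.00, 1.09] (all ~1)
#>   Mean depth: gDNA 27212x, cDNA 9178x
```

The thymus overexpresses the protective allele 1.5-fold while the
thyroid does not, and every gDNA control ratio rounds to 1. On the qPCR
side, the isoform arithmetic on the thyroid expression medians:

```r
print(isoform_profile(2860, 2135, 303))
#> Isoform profile: flTSHR 2860, ST4 2135, ST5 303 | fl/ST4 1.34, ST5 share 5.7%
```

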