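Package: tshrasq
Title: Allele-Specific TSHR Transcription and Splice-Isoform Expression
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies allele-specific transcription at a heterozygous
    intronic SNP (rs179247 in TSHR intron 1) from targeted amplicon
    deep-sequencing of genomic DNA and pre-mRNA-derived cDNA: read
    alignment against the amplicon reference, per-sample allele pileup
    with quality and strand-balance QC, genotype calling from gDNA,
    and tissue-level allelic-imbalance statistics. A second arm
    quantifies full-length and alternatively spliced TSHR transcript
    isoforms (flTSHR, ST4, ST5) from qPCR Ct triplicates via
    GAPDH-normalised comparative-Ct expression, isoform ratios and
    shares, and nonparametric genotype-association models. Includes a
    seedable synthetic-data generator for paired-end amplicon reads and
    qPCR cohorts so the whole pipeline is testable without external
    data, and ships the study's per-sample allele-count table as a
    plain-text fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
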