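test_that("exact substrings and their reverse complements align as expected", {
  ref <- tiny_ref()
  sub <- substr(ref$sequence, 51, 90)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
  aln <- align_reads(reads_df(c(sub, rc)), ref)
  expect_equal(nrow(aln), 2)
  expect_equal(aln$offset, c(50, 50))
  expect_equal(aln$orientation, c("fwd", "rev"))
  expect_equal(aln$identity, c(1, 1))
})

test_that("simulated reads map to offset 0 with the simulator's orientations", {
  ref <- tiny_ref()
  rs <- simulate_reads(ref, simulation_config(allele_fraction = 0.5,
                                              depth = 1000,
                                              error_rate = 0.005, seed = 21))
  aln <- align_reads(rs$r1, ref, min_identity = 0.9)
  expect_equal(nrow(aln), 1000)
  expect_true(all(aln$offset == 0))
  m <- merge(data.frame(fragment_id = sub("/1$", "", aln$read_id),
                        mapped_orientation = aln$orientation,
                        stringsAsFactors = FALSE),
             rs$truth, by = "fragment_id")
  expect_equal(nrow(m), 1000)
  expect_identical(m$mapped_orientation, m$orientation)
})

test_that("ambiguous multi-offset hits are discarded, low identity counted", {
  # tandem-repeat reference: a short repeat-unit read maps equally well
  # at two offsets and must be dropped as ambiguous
  ref <- amplicon_reference(strrep("ACGTTGCA", 6), snp_pos = 2,
                            allele_ref = "G", allele_alt = "A")
  aln <- align_reads(reads_df("ACGTTGCAACGTTGCA"), ref)
  expect_equal(nrow(aln), 0)
  expect_equal(attr(aln, "discarded")[["ambiguous"]], 1)

  junk <- reads_df(strrep("A", 48))
  aln2 <- align_reads(junk, ref, min_identity = 0.9)
  expect_equal(nrow(aln2), 0)
  expect_equal(attr(aln2, "discarded")[["low_identity"]], 1)
})

test_that("gapped rescue recovers a read with a deletion and keeps the SNP call", {
  ref <- tiny_ref()
  full <- ref$sequence
  # delete 1 bp well upstream of the SNP (position 20)
  del <- paste0(substr(full, 1, 19), substr(full, 21, 233))
  aln <- align_reads(reads_df(del), ref, min_identity = 0.95)
  expect_equal(nrow(aln), 1)
  expect_true(aln$gapped)
  ac <- pileup_alleles(aln, ref)
  expect_equal(ac$depth, 1)
  expect_equal(ac$count_ref, 1)
})

test_that("pileup classifies alt, ref, other and low-quality bases", {
  ref <- tiny_ref()
  alt_seq <- ref$sequence
  substr(alt_seq, 117, 117) <- "G"
  other_seq <- ref$sequence
  substr(other_seq, 117, 117) <- "C"
  reads <- reads_df(c(rep(alt_seq, 60), rep(ref$sequence, 40), other_seq))
  aln <- align_reads(reads, ref)
  ac <- pileup_alleles(aln, ref)
  expect_equal(ac$depth, 101)
  expect_equal(ac$count_alt, 60)
  expect_equal(ac$count_ref, 40)
  expect_equal(ac$count_other, 1)

  # a high-identity read whose SNP base is below Q20 goes to count_other
  lowq <- strrep("F", 233)
  substr(lowq, 117, 117) <- "+"  # Phred 10
  aln2 <- align_reads(reads_df(alt_seq, quals = lowq), ref)
  ac2 <- pileup_alleles(aln2, ref, min_base_quality = 20)
  expect_equal(ac2$count_other, 1)
  expect_equal(ac2$count_alt, 0)
})

test_that("no-coverage pileup returns depth 0 rather than an error", {
  ref <- tiny_ref()
  head_only <- substr(ref$sequence, 1, 50)  # never reaches the SNP
  aln <- align_reads(reads_df(head_only), ref)
  ac <- pileup_alleles(aln, ref)
  expect_equal(ac$depth, 0)
  expect_error(allele_stats(ac), "depth 0")
})

test_that("sequencing-error leakage into count_other matches e*2/3", {
  # a substitution at the SNP lands on either of the 2 non-allele bases
  # with probability 2/3
  ref <- tiny_ref()
  rs <- simulate_reads(ref, simulation_config(allele_fraction = 0.5,
                                              depth = 10000,
                                              error_rate = 0.01, seed = 31))
  ac <- pileup_alleles(align_reads(rs$r1, ref), ref)
  expected <- 10000 * 0.01 * 2 / 3
  se <- sqrt(10000 * 0.01 * 2 / 3)
  expect_lt(abs(ac$count_other - expected), 3 * se)
  expect_equal(ac$count_alt + ac$count_ref + ac$count_other, ac$depth)
  expect_equal(ac$fwd_reads + ac$rev_reads, ac$depth)
})

test_that("allele statistics reproduce the published per-sample arithmetic", {
  # thyroid donor 102 cDNA and thymus donor 117 cDNA rows
  st <- allele_stats(ac_of(4926, 9305 - 4926))
  expect_equal(round(st$frequency_alt, 2), 52.94)
  expect_equal(st$ratio_ga, 4926 / 4379)
  st2 <- allele_stats(ac_of(3764, 5912 - 3764))
  expect_equal(round(st2$frequency_alt, 2), 63.67)
  st3 <- allele_stats(ac_of(500, 500))
  expect_equal(st3$frequency_alt, 50)
  expect_equal(st3$ratio_ga, 1)
  st4 <- allele_stats(ac_of(100, 0))
  expect_identical(st4$ratio_ga, Inf)
  expect_true("ratio_undefined" %in% st4$flags)
})

test_that("genotype calls follow the closed heterozygote band on gDNA", {
  expect_equal(call_genotype(ac_of(15054, 29548 - 15054)), "het")
  expect_equal(call_genotype(ac_of(990, 10)), "hom_alt")
  expect_equal(call_genotype(ac_of(10, 990)), "hom_ref")
  expect_equal(call_genotype(ac_of(350, 650)), "het")   # f = 0.35, closed
  expect_equal(call_genotype(ac_of(650, 350)), "het")   # f = 0.65, closed
  gt <- call_genotype(ac_of(100, 100), min_depth = 500)
  expect_equal(as.character(gt), "unknown")
  expect_match(attr(gt, "reason"), "depth")
})

test_that("sample QC flags low depth and strand bias with reasons", {
  good <- allele_count(9305, 4926, 4379, 0, 4559, 4746)  # balance 0.49
  expect_true(qc_sample(good)$qc_pass)
  biased <- allele_count(1000, 500, 500, 0, 200, 800)    # balance 0.2
  qb <- qc_sample(biased)
  expect_false(qb$qc_pass)
  expect_true(any(grepl("strand bias", qb$reasons)))
  shallow <- allele_count(342, 185, 157, 0, 164, 178)
  expect_true(qc_sample(shallow, min_depth = 100)$qc_pass)
  expect_false(qc_sample(shallow, min_depth = 500)$qc_pass)
})

test_that("allele_count enforces its bookkeeping invariants", {
  expect_error(allele_count(10, 5, 4, 0), "equal depth")
  expect_error(allele_count(10, 6, 4, 0, 3, 3), "fwd_reads")
  expect_error(allele_count(10, -1, 11, 0), "non-negative")
})

test_that("cohort summary on the packaged counts matches the published headline", {
  res <- fixture_asq_results()
  summ <- cohort_asq_summary(res)
  g <- summ$groups
  tm_c <- g[g$tissue == "thymus" & g$material == "cDNA", ]
  expect_equal(tm_c$n, 19)
  expect_equal(round(tm_c$mean_frequency, 1), 59.1)
  expect_equal(round(tm_c$mean_ratio, 1), 1.5)
  expect_equal(round(tm_c$sd_ratio, 1), 0.2)
  ty_c <- g[g$tissue == "thyroid" & g$material == "cDNA", ]
  expect_equal(round(ty_c$min_frequency, 2), 45.13)
  expect_equal(round(ty_c$max_frequency, 2), 54.85)
  # both test families are reported and agree that the thymus cDNA
  # imbalance is real
  expect_lt(summ$kruskal$p_value, 0.001)
  expect_lt(summ$t_cdna_ratio$p_value, 0.001)
  expect_s3_class(summ$t_cdna_ratio, "tshr_stat")
  expect_equal(summ$t_cdna_ratio$test_name, "Welch t")
})

test_that("every gDNA sample shows the biallelic 1:1 control ratio", {
  res <- fixture_asq_results()
  gd <- res[res$material == "gDNA", ]
  expect_equal(nrow(gd), 27)
  expect_true(all(gd$ratio_ga >= 0.99 & gd$ratio_ga <= 1.09))
  expect_true(all(round(gd$ratio_ga) == 1))
})

test_that("degenerate summary groups collapse to SD 0 and min = max = mean", {
  res <- data.frame(
    sample_id = c("a", "b", "c"), tissue = "thymus", material = "cDNA",
    depth = 1000L, count_alt = 600L, count_ref = 400L, count_other = 0L,
    balance = 0.5, frequency_alt = 60, ratio_ga = 1.5, qc_pass = TRUE,
    qc_reasons = "", stringsAsFactors = FALSE)
  g <- cohort_asq_summary(res)$groups
  expect_equal(g$sd_frequency, 0)
  expect_equal(g$min_frequency, g$max_frequency)
  expect_equal(g$min_frequency, g$mean_frequency)
})

test_that("report formatting matches the published layout and round-trips", {
  res <- fixture_asq_results()
  rep <- table1_report(res)
  row102 <- strsplit(rep[which(startsWith(rep[-1], "102\tthyroid\tgDNA")) + 1],
                     "\t")[[1]]
  expect_equal(row102[4:7], c("29548x", "0.49", "15,054", "50.95"))
  back <- parse_table1_report(rep)
  expect_equal(back$depth, res$depth)
  expect_equal(back$count_alt, res$count_alt)
  expect_equal(back$sample_id, res$sample_id)

  zero <- asq_results(list(allele_count(0, 0, 0, 0, 0, 0)), "z", "thymus",
                      "cDNA")
  repz <- table1_report(zero)
  expect_match(repz[2], "NA$")
})
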