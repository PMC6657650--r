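test_that("reference construction honours length, SNP placement and seed", {
  ref <- make_amplicon_reference(233, 116, 0.40, seed = 1)
  expect_s3_class(ref, "amplicon_reference")
  expect_equal(nchar(ref$sequence), 233)
  expect_equal(substr(ref$sequence, 117, 117), "A")
  ref2 <- make_amplicon_reference(233, 116, 0.40, seed = 1)
  expect_identical(ref$sequence, ref2$sequence)
  ref3 <- make_amplicon_reference(233, 116, 0.40, seed = 2)
  expect_false(identical(ref$sequence, ref3$sequence))
})

test_that("reference generation tracks the requested GC content", {
  ref <- make_amplicon_reference(length = 5000, snp_offset = 2500,
                                 gc_content = 0.40, seed = 4)
  gc <- mean(strsplit(ref$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.40), 0.03)
})

test_that("reference construction rejects out-of-range or degenerate input", {
  expect_error(make_amplicon_reference(10, 10, 0.4, seed = 1), "snp_offset")
  expect_error(make_amplicon_reference(10, -1, 0.4, seed = 1), "snp_offset")
  expect_error(make_amplicon_reference(10, 5, 0, seed = 1), "gc_content")
  expect_error(amplicon_reference("ACGT", 1, allele_ref = "C",
                                  allele_alt = "C"), "differ")
  expect_error(amplicon_reference("ACGT", 0, allele_ref = "C",
                                  allele_alt = "G"), "neither allele")
  expect_error(amplicon_reference("", 0), "non-empty")
})

test_that("degenerate allele fractions and zero depth behave as forced", {
  ref <- tiny_ref()
  rs <- simulate_reads(ref, simulation_config(allele_fraction = 1,
                                              depth = 100, error_rate = 0,
                                              seed = 2))
  bf <- brute_force_counts(rs)
  expect_equal(unname(bf["alt"]), 100)
  expect_equal(unname(bf["ref"]), 0)
  expect_true(all(rs$truth$true_allele == "alt"))

  rs0 <- simulate_reads(ref, simulation_config(depth = 0, seed = 1))
  expect_equal(nrow(rs0$r1), 0)
  expect_equal(nrow(rs0$truth), 0)
})

test_that("simulation is byte-identical under a fixed seed", {
  ref <- tiny_ref()
  cfg <- simulation_config(allele_fraction = 0.6, depth = 50,
                           error_rate = 0.01, seed = 11)
  rs1 <- simulate_reads(ref, cfg)
  rs2 <- simulate_reads(ref, cfg)
  expect_identical(rs1$r1, rs2$r1)
  expect_identical(rs1$r2, rs2$r2)
  expect_identical(rs1$truth, rs2$truth)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_read_set(rs1, d1); write_read_set(rs2, d2)
  expect_identical(readLines(file.path(d1, "sim_R1.fastq")),
                   readLines(file.path(d2, "sim_R1.fastq")))
})

test_that("truth table matches direct FASTQ inspection for error-free reads", {
  ref <- tiny_ref()
  for (s in 1:20) {
    rs <- simulate_reads(ref, simulation_config(allele_fraction = 0.55,
                                                depth = 200, error_rate = 0,
                                                seed = s))
    bf <- brute_force_counts(rs)
    expect_equal(unname(bf["alt"]), sum(rs$truth$true_allele == "alt"))
    expect_equal(unname(bf["other"]), 0)
  }
})

test_that("alt counts stay inside the 3-SE binomial envelope across seeds", {
  ref <- tiny_ref()
  hits <- 0L
  for (s in 1:100) {
    rs <- simulate_reads(ref, simulation_config(allele_fraction = 0.5,
                                                depth = 10000, error_rate = 0,
                                                seed = s))
    n_alt <- sum(rs$truth$true_allele == "alt")
    if (abs(n_alt - 5000) <= 3 * sqrt(10000 * 0.25)) hits <- hits + 1L
  }
  expect_gte(hits, 99L)
})

test_that("observed alt fraction converges to the substitution-corrected mean", {
  # E[f_obs] = b(1-e) + (1-b) e/3: an alt fragment is miscalled away with
  # probability e, a ref fragment miscalled to alt with probability e/3.
  ref <- tiny_ref()
  b <- 0.6; e <- 0.01
  obs <- vapply(1:40, function(s) {
    rs <- simulate_reads(ref, simulation_config(allele_fraction = b,
                                                depth = 2000, error_rate = e,
                                                seed = 100 + s))
    bf <- brute_force_counts(rs)
    bf[["alt"]] / 2000
  }, numeric(1))
  expected <- b * (1 - e) + (1 - b) * e / 3
  se_mean <- sqrt(expected * (1 - expected) / 2000) / sqrt(40)
  expect_lt(abs(mean(obs) - expected), 4 * se_mean)
})

test_that("paired reads are full-amplicon mirror images at default length", {
  ref <- tiny_ref()
  rs <- simulate_reads(ref, simulation_config(depth = 20, error_rate = 0.01,
                                              seed = 5))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rs$r2$sequence)))
  expect_identical(rs$r1$sequence, rc)
})

test_that("config validation rejects out-of-range probabilities and depths", {
  expect_error(simulation_config(allele_fraction = 1.2), "allele_fraction")
  expect_error(simulation_config(error_rate = 1), "error_rate")
  expect_error(simulation_config(depth = -1), "depth")
  expect_error(simulation_config(fwd_fraction = -0.1), "fwd_fraction")
})

test_that("qPCR cohort has the study's sample-sheet structure", {
  cohort <- simulate_qpcr_cohort(qpcr_cohort_config(n_thyroid = 49,
                                                    n_thymus = 39, seed = 3))
  expect_equal(nrow(cohort$samples), 88)
  expect_equal(sum(cohort$samples$tissue == "thyroid"), 49)
  expect_equal(sum(cohort$samples$tissue == "thymus"), 39)
  expect_equal(nrow(cohort$ct), 88 * 4)
  expect_true(all(c("genotype_rs179247", "genotype_rs12101255",
                    "genotype_rs2288495") %in% names(cohort$samples)))
  expect_true(all(cohort$ct$ct1 > 0))
  cohort2 <- simulate_qpcr_cohort(qpcr_cohort_config(n_thyroid = 49,
                                                     n_thymus = 39, seed = 3))
  expect_identical(cohort, cohort2)
})

test_that("noiseless qPCR simulation round-trips the configured medians", {
  cohort <- simulate_qpcr_cohort(noiseless_qpcr_config(seed = 6))
  expr <- expression_table(cohort$ct)
  expr <- merge(expr, cohort$samples[, c("sample_id", "tissue")],
                by = "sample_id")
  thy <- expr[expr$tissue == "thyroid", ]
  tmu <- expr[expr$tissue == "thymus", ]
  expect_equal(thy$flTSHR, rep(2860, nrow(thy)))
  expect_equal(thy$ST4, rep(2135, nrow(thy)))
  expect_equal(thy$ST5, rep(303, nrow(thy)))
  expect_equal(tmu$flTSHR, rep(651, nrow(tmu)))
  expect_equal(tmu$ST5, rep(15, nrow(tmu)))
})

test_that("qPCR config validation catches bad medians and frequencies", {
  expect_error(qpcr_cohort_config(
    medians = list(thyroid = c(flTSHR = -1, ST4 = 1, ST5 = 1),
                   thymus = c(flTSHR = 1, ST4 = 1, ST5 = 1))), "positive")
  expect_error(qpcr_cohort_config(
    genotype_freqs = list(rs179247 = c(AA = 0.5, AG = 0.4, GG = 0.2))),
    "sum to 1")
})

test_that("genotype effect multipliers scale the configured gene", {
  eff <- data.frame(snp = "rs179247", genotype = "AA", gene = "ST4",
                    multiplier = 2, stringsAsFactors = FALSE)
  cfg <- noiseless_qpcr_config(n_thyroid = 30L, n_thymus = 0L, seed = 9)
  cfg$effects <- eff
  cohort <- simulate_qpcr_cohort(cfg)
  expr <- merge(expression_table(cohort$ct),
                cohort$samples[, c("sample_id", "genotype_rs179247")],
                by = "sample_id")
  aa <- expr$ST4[expr$genotype_rs179247 == "AA"]
  rest <- expr$ST4[expr$genotype_rs179247 != "AA"]
  expect_true(all(abs(aa - 2 * 2135) < 1e-6))
  expect_true(all(abs(rest - 2135) < 1e-6))
})
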