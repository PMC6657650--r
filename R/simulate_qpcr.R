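# Lognormal spread parameter from a median/IQR pair: for X = m*exp(s*Z),
# IQR = m*(exp(q*s) - exp(-q*s)) with q = qnorm(0.75), so
# s = asinh((IQR/m)/2)/q.
sigma_from_iqr <- function(median, iqr) {
  stopifnot(median > 0, iqr >= 0)
  asinh((iqr / median) / 2) / stats::qnorm(0.75)
}

.default_medians <- list(
  thyroid = c(flTSHR = 2860, ST4 = 2135, ST5 = 303),
  thymus  = c(flTSHR = 651,  ST4 = 337,  ST5 = 15)
)
.default_iqrs <- list(
  thyroid = c(flTSHR = 1792, ST4 = 961, ST5 = 104),
  thymus  = c(flTSHR = 580,  ST4 = 299, ST5 = 8)
)
# Genotype frequencies are not printed for this cohort; Hardy-Weinberg
# values at typical European allele frequencies are used (risk alleles:
# A for rs179247, T for rs12101255; rs2288495 is the non-associated
# control SNP).
.default_genotype_freqs <- list(
  rs179247   = c(AA = 0.36, AG = 0.48, GG = 0.16),
  rs12101255 = c(TT = 0.12, TC = 0.46, CC = 0.42),
  rs2288495  = c(CC = 0.49, CT = 0.42, TT = 0.09)
)

#' Configuration for the synthetic qPCR cohort
#'
#' Defaults reproduce the study conditions: 49 thyroid and 39 thymus
#' donors; per-tissue isoform medians and IQRs (copies per 100,000 GAPDH)
#' matching the printed cohort descriptives; no genotype effect on
#' splicing (all multipliers 1); thymus ages split pediatric (0-11 y,
#' 31/39) vs adult (40-72 y).
#'
#' @param n_thyroid,n_thymus Donors per tissue.
#' @param medians,iqrs Named lists (`thyroid`, `thymus`) of named vectors
#'   over genes `flTSHR`, `ST4`, `ST5`: median expression and IQR in
#'   copies per 100,000 GAPDH. Expression is drawn lognormally around the
#'   median with spread matched to the IQR.
#' @param genotype_freqs Named list per SNP of genotype frequencies
#'   (must each sum to 1).
#' @param effects Optional data frame (`snp`, `genotype`, `gene`,
#'   `multiplier`) of multiplicative genotype effects on true expression;
#'   empty by default (null splicing effect).
#' @param ct_gapdh Reference GAPDH threshold cycle.
#' @param ct_noise_sd Gaussian SD of replicate Ct noise, cycles.
#' @param pediatric_fraction Fraction of thymus donors in the 0-11 y
#'   band; the rest are adults in `adult_age_range`.
#' @param pediatric_age_range,adult_age_range,thyroid_age_range Age
#'   ranges (years) sampled uniformly.
#' @param seed Integer seed.
#'
#' @return A validated list of class `qpcr_cohort_config`.
#' @export
qpcr_cohort_config <- function(n_thyroid = 49L, n_thymus = 39L,
                               medians = .default_medians,
                               iqrs = .default_iqrs,
                               genotype_freqs = .default_genotype_freqs,
                               effects = NULL,
                               ct_gapdh = 18,
                               ct_noise_sd = 0.15,
                               pediatric_fraction = 31 / 39,
                               pediatric_age_range = c(0, 11),
                               adult_age_range = c(40, 72),
                               thyroid_age_range = c(15, 71),
                               seed = 1L) {
  if (!is_scalar_number(n_thyroid) || n_thyroid < 0 ||
      !is_scalar_number(n_thymus) || n_thymus < 0) {
    stopf("cohort sizes must be non-negative integers")
  }
  genes <- c("flTSHR", "ST4", "ST5")
  for (tis in c("thyroid", "thymus")) {
    m <- medians[[tis]]; q <- iqrs[[tis]]
    if (is.null(m) || !all(genes %in% names(m)) || any(m[genes] <= 0)) {
      stopf("medians$%s must be positive for %s", tis,
            paste(genes, collapse = ", "))
    }
    if (is.null(q) || !all(genes %in% names(q)) || any(q[genes] < 0)) {
      stopf("iqrs$%s must be non-negative for %s", tis,
            paste(genes, collapse = ", "))
    }
  }
  for (snp in names(genotype_freqs)) {
    fr <- genotype_freqs[[snp]]
    if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8) {
      stopf("genotype frequencies for %s must be non-negative and sum to 1", snp)
    }
  }
  if (is.null(effects)) {
    effects <- data.frame(snp = character(0), genotype = character(0),
                          gene = character(0), multiplier = numeric(0),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("snp", "genotype", "gene", "multiplier") %in% names(effects)))
  if (!is_scalar_number(ct_noise_sd) || ct_noise_sd < 0) {
    stopf("`ct_noise_sd` must be >= 0")
  }
  check_prob(pediatric_fraction, "pediatric_fraction")
  structure(
    list(n_thyroid = as.integer(n_thyroid), n_thymus = as.integer(n_thymus),
         medians = medians, iqrs = iqrs, genotype_freqs = genotype_freqs,
         effects = effects, ct_gapdh = ct_gapdh, ct_noise_sd = ct_noise_sd,
         pediatric_fraction = pediatric_fraction,
         pediatric_age_range = pediatric_age_range,
         adult_age_range = adult_age_range,
         thyroid_age_range = thyroid_age_range,
         seed = as.integer(seed)),
    class = "qpcr_cohort_config"
  )
}

#' Simulate a qPCR cohort of Ct triplicates
#'
#' For each donor and gene, a true expression value (copies per 100,000
#' GAPDH) is drawn lognormally around the tissue-and-gene median, scaled
#' by any configured genotype multiplier, converted to a target threshold
#' cycle via `Ct_target = Ct_GAPDH - log2(expression / 100000)`, and
#' emitted as a triplicate with Gaussian Ct noise. Genotypes are drawn
#' from the configured frequencies; ages and sex follow the tissue
#' demographics.
#'
#' @param cfg A [qpcr_cohort_config()].
#' @return A list with `ct` (data frame: `sample_id`, `gene`,
#'   `ct1`..`ct3`) and `samples` (sample sheet: `sample_id`, `tissue`,
#'   `age`, `sex`, one `genotype_<snp>` column per SNP,
#'   `gdna_contamination_free`).
#' @export
simulate_qpcr_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "qpcr_cohort_config"))
  genes <- c("flTSHR", "ST4", "ST5")
  with_seed(cfg$seed, {
    tissues <- c(rep("thyroid", cfg$n_thyroid), rep("thymus", cfg$n_thymus))
    n <- length(tissues)
    ids <- sprintf("%s_%02d", tissues, c(seq_len(cfg$n_thyroid),
                                         seq_len(cfg$n_thymus)))
    age <- numeric(n)
    thy <- tissues == "thyroid"
    age[thy] <- stats::runif(sum(thy), cfg$thyroid_age_range[1],
                             cfg$thyroid_age_range[2])
    n_tm <- sum(!thy)
    if (n_tm > 0) {
      n_ped <- round(cfg$pediatric_fraction * n_tm)
      ped <- sample(c(rep(TRUE, n_ped), rep(FALSE, n_tm - n_ped)))
      a <- numeric(n_tm)
      a[ped] <- stats::runif(sum(ped), cfg$pediatric_age_range[1],
                             cfg$pediatric_age_range[2])
      a[!ped] <- stats::runif(sum(!ped), cfg$adult_age_range[1],
                              cfg$adult_age_range[2])
      age[!thy] <- a
    }
    sex <- ifelse(stats::runif(n) < ifelse(thy, 43 / 50, 15 / 39), "F", "M")
    samples <- data.frame(sample_id = ids, tissue = tissues,
                          age = round(age, 1), sex = sex,
                          stringsAsFactors = FALSE)
    for (snp in names(cfg$genotype_freqs)) {
      fr <- cfg$genotype_freqs[[snp]]
      samples[[paste0("genotype_", snp)]] <-
        sample(names(fr), n, replace = TRUE, prob = fr)
    }
    samples$gdna_contamination_free <- TRUE

    ct <- vector("list", n)
    for (i in seq_len(n)) {
      mult <- setNames(rep(1, length(genes)), genes)
      if (nrow(cfg$effects)) {
        for (k in seq_len(nrow(cfg$effects))) {
          eff <- cfg$effects[k, ]
          g_col <- paste0("genotype_", eff$snp)
          if (g_col %in% names(samples) &&
              samples[[g_col]][i] == eff$genotype && eff$gene %in% genes) {
            mult[[eff$gene]] <- mult[[eff$gene]] * eff$multiplier
          }
        }
      }
      med <- cfg$medians[[tissues[i]]][genes]
      sig <- vapply(genes, function(g)
        sigma_from_iqr(cfg$medians[[tissues[i]]][[g]],
                       cfg$iqrs[[tissues[i]]][[g]]), numeric(1))
      expr <- med * exp(sig * stats::rnorm(length(genes))) * mult[genes]
      ct_target <- cfg$ct_gapdh - log2(expr / 1e5)
      gene_names <- c(genes, "GAPDH")
      ct_means <- c(ct_target, cfg$ct_gapdh)
      reps <- matrix(stats::rnorm(3 * length(gene_names), mean = ct_means,
                                  sd = cfg$ct_noise_sd),
                     nrow = length(gene_names))
      ct[[i]] <- data.frame(sample_id = ids[i], gene = gene_names,
                            ct1 = reps[, 1], ct2 = reps[, 2], ct3 = reps[, 3],
                            stringsAsFactors = FALSE)
    }
    list(ct = do.call(rbind, ct), samples = samples)
  })
}
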