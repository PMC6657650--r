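# qPCR expression arm: triplicate averaging with CV QC, comparative-Ct
# normalisation to GAPDH, isoform ratios/shares, and the
# genotype-association and age-contrast analyses.

#' Average a Ct triplicate with CV quality control
#'
#' The triplicate mean is the working Ct; the coefficient of variation
#' (sample SD / mean, on the Ct scale) must stay below `cv_limit` for
#' the record to pass QC.
#'
#' @param ct_values Numeric vector of exactly three replicate Ct values,
#'   all finite and positive.
#' @param cv_limit CV threshold (default 0.15, i.e. 15%).
#' @return A list: `mean_ct`, `cv`, `qc_pass`.
#' @export
average_triplicate <- function(ct_values, cv_limit = 0.15) {
  if (length(ct_values) != 3L) {
    stopf("a Ct record must contain exactly 3 replicate values, got %d",
          length(ct_values))
  }
  ct_values <- as.numeric(ct_values)
  if (any(!is.finite(ct_values)) || any(ct_values <= 0)) {
    stopf("Ct values must be finite and positive")
  }
  m <- mean(ct_values)
  cv <- stats::sd(ct_values) / m
  list(mean_ct = m, cv = cv, qc_pass = cv < cv_limit)
}

#' GAPDH-normalised expression by the comparative-Ct method
#'
#' With GAPDH as both normaliser and calibrator the comparative-Ct
#' quantity reduces to `2^(Ct_GAPDH - Ct_target)`, reported as copies
#' per 100,000 copies of GAPDH. Amplification efficiency is assumed
#' perfect (factor `efficiency` per cycle, default 2).
#'
#' @param ct_target,ct_gapdh Mean threshold cycles for the target gene
#'   and GAPDH.
#' @param efficiency Per-cycle amplification factor (default 2;
#'   exposed for sensitivity analysis, no standard-curve correction).
#' @return Expression in copies per 100,000 GAPDH copies.
#' @export
normalize_expression <- function(ct_target, ct_gapdh, efficiency = 2) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_gapdh))) {
    stopf("Ct values must be finite")
  }
  efficiency^(ct_gapdh - ct_target) * 1e5
}

#' Isoform profile: ratios and shares of flTSHR, ST4, ST5
#'
#' @param fl,st4,st5 Expression values (copies per 100,000 GAPDH);
#'   `fl` and `st4` must be positive, `st5` may be 0 (its ratios are
#'   then undefined and returned as `NA` with a flag; the share is still
#'   computed).
#' @return A list of class `isoform_profile`: `fl`, `st4`, `st5`,
#'   `ratio_fl_st4`, `ratio_fl_st5`, `ratio_st4_st5`, `st5_share`
#'   (st5 / (fl + st4 + st5)), `flags`.
#' @export
isoform_profile <- function(fl, st4, st5) {
  if (!is_scalar_number(fl) || !is_scalar_number(st4) ||
      !is_scalar_number(st5) || fl <= 0 || st4 <= 0 || st5 < 0) {
    stopf("expressions must be positive (st5 may be zero)")
  }
  flags <- character(0)
  if (st5 == 0) {
    r_fl_st5 <- NA_real_; r_st4_st5 <- NA_real_
    flags <- "st5_ratios_undefined"
  } else {
    r_fl_st5 <- fl / st5; r_st4_st5 <- st4 / st5
  }
  structure(
    list(fl = fl, st4 = st4, st5 = st5,
         ratio_fl_st4 = fl / st4, ratio_fl_st5 = r_fl_st5,
         ratio_st4_st5 = r_st4_st5,
         st5_share = st5 / (fl + st4 + st5), flags = flags),
    class = "isoform_profile")
}

#' @export
print.isoform_profile <- function(x, ...) {
  cat(sprintf(
    "Isoform profile: flTSHR %.4g, ST4 %.4g, ST5 %.4g | fl/ST4 %.2f, ST5 share %.1f%%\n",
    x$fl, x$st4, x$st5, x$ratio_fl_st4, 100 * x$st5_share))
  invisible(x)
}

#' Expression table from a Ct triplicate table
#'
#' Averages each sample x gene triplicate, normalises the three isoforms
#' to the sample's GAPDH Ct, and derives the per-sample isoform profile.
#'
#' @param ct A data frame with columns `sample_id`, `gene`
#'   (flTSHR, ST4, ST5, GAPDH), `ct1`, `ct2`, `ct3`, e.g. from
#'   [simulate_qpcr_cohort()] or [read_ct_table()].
#' @param cv_limit Triplicate CV threshold (see [average_triplicate()]).
#' @param efficiency Amplification factor (see [normalize_expression()]).
#' @return A data frame with one row per sample: expression of each
#'   isoform, the isoform ratios and ST5 share, and `cv_qc_pass`
#'   (all four triplicates within the CV limit).
#' @export
expression_table <- function(ct, cv_limit = 0.15, efficiency = 2) {
  stopifnot(is.data.frame(ct),
            all(c("sample_id", "gene", "ct1", "ct2", "ct3") %in% names(ct)))
  genes <- c("flTSHR", "ST4", "ST5", "GAPDH")
  out <- lapply(split(ct, ct$sample_id), function(d) {
    if (!all(genes %in% d$gene)) {
      stopf("sample %s lacks a Ct record for %s", d$sample_id[1],
            paste(setdiff(genes, d$gene), collapse = ", "))
    }
    avg <- lapply(genes, function(g) {
      row <- d[d$gene == g, , drop = FALSE][1, ]
      average_triplicate(c(row$ct1, row$ct2, row$ct3), cv_limit)
    })
    names(avg) <- genes
    expr <- vapply(c("flTSHR", "ST4", "ST5"), function(g)
      normalize_expression(avg[[g]]$mean_ct, avg[["GAPDH"]]$mean_ct,
                           efficiency), numeric(1))
    prof <- isoform_profile(expr[["flTSHR"]], expr[["ST4"]], expr[["ST5"]])
    data.frame(sample_id = d$sample_id[1],
               flTSHR = expr[["flTSHR"]], ST4 = expr[["ST4"]],
               ST5 = expr[["ST5"]],
               ratio_fl_st4 = prof$ratio_fl_st4,
               ratio_st4_fl = prof$st4 / prof$fl,
               ratio_st5_fl = prof$st5 / prof$fl,
               st5_share = prof$st5_share,
               cv_qc_pass = all(vapply(avg, `[[`, logical(1), "qc_pass")),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

risk_alleles <- c(rs179247 = "A", rs12101255 = "T", rs2288495 = "T")

count_risk_alleles <- function(genotypes, risk_allele) {
  vapply(strsplit(genotypes, "", fixed = TRUE),
         function(g) sum(g == risk_allele), integer(1))
}

#' Genotype-association analysis of splicing endpoints
#'
#' Groups a per-sample endpoint (ST4 or ST5 expression, or their ratio
#' to flTSHR) by SNP genotype and tests for an effect. The codominant
#' model compares the three genotype groups by Kruskal-Wallis with
#' Dunn's post hoc; the dominant and recessive models collapse to two
#' groups around the risk allele (dominant: carriers vs non-carriers;
#' recessive: risk homozygotes vs the rest) and use Mann-Whitney.
#'
#' @param values Numeric endpoint per sample.
#' @param genotypes Genotype strings (e.g. "AA", "AG", "GG") parallel to
#'   `values`.
#' @param model "codominant", "dominant" or "recessive".
#' @param risk_allele Single base defining the risk orientation for the
#'   two-group collapses (A for rs179247, T for rs12101255).
#' @return A `tshr_stat` (with `pairwise` filled for the codominant
#'   model), or, when a required group is empty or has n < 2, a list of
#'   class `tshr_skipped` with the reason.
#' @export
genotype_splicing_analysis <- function(values, genotypes,
                                       model = c("codominant", "dominant",
                                                 "recessive"),
                                       risk_allele = "A") {
  model <- match.arg(model)
  stopifnot(length(values) == length(genotypes))
  ok <- is.finite(values) & !is.na(genotypes)
  values <- values[ok]; genotypes <- genotypes[ok]
  skipped <- function(reason) structure(list(skipped = TRUE, reason = reason,
                                             model = model),
                                        class = "tshr_skipped")
  if (model == "codominant") {
    groups <- split(values, genotypes)
    groups <- groups[lengths(groups) > 0L]
    if (length(groups) < 2L) {
      return(skipped("fewer than two genotype groups present"))
    }
    if (any(lengths(groups) < 2L)) {
      return(skipped(sprintf("genotype group(s) with n < 2: %s",
                             paste(names(groups)[lengths(groups) < 2L],
                                   collapse = ", "))))
    }
    kw <- kruskal_wallis(groups)
    kw$pairwise <- dunns_test(groups)$pairwise
    kw$test_name <- "Kruskal-Wallis + Dunn (codominant)"
    return(kw)
  }
  n_risk <- count_risk_alleles(genotypes, risk_allele)
  grp <- if (model == "recessive") n_risk == 2L else n_risk >= 1L
  lab <- if (model == "recessive") c("risk_hom", "other")
         else c("carrier", "non_carrier")
  x <- values[grp]; y <- values[!grp]
  if (length(x) < 2L || length(y) < 2L) {
    return(skipped(sprintf("%s model group(s) with n < 2", model)))
  }
  mw <- mann_whitney_u(x, y)
  names(mw$groups)[1] <- "group"
  mw$groups$group <- lab
  mw$test_name <- sprintf("Mann-Whitney U (%s model, risk allele %s)",
                          model, risk_allele)
  mw
}

#' @export
print.tshr_skipped <- function(x, ...) {
  cat(sprintf("Analysis skipped (%s model): %s\n", x$model, x$reason))
  invisible(x)
}

#' Pediatric-vs-adult expression contrast
#'
#' Welch t test of an expression endpoint between two age bands, with
#' group means and SEM, as used for thymic flTSHR involution.
#'
#' @param expression Numeric expression per sample.
#' @param age Ages in years, parallel to `expression`.
#' @param bands List of two numeric ranges (inclusive), default
#'   pediatric 0-11 y vs adult 40-80 y.
#' @return A `tshr_stat`; errors if either band has n < 2.
#' @export
age_group_comparison <- function(expression, age,
                                 bands = list(pediatric = c(0, 11),
                                              adult = c(40, 80))) {
  stopifnot(length(expression) == length(age), length(bands) == 2L)
  sel <- lapply(bands, function(b) expression[age >= b[1] & age <= b[2]])
  if (any(lengths(sel) < 2L)) {
    stopf("each age band needs n >= 2 (got %s)",
          paste(lengths(sel), collapse = ", "))
  }
  tt <- t_test(sel[[1]], sel[[2]], welch = TRUE)
  names(tt$groups)[1] <- "group"
  tt$groups$group <- names(bands)
  tt$test_name <- "Welch t (age bands)"
  tt
}
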