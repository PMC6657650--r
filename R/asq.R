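# Cohort-level allele-specific quantification: per-sample results,
# tissue-by-material summaries with imbalance tests, and the
# human-readable per-sample report.

#' Build per-sample ASQ results from allele counts
#'
#' Assembles the per-sample table downstream summaries consume:
#' frequency and G/A ratio from [allele_stats()], QC from [qc_sample()].
#'
#' @param counts A list of [allele_count()] objects.
#' @param sample_id,tissue,material Character vectors parallel to
#'   `counts` (`tissue` in {thymus, thyroid}, `material` in
#'   {gDNA, cDNA}).
#' @param balance_band,min_depth Passed to [qc_sample()].
#' @return A data frame with one row per sample x material:
#'   `sample_id`, `tissue`, `material`, `depth`, `count_alt`,
#'   `count_ref`, `count_other`, `balance`, `frequency_alt`, `ratio_ga`,
#'   `qc_pass`, `qc_reasons`.
#' @export
asq_results <- function(counts, sample_id, tissue, material,
                        balance_band = c(0.4, 0.6), min_depth = 100L) {
  stopifnot(length(counts) == length(sample_id),
            length(counts) == length(tissue),
            length(counts) == length(material))
  if (!all(tissue %in% c("thymus", "thyroid"))) {
    stopf("`tissue` must be 'thymus' or 'thyroid'")
  }
  if (!all(material %in% c("gDNA", "cDNA"))) {
    stopf("`material` must be 'gDNA' or 'cDNA'")
  }
  rows <- lapply(seq_along(counts), function(i) {
    ac <- counts[[i]]
    stopifnot(inherits(ac, "allele_count"))
    qc <- qc_sample(ac, balance_band = balance_band, min_depth = min_depth)
    if (ac$depth > 0L) {
      st <- allele_stats(ac)
      freq <- st$frequency_alt; ratio <- st$ratio_ga
      if (length(st$flags)) qc$reasons <- c(qc$reasons, st$flags)
    } else {
      freq <- NA_real_; ratio <- NA_real_
    }
    data.frame(sample_id = sample_id[i], tissue = tissue[i],
               material = material[i], depth = ac$depth,
               count_alt = ac$count_alt, count_ref = ac$count_ref,
               count_other = ac$count_other, balance = ac$balance,
               frequency_alt = freq, ratio_ga = ratio,
               qc_pass = qc$qc_pass && ac$depth > 0L,
               qc_reasons = paste(qc$reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tissue-level allelic-imbalance summary
#'
#' Summarises QC-passing samples by tissue x material group (n, mean,
#' SD, min, max of the G-allele frequency and the G/A ratio) and runs
#' the between-group tests: Kruskal-Wallis with Dunn's post hoc across
#' all four groups on the G/A ratio, and a t test (Welch by default) for
#' the headline thymus-vs-thyroid cDNA contrast on both the ratio and
#' the frequency. Both test families are reported; neither is
#' privileged.
#'
#' @param results A data frame from [asq_results()] (or the Table 1
#'   fixture via [fixture_asq_results()]). Only rows with
#'   `qc_pass = TRUE` enter the summary; callers wanting the
#'   heterozygote-only analysis should subset before calling.
#' @param welch Use Welch's t test for the cDNA contrast (default TRUE).
#' @return An object of class `asq_summary`: list with `groups` (one row
#'   per tissue x material: descriptives of frequency and ratio, SD
#'   omitted with a flag for n < 2), `kruskal`, `dunn` (on ratios across
#'   groups), `t_cdna_ratio`, `t_cdna_frequency`, and `n_excluded`.
#' @export
cohort_asq_summary <- function(results, welch = TRUE) {
  stopifnot(is.data.frame(results),
            all(c("tissue", "material", "frequency_alt", "ratio_ga") %in%
                  names(results)))
  n_excluded <- sum(!results$qc_pass)
  res <- results[results$qc_pass & is.finite(results$ratio_ga), , drop = FALSE]
  if (nrow(res) == 0L) stopf("no QC-passing samples to summarise")
  res$group <- paste(res$tissue, res$material, sep = ".")
  groups <- split(res, res$group)
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    n <- nrow(d)
    data.frame(
      tissue = d$tissue[1], material = d$material[1], n = n,
      mean_frequency = mean(d$frequency_alt),
      sd_frequency = if (n >= 2) stats::sd(d$frequency_alt) else NA_real_,
      min_frequency = min(d$frequency_alt),
      max_frequency = max(d$frequency_alt),
      mean_ratio = mean(d$ratio_ga),
      sd_ratio = if (n >= 2) stats::sd(d$ratio_ga) else NA_real_,
      min_ratio = min(d$ratio_ga), max_ratio = max(d$ratio_ga),
      sd_flag = n < 2,
      stringsAsFactors = FALSE)
  }))
  ratio_groups <- lapply(groups, function(d) d$ratio_ga)
  kw <- if (length(ratio_groups) >= 2) kruskal_wallis(ratio_groups) else NULL
  dn <- if (length(ratio_groups) >= 2) dunns_test(ratio_groups) else NULL
  cdna <- res[res$material == "cDNA", , drop = FALSE]
  t_ratio <- t_freq <- NULL
  if (all(c("thymus", "thyroid") %in% cdna$tissue)) {
    tm <- cdna[cdna$tissue == "thymus", ]
    ty <- cdna[cdna$tissue == "thyroid", ]
    if (nrow(tm) >= 2 && nrow(ty) >= 2) {
      t_ratio <- t_test(tm$ratio_ga, ty$ratio_ga, welch = welch)
      t_freq <- t_test(tm$frequency_alt, ty$frequency_alt, welch = welch)
    }
  }
  structure(list(groups = summ, kruskal = kw, dunn = dn,
                 t_cdna_ratio = t_ratio, t_cdna_frequency = t_freq,
                 n_excluded = n_excluded),
            class = "asq_summary")
}

#' @export
print.asq_summary <- function(x, ...) {
  cat("Allele-specific quantification summary (G = protective allele)\n")
  g <- x$groups
  for (i in seq_len(nrow(g))) {
    cat(sprintf(
      "  %-7s %-5s n=%2d  freq %.1f%% [%.1f-%.1f]  G/A ratio %.1f +/- %s\n",
      g$tissue[i], g$material[i], g$n[i], g$mean_frequency[i],
      g$min_frequency[i], g$max_frequency[i], g$mean_ratio[i],
      ifelse(is.na(g$sd_ratio[i]), "NA", sprintf("%.1f", g$sd_ratio[i]))))
  }
  if (!is.null(x$kruskal)) {
    cat(sprintf("  Kruskal-Wallis on G/A ratios: H = %.3f, p = %.3g\n",
                x$kruskal$statistic, x$kruskal$p_value))
  }
  if (!is.null(x$t_cdna_ratio)) {
    cat(sprintf("  Thymus vs thyroid cDNA ratio (%s): t = %.3f, p = %.3g\n",
                x$t_cdna_ratio$test_name, x$t_cdna_ratio$statistic,
                x$t_cdna_ratio$p_value))
  }
  if (x$n_excluded > 0) cat(sprintf("  (%d sample(s) excluded by QC)\n",
                                    x$n_excluded))
  invisible(x)
}

#' Format the per-sample report table
#'
#' Renders one row per sample x material in the assay's report layout:
#' depth as "<n>x", balance at 2 decimals, G-allele counts with a
#' thousands separator, frequency at 2 decimals ("NA" at depth 0).
#'
#' @param results A data frame from [asq_results()] or
#'   [fixture_asq_results()].
#' @return A character vector of tab-separated lines (header first), of
#'   class `table1_report`. [parse_table1_report()] inverts it.
#' @export
table1_report <- function(results) {
  stopifnot(is.data.frame(results))
  header <- paste(c("sample", "tissue", "material", "depth", "balance",
                    "counts_g", "frequency_g_pct"), collapse = "\t")
  lines <- vapply(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    paste(c(r$sample_id, r$tissue, r$material,
            paste0(r$depth, "x"),
            ifelse(is.na(r$balance), "NA", sprintf("%.2f", r$balance)),
            formatC(r$count_alt, big.mark = ",", format = "d"),
            ifelse(r$depth > 0, sprintf("%.2f", 100 * r$count_alt / r$depth),
                   "NA")),
          collapse = "\t")
  }, character(1))
  structure(c(header, lines), class = "table1_report")
}

#' @export
print.table1_report <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}

#' Parse a formatted per-sample report back into counts
#'
#' Exact inverse of [table1_report()] for the integer fields (depth,
#' G counts); balance and frequency come back at their printed 2-decimal
#' precision.
#'
#' @param lines Character vector as produced by [table1_report()].
#' @return A data frame with columns `sample_id`, `tissue`, `material`,
#'   `depth`, `count_alt`, `balance`, `frequency_alt`.
#' @export
parse_table1_report <- function(lines) {
  lines <- unclass(lines)
  if (length(lines) < 1L) stopf("empty report")
  body <- lines[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 7L)
  if (length(bad)) stopf("malformed report line %d", bad[1] + 1L)
  m <- do.call(rbind, parts)
  data.frame(
    sample_id = m[, 1], tissue = m[, 2], material = m[, 3],
    depth = as.integer(sub("x$", "", m[, 4])),
    count_alt = as.integer(gsub(",", "", m[, 6], fixed = TRUE)),
    balance = suppressWarnings(as.numeric(m[, 5])),
    frequency_alt = suppressWarnings(as.numeric(m[, 7])),
    stringsAsFactors = FALSE)
}
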