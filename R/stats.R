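# Statistical tests used by the ASQ and qPCR analyses. Base R carries the
# computations (wilcox.test, kruskal.test, t.test, quantile); the wrappers
# pin down the conventions the pipeline relies on (exact-vs-approximate
# switching, tie handling, zero-variance guards) and return a uniform
# result object with group descriptives.

new_stat_result <- function(test_name, statistic, p_value, groups = NULL,
                            pairwise = NULL, flags = character(0)) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(
    list(test_name = test_name, statistic = statistic, p_value = p_value,
         groups = groups, pairwise = pairwise, flags = flags),
    class = "tshr_stat"
  )
}

#' @export
print.tshr_stat <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  if (!is.null(x$groups)) {
    cat("Group descriptives:\n")
    print(x$groups, digits = 4)
  }
  if (!is.null(x$pairwise)) {
    cat("Pairwise comparisons:\n")
    print(x$pairwise, digits = 4)
  }
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Descriptive statistics
#'
#' Returns the descriptives the analyses report: mean with sample SD
#' (n - 1) and SEM, and median with linear-interpolation (type 7)
#' quartiles, IQR and semi-interquartile range (SIR = IQR/2).
#'
#' @param x Numeric vector, n >= 1.
#' @return A one-row data frame with columns `n`, `mean`, `sd`, `sem`,
#'   `median`, `iqr`, `sir`, `min`, `max`. For n = 1, `sd` and `sem` are
#'   `NA` and the result carries attribute `flag = "sd_undefined"`.
#' @export
descriptive <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 1L || anyNA(x)) stopf("`x` must be non-empty and NA-free")
  n <- length(x)
  s <- if (n > 1L) stats::sd(x) else NA_real_
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  out <- data.frame(n = n, mean = mean(x), sd = s,
                    sem = if (n > 1L) s / sqrt(n) else NA_real_,
                    median = stats::median(x), iqr = q[2] - q[1],
                    sir = (q[2] - q[1]) / 2, min = min(x), max = max(x))
  if (n == 1L) attr(out, "flag") <- "sd_undefined"
  out
}

group_descriptives <- function(groups) {
  do.call(rbind, lapply(names(groups), function(nm) {
    d <- descriptive(groups[[nm]])
    cbind(group = nm, d, stringsAsFactors = FALSE)
  }))
}

#' Mann-Whitney U test
#'
#' Two-sided by default. The exact null distribution is used for small
#' tie-free samples (combined n <= 12); otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param alternative One of "two.sided", "less", "greater".
#' @return A `tshr_stat` with the U statistic (number of (x, y) pairs
#'   with x before y in rank order, as in `wilcox.test`), the p-value,
#'   and per-group descriptives.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) stopf("both groups must be non-empty")
  has_ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 12L) && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = exact, correct = TRUE))
  new_stat_result("Mann-Whitney U", unname(wt$statistic),
                  min(1, wt$p.value),
                  groups = group_descriptives(list(x = x, y = y)),
                  flags = if (exact) "exact" else "normal_approximation")
}

# Tie-corrected Kruskal-Wallis H on a list of groups; returns the pieces
# Dunn's test reuses (pooled ranks, tie term).
kw_pieces <- function(groups) {
  v <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(v)
  r <- rank(v)
  tie_tab <- table(v)
  tie_term <- sum(tie_tab^3 - tie_tab)
  rbar <- tapply(r, g, mean)
  n_i <- lengths(groups)
  H0 <- 12 / (N * (N + 1)) * sum(n_i * (rbar - (N + 1) / 2)^2)
  C <- 1 - tie_term / (N^3 - N)
  list(H = if (C > 0) H0 / C else 0, N = N, ranks = r, g = g,
       tie_term = tie_term, n_i = n_i, rbar = rbar)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H compared to the chi-square distribution with k - 1
#' degrees of freedom. A fully degenerate input (all values identical)
#' returns H = 0, p = 1 rather than an error.
#'
#' @param groups A list of numeric vectors (>= 2 groups, each n >= 1,
#'   total N >= 3).
#' @return A `tshr_stat` with H, p, and per-group descriptives.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 2L || any(lengths(groups) < 1L) ||
      sum(lengths(groups)) < 3L) {
    stopf("need >= 2 groups, each non-empty, total N >= 3")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  v <- unlist(groups, use.names = FALSE)
  if (length(unique(v)) == 1L) {
    return(new_stat_result("Kruskal-Wallis", 0, 1,
                           groups = group_descriptives(groups),
                           flags = "degenerate_all_equal"))
  }
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kt <- stats::kruskal.test(v, g)
  new_stat_result("Kruskal-Wallis", unname(kt$statistic),
                  min(1, kt$p.value),
                  groups = group_descriptives(groups))
}

#' Dunn's post hoc test
#'
#' Pairwise z statistics on mean ranks with the pooled tie-corrected
#' variance, following a Kruskal-Wallis test. P-values are two-sided and
#' adjusted for the number of comparisons by Bonferroni multiplication
#' (capped at 1), the "multiple comparison test" convention of common
#' graphing software; Holm is available as an option.
#'
#' @param groups A list of >= 2 numeric groups.
#' @param p_adjust "bonferroni" (default) or "holm".
#' @return A `tshr_stat` whose `pairwise` element is a data frame with
#'   columns `group1`, `group2`, `z`, `p`, `p_adjusted`.
#' @export
dunns_test <- function(groups, p_adjust = c("bonferroni", "holm")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(is.list(groups))
  if (length(groups) < 2L) stopf("Dunn's test needs >= 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  kp <- kw_pieces(groups)
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  degenerate <- length(unique(unlist(groups, use.names = FALSE))) == 1L
  res <- data.frame(group1 = names(groups)[pairs[1, ]],
                    group2 = names(groups)[pairs[2, ]],
                    z = numeric(m), p = numeric(m), p_adjusted = numeric(m),
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    if (degenerate) {
      res$z[j] <- 0; res$p[j] <- 1
      next
    }
    se <- sqrt((kp$N * (kp$N + 1) / 12 -
                  kp$tie_term / (12 * (kp$N - 1))) *
                 (1 / kp$n_i[i1] + 1 / kp$n_i[i2]))
    z <- (kp$rbar[[i1]] - kp$rbar[[i2]]) / se
    res$z[j] <- z
    res$p[j] <- 2 * stats::pnorm(-abs(z))
  }
  res$p_adjusted <- switch(p_adjust,
    bonferroni = pmin(1, res$p * m),
    holm = stats::p.adjust(res$p, method = "holm"))
  new_stat_result("Dunn's post hoc", NA_real_, NA_real_,
                  groups = group_descriptives(groups), pairwise = res,
                  flags = p_adjust)
}

#' Two-sample t test
#'
#' Welch's unequal-variance form by default; Student's pooled form on
#' request. Two-sided. Degenerate zero-variance inputs are handled:
#' identical constant groups give p = 1, separated constant groups give
#' the p -> 0 sentinel with a `zero_variance` flag.
#'
#' @param x,y Numeric samples, each n >= 2.
#' @param welch Use Welch's unequal-variance test (default `TRUE`).
#' @return A `tshr_stat` with t, p, and per-group descriptives.
#' @export
t_test <- function(x, y, welch = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) stopf("both groups need n >= 2")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(new_stat_result("Welch t", 0, 1,
                             groups = group_descriptives(list(x = x, y = y)),
                             flags = "zero_variance"))
    }
    return(new_stat_result("Welch t", Inf, 0,
                           groups = group_descriptives(list(x = x, y = y)),
                           flags = "zero_variance"))
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  new_stat_result(if (welch) "Welch t" else "Student t",
                  unname(tt$statistic), min(1, tt$p.value),
                  groups = group_descriptives(list(x = x, y = y)))
}
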