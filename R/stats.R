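# Group-comparison statistics.  Every function returns a `qs_stat` row so a
# whole study's p-values can be pooled and corrected jointly at the end
# (the study-wide Benjamini-Hochberg pass).

qs_stat <- function(test, statistic, p_raw, effect, n1, n2 = NA_integer_,
                    extra = NULL) {
  out <- data.frame(test = test, statistic = statistic, p_raw = p_raw,
                    p_adj = NA_real_, effect = effect,
                    n1 = n1, n2 = n2, stringsAsFactors = FALSE)
  if (!is.null(extra)) attr(out, "extra") <- extra
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null distribution when the smaller sample has at most 8
#' observations and the pooled data are tie-free; otherwise the normal
#' approximation with continuity and tie correction.  The effect summary is
#' the difference of medians (x minus y).
#'
#' @param x,y Numeric samples (non-empty).
#' @param test Label recorded in the result row.
#' @return A one-row `data.frame` with columns `test`, `statistic`
#'   (rank-sum W), `p_raw`, `p_adj` (`NA` until the study-wide pass),
#'   `effect`, `n1`, `n2`.
#' @export
wilcoxon_rank_sum <- function(x, y, test = "wilcoxon") {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  qs_stat(test, unname(wt$statistic), wt$p.value,
          stats::median(x) - stats::median(y), length(x), length(y))
}

#' Wilson score confidence interval for a proportion
#'
#' @param k Number of successes.
#' @param n Number of trials (>= 1).
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Two-proportion test with per-group Wilson intervals
#'
#' Two-sided chi-square test of equal proportions with continuity
#' correction; each group additionally gets a Wilson 95% confidence
#' interval (attached as the `extra` attribute and as columns).
#'
#' @param k1,n1,k2,n2 Successes and trials per group.
#' @inheritParams wilcoxon_rank_sum
#' @return One-row `data.frame`; `effect` is the proportion difference, and
#'   columns `ci1_lower`, `ci1_upper`, `ci2_lower`, `ci2_upper` carry the
#'   Wilson intervals.
#' @export
prop_test_ci <- function(k1, n1, k2, n2, test = "prop") {
  if (n1 < 1 || n2 < 1) stop("group sizes must be >= 1")
  pt <- suppressWarnings(stats::prop.test(c(k1, k2), c(n1, n2),
                                          correct = TRUE))
  ci1 <- wilson_ci(k1, n1)
  ci2 <- wilson_ci(k2, n2)
  out <- qs_stat(test, unname(pt$statistic), pt$p.value,
                 k1 / n1 - k2 / n2, n1, n2)
  out$ci1_lower <- ci1[1]; out$ci1_upper <- ci1[2]
  out$ci2_lower <- ci2[1]; out$ci2_upper <- ci2[2]
  out
}

#' ANCOVA group effect with one covariate
#'
#' Ordinary least squares `y ~ group + covariate` (no interaction); the
#' result is the two-sided t-test of the group coefficient, with the
#' coefficient itself as the effect estimate.  Residual diagnostics
#' (Shapiro normality p, Breusch-Pagan-style heteroscedasticity p) are
#' attached for inspection rather than auto-remediation.
#'
#' @param y Numeric response.
#' @param group Two-level factor (or coercible); >= 3 observations per level.
#' @param covariate Numeric covariate.
#' @inheritParams wilcoxon_rank_sum
#' @return One-row `data.frame`; `attr(, "extra")` holds diagnostics.
#' @export
ancova_group_effect <- function(y, group, covariate, test = "ancova") {
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (min(table(group)) < 3) stop("need >= 3 observations per group")
  if (stats::var(covariate) == 0 ||
      abs(stats::cor(as.numeric(group), covariate)) > 1 - 1e-12)
    stop("covariate collinear with group or constant")
  fit <- stats::lm(y ~ group + covariate)
  sm <- summary(fit)$coefficients
  row <- grep("^group", rownames(sm))
  res <- stats::residuals(fit)
  diag <- list(
    shapiro_p = if (length(res) >= 3 && length(res) <= 5000)
      stats::shapiro.test(res)$p.value else NA_real_,
    bp_p = tryCatch(
      stats::anova(stats::lm(res^2 ~ stats::fitted(fit)))[["Pr(>F)"]][1],
      error = function(e) NA_real_))
  qs_stat(test, sm[row, "t value"], sm[row, "Pr(>|t|)"],
          sm[row, "Estimate"], sum(group == levels(group)[1]),
          sum(group == levels(group)[2]), extra = diag)
}

#' Spearman partial correlation
#'
#' Ranks all three variables, computes the first-order partial correlation
#' of x and y given z on the ranks, and tests it two-sidedly with the
#' t-approximation on n - 3 degrees of freedom.
#'
#' @param x,y,z Numeric vectors of equal length >= 4.
#' @inheritParams wilcoxon_rank_sum
#' @return One-row `data.frame` (`effect` = partial rho); a zero-variance
#'   input yields `NA` statistic and p rather than an error.
#' @export
spearman_partial <- function(x, y, z, test = "spearman_partial") {
  n <- length(x)
  if (length(y) != n || length(z) != n || n < 4)
    stop("x, y, z must have equal length >= 4")
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  if (stats::var(rx) == 0 || stats::var(ry) == 0 || stats::var(rz) == 0)
    return(qs_stat(test, NA_real_, NA_real_, NA_real_, n))
  rxy <- stats::cor(rx, ry); rxz <- stats::cor(rx, rz); ryz <- stats::cor(ry, rz)
  den <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (den == 0) return(qs_stat(test, NA_real_, NA_real_, NA_real_, n))
  rho <- (rxy - rxz * ryz) / den
  rho <- min(max(rho, -1), 1)
  tval <- rho * sqrt((n - 3) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = n - 3)
  qs_stat(test, tval, p, rho, n)
}

#' Benjamini-Hochberg adjustment across a study
#'
#' Standard step-up FDR adjustment (monotone, capped at 1), mapped back to
#' input order.  The pipeline collects every p-value a run produces and
#' corrects them jointly in one pass.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (`NA`s passed
#'   through).
#' @return Adjusted p-values, same length and order.
#' @export
bh_correct <- function(p) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Bind heterogeneous test-result rows into one table
#'
#' Pads columns (e.g. the Wilson CI columns only proportion tests carry)
#' with `NA` so rows from different tests stack.
#'
#' @param rows List of one-row `qs_stat` data frames.
#' @return A single data frame.
#' @export
rbind_stats <- function(rows) {
  rows <- rows[!vapply(rows, is.null, logical(1))]
  cols <- unique(unlist(lapply(rows, names)))
  do.call(rbind, lapply(rows, function(r) {
    for (cn in setdiff(cols, names(r))) r[[cn]] <- NA_real_
    r[cols]
  }))
}

#' Apply the study-wide BH pass to a results table
#'
#' @param results Data frame of `qs_stat` rows (column `p_raw`).
#' @return The table with `p_adj` filled.
#' @export
finalize_results <- function(results) {
  results$p_adj <- bh_correct(results$p_raw)
  results
}
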