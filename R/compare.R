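#' Systematic gamma-counter correction factor
#'
#' A gamma counter calibrated with a surrogate isotope reads carbon-11
#' activity with a roughly constant multiplicative bias relative to the
#' absolute (mass-based) LC-MS/MS determination.  The per-preparation
#' correction factor is estimated as the geometric mean of the
#' gamma/reference ratios — the maximum-likelihood estimator for a shared
#' multiplicative factor under lognormal noise.  A corrected gamma value is
#' `gamma / factor`.
#'
#' @param gamma_values Positive gamma-counter readings.
#' @param reference_values Matching positive reference (LC-MS/MS based)
#'   values, same length >= 1.
#' @return The unitless correction factor.
#' @examples
#' gamma_correction_factor(2349, 1726)   # 1.361
#' @export
gamma_correction_factor <- function(gamma_values, reference_values) {
  if (length(gamma_values) != length(reference_values) ||
      length(gamma_values) < 1)
    .stopf("need >= 1 (gamma, reference) pair of equal length")
  if (any(gamma_values <= 0) || any(reference_values <= 0))
    .stopf("all values must be > 0")
  .geomean(gamma_values / reference_values)
}

#' @rdname gamma_correction_factor
#' @param x Values to correct (vectorized).
#' @param factor A correction factor from `gamma_correction_factor()`.
#' @export
apply_gamma_correction <- function(x, factor) {
  .check_scalar(factor, "factor", positive = TRUE)
  x / factor
}

#' Percent by which a value falls below a reference
#'
#' `100 * (reference - a) / reference`: the convention used when one
#' method's AUC is reported as "X% lower" than a reference method's.
#'
#' @param a Value under test.
#' @param reference Reference value, > 0.
#' @return Percent difference (positive when `a < reference`).
#' @examples
#' percent_lower(368, 536)  # 31.3 -> "31% lower"
#' @export
percent_lower <- function(a, reference) {
  if (any(reference <= 0)) .stopf("'reference' must be > 0")
  100 * (reference - a) / reference
}

#' Test-retest style variability between two measurements
#'
#' Absolute difference divided by the mean of the pair, in percent:
#' `100 * |a - b| / ((a + b)/2)`.  Symmetric in its arguments.
#'
#' @param a,b Measurements; `a + b > 0`.
#' @return Percent variability.
#' @export
var_percent <- function(a, b) {
  if (any(a + b <= 0)) .stopf("var_percent undefined when a + b <= 0")
  100 * abs(a - b) / ((a + b) / 2)
}

#' Absolute-agreement intraclass correlation (single measures)
#'
#' Two-way model, absolute-agreement, single-measures ICC — ICC(A,1) —
#' from the standard mean-squares decomposition of an n subjects x k
#' methods table:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the row (subject), column
#' (method), and error mean squares.  Unlike Pearson's r, this penalizes a
#' constant offset between methods, which is why correcting a systematic
#' bias raises the ICC while leaving r unchanged.
#'
#' @param a,b Paired measurements from the two methods, length n >= 3.
#' @return The ICC (<= 1).  Identical series return exactly 1; degenerate
#'   input (zero variance but non-identical) is an error.
#' @export
icc_absolute_agreement <- function(a, b) {
  n <- length(a)
  if (length(b) != n || n < 3) .stopf("need >= 3 pairs of equal length")
  if (identical(all.equal(a, b, tolerance = 0), TRUE) || all(a == b))
    return(1)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    .stopf("degenerate input: zero variance in both series")
  k <- 2
  m <- cbind(a, b)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Paired t test and Pearson correlation for method pairs
#'
#' Thin wrappers with the conventions used throughout the package: the
#' paired t statistic is `mean(d)/(sd(d)/sqrt(n))` with a two-sided p from
#' the t distribution on n - 1 degrees of freedom; identical series give
#' t = 0, p = 1.
#'
#' @param a,b Paired measurements, length n >= 2.
#' @return `paired_t()`: list with `t_stat`, `p_value`, `df`.
#'   `pearson_r()`: the correlation coefficient.
#' @export
paired_t <- function(a, b) {
  n <- length(a)
  if (length(b) != n || n < 2) .stopf("need >= 2 pairs of equal length")
  d <- a - b
  scale <- max(abs(c(a, b)), 1e-300)
  if (all(abs(d) <= 1e-12 * scale))
    return(list(t_stat = 0, p_value = 1, df = n - 1L))
  if (stats::sd(d) <= 1e-12 * scale)
    .stopf("zero variance of differences with non-zero mean: t undefined")
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t_stat = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' @rdname paired_t
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    .stopf("need >= 2 pairs of equal length")
  stats::cor(a, b)
}

#' Full method comparison between an LC-MS/MS AIF and radiometric AIFs
#'
#' Computes, per subject, trapezoidal AUCs for the LC-MS/MS AIF and the
#' uncorrected and corrected radiometric AIFs, then the across-subject
#' comparison statistics: mean percent-lower differences, per-subject
#' mean-based percent differences (VAR form), Pearson r, absolute-agreement
#' ICC, and paired t tests.
#'
#' @param auc_lcms,auc_rad_uncorrected,auc_rad_corrected Numeric vectors of
#'   per-subject AUCs (kBq x min/mL), equal length.
#' @return Object of class `method_comparison` (a list; see fields).
#' @export
compare_aif_methods <- function(auc_lcms, auc_rad_uncorrected,
                                auc_rad_corrected) {
  n <- length(auc_lcms)
  if (length(auc_rad_uncorrected) != n || length(auc_rad_corrected) != n)
    .stopf("AUC vectors must have equal length")
  small <- n < 3
  if (small)
    warning("fewer than 3 subjects: VAR summaries and ICC suppressed",
            call. = FALSE)
  res <- list(
    n = n,
    auc_lcms_mean = mean(auc_lcms),
    auc_rad_uncorrected_mean = mean(auc_rad_uncorrected),
    auc_rad_corrected_mean = mean(auc_rad_corrected),
    auc_lcms_sd = stats::sd(auc_lcms),
    auc_rad_uncorrected_sd = stats::sd(auc_rad_uncorrected),
    auc_rad_corrected_sd = stats::sd(auc_rad_corrected),
    pct_diff_uncorrected = percent_lower(mean(auc_lcms),
                                         mean(auc_rad_uncorrected)),
    pct_diff_corrected = percent_lower(mean(auc_lcms),
                                       mean(auc_rad_corrected)),
    var_pct_uncorrected = var_percent(auc_lcms, auc_rad_uncorrected),
    var_pct_corrected = var_percent(auc_lcms, auc_rad_corrected),
    pearson_uncorrected = if (n >= 2 && stats::sd(auc_lcms) > 0 &&
                              stats::sd(auc_rad_uncorrected) > 0)
      pearson_r(auc_lcms, auc_rad_uncorrected) else NA_real_,
    pearson_corrected = if (n >= 2 && stats::sd(auc_lcms) > 0 &&
                            stats::sd(auc_rad_corrected) > 0)
      pearson_r(auc_lcms, auc_rad_corrected) else NA_real_,
    icc_uncorrected = if (!small) icc_absolute_agreement(
                        auc_lcms, auc_rad_uncorrected) else NA_real_,
    icc_corrected = if (!small) icc_absolute_agreement(
                      auc_lcms, auc_rad_corrected) else NA_real_,
    t_uncorrected = if (n >= 2) tryCatch(
      paired_t(auc_lcms, auc_rad_uncorrected),
      error = function(e) list(t_stat = NA_real_, p_value = NA_real_,
                               df = n - 1L)) else NULL,
    t_corrected = if (n >= 2) tryCatch(
      paired_t(auc_lcms, auc_rad_corrected),
      error = function(e) list(t_stat = NA_real_, p_value = NA_real_,
                               df = n - 1L)) else NULL,
    per_subject = data.frame(
      subject = seq_len(n),
      auc_lcms = auc_lcms,
      auc_rad_uncorrected = auc_rad_uncorrected,
      auc_rad_corrected = auc_rad_corrected,
      diff_pct_uncorrected = var_percent(auc_lcms, auc_rad_uncorrected),
      diff_pct_corrected = var_percent(auc_lcms, auc_rad_corrected))
  )
  class(res) <- "method_comparison"
  res
}

#' @export
print.method_comparison <- function(x, digits = 3, ...) {
  cat("AIF method comparison (AUC, kBq x min/mL)\n")
  cat(sprintf("  n subjects: %d\n", x$n))
  cat(sprintf("  mean AUC  LC-MS/MS: %.*g   radiometric: %.*g   corrected: %.*g\n",
              digits, x$auc_lcms_mean, digits, x$auc_rad_uncorrected_mean,
              digits, x$auc_rad_corrected_mean))
  cat(sprintf("  LC-MS/MS lower than radiometric by %.1f%% (uncorrected), %.1f%% (corrected)\n",
              x$pct_diff_uncorrected, x$pct_diff_corrected))
  if (!is.na(x$icc_uncorrected))
    cat(sprintf("  VAR %.0f%% / %.0f%%, Pearson r %.2f / %.2f, ICC %.2f / %.2f (uncorr / corr)\n",
                mean(x$var_pct_uncorrected), mean(x$var_pct_corrected),
                x$pearson_uncorrected, x$pearson_corrected,
                x$icc_uncorrected, x$icc_corrected))
  if (!is.null(x$t_uncorrected))
    cat(sprintf("  paired t: %.3g (p = %.3g) uncorrected, %.3g (p = %.3g) corrected\n",
                x$t_uncorrected$t_stat, x$t_uncorrected$p_value,
                x$t_corrected$t_stat, x$t_corrected$p_value))
  invisible(x)
}
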