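# Internal helpers shared across modules.

#' @noRd
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
.check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                          finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    .stopf("'%s' must be a single non-missing number", name)
  if (finite && !is.finite(x)) .stopf("'%s' must be finite", name)
  if (positive && x <= 0) .stopf("'%s' must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) .stopf("'%s' must be >= 0 (got %g)", name, x)
  invisible(x)
}

#' @noRd
.check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    .stopf("%s is missing required column(s): %s", what,
           paste(missing, collapse = ", "))
  invisible(df)
}

# Lognormal multiplicative noise with unit mean and coefficient of variation
# cv.  cv = 0 returns exact ones so that zero-noise worlds are bit-exact.
#' @noRd
.lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' @noRd
.geomean <- function(x) exp(mean(log(x)))
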