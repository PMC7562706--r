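#' Sampled time series (concentration or activity concentration)
#'
#' A minimal container for an arterial sampling curve: strictly increasing
#' times (minutes post-injection) with non-negative values in a declared
#' unit, either `"pM"` (carrier concentration) or `"kBq/mL"` (radioactivity
#' concentration).  Dimensionless series (parent fractions) use `"1"`.
#'
#' @param times_min Sampling times, strictly increasing, >= 0.
#' @param values Measurements, same length, >= 0.
#' @param unit `"pM"`, `"kBq/mL"`, or `"1"`.
#' @return Object of class `aif_ts`.
#' @export
aif_ts <- function(times_min, values, unit = c("kBq/mL", "pM", "1")) {
  unit <- match.arg(unit)
  if (length(times_min) != length(values))
    .stopf("times and values must have equal length")
  if (length(times_min) && any(diff(times_min) <= 0))
    .stopf("times must be strictly increasing")
  if (any(!is.finite(values)) || any(values < 0))
    .stopf("values must be finite and >= 0")
  structure(list(times_min = as.numeric(times_min),
                 values = as.numeric(values), unit = unit),
            class = "aif_ts")
}

#' @export
print.aif_ts <- function(x, ...) {
  cat(sprintf("<aif_ts> %d points, %.3g-%.3g min, unit %s\n",
              length(x$times_min), min(x$times_min), max(x$times_min),
              x$unit))
  invisible(x)
}

#' @export
as.data.frame.aif_ts <- function(x, ...) {
  data.frame(time_min = x$times_min, value = x$values, unit = x$unit)
}

#' Transform a carrier concentration curve into an AIF in activity units
#'
#' Multiplies each carrier concentration by the molar activity of the
#' injected preparation: pM x GBq/umol = Bq/mL, divided by 1000 to give
#' kBq/mL.  This is the step that makes a non-radiometric AIF: the mass
#' curve measured by LC-MS/MS becomes a radioactivity curve through Am.
#'
#' @param conc An [aif_ts()] in pM.
#' @param am_gbq_per_umol Molar activity (GBq/umol), > 0.
#' @return An [aif_ts()] in kBq/mL on the same time grid.
#' @export
carrier_curve_to_activity <- function(conc, am_gbq_per_umol) {
  stopifnot(inherits(conc, "aif_ts"))
  if (conc$unit != "pM")
    .stopf("expected a pM concentration curve, got unit '%s'", conc$unit)
  .check_scalar(am_gbq_per_umol, "am_gbq_per_umol", positive = TRUE)
  aif_ts(conc$times_min, conc$values * am_gbq_per_umol / 1000, "kBq/mL")
}

#' @rdname carrier_curve_to_activity
#' @param activity An [aif_ts()] in kBq/mL.
#' @export
activity_curve_to_carrier <- function(activity, am_gbq_per_umol) {
  stopifnot(inherits(activity, "aif_ts"))
  if (activity$unit != "kBq/mL")
    .stopf("expected a kBq/mL activity curve, got unit '%s'", activity$unit)
  .check_scalar(am_gbq_per_umol, "am_gbq_per_umol", positive = TRUE)
  aif_ts(activity$times_min, activity$values * 1000 / am_gbq_per_umol, "pM")
}

#' Metabolite-corrected radiometric AIF
#'
#' Pointwise product of a total plasma radioactivity curve (gamma counter)
#' with the parent fraction determined by radio-HPLC.  Parent fractions on
#' a different grid are interpolated linearly onto the activity times; no
#' extrapolation beyond the measured fraction range is performed.
#'
#' @param total_activity An [aif_ts()] in kBq/mL.
#' @param parent_fraction An [aif_ts()] with unit `"1"`, values in `[0, 1]`.
#' @return An [aif_ts()] in kBq/mL (parent-only radioactivity).
#' @export
radiometric_aif <- function(total_activity, parent_fraction) {
  stopifnot(inherits(total_activity, "aif_ts"),
            inherits(parent_fraction, "aif_ts"))
  if (total_activity$unit != "kBq/mL")
    .stopf("total activity must be in kBq/mL")
  if (any(parent_fraction$values < 0) || any(parent_fraction$values > 1))
    .stopf("parent fractions must lie in [0, 1]")
  tt <- total_activity$times_min
  if (min(tt) < min(parent_fraction$times_min) ||
      max(tt) > max(parent_fraction$times_min))
    .stopf(paste0("activity times extend beyond the measured parent-",
                  "fraction range; extrapolation is not performed"))
  f <- stats::approx(parent_fraction$times_min, parent_fraction$values,
                     xout = tt, method = "linear")$y
  aif_ts(tt, total_activity$values * f, "kBq/mL")
}

#' Trapezoidal area under a sampled curve
#'
#' \eqn{\sum_i (t_{i+1}-t_i)(v_i+v_{i+1})/2} over the observed range.
#' No extrapolation to time zero or to infinity is performed.
#'
#' @param ts An [aif_ts()], or a numeric vector of values with `times`
#'   supplied.
#' @param times Sampling times when `ts` is a bare numeric vector.
#' @return Area in (value unit) x min.
#' @export
auc_trapezoid <- function(ts, times = NULL) {
  if (inherits(ts, "aif_ts")) {
    v <- ts$values; t <- ts$times_min
  } else {
    v <- ts; t <- times
    if (is.null(t)) .stopf("'times' required for a bare numeric vector")
  }
  if (length(v) < 2) .stopf("AUC requires >= 2 points")
  sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}
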