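#' 13C/12C channel ratio of a carrier
#'
#' Ratio of the peak area in the 13C-isotopologue channel to that in the
#' 12C channel, times 100.  Measured on the reference (natural-abundance)
#' compound this gives the natural M+1/M ratio of the product ion; measured
#' on the carrier in a radiotracer dose it additionally reflects cyclotron
#' 13C enrichment at the labeling site.
#'
#' @param area_13c,area_12c Peak areas (arbitrary units); `area_12c > 0`.
#' @param source `"reference_compound"` or `"dose_carrier"`.
#' @return An object of class `carrier_ratio` with field `ratio_pct`.
#' @export
ratio_13_12 <- function(area_13c, area_12c,
                        source = c("dose_carrier", "reference_compound")) {
  source <- match.arg(source)
  .check_scalar(area_13c, "area_13c", nonneg = TRUE)
  .check_scalar(area_12c, "area_12c", positive = TRUE)
  structure(list(ratio_pct = 100 * area_13c / area_12c, source = source),
            class = "carrier_ratio")
}

#' @export
print.carrier_ratio <- function(x, ...) {
  cat(sprintf("<carrier_ratio> %.4g%% (%s)\n", x$ratio_pct, x$source))
  invisible(x)
}

# Shared core: A* / (A + A*) x Am*, with A* corrected for radioactive
# molecules that carry a natural heavy isotope elsewhere in the fragment
# (they fall outside the 11C channel, so the 11C area underestimates the
# radioactive species by the factor 1/(1 + natural/100), first order).
#' @noRd
.am_core <- function(area_11c, carrier_area_sum, natural_ratio_pct,
                     constants) {
  a_star <- area_11c * (1 + natural_ratio_pct / 100)
  frac <- a_star / (carrier_area_sum + a_star)
  frac * constants$am_star_gbq_per_umol
}

#' Molar activity from the 11C/13C isotopologue pair
#'
#' Determines the molar activity \eqn{A_m} of a radiotracer preparation
#' from the peak areas of the radioactive (11C) and heavy-carrier (13C)
#' isotopologue channels alone.  Monitoring only these two channels avoids
#' saturating the detector with the far more abundant 12C species.  The 12C
#' area is reconstructed from the 13C area via the carrier's measured
#' 13C/12C ratio:
#' \deqn{A = A_{13} \times 100 / r + A_{13}, \quad
#'       A^* = A_{11} (1 + r_{nat}/100), \quad
#'       A_m = \frac{A^*}{A + A^*} A_m^*.}
#'
#' @param area_11c,area_13c Peak areas; `area_13c > 0`, `area_11c >= 0`.
#' @param carrier_ratio A [ratio_13_12()] result (or a bare percent) giving
#'   the 13C/12C ratio measured in the same carrier.
#' @param natural_ratio_pct The reference compound's natural M+1/M ratio
#'   (%), used to account for 11C molecules carrying a natural heavy
#'   isotope elsewhere in the fragment.
#' @param constants A [nuclide_constants()] object.
#' @return Object of class `molar_activity`: `am_gbq_per_umol`, `mode`.
#' @export
am_from_pair <- function(area_11c, area_13c, carrier_ratio,
                         natural_ratio_pct = 0,
                         constants = nuclide_constants()) {
  .check_scalar(area_11c, "area_11c", nonneg = TRUE)
  .check_scalar(area_13c, "area_13c", positive = TRUE)
  ratio_pct <- if (inherits(carrier_ratio, "carrier_ratio"))
    carrier_ratio$ratio_pct else carrier_ratio
  .check_scalar(ratio_pct, "carrier_ratio", positive = TRUE)
  .check_scalar(natural_ratio_pct, "natural_ratio_pct", nonneg = TRUE)
  area_12c_est <- area_13c * 100 / ratio_pct
  am <- .am_core(area_11c, area_12c_est + area_13c, natural_ratio_pct,
                 constants)
  structure(list(am_gbq_per_umol = am, mode = "pair",
                 ratio_13_12_pct = ratio_pct),
            class = "molar_activity")
}

#' Molar activity from the full 11C/12C/13C isotopologue triad
#'
#' As [am_from_pair()], but with the 12C channel measured directly (feasible
#' at high molar activity, where dilution keeps the 12C signal inside the
#' detector's linear range).  The carrier area sum is simply
#' \eqn{A = A_{12} + A_{13}}.
#'
#' @inheritParams am_from_pair
#' @param area_12c Peak area of the 12C channel, > 0.
#' @return Object of class `molar_activity` with `mode = "triad"`.
#' @export
am_from_triad <- function(area_11c, area_12c, area_13c,
                          natural_ratio_pct = 0,
                          constants = nuclide_constants()) {
  .check_scalar(area_11c, "area_11c", nonneg = TRUE)
  .check_scalar(area_12c, "area_12c", positive = TRUE)
  .check_scalar(area_13c, "area_13c", nonneg = TRUE)
  .check_scalar(natural_ratio_pct, "natural_ratio_pct", nonneg = TRUE)
  am <- .am_core(area_11c, area_12c + area_13c, natural_ratio_pct,
                 constants)
  structure(list(am_gbq_per_umol = am, mode = "triad",
                 ratio_13_12_pct = 100 * area_13c / area_12c),
            class = "molar_activity")
}

#' @export
print.molar_activity <- function(x, ...) {
  cat(sprintf("<molar_activity> Am = %.4g GBq/umol (%s mode)\n",
              x$am_gbq_per_umol, x$mode))
  invisible(x)
}

#' Replicate summary of molar-activity determinations
#'
#' Computes per-replicate molar activities (pair or triad mode, chosen by
#' whether `area_12c` is available) and reports mean, SD and n.  No outlier
#' rejection is applied.
#'
#' @param areas Data frame with columns `area_11c`, `area_13c`, optionally
#'   `area_12c` (all-NA or absent selects pair mode).
#' @param carrier_ratio 13C/12C ratio (%) measured in the carrier; required
#'   in pair mode.
#' @inheritParams am_from_pair
#' @return List: `am_gbq_per_umol_mean`, `sd`, `n`, `mode`, `per_replicate`.
#' @export
am_replicates <- function(areas, carrier_ratio = NULL,
                          natural_ratio_pct = 0,
                          constants = nuclide_constants()) {
  .check_columns(areas, c("area_11c", "area_13c"), "dose-analysis table")
  have12 <- "area_12c" %in% names(areas) && !all(is.na(areas$area_12c))
  mode <- if (have12) "triad" else "pair"
  ams <- vapply(seq_len(nrow(areas)), function(i) {
    if (have12)
      am_from_triad(areas$area_11c[i], areas$area_12c[i], areas$area_13c[i],
                    natural_ratio_pct, constants)$am_gbq_per_umol
    else {
      if (is.null(carrier_ratio))
        .stopf("pair mode requires 'carrier_ratio'")
      am_from_pair(areas$area_11c[i], areas$area_13c[i], carrier_ratio,
                   natural_ratio_pct, constants)$am_gbq_per_umol
    }
  }, numeric(1))
  list(am_gbq_per_umol_mean = mean(ams),
       sd = if (length(ams) > 1) stats::sd(ams) else NA_real_,
       n = length(ams), mode = mode, per_replicate = ams)
}

#' Radioactivity carried by a known amount of tracer
#'
#' The radioactivity equivalent of a carrier amount at a given molar
#' activity.  Unit algebra: pmol x GBq/umol = kBq.
#'
#' @param carrier_pmol Carrier amount in pmol (vectorized, >= 0).
#' @param am_gbq_per_umol Molar activity in GBq/umol (>= 0).
#' @return Radioactivity in kBq.
#' @examples
#' radioactivity_from_carrier(15.2, 200.4)  # ~3046 kBq
#' @export
radioactivity_from_carrier <- function(carrier_pmol, am_gbq_per_umol) {
  if (any(carrier_pmol < 0) || any(am_gbq_per_umol < 0))
    .stopf("inputs must be >= 0")
  carrier_pmol * am_gbq_per_umol
}

#' @rdname radioactivity_from_carrier
#' @param kbq Radioactivity in kBq (vectorized, >= 0).
#' @export
carrier_from_radioactivity <- function(kbq, am_gbq_per_umol) {
  if (any(kbq < 0)) .stopf("'kbq' must be >= 0")
  if (any(am_gbq_per_umol <= 0))
    .stopf("'am_gbq_per_umol' must be > 0")
  kbq / am_gbq_per_umol
}

#' Enrichment of the carrier 13C/12C ratio with molar activity
#'
#' Ordinary least-squares fit of the carrier 13C/12C ratio (%) against the
#' molar activity of the preparation.  In the co-production model the
#' cyclotron generates stable 13C alongside 11C, so the ratio rises with
#' beam exposure — and hence with the achieved molar activity — and
#' extrapolates at \eqn{A_m = 0} to the natural-abundance ratio of the
#' reference compound.
#'
#' @param am Molar activities (GBq/umol), length >= 2, not all equal.
#' @param ratio_pct Carrier 13C/12C ratios (%), same length.
#' @return Object of class `enrichment_line`: `slope` (% per GBq/umol),
#'   `intercept_pct`, `pearson_r`, `n`.
#' @export
fit_enrichment_line <- function(am, ratio_pct) {
  if (length(am) != length(ratio_pct) || length(am) < 2)
    .stopf("need >= 2 (am, ratio) pairs of equal length")
  if (length(unique(am)) < 2)
    .stopf("degenerate fit: all molar activities identical")
  fit <- stats::lm(ratio_pct ~ am)
  r <- if (stats::var(ratio_pct) == 0) 1 else stats::cor(am, ratio_pct)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept_pct = unname(stats::coef(fit)[1]),
                 pearson_r = r, n = length(am)),
            class = "enrichment_line")
}

#' @export
print.enrichment_line <- function(x, ...) {
  cat(sprintf(
    "<enrichment_line> ratio%% = %.4g + %.3g x Am; r = %.4f (n = %d)\n",
    x$intercept_pct, x$slope, x$pearson_r, x$n))
  invisible(x)
}
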