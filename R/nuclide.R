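#' Physical constants for a radionuclide
#'
#' Bundles the half-life, decay constant \eqn{\lambda = \ln 2 / t_{1/2}},
#' Avogadro's number, and the carrier-free molar activity
#' \eqn{A_m^* = \lambda N_A} (Bq/mol) — the molar activity a tracer would
#' have if every molecule carried a radioactive atom.  Defaults describe
#' carbon-11 (\eqn{t_{1/2}} = 20.4 min), the radionuclide of the motivating
#' assay; any positron emitter can be described by overriding the half-life.
#'
#' @param half_life_s Half-life in seconds. Default 20.4 minutes (carbon-11).
#' @param avogadro Avogadro's number (1/mol). The 2019 SI exact value.
#' @return An object of class `nuclide_constants` with fields
#'   `half_life_s`, `decay_constant_per_s`, `avogadro`,
#'   `am_star_bq_per_mol`, and `am_star_gbq_per_umol`.
#' @examples
#' cc <- nuclide_constants()
#' cc$am_star_bq_per_mol   # ~3.41e20 Bq/mol
#' @export
nuclide_constants <- function(half_life_s = 20.4 * 60,
                              avogadro = 6.02214076e23) {
  .check_scalar(half_life_s, "half_life_s", positive = TRUE)
  .check_scalar(avogadro, "avogadro", positive = TRUE)
  lambda <- log(2) / half_life_s
  am_star <- lambda * avogadro
  structure(
    list(
      half_life_s = half_life_s,
      decay_constant_per_s = lambda,
      avogadro = avogadro,
      am_star_bq_per_mol = am_star,
      # 1 GBq/umol = 1e15 Bq/mol
      am_star_gbq_per_umol = am_star / 1e15
    ),
    class = "nuclide_constants"
  )
}

#' @export
print.nuclide_constants <- function(x, ...) {
  cat(sprintf(
    "<nuclide_constants> t1/2 = %.4g min, lambda = %.6g /s, Am* = %.4g Bq/mol (%.1f GBq/umol)\n",
    x$half_life_s / 60, x$decay_constant_per_s, x$am_star_bq_per_mol,
    x$am_star_gbq_per_umol))
  invisible(x)
}

#' Carrier-free molar activity
#'
#' \eqn{A_m^* = (\ln 2 / t_{1/2}) \times N_A}: the theoretical maximum molar
#' activity of a tracer labeled with the given radionuclide, in Bq/mol.
#'
#' @param half_life_s Half-life in seconds.
#' @param avogadro Avogadro's number (1/mol).
#' @return Carrier-free molar activity in Bq/mol.
#' @examples
#' carrier_free_molar_activity(20.4 * 60) # carbon-11: ~3.41e20 Bq/mol
#' @export
carrier_free_molar_activity <- function(half_life_s,
                                        avogadro = 6.02214076e23) {
  .check_scalar(half_life_s, "half_life_s", positive = TRUE)
  (log(2) / half_life_s) * avogadro
}

#' Decay-correct a radioactivity measurement
#'
#' Moves an activity along the exponential decay law.  With
#' `direction = "back_to_reference"` a measurement taken `elapsed_s` seconds
#' after the reference timestamp (end of synthesis, by the package's
#' convention) is corrected back by multiplying with
#' \eqn{e^{+\lambda t}}; `direction = "forward"` decays a reference activity
#' forward with \eqn{e^{-\lambda t}}.
#'
#' @param activity Activity (any fixed unit, e.g. Bq or kBq); vectorized.
#' @param elapsed_s Elapsed time in seconds, non-negative.
#' @param constants A [nuclide_constants()] object.
#' @param direction `"back_to_reference"` or `"forward"`.
#' @return Corrected activity, same unit as the input.
#' @export
decay_correct <- function(activity, elapsed_s,
                          constants = nuclide_constants(),
                          direction = c("back_to_reference", "forward")) {
  direction <- match.arg(direction)
  if (any(!is.finite(activity)) || any(activity < 0))
    .stopf("'activity' must be finite and >= 0")
  .check_scalar(elapsed_s, "elapsed_s", nonneg = TRUE)
  sgn <- if (direction == "back_to_reference") 1 else -1
  activity * exp(sgn * constants$decay_constant_per_s * elapsed_s)
}

#' Convert between radioactivity and amount of substance
#'
#' Radioactivity is \eqn{A = \lambda N}: the decay constant times the number
#' of undecayed atoms.  `activity_to_amount()` returns the amount (mol) of a
#' pure radioactive species carrying a given activity,
#' \eqn{n = A / (\lambda N_A)}; `amount_to_activity()` is its exact inverse.
#'
#' @param activity Activity in Bq (vectorized, >= 0).
#' @param amount Amount in mol (vectorized, >= 0).
#' @param constants A [nuclide_constants()] object.
#' @return Amount in mol, or activity in Bq.
#' @examples
#' cc <- nuclide_constants()
#' activity_to_amount(cc$am_star_bq_per_mol, cc) # exactly 1 mol
#' @export
activity_to_amount <- function(activity, constants = nuclide_constants()) {
  if (any(!is.finite(activity)) || any(activity < 0))
    .stopf("'activity' must be finite and >= 0")
  activity / (constants$decay_constant_per_s * constants$avogadro)
}

#' @rdname activity_to_amount
#' @export
amount_to_activity <- function(amount, constants = nuclide_constants()) {
  if (any(!is.finite(amount)) || any(amount < 0))
    .stopf("'amount' must be finite and >= 0")
  amount * constants$decay_constant_per_s * constants$avogadro
}

#' Elemental composition of a monitored product ion
#'
#' Describes the fragment ion monitored in an MRM transition by its atom
#' counts; used to predict the natural-abundance M+1/M ratio of the ion
#' (the heavy-isotopologue channel picks up light-isotope molecules that
#' carry a single natural 13C, 2H, 15N or 17O atom).
#'
#' @param n_carbon,n_hydrogen,n_nitrogen,n_oxygen Non-negative atom counts.
#' @param contains_label_site Does the fragment retain the radiolabeled
#'   carbon?  If `TRUE`, `n_carbon` must be at least 1.
#' @return An object of class `product_ion`.
#' @export
product_ion <- function(n_carbon, n_hydrogen = 0, n_nitrogen = 0,
                        n_oxygen = 0, contains_label_site = TRUE) {
  for (nm in c("n_carbon", "n_hydrogen", "n_nitrogen", "n_oxygen")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != round(v))
      .stopf("'%s' must be a single non-negative integer", nm)
  }
  if (isTRUE(contains_label_site) && n_carbon < 1)
    .stopf("a fragment containing the label site must have n_carbon >= 1")
  structure(list(n_carbon = n_carbon, n_hydrogen = n_hydrogen,
                 n_nitrogen = n_nitrogen, n_oxygen = n_oxygen,
                 contains_label_site = isTRUE(contains_label_site)),
            class = "product_ion")
}

#' Natural per-atom heavy-isotope abundance ratios
#'
#' Heavy/light isotope ratios, in percent per atom.  The 13C/12C ratio in
#' the natural environment is about 1.1% and is the dominant contribution;
#' 2H, 15N and 17O contribute minor terms.  Defaults follow standard
#' reference abundances and are overridable (natural 13C varies slightly
#' with carbon source).
#'
#' @param r13_pct 13C/12C ratio (%), default 1.082.
#' @param r2h_pct 2H/1H ratio (%), default 0.0115.
#' @param r15n_pct 15N/14N ratio (%), default 0.365.
#' @param r17o_pct 17O/16O ratio (%), default 0.038.
#' @return An object of class `isotope_abundances`.
#' @export
isotope_abundances <- function(r13_pct = 1.082, r2h_pct = 0.0115,
                               r15n_pct = 0.365, r17o_pct = 0.038) {
  for (nm in c("r13_pct", "r2h_pct", "r15n_pct", "r17o_pct")) {
    v <- get(nm)
    .check_scalar(v, nm, nonneg = TRUE)
    if (v > 5) .stopf("'%s' must be in [0, 5] percent (got %g)", nm, v)
  }
  structure(list(r13_pct = r13_pct, r2h_pct = r2h_pct,
                 r15n_pct = r15n_pct, r17o_pct = r17o_pct),
            class = "isotope_abundances")
}

#' First-order natural M+1/M ratio of a product ion
#'
#' The expected ratio (in percent) of the M+1 isotopologue channel to the
#' monoisotopic channel for a fragment ion at natural abundance:
#' \deqn{n_C r_{13} + n_H r_{2H} + n_N r_{15N} + n_O r_{17O}.}
#' First-order in the per-atom ratios, which is adequate below ~10%;
#' M+2 species are not modeled.
#'
#' @param composition A [product_ion()].
#' @param abundances An [isotope_abundances()].
#' @return Percent M+1/M ratio.
#' @examples
#' # a C8 H9 O fragment at default abundances: ~8.8%
#' natural_m1_ratio(product_ion(8, 9, 0, 1))
#' @export
natural_m1_ratio <- function(composition,
                             abundances = isotope_abundances()) {
  stopifnot(inherits(composition, "product_ion"),
            inherits(abundances, "isotope_abundances"))
  with(composition,
       n_carbon * abundances$r13_pct + n_hydrogen * abundances$r2h_pct +
       n_nitrogen * abundances$r15n_pct + n_oxygen * abundances$r17o_pct)
}
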