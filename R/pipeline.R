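#' Study configuration
#'
#' Flat configuration of the pipeline: nuclide constants, isotope
#' abundances, the analyte molar mass, and correction-policy flags.  Kept
#' as a plain named list so it can round-trip through a JSON file; keys
#' are validated with explicit messages naming the offending entry.
#'
#' @param half_life_min Radionuclide half-life (min).
#' @param r13_pct,r2h_pct,r15n_pct,r17o_pct Natural per-atom isotope
#'   ratios (%), see [isotope_abundances()].
#' @param natural_ratio_pct Natural M+1/M ratio of the monitored product
#'   ion (%).
#' @param analyte_molar_mass Analyte molar mass (g/mol), PBR28 default.
#' @param apply_skew_correction,apply_gamma_correction Policy flags.
#' @param calibration_weighting `"none"` or `"1/x2"`.
#' @param seed Default seed for simulation subcommands.
#' @return A list of class `study_config`.
#' @export
study_config <- function(half_life_min = 20.4,
                         r13_pct = 1.082, r2h_pct = 0.0115,
                         r15n_pct = 0.365, r17o_pct = 0.038,
                         natural_ratio_pct = 9.16,
                         analyte_molar_mass = 347.4,
                         apply_skew_correction = TRUE,
                         apply_gamma_correction = TRUE,
                         calibration_weighting = "1/x2",
                         seed = 1L) {
  cfg <- list(half_life_min = half_life_min, r13_pct = r13_pct,
              r2h_pct = r2h_pct, r15n_pct = r15n_pct,
              r17o_pct = r17o_pct,
              natural_ratio_pct = natural_ratio_pct,
              analyte_molar_mass = analyte_molar_mass,
              apply_skew_correction = apply_skew_correction,
              apply_gamma_correction = apply_gamma_correction,
              calibration_weighting = calibration_weighting,
              seed = seed)
  validate_config(cfg)
}

#' @rdname study_config
#' @param cfg A named list of configuration entries.
#' @export
validate_config <- function(cfg) {
  numeric_pos <- c("half_life_min", "natural_ratio_pct",
                   "analyte_molar_mass")
  for (key in numeric_pos)
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1L ||
        !is.finite(cfg[[key]]) || cfg[[key]] <= 0)
      .stopf("config key '%s' must be a single positive number", key)
  for (key in c("r13_pct", "r2h_pct", "r15n_pct", "r17o_pct")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 ||
        v > 5)
      .stopf("config key '%s' must be a number in [0, 5] percent", key)
  }
  for (key in c("apply_skew_correction", "apply_gamma_correction"))
    if (!is.logical(cfg[[key]]) || length(cfg[[key]]) != 1L ||
        is.na(cfg[[key]]))
      .stopf("config key '%s' must be TRUE or FALSE", key)
  if (!cfg$calibration_weighting %in% c("none", "1/x2"))
    .stopf("config key 'calibration_weighting' must be 'none' or '1/x2'")
  structure(cfg, class = "study_config")
}

#' @rdname study_config
#' @param path Path of a JSON configuration file.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- unclass(study_config())
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  defaults[names(raw)] <- raw
  validate_config(defaults)
}

#' @rdname study_config
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @noRd
.cfg_constants <- function(config) {
  nuclide_constants(half_life_s = config$half_life_min * 60)
}

#' Molar-activity stage: dose-analysis table to Am report
#'
#' Reads (or accepts) a dose-analysis table — one row per replicate
#' injection with columns `prep_id`, `replicate`, `area_11c`, `area_12c`
#' (may be empty/NA for pair mode), `area_13c`, `minutes_after_eos` — plus
#' a carrier 13C/12C ratio per preparation, and reports per-preparation
#' molar activity with replicate statistics.  11C areas are decay-corrected
#' back to end of synthesis before the isotopologue arithmetic.
#'
#' @param dose Data frame or CSV path with the dose-analysis schema.
#' @param carrier_ratio_pct Named vector (by prep_id) or single value of
#'   carrier 13C/12C ratios (%); required for pair-mode preparations.
#' @param config A [study_config()].
#' @return Data frame: `prep_id`, `am_gbq_per_umol_mean`, `sd`, `n`,
#'   `ratio_13_12_pct`, `mode`.
#' @export
run_am <- function(dose, carrier_ratio_pct = NULL,
                   config = study_config()) {
  if (is.character(dose)) dose <- utils::read.csv(dose)
  if (!nrow(dose)) .stopf("dose-analysis table is empty")
  .check_columns(dose, c("prep_id", "replicate", "area_11c", "area_13c"),
                 "dose-analysis table")
  if (!"minutes_after_eos" %in% names(dose)) dose$minutes_after_eos <- 0
  cc <- .cfg_constants(config)
  out <- lapply(split(dose, dose$prep_id), function(d) {
    d$area_11c <- decay_correct(d$area_11c, d$minutes_after_eos[1] * 60,
                                cc, "back_to_reference")
    ratio <- if (!is.null(carrier_ratio_pct)) {
      if (!is.null(names(carrier_ratio_pct)))
        carrier_ratio_pct[[as.character(d$prep_id[1])]]
      else carrier_ratio_pct
    } else NULL
    res <- am_replicates(d, carrier_ratio = ratio,
                         natural_ratio_pct = config$natural_ratio_pct,
                         constants = cc)
    rpct <- if (res$mode == "triad")
      mean(100 * d$area_13c / d$area_12c) else ratio
    data.frame(prep_id = d$prep_id[1],
               am_gbq_per_umol_mean = res$am_gbq_per_umol_mean,
               sd = res$sd, n = res$n,
               ratio_13_12_pct = rpct, mode = res$mode,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' AIF stage: plasma, calibration and gamma tables to AIFs + comparison
#'
#' For each subject: fits the calibration curve, quantifies the plasma
#' carrier (with skew correction), converts the carrier curve to an AIF in
#' kBq/mL via the preparation's Am, builds the metabolite-corrected
#' radiometric AIF from the gamma series and parent fractions, estimates
#' the preparation-specific gamma correction factor from the paired
#' curves, and computes per-subject AUCs and the across-subject
#' method-comparison statistics.
#'
#' @param plasma Data frame/CSV: `subject_id`, `time_min`, `analyte_area`,
#'   `is_area`, `is_conc_pM`.
#' @param calibration Data frame/CSV: `level`, `nominal_conc`
#'   (pM), `analyte_area`, `is_area`.
#' @param gamma Data frame/CSV: `subject_id`, `time_min`,
#'   `total_kbq_per_ml`.
#' @param parent_fraction Data frame/CSV: `subject_id`, `time_min`,
#'   `fraction`.
#' @param am_gbq_per_umol Named vector (by subject_id) or single molar
#'   activity.
#' @param carrier_ratio_pct Named vector or single carrier 13C/12C
#'   ratio (%) for the skew correction (x); the reference ratio (y) is
#'   `config$natural_ratio_pct`.
#' @param config A [study_config()].
#' @return A list of class `aif_bundle`: `curves` (long data frame with
#'   method in lcms / radiometric_raw / radiometric_corrected), `aucs`
#'   (per subject), `correction_factors`, and `comparison`
#'   (a [compare_aif_methods()] result, `NULL` if fewer than 2 subjects).
#' @export
run_aif <- function(plasma, calibration, gamma, parent_fraction,
                    am_gbq_per_umol, carrier_ratio_pct = NULL,
                    config = study_config()) {
  read <- function(x) if (is.character(x)) utils::read.csv(x) else x
  plasma <- read(plasma); calibration <- read(calibration)
  gamma <- read(gamma); parent_fraction <- read(parent_fraction)
  .check_columns(plasma, c("subject_id", "time_min", "analyte_area",
                           "is_area"), "plasma table")
  .check_columns(gamma, c("subject_id", "time_min", "total_kbq_per_ml"),
                 "gamma table")
  .check_columns(parent_fraction, c("subject_id", "time_min", "fraction"),
                 "parent-fraction table")
  curve <- fit_calibration(calibration, conc_unit = "pM",
                           weighting = config$calibration_weighting)
  subjects <- unique(plasma$subject_id)
  pick <- function(v, id, what) {
    if (is.null(v)) .stopf("'%s' is required", what)
    if (!is.null(names(v))) {
      if (!id %in% names(v))
        .stopf("no %s supplied for subject '%s'", what, id)
      v[[id]]
    } else v
  }
  curves <- list(); aucs <- list(); factors <- numeric(0)
  for (id in subjects) {
    pl <- plasma[plasma$subject_id == id, , drop = FALSE]
    ga <- gamma[gamma$subject_id == id, , drop = FALSE]
    pf <- parent_fraction[parent_fraction$subject_id == id, ,
                          drop = FALSE]
    if (!nrow(ga) || !nrow(pf))
      .stopf("subject '%s' missing gamma or parent-fraction data", id)
    if (!isTRUE(all.equal(pl$time_min, ga$time_min)))
      .stopf("subject '%s': plasma and gamma time grids differ", id)
    am <- pick(am_gbq_per_umol, id, "am_gbq_per_umol")
    x <- if (config$apply_skew_correction)
      pick(carrier_ratio_pct, id, "carrier_ratio_pct")
    else config$natural_ratio_pct
    q <- quantify_plasma(pl, curve, x_pct = x,
                         y_pct = config$natural_ratio_pct,
                         molar_mass_g_per_mol = config$analyte_molar_mass)
    conc <- aif_ts(q$time_min, q$carrier_pM_corrected, "pM")
    lcms <- carrier_curve_to_activity(conc, am)
    total <- aif_ts(ga$time_min, ga$total_kbq_per_ml, "kBq/mL")
    pfts <- aif_ts(pf$time_min, pf$fraction, "1")
    rad_raw <- radiometric_aif(total, pfts)
    ok <- rad_raw$values > 0 & lcms$values > 0
    fac <- if (config$apply_gamma_correction && any(ok))
      gamma_correction_factor(rad_raw$values[ok], lcms$values[ok])
    else 1
    rad_cor <- aif_ts(rad_raw$times_min,
                      apply_gamma_correction(rad_raw$values, fac),
                      "kBq/mL")
    factors[[id]] <- fac
    curves[[id]] <- rbind(
      data.frame(subject_id = id, time_min = lcms$times_min,
                 value = lcms$values, unit = "kBq/mL", method = "lcms"),
      data.frame(subject_id = id, time_min = rad_raw$times_min,
                 value = rad_raw$values, unit = "kBq/mL",
                 method = "radiometric_raw"),
      data.frame(subject_id = id, time_min = rad_cor$times_min,
                 value = rad_cor$values, unit = "kBq/mL",
                 method = "radiometric_corrected"))
    aucs[[id]] <- data.frame(
      subject_id = id,
      auc_lcms = auc_trapezoid(lcms),
      auc_rad_uncorrected = auc_trapezoid(rad_raw),
      auc_rad_corrected = auc_trapezoid(rad_cor),
      correction_factor = fac, stringsAsFactors = FALSE)
  }
  aucs <- do.call(rbind, aucs); rownames(aucs) <- NULL
  comparison <- if (nrow(aucs) >= 2)
    compare_aif_methods(aucs$auc_lcms, aucs$auc_rad_uncorrected,
                        aucs$auc_rad_corrected)
  else {
    warning("single subject: method-comparison statistics suppressed",
            call. = FALSE)
    NULL
  }
  structure(list(curves = do.call(rbind, c(curves,
                                           make.row.names = FALSE)),
                 aucs = aucs, correction_factors = factors,
                 calibration_curve = curve, comparison = comparison),
            class = "aif_bundle")
}

#' End-to-end synthetic run: simulate, quantify, compare, verify
#'
#' Simulates a complete study, runs the molar-activity and AIF stages on
#' the simulated tables exactly as they would run on real exports, and
#' appends a recovery table comparing every pipeline estimate with its
#' generator ground truth.
#'
#' @param config A [study_config()]; `config$seed` drives all randomness.
#' @param n_subjects Number of subjects.
#' @param production_cfg,subject_cfg Generator configurations.
#' @param ... Passed to [simulate_study()].
#' @return A list of class `end_to_end`: `study`, `am_report`,
#'   `aif` (an `aif_bundle`), and `recovery` (data frame with columns
#'   quantity, subject, truth, estimate, rel_error).
#' @export
run_end_to_end <- function(config = study_config(), n_subjects = 8,
                           production_cfg = production_config(),
                           subject_cfg = subject_config(), ...) {
  study <- simulate_study(n_subjects = n_subjects,
                          production_cfg = production_cfg,
                          subject_cfg = subject_cfg,
                          seed = config$seed, ...)
  dose <- do.call(rbind, lapply(study$productions, `[[`, "dose_areas"))
  ratios <- vapply(study$productions, function(p)
    mean(100 * p$ratio_areas$area_13c / p$ratio_areas$area_12c),
    numeric(1))
  names(ratios) <- vapply(study$productions, `[[`, character(1),
                          "prep_id")
  am_report <- run_am(dose, carrier_ratio_pct = ratios, config = config)
  plasma <- do.call(rbind, lapply(study$subjects, `[[`, "plasma_ms"))
  gamma <- do.call(rbind, lapply(study$subjects, `[[`, "gamma"))
  pf <- do.call(rbind, lapply(study$subjects, `[[`, "parent_fraction"))
  ams <- am_report$am_gbq_per_umol_mean
  names(ams) <- vapply(study$subjects, `[[`, character(1), "subject_id")
  xr <- ratios
  names(xr) <- names(ams)
  aif <- run_aif(plasma, study$calibration, gamma, pf,
                 am_gbq_per_umol = ams, carrier_ratio_pct = xr,
                 config = config)
  rec <- list()
  for (i in seq_along(study$subjects)) {
    s <- study$subjects[[i]]; p <- study$productions[[i]]
    est_am <- am_report$am_gbq_per_umol_mean[
      am_report$prep_id == p$prep_id]
    rec[[length(rec) + 1L]] <- data.frame(
      quantity = "am_gbq_per_umol", subject = s$subject_id,
      truth = p$truth$am_gbq_per_umol, estimate = est_am)
    rec[[length(rec) + 1L]] <- data.frame(
      quantity = "gamma_bias", subject = s$subject_id,
      truth = s$truth$gamma_bias,
      estimate = unname(aif$correction_factors[s$subject_id]))
    rec[[length(rec) + 1L]] <- data.frame(
      quantity = "auc_parent_kbq_min_per_ml", subject = s$subject_id,
      truth = auc_trapezoid(s$truth$parent_kbq_per_ml,
                            times = s$config$schedule),
      estimate = aif$aucs$auc_lcms[aif$aucs$subject_id == s$subject_id])
  }
  recovery <- do.call(rbind, rec)
  recovery$rel_error <- abs(recovery$estimate / recovery$truth - 1)
  structure(list(study = study, am_report = am_report, aif = aif,
                 recovery = recovery),
            class = "end_to_end")
}

#' @export
print.end_to_end <- function(x, ...) {
  cat(sprintf("<end_to_end> %d subjects; max |rel error| of recovery: %.3g\n",
              length(x$study$subjects), max(x$recovery$rel_error)))
  if (!is.null(x$aif$comparison)) print(x$aif$comparison)
  invisible(x)
}

#' Write a simulated study to a directory of CSV files
#'
#' Dumps the full interchange bundle consumed by the analysis stages:
#' `dose_areas.csv`, `carrier_ratios.csv`, `calibration.csv`,
#' `plasma.csv`, `gamma.csv`, `parent_fraction.csv`, a ground-truth
#' sidecar `truth.csv`, and the configuration snapshot `config.json` with
#' a provenance record (`provenance.json`: config hash, seed, schema
#' version).
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @param config A [study_config()].
#' @return Invisibly, the directory path.
#' @export
write_study_csv <- function(study, dir, config = study_config()) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  w(do.call(rbind, lapply(study$productions, `[[`, "dose_areas")),
    "dose_areas.csv")
  w(do.call(rbind, lapply(study$productions, function(p)
    data.frame(prep_id = p$prep_id,
               ratio_13_12_pct = mean(100 * p$ratio_areas$area_13c /
                                        p$ratio_areas$area_12c)))),
    "carrier_ratios.csv")
  w(study$calibration, "calibration.csv")
  w(do.call(rbind, lapply(study$subjects, `[[`, "plasma_ms")),
    "plasma.csv")
  w(do.call(rbind, lapply(study$subjects, `[[`, "gamma")), "gamma.csv")
  w(do.call(rbind, lapply(study$subjects, `[[`, "parent_fraction")),
    "parent_fraction.csv")
  w(do.call(rbind, lapply(seq_along(study$subjects), function(i) {
    p <- study$productions[[i]]; s <- study$subjects[[i]]
    data.frame(subject_id = s$subject_id, prep_id = p$prep_id,
               am_true = p$truth$am_gbq_per_umol,
               ratio_true_pct = p$truth$ratio_13_12_pct,
               gamma_bias = s$truth$gamma_bias)
  })), "truth.csv")
  cfg_path <- file.path(dir, "config.json")
  write_config(config, cfg_path)
  prov <- list(schema_version = "1.0",
               seed = study$seed,
               config_md5 = unname(tools::md5sum(cfg_path)),
               n_subjects = length(study$subjects),
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
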