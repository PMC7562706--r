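test_that("calibration fit recovers an exact line and is order invariant", {
  std <- data.frame(nominal_conc = c(10, 5, 2.5, 1.25, 0.625),
                    analyte_area = 0.01 * c(10, 5, 2.5, 1.25, 0.625) * 1e5,
                    is_area = 1e5)
  cv <- fit_calibration(std)
  expect_equal(cv$slope, 0.01, tolerance = 1e-12)
  expect_equal(cv$intercept, 0, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  perm <- fit_calibration(std[sample(nrow(std)), ])
  expect_equal(perm$slope, cv$slope, tolerance = 1e-12)
  expect_equal(perm$intercept, cv$intercept, tolerance = 1e-12)
  expect_error(fit_calibration(std[1:2, ]), "3 distinct")
})

test_that("noisy dilution series recovers the true sensitivity", {
  sens <- 0.1
  tab <- simulate_calibration(sensitivity = sens, cv = 0.02, seed = 99)
  fit <- stats::lm(I(analyte_area / is_area) ~ nominal_conc, data = tab)
  est <- unname(coef(fit)[2])
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(est - sens), 3 * se)
  pkg <- fit_calibration(tab)
  expect_equal(pkg$slope, est, tolerance = 1e-12)
})

test_that("quantification inverts the calibration exactly", {
  tab <- simulate_calibration(sensitivity = 0.05, cv = 0, seed = 1,
                              conc_unit = "pM")
  curve <- fit_calibration(tab, conc_unit = "pM")
  # a noiseless standard returns its nominal concentration
  for (i in seq_len(nrow(tab))) {
    q <- quantify_sample(tab$analyte_area[i], tab$is_area[i], curve)
    expect_equal(q$conc, tab$nominal_conc[i], tolerance = 1e-9)
  }
  # synthetic plasma sample at a known concentration, zero noise
  q <- quantify_sample(0.05 * 71.8 * 1e5, 1e5, curve)
  expect_equal(q$conc, 71.8, tolerance = 1e-9)
  # monotone increasing in analyte area
  concs <- vapply(c(1, 2, 4, 8) * 1e3, function(a)
    quantify_sample(a, 1e5, curve)$conc, numeric(1))
  expect_true(all(diff(concs) > 0))
  # baseline sample clamps to zero with a flag
  expect_warning(q0 <- quantify_sample(0, 1e5,
    fit_calibration(data.frame(nominal_conc = c(1, 2, 4),
                               analyte_area = c(1.1, 2, 4) * 10,
                               is_area = 10))), "below blank")
  expect_identical(q0$conc, 0)
  expect_true("below_blank" %in% q0$flags)
  # below-LLOQ values are flagged, not censored
  ql <- quantify_sample(0.05 * 0.1 * 1e5, 1e5, curve)
  expect_equal(ql$conc, 0.1, tolerance = 1e-9)
  expect_true("below_lloq" %in% ql$flags)
})

test_that("unit conversion round-trips through the molar mass", {
  x <- c(10, 0.3125)
  pm <- convert_conc(x, "ng/mL", "pM")
  expect_equal(convert_conc(pm, "pM", "ng/mL"), x, tolerance = 1e-12)
  # 1 ng/mL of a 347.4 g/mol analyte is ~2879 pM
  expect_equal(convert_conc(1, "ng/mL", "pM"), 1e6 / 347.4,
               tolerance = 1e-12)
  expect_error(convert_conc(1, "ng/mL", "mM"), "units")
})

test_that("skew correction matches its closed form and stays bounded", {
  expect_identical(skew_correct(100, 9.16, 9.16), 100)
  expect_equal(skew_correct(100, 10.08, 9.16), 100.8428,
               tolerance = 1e-6)
  # linear in c
  expect_equal(skew_correct(7 * 13, 10.08, 9.16),
               7 * skew_correct(13, 10.08, 9.16), tolerance = 1e-12)
  # |correction - 1| <= |x - y|/100 for x, y >= 0
  set.seed(21)
  for (i in 1:50) {
    x <- runif(1, 0, 15); y <- runif(1, 0, 15)
    expect_lte(abs(skew_correct(1, x, y) - 1), abs(x - y) / 100 + 1e-15)
  }
  expect_error(skew_correct(1, -101, 9), "-100")
})

test_that("quantify_plasma produces a tidy corrected table", {
  tab <- simulate_calibration(sensitivity = 0.001, cv = 0, seed = 1,
                              levels = 8000 / 2^(0:8), conc_unit = "pM")
  curve <- fit_calibration(tab, conc_unit = "pM")
  plasma <- data.frame(time_min = c(1, 10, 90),
                       analyte_area = 0.001 * c(2000, 71.8, 6.34) * 1e5,
                       is_area = 1e5)
  out <- quantify_plasma(plasma, curve, x_pct = 10.08, y_pct = 9.16)
  expect_equal(out$carrier_pM_raw, c(2000, 71.8, 6.34), tolerance = 1e-9)
  expect_equal(out$carrier_pM_corrected,
               (100 + 10.08) / (100 + 9.16) * out$carrier_pM_raw,
               tolerance = 1e-12)
  expect_true(all(c("time_min", "flags") %in% names(out)))
})
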