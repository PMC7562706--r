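test_that("carrier/activity curve conversion follows the unit algebra", {
  conc <- aif_ts(c(1.25, 2.5), c(140.1, 70), "pM")
  act <- carrier_curve_to_activity(conc, 385.9)
  # pM x GBq/umol / 1000 -> kBq/mL (independent arithmetic)
  expect_equal(act$values[1], 140.1 * 385.9 / 1000, tolerance = 1e-12)
  expect_equal(act$values[1], 54.07, tolerance = 1e-3)
  expect_identical(act$unit, "kBq/mL")
  # zero concentration maps to zero activity
  z <- carrier_curve_to_activity(aif_ts(1:2, c(0, 0), "pM"), 100)
  expect_identical(z$values, c(0, 0))
  # round trip
  back <- activity_curve_to_carrier(act, 385.9)
  expect_equal(back$values, conc$values, tolerance = 1e-12)
  expect_error(carrier_curve_to_activity(act, 385.9), "pM")
  expect_error(aif_ts(c(1, 1), c(2, 3), "pM"), "strictly increasing")
})

test_that("radiometric AIF is the metabolite-corrected product", {
  tot <- aif_ts(c(1, 5, 10), c(100, 40, 10), "kBq/mL")
  ones <- aif_ts(c(0, 12), c(1, 1), "1")
  expect_equal(radiometric_aif(tot, ones)$values, tot$values)
  half <- aif_ts(c(0, 12), c(0.5, 0.5), "1")
  expect_equal(radiometric_aif(tot, half)$values, tot$values / 2)
  # linear interpolation of the parent fraction onto the activity grid
  pf <- aif_ts(c(0, 10), c(1, 0.5), "1")
  out <- radiometric_aif(tot, pf)
  expect_equal(out$values, tot$values * c(0.95, 0.75, 0.5),
               tolerance = 1e-12)
  # no extrapolation beyond the measured fraction range
  expect_error(radiometric_aif(aif_ts(c(1, 20), c(1, 1), "kBq/mL"), pf),
               "extrapolation")
  expect_error(radiometric_aif(tot, aif_ts(c(0, 12), c(0.2, 1.4), "1")),
               "values must be finite and >= 0|\\[0, 1\\]")
})

test_that("trapezoidal AUC matches closed forms and is additive", {
  expect_equal(auc_trapezoid(rep(1, 11), times = 0:10), 10)
  expect_equal(auc_trapezoid(c(0, 2), times = c(0, 2)), 2)
  # dense exponential against the analytic integral, within 0.01%
  t <- seq(0, 90, length.out = 1000)
  v <- exp(-t / 10)
  expect_equal(auc_trapezoid(v, times = t), 10 * (1 - exp(-9)),
               tolerance = 1e-4)
  # additive over contiguous intervals sharing a grid point
  i <- 500
  expect_equal(auc_trapezoid(v[1:i], times = t[1:i]) +
                 auc_trapezoid(v[i:1000], times = t[i:1000]),
               auc_trapezoid(v, times = t), tolerance = 1e-12)
  tl <- c(0, 1, 2); vl <- c(0, 1, 2)
  with_mid <- auc_trapezoid(c(0, 0.5, 1, 2), times = c(0, 0.5, 1, 2))
  expect_equal(with_mid, auc_trapezoid(vl, times = tl), tolerance = 1e-12)
  expect_error(auc_trapezoid(1, times = 1), ">= 2")
})

test_that("gamma correction factor reproduces the printed worked example", {
  f <- gamma_correction_factor(2349, 1726)
  expect_equal(f, 1.361, tolerance = 1e-3)
  expect_equal(apply_gamma_correction(29.81, f), 21.90, tolerance = 1e-3)
  expect_identical(gamma_correction_factor(c(5, 5), c(5, 5)), 1)
  # geometric mean of the per-pair ratios
  g <- c(130, 140, 125); l <- c(100, 101, 99)
  expect_equal(gamma_correction_factor(g, l), exp(mean(log(g / l))),
               tolerance = 1e-12)
  expect_error(gamma_correction_factor(c(1, -1), c(1, 1)), "> 0")
})

test_that("percent_lower and var_percent use their printed conventions", {
  expect_equal(round(percent_lower(368, 536)), 31)
  expect_equal(round(percent_lower(368, 399)), 8)
  expect_identical(percent_lower(5, 5), 0)
  expect_equal(var_percent(328, 470), 100 * (470 - 328) / 399,
               tolerance = 1e-12)
  expect_identical(var_percent(7, 7), 0)
  expect_equal(var_percent(328, 470), var_percent(470, 328))
  # first-order agreement of the two conventions for small differences
  for (eps in c(1e-3, 1e-4)) {
    a <- 100 * (1 - eps)
    expect_equal(percent_lower(a, 100), var_percent(a, 100),
                 tolerance = eps * 100)
  }
  expect_error(var_percent(0, 0), "undefined")
})

test_that("absolute-agreement ICC matches an independent ANOVA oracle", {
  expect_identical(icc_absolute_agreement(c(1, 2, 3), c(1, 2, 3)), 1)
  # small fixed examples against the aov() mean-squares decomposition
  cases <- list(list(a = c(9, 6, 8, 7), b = c(2, 1, 4, 1)),
                list(a = c(10, 14, 18, 22, 30), b = c(11, 13, 20, 21, 31)),
                list(a = c(1, 2, 3, 4), b = c(1.32, 2.6, 4.1, 5.2)))
  for (cs in cases)
    expect_equal(icc_absolute_agreement(cs$a, cs$b),
                 icc_a1_oracle(cs$a, cs$b), tolerance = 1e-10)
  # a constant offset lowers ICC but leaves Pearson r unchanged
  a <- c(10, 14, 18, 22, 30)
  expect_lt(icc_absolute_agreement(a, a + 8),
            icc_absolute_agreement(a, a + 0.1))
  expect_equal(pearson_r(a, a + 8), pearson_r(a, a + 0.1),
               tolerance = 1e-12)
  expect_error(icc_absolute_agreement(c(1, 1, 1), c(1, 1, 2.5)),
               NA)  # non-degenerate: row variance exists via method 2
  expect_error(icc_absolute_agreement(c(1, 1, 1), c(2, 2, 2)),
               "degenerate")
})

test_that("paired t and Pearson follow their standard definitions", {
  a <- c(328, 308, 284, 333, 336, 346, 380, 348) / 1  # 8 subjects
  b <- a * 1.3 + c(5, -8, 3, 0, -2, 7, -4, 1)
  d <- a - b
  oracle_t <- mean(d) / (sd(d) / sqrt(length(d)))
  res <- paired_t(a, b)
  expect_equal(res$t_stat, oracle_t, tolerance = 1e-12)
  expect_equal(res$df, length(a) - 1)
  expect_equal(res$p_value,
               2 * pt(abs(oracle_t), df = length(a) - 1,
                      lower.tail = FALSE), tolerance = 1e-12)
  ident <- paired_t(a, a)
  expect_identical(ident$t_stat, 0)
  expect_identical(ident$p_value, 1)
  expect_equal(pearson_r(a, 3 * a + 2), 1, tolerance = 1e-12)
  expect_error(paired_t(a, a + 5), "undefined")
})

test_that("method comparison bundles the statistics coherently", {
  set.seed(5)
  lcms <- rnorm(8, 368, 70)
  rad <- lcms * 1.32 * exp(rnorm(8, 0, 0.02))
  corr <- rad / gamma_correction_factor(rad, lcms)
  cmp <- compare_aif_methods(lcms, rad, corr)
  expect_equal(cmp$pct_diff_uncorrected,
               percent_lower(mean(lcms), mean(rad)), tolerance = 1e-12)
  expect_gt(cmp$icc_corrected, cmp$icc_uncorrected)
  expect_equal(cmp$pearson_corrected, cmp$pearson_uncorrected,
               tolerance = 1e-12)  # common factor leaves r untouched
  expect_warning(compare_aif_methods(1:2, 2:3, 2:3 + 0.5), "fewer than 3")
})
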