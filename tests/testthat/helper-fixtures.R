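# Shared fixtures: noise-free generator configurations and a small
# deterministic study used across test files.

noiseless_production_cfg <- function(...) {
  production_config(ms_area_cv = 0, ...)
}

noiseless_subject_cfg <- function(...) {
  subject_config(gamma_cv = 0, ms_cv = 0, ...)
}

noiseless_study <- function(seed = 42, n_subjects = 8) {
  simulate_study(n_subjects = n_subjects,
                 production_cfg = noiseless_production_cfg(),
                 subject_cfg = noiseless_subject_cfg(),
                 gamma_bias_sd = 0, subject_cv = 0, calibration_cv = 0,
                 seed = seed)
}

# independent ICC(A,1) oracle: mean squares via aov() on the long layout
icc_a1_oracle <- function(a, b) {
  n <- length(a)
  d <- data.frame(y = c(a, b),
                  subject = factor(rep(seq_len(n), 2)),
                  method = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subject + method, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
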