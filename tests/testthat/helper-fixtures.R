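# Shared fixtures: small cosinor datasets built in code.

study_times <- seq(0, 24, by = 4)

# one-group cosinor observations on the study grid
gen_cosinor_data <- function(mesor = 10, amplitude = 3, acrophase = 18,
                             sigma = 0.5, reps = 5, times = study_times,
                             period_h = 24) {
  t_all <- rep(times, each = reps)
  y <- cosinor_curve(t_all, mesor, amplitude, acrophase, period_h)
  if (sigma > 0) y <- y + rnorm(length(y), sd = sigma)
  list(times = t_all, values = y)
}

# balanced two-group dataset with given offsets
gen_twogroup_data <- function(design, mesor = 10, amplitude = 3,
                              acrophase = 18, d_mesor = 0,
                              d_amplitude = 0, d_acrophase = 0,
                              sigma = 0.5, period_h = 24) {
  g <- as.numeric(design$group == levels(design$group)[2L])
  mu <- ifelse(g == 0,
    cosinor_curve(design$time_h, mesor, amplitude, acrophase, period_h),
    cosinor_curve(design$time_h, mesor + d_mesor,
                  amplitude + d_amplitude, acrophase + d_acrophase,
                  period_h))
  mu + rnorm(nrow(design), sd = sigma)
}

expect_phase_equal <- function(a, b, tol = 1e-6, period = 24) {
  d <- abs((a - b + period / 2) %% period - period / 2)
  expect_lt(d, tol)
}
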