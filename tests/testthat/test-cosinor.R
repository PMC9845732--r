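test_that("harmonic basis hits its landmark values", {
  expect_equal(unname(harmonic_basis(0)[1, ]), c(1, 1, 0))
  expect_equal(unname(harmonic_basis(6)[1, ]), c(1, 0, 1),
               tolerance = 1e-12)
  expect_equal(unname(harmonic_basis(12)[1, ]), c(1, -1, 0),
               tolerance = 1e-12)
  expect_error(harmonic_basis(0, period_h = 0), "period")
})

test_that("noiseless cosinor is recovered exactly", {
  d <- gen_cosinor_data(mesor = 10, amplitude = 3, acrophase = 18,
                        sigma = 0)
  fit <- cosinor_fit(d$times, d$values)
  expect_equal(fit$coefficients[["mesor"]], 10, tolerance = 1e-8)
  expect_equal(fit$coefficients[["amplitude"]], 3, tolerance = 1e-8)
  expect_equal(fit$coefficients[["acrophase"]], 18, tolerance = 1e-8)
  expect_equal(fit$sse, 0, tolerance = 1e-16)
  expect_lt(fit$amplitude_pvalue, 1e-10)
})

test_that("constant response degenerates gracefully", {
  t_all <- rep(study_times, each = 2)
  fit <- cosinor_fit(t_all, rep(5, length(t_all)))
  expect_equal(fit$coefficients[["mesor"]], 5)
  expect_equal(fit$coefficients[["amplitude"]], 0, tolerance = 1e-12)
  expect_equal(fit$amplitude_pvalue, 1)
  expect_true(fit$acrophase_unstable)
  expect_true(is.na(confint(fit)["acrophase", "lower"]))
})

test_that("linearized fit equals an independent normal-equations solve", {
  set.seed(21)
  d <- gen_cosinor_data(sigma = 0.5)
  fit <- cosinor_fit(d$times, d$values)
  # brute-force oracle: explicit normal equations, no shared code path
  X <- cbind(1, cos(2 * pi * d$times / 24), sin(2 * pi * d$times / 24))
  beta <- solve(t(X) %*% X, t(X) %*% d$values)
  expect_equal(fit$coefficients[["mesor"]], beta[1], tolerance = 1e-10)
  expect_equal(fit$coefficients[["amplitude"]],
               sqrt(beta[2]^2 + beta[3]^2), tolerance = 1e-10)
  expect_phase_equal(fit$coefficients[["acrophase"]],
                     (atan2(beta[3], beta[2]) * 24 / (2 * pi)) %% 24,
                     tol = 1e-10)
  # residual variance against the hand formula
  expect_equal(fit$sigma2,
               sum((d$values - X %*% beta)^2) / (length(d$values) - 3),
               tolerance = 1e-10)
})

test_that("nonlinear and linearized routes agree on random data", {
  set.seed(31)
  for (i in 1:20) {
    d <- gen_cosinor_data(mesor = runif(1, -5, 15),
                          amplitude = runif(1, 0.5, 6),
                          acrophase = runif(1, 0, 24),
                          sigma = runif(1, 0.1, 1), reps = 3)
    ols <- cosinor_fit(d$times, d$values, method = "ols")
    nls <- cosinor_fit(d$times, d$values, method = "nls")
    expect_equal(nls$coefficients[["mesor"]], ols$coefficients[["mesor"]],
                 tolerance = 1e-6)
    expect_equal(nls$coefficients[["amplitude"]],
                 ols$coefficients[["amplitude"]], tolerance = 1e-6)
    expect_phase_equal(nls$coefficients[["acrophase"]],
                       ols$coefficients[["acrophase"]], tol = 1e-5)
    expect_equal(nls$se, ols$se, tolerance = 1e-4)
  }
})

test_that("a negative-amplitude start converges to the canonical form", {
  set.seed(41)
  d <- gen_cosinor_data(mesor = 8, amplitude = 2, acrophase = 6,
                        sigma = 0.2)
  fit <- cosinor_fit(d$times, d$values, method = "nls",
                     init = c(mesor = 8, amplitude = -2, acrophase = 18))
  expect_gte(fit$coefficients[["amplitude"]], 0)
  expect_phase_equal(fit$coefficients[["acrophase"]], 6, tol = 0.5)
})

test_that("fits obey shift equivariances", {
  set.seed(51)
  d <- gen_cosinor_data(sigma = 0.3)
  base <- cosinor_fit(d$times, d$values)
  for (delta in c(3, 7.5, -4)) {
    shifted <- cosinor_fit(d$times + delta, d$values)
    expect_equal(shifted$coefficients[["mesor"]],
                 base$coefficients[["mesor"]], tolerance = 1e-8)
    expect_equal(shifted$coefficients[["amplitude"]],
                 base$coefficients[["amplitude"]], tolerance = 1e-8)
    expect_phase_equal(shifted$coefficients[["acrophase"]],
                       (base$coefficients[["acrophase"]] + delta) %% 24,
                       tol = 1e-8)
    expect_equal(shifted$sse, base$sse, tolerance = 1e-8)
  }
  for (cc in c(-2, 5)) {
    lifted <- cosinor_fit(d$times, d$values + cc)
    expect_equal(lifted$coefficients[["mesor"]],
                 base$coefficients[["mesor"]] + cc, tolerance = 1e-10)
    expect_equal(lifted$coefficients[["amplitude"]],
                 base$coefficients[["amplitude"]], tolerance = 1e-10)
  }
})

test_that("degenerate designs are rejected", {
  expect_error(cosinor_fit(c(0, 12), c(1, 2)), "4 distinct")
  expect_error(cosinor_fit(c(0, 24, 48, 72), c(1, 2, 1, 2)),
               "rank-deficient")
})

test_that("per-feature-per-group fit table has the promised layout", {
  d <- make_study_design(reps = 2)
  set.seed(61)
  truth <- plant_categories(c(SAME = 2), sigma = 0.5, snr = 4)
  sim <- simulate_expression(d, truth, noise = "gaussian", seed = 62)
  tab <- fit_cosinor_all(sim$matrix, d)
  expect_equal(nrow(tab), 2 * 2) # feature x group
  expect_true(all(c("feature", "group", "mesor", "amplitude",
                    "acrophase", "amplitude_pvalue", "n",
                    "converged") %in% names(tab)))
  expect_equal(unique(tab$n), nrow(d) / 2)
  expect_true(all(tab$amplitude >= 0))
})
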