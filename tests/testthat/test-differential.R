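test_that("offsets equal separate-fit differences on balanced data", {
  d <- make_study_design(reps = 4)
  set.seed(71)
  for (i in 1:10) {
    y <- gen_twogroup_data(d, mesor = runif(1, 2, 10),
                           amplitude = runif(1, 1, 5),
                           acrophase = runif(1, 0, 24),
                           d_mesor = runif(1, -2, 2),
                           d_amplitude = runif(1, -0.8, 2),
                           d_acrophase = runif(1, -3, 3), sigma = 0.4)
    joint <- cosinor_diff(d$time_h, y, d$group)
    ref <- cosinor_fit(d$time_h[d$group == "AIN93G"],
                       y[d$group == "AIN93G"])
    trt <- cosinor_fit(d$time_h[d$group == "HFD"],
                       y[d$group == "HFD"])
    off <- setNames(joint$offsets$estimate, joint$offsets$offset)
    expect_equal(off[["d_mesor"]],
                 trt$coefficients[["mesor"]] - ref$coefficients[["mesor"]],
                 tolerance = 1e-6)
    expect_equal(off[["d_amplitude"]],
                 trt$coefficients[["amplitude"]] -
                   ref$coefficients[["amplitude"]], tolerance = 1e-6)
    expect_phase_equal(off[["d_acrophase"]],
                       trt$coefficients[["acrophase"]] -
                         ref$coefficients[["acrophase"]], tol = 1e-6)
  }
})

test_that("identical groups give null offsets and no significance", {
  d <- make_study_design(reps = 3)
  set.seed(72)
  one <- gen_cosinor_data(reps = 3, sigma = 0.3)
  y <- rep(NA_real_, nrow(d)) # duplicate one group's data into both
  y[d$group == "AIN93G"] <- one$values[order(one$times)]
  y[d$group == "HFD"] <- one$values[order(one$times)]
  ord <- order(d$time_h)
  fit <- cosinor_diff(d$time_h, y, d$group)
  expect_equal(fit$offsets$estimate, rep(0, 3), tolerance = 1e-8)
  expect_false(any(fit$offsets$significant))
  # shared model reproduces the single-group fit's SSE
  single <- cosinor_fit(one$times, one$values)
  pooled <- diffrhythm:::fit_offset_constrained(
    d$time_h, y, as.numeric(d$group == "HFD"), 24,
    c(d_mesor = FALSE, d_amplitude = FALSE, d_acrophase = FALSE))
  expect_equal(pooled$sse, 2 * single$sse, tolerance = 1e-8)
})

test_that("group-label swap negates the offsets", {
  d <- make_study_design(reps = 3)
  set.seed(73)
  y <- gen_twogroup_data(d, d_mesor = 1.5, d_amplitude = 1,
                         d_acrophase = 2, sigma = 0.4)
  fwd <- cosinor_diff(d$time_h, y, d$group)
  rev <- cosinor_diff(d$time_h, y, d$group, reference = "HFD")
  o1 <- setNames(fwd$offsets$estimate, fwd$offsets$offset)
  o2 <- setNames(rev$offsets$estimate, rev$offsets$offset)
  expect_equal(o2[["d_mesor"]], -o1[["d_mesor"]], tolerance = 1e-8)
  expect_equal(o2[["d_amplitude"]], -o1[["d_amplitude"]],
               tolerance = 1e-8)
  expect_phase_equal(o2[["d_acrophase"]], -o1[["d_acrophase"]],
                     tol = 1e-8)
})

test_that("CI and p-value decisions coincide", {
  d <- make_study_design(reps = 3)
  set.seed(74)
  for (i in 1:15) {
    y <- gen_twogroup_data(d, d_mesor = runif(1, -1, 1),
                           d_amplitude = runif(1, -0.5, 0.5),
                           sigma = 0.6)
    fit <- cosinor_diff(d$time_h, y, d$group)
    o <- fit$offsets[!is.na(fit$offsets$se), ]
    ci_excl <- o$lower > 0 | o$upper < 0
    expect_equal(o$significant, ci_excl)
    expect_equal(o$significant, o$p <= 0.05)
  }
})

test_that("linear and Levenberg-Marquardt offset routes agree", {
  d <- make_study_design(reps = 3)
  set.seed(75)
  for (i in 1:8) {
    y <- gen_twogroup_data(d, d_mesor = runif(1, -2, 2),
                           d_amplitude = runif(1, 0, 1.5),
                           d_acrophase = runif(1, -4, 4), sigma = 0.4)
    lin <- cosinor_diff(d$time_h, y, d$group, method = "linear")
    nls <- cosinor_diff(d$time_h, y, d$group, method = "nls")
    expect_equal(nls$offsets$estimate[1:2], lin$offsets$estimate[1:2],
                 tolerance = 1e-6)
    expect_phase_equal(nls$offsets$estimate[3], lin$offsets$estimate[3],
                       tol = 1e-5)
    expect_equal(nls$sse, lin$sse, tolerance = 1e-8)
  }
})

test_that("acrophase offset is flagged unstable under rhythm collapse", {
  d <- make_study_design(reps = 3)
  set.seed(76)
  y <- gen_twogroup_data(d, amplitude = 3, d_amplitude = -3, sigma = 0.4)
  fit <- cosinor_diff(d$time_h, y, d$group)
  expect_true(fit$acrophase_unstable)
  expect_true(is.na(fit$offsets$se[fit$offsets$offset == "d_acrophase"]))
})

test_that("nested selection recovers a mesor-only difference", {
  d <- make_study_design(reps = 5)
  set.seed(77)
  hits <- 0L
  n_rep <- 60L
  for (i in seq_len(n_rep)) {
    y <- gen_twogroup_data(d, amplitude = 3, d_mesor = 5 * 0.5,
                           sigma = 0.5)
    sel <- nested_model_select(d$time_h, y, d$group)$selected
    if (sel[["d_mesor"]] && !sel[["d_amplitude"]] &&
        !sel[["d_acrophase"]]) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("nested selection keeps the shared model under the null", {
  d <- make_study_design(reps = 5)
  set.seed(78)
  n_rep <- 200L
  all_shared <- 0L
  for (i in seq_len(n_rep)) {
    y <- gen_twogroup_data(d, amplitude = 3, sigma = 0.5)
    sel <- nested_model_select(d$time_h, y, d$group)$selected
    if (!any(sel)) all_shared <- all_shared + 1L
  }
  # each of 3 tests keeps its offset out w.p. ~0.95; allow a wide band
  # around (1 - alpha)^3 ~ 0.857 for 200 replicates
  expect_gte(all_shared / n_rep, 0.78)
  expect_lte(all_shared / n_rep, 0.94)
})

test_that("percent offset summary reproduces published-style arithmetic", {
  # offset convention: treatment - reference on printed estimates
  expect_equal(2.27 - 0.89, 1.38)
  d <- make_study_design(reps = 5)
  y <- gen_twogroup_data(d, mesor = 5, amplitude = 2, d_mesor = 5,
                         d_amplitude = 2, sigma = 0)
  fit <- cosinor_diff(d$time_h, y, d$group)
  ps <- percent_offset_summary(fit)
  expect_equal(ps$percent[ps$parameter == "mesor"], 100)
  expect_equal(ps$percent[ps$parameter == "amplitude"], 100)
  expect_equal(ps$direction, c("increase", "increase"))
})
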