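test_that("low-count filter keeps exactly the features at threshold", {
  d <- make_study_design(reps = 1)
  n <- nrow(d)
  m <- rbind(at25 = rep(25, n), zero = rep(0, n), high = rep(100, n))
  colnames(m) <- d$sample_id
  m <- expression_matrix(m, d, scale = "counts")
  f <- filter_low_counts(m)
  expect_equal(rownames(f$matrix), c("at25", "high"))
  expect_equal(f$n_dropped, 1L)
  expect_equal(f$dropped, "zero")

  # constructed fixture: 40 of 100 features planted below the threshold
  set.seed(81)
  means <- c(runif(60, 30, 200), runif(40, 0, 20))
  mm <- t(sapply(means, function(mu) rep(round(mu), n)))
  rownames(mm) <- sprintf("f%03d", 1:100)
  colnames(mm) <- d$sample_id
  ff <- filter_low_counts(expression_matrix(mm, d, scale = "counts"))
  expect_equal(ff$n_retained, 60L)
  expect_setequal(ff$dropped, sprintf("f%03d", 61:100))

  expect_error(filter_low_counts(matrix(-1, 1, n)), "non-negative")

  # alternative statistics
  m2 <- matrix(c(rep(24, n - 1), 1000), 1, n,
               dimnames = list("spiky", d$sample_id))
  expect_equal(filter_low_counts(m2, stat = "min")$n_retained, 0L)
  expect_equal(filter_low_counts(m2, stat = "total")$n_retained, 1L)
})

test_that("candidate models have the documented structure", {
  d <- make_study_design(reps = 3)
  models <- candidate_models(d)
  expect_named(models, c("ARRHY", "LOSS", "GAIN", "SAME", "CHANGE"))
  expect_equal(unname(vapply(models, ncol, 1L)), c(2L, 4L, 4L, 4L, 6L))
  expect_true(all(vapply(models, nrow, 1L) == 42L))
  # SAME's column space is contained in CHANGE's (nesting)
  fitted_same <- qr.fitted(qr(models$CHANGE), models$SAME)
  expect_equal(unname(fitted_same), unname(models$SAME),
               tolerance = 1e-10)
})

test_that("planted categories are recovered with high probability", {
  d <- make_study_design(reps = 3)
  cfg <- rhythm_config()
  set.seed(82)
  n_rep <- 100L
  for (cat in c("ARRHY", "LOSS", "SAME")) {
    truth <- plant_categories(setNames(n_rep, cat), sigma = 1, snr = 5)
    sim <- simulate_expression(d, truth, noise = "gaussian", seed = 83)
    res <- classify_features(sim$matrix, d, cfg)
    acc <- mean(res$category == cat)
    expect_gte(acc, if (cat == "ARRHY") 0.9 else 0.95)
  }
})

test_that("weights are invariant under positive affine transforms", {
  d <- make_study_design(reps = 3)
  set.seed(84)
  truth <- plant_categories(c(CHANGE = 3), sigma = 1, snr = 3)
  sim <- simulate_expression(d, truth, noise = "gaussian", seed = 85)
  r1 <- classify_features(sim$matrix, d)
  r2 <- classify_features(2.5 * sim$matrix + 7, d)
  wcols <- grep("^w_", names(r1))
  expect_equal(r1[wcols], r2[wcols], tolerance = 1e-8)
  expect_equal(r1$category, r2$category)
})

test_that("categorize_all partitions features and is deterministic", {
  d <- make_study_design(reps = 3)
  set.seed(86)
  truth <- plant_categories(c(ARRHY = 4, LOSS = 4, GAIN = 4, SAME = 4,
                              CHANGE = 4), sigma = 0.3, snr = 8)
  sim <- simulate_expression(d, truth, noise = "gaussian", seed = 87)
  catz <- categorize_all(sim$matrix, d)
  expect_equal(sum(catz$counts), nrow(sim$matrix))
  expect_setequal(catz$categories$feature, rownames(sim$matrix))
  # very high signal-to-noise: every planted category recovered
  expect_equal(unname(catz$counts[RHYTHM_CATEGORIES]),
               rep(4L, 5))
  # duplicated rows classify identically; rerun is identical
  m2 <- sim$matrix[c(1, 1, 10, 10), ]
  rownames(m2) <- c("a1", "a2", "b1", "b2")
  r <- classify_features(m2, d)
  expect_equal(r$category[1], r$category[2])
  expect_equal(r$category[3], r$category[4])
  expect_identical(categorize_all(sim$matrix, d)$categories,
                   catz$categories)
})

test_that("empty matrices and count matrices are handled", {
  d <- make_study_design(reps = 3)
  empty <- matrix(numeric(), 0, nrow(d),
                  dimnames = list(NULL, d$sample_id))
  catz <- categorize_all(empty, d)
  expect_equal(sum(catz$counts), 0L)

  set.seed(88)
  truth <- plant_categories(c(SAME = 3), sigma = 0.4, snr = 6,
                            mesor_range = c(7, 9))
  sim <- simulate_expression(d, truth, noise = "nb", seed = 89)
  expect_equal(attr(sim$matrix, "scale"), "counts")
  catz2 <- categorize_all(sim$matrix, d)
  expect_equal(sum(catz2$counts), catz2$filter$n_retained)
})

test_that("circular-plot records carry amplitude ratio and phase shift", {
  d <- make_study_design(reps = 3)
  set.seed(90)
  truth <- plant_categories(c(CHANGE = 5), sigma = 0.3, snr = 8)
  sim <- simulate_expression(d, truth, noise = "gaussian", seed = 91)
  catz <- categorize_all(sim$matrix, d)
  circ <- catz$circular
  expect_true(all(circ$category != "ARRHY"))
  expect_true(all(is.finite(circ$log2_amp_ratio)))
  expect_true(all(circ$phase_diff_h > -12 & circ$phase_diff_h <= 12))
  # planted: treatment amplitude 1.8-2.5x reference
  expect_true(all(circ$log2_amp_ratio > 0))
})

test_that("the F-test screen controls error rates sensibly", {
  d <- make_study_design(reps = 3)
  set.seed(92)
  truth <- plant_categories(c(ARRHY = 50, SAME = 50), sigma = 1, snr = 5)
  sim <- simulate_expression(d, truth, noise = "gaussian", seed = 93)
  ft <- rhythm_ftest(sim$matrix, d)
  sig <- ft$q <= 0.05
  planted <- sim$truth$category[match(ft$feature, sim$truth$feature)]
  expect_gte(mean(sig[planted == "SAME"]), 0.95) # power at snr 5
  expect_lte(mean(sig[planted == "ARRHY"]), 0.1) # FDR-ish control
})
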