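#' Percent increase of a value over a positive reference
#'
#' `100 * (new / ref - 1)`, as quoted in report prose ("elevated by X%").
#'
#' @param ref positive reference value(s).
#' @param new new value(s).
#' @param round_out round to the nearest integer percent (report
#'   convention); set FALSE for full precision.
#' @return percent increase.
#' @export
percent_increase <- function(ref, new, round_out = TRUE) {
  if (any(ref <= 0)) stop("reference must be > 0")
  p <- 100 * (new / ref - 1)
  if (round_out) round(p) else p
}

#' Percent decrease of a value from a positive reference
#'
#' `100 * (1 - new / ref)` ("decreased by X%").
#'
#' @inheritParams percent_increase
#' @return percent decrease.
#' @export
percent_decrease <- function(ref, new, round_out = TRUE) {
  if (any(ref <= 0)) stop("reference must be > 0")
  p <- 100 * (1 - new / ref)
  if (round_out) round(p) else p
}

#' Signed percent difference between two group means
#'
#' `100 * (mean_trt - mean_ref) / mean_ref`: positive when the treatment
#' mean is greater ("X% greater"), negative when less.
#'
#' @param mean_ref positive reference-group mean.
#' @param mean_trt treatment-group mean.
#' @inheritParams percent_increase
#' @export
percent_difference_of_means <- function(mean_ref, mean_trt,
                                        round_out = TRUE) {
  if (any(mean_ref <= 0)) stop("reference mean must be > 0")
  p <- 100 * (mean_trt - mean_ref) / mean_ref
  if (round_out) round(p) else p
}

#' Two-sample comparison of groups pooled across time points
#'
#' Classic pooled-variance Student t test (the default; Welch available)
#' comparing all observations of the two groups regardless of sampling
#' time, with group means and standard errors of the mean, as in a
#' combined-timepoint comparison table.
#'
#' @param values numeric observations.
#' @param group two-level factor/character, reference level first.
#' @param var_equal pooled-variance Student test (TRUE, default) or
#'   Welch.
#' @param feature optional feature label carried into the record.
#' @return one-row data frame: feature, per-group mean, sem, n, t, p.
#' @export
combined_group_test <- function(values, group, var_equal = TRUE,
                                feature = NA_character_) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("two groups required")
  sp <- split(values, group)
  n <- vapply(sp, length, 1L)
  if (any(n < 2L)) stop("need n >= 2 per group")
  means <- vapply(sp, mean, 1)
  sems <- vapply(sp, function(v) stats::sd(v) / sqrt(length(v)), 1)
  if (all(sems == 0)) {
    # degenerate: no variance anywhere; identical means give p = 1
    tt <- list(statistic = c(t = 0),
               p.value = if (means[1L] == means[2L]) 1 else 0)
    flag <- TRUE
  } else {
    tt <- stats::t.test(sp[[2L]], sp[[1L]], var.equal = var_equal)
    flag <- FALSE
  }
  data.frame(feature = feature,
             mean_ref = means[1L], sem_ref = sems[1L], n_ref = n[1L],
             mean_trt = means[2L], sem_trt = sems[2L], n_trt = n[2L],
             t = unname(tt$statistic), p = tt$p.value,
             degenerate = flag, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Combined-timepoint group tests for every matrix row
#'
#' @param mat expression matrix.
#' @param design a [sample_design()].
#' @inheritParams combined_group_test
#' @return data frame with one [combined_group_test()] record per
#'   feature.
#' @export
combined_group_tests <- function(mat, design, var_equal = TRUE) {
  out <- lapply(rownames(mat), function(f)
    combined_group_test(mat[f, ], design$group, var_equal, feature = f))
  do.call(rbind, out)
}

#' Fitted cosinor curve points for external plotting
#'
#' @param fit a `cosinor_fit` or `cosinor_diff`.
#' @param times_grid evaluation grid (hours).
#' @return data frame of time and fitted value (per group for a
#'   two-group fit).
#' @export
fitted_curve <- function(fit, times_grid = seq(0, 24, by = 0.25)) {
  if (inherits(fit, "cosinor_diff")) {
    do.call(rbind, lapply(fit$groups, function(g)
      data.frame(group = g, time_h = times_grid,
                 fitted = predict(fit, times_grid,
                                  group = rep(g, length(times_grid))),
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(time_h = times_grid, fitted = predict(fit, times_grid))
  }
}

#' Published rhythm-parameter and group-mean tables
#'
#' Loads the packaged point-estimate tables (circadian-gene and
#' lipid-gene cosinor parameter estimates per diet group, the
#' combined-timepoint group means, and liver lipid content means) used by
#' the report-level percent-change summaries.
#'
#' @param which one of `"circadian_params"`, `"lipid_params"`,
#'   `"combined_means"`, `"liver_lipids"`.
#' @return data frame.
#' @export
published_estimates <- function(which = c("circadian_params",
                                          "lipid_params",
                                          "combined_means",
                                          "liver_lipids")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".tsv"),
                      package = "diffrhythm", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Percent-change summary of a parameter table
#'
#' Given a table of per-gene reference and treatment estimates for one
#' rhythm parameter, reports each gene's direction of change and integer
#' percent change, using the increase/decrease conventions of
#' [percent_increase()] and [percent_decrease()].
#'
#' @param est data frame with columns `gene`, `reference`, `treatment`.
#' @return data frame: gene, reference, treatment, direction, percent.
#' @export
percent_change_table <- function(est) {
  stopifnot(all(c("gene", "reference", "treatment") %in% names(est)))
  dir <- ifelse(est$treatment >= est$reference, "increase", "decrease")
  pct <- ifelse(dir == "increase",
                percent_increase(est$reference, est$treatment),
                percent_decrease(est$reference, est$treatment))
  data.frame(gene = est$gene, reference = est$reference,
             treatment = est$treatment, direction = dir, percent = pct,
             stringsAsFactors = FALSE)
}
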