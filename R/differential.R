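# Wrap an hour difference into (-T/2, T/2].
wrap_phase <- function(d, period_h = 24) {
  w <- (d + period_h / 2) %% period_h - period_h / 2
  ifelse(w == -period_h / 2, period_h / 2, w)
}

# Six-column group-offset harmonic basis:
# (1, cos, sin, g, g*cos, g*sin) with g = 1 for the treatment group.
offset_basis <- function(times, g, period_h) {
  B <- harmonic_basis(times, period_h)
  cbind(B, g = g, gcos = g * B[, 2L], gsin = g * B[, 3L])
}

#' Two-group cosinor with treatment offsets
#'
#' Jointly fits both groups with the treatment group's parameters
#' expressed as offsets from the reference group's:
#' `y = (M + g*dM) + (A + g*dA) * cos(2*pi/T * (t - phi - g*dphi))`,
#' `g = 0` for reference, `g = 1` for treatment. The offsets `dM`
#' (mesor), `dA` (amplitude) and `dphi` (acrophase, wrapped into
#' `(-T/2, T/2]`) carry Wald t confidence intervals with
#' `n_total - 6` degrees of freedom; an offset whose interval excludes 0
#' is called significant (equivalently p <= 1 - level).
#'
#' The default route exploits that the full offset model is intrinsically
#' linear: both groups' harmonics are estimated by least squares on a
#' six-column basis and the offset scale is reached by the delta method,
#' which yields exactly the converged nonlinear-least-squares solution and
#' its Jacobian-based covariance. `method = "nls"` runs the
#' Levenberg-Marquardt fit in the offset parameterization directly as a
#' cross-check.
#'
#' When either group is effectively arrhythmic (zero-amplitude p >= 0.5),
#' the acrophase offset is flagged unstable and its interval suppressed,
#' since a phase difference with a collapsed rhythm is not identified.
#'
#' @param times sampling times (hours) for all samples.
#' @param values response vector.
#' @param group two-level factor/character; first level (or `reference`)
#'   is the reference group.
#' @param period_h fixed period (hours).
#' @param level confidence level for offset intervals.
#' @param reference reference group label.
#' @param method `"linear"` (exact, default) or `"nls"`.
#' @return object of class `"cosinor_diff"` with components `reference`
#'   (parameter estimates and SEs), `offsets` (estimate, se, ci, p,
#'   significant per offset), `n`, `df` and the underlying fits.
#' @examples
#' d <- make_study_design(reps = 3)
#' set.seed(42)
#' y <- with(d, 5 + 2 * (group == levels(group)[2]) +
#'   3 * cos(2 * pi / 24 * (time_h - 18))) + rnorm(nrow(d), sd = 0.5)
#' fit <- cosinor_diff(d$time_h, y, d$group)
#' summary(fit)
#' @export
cosinor_diff <- function(times, values, group, period_h = 24,
                         level = 0.95, reference = NULL,
                         method = c("linear", "nls")) {
  method <- match.arg(method)
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("two groups required")
  if (!is.null(reference)) group <- stats::relevel(group, reference)
  g <- as.numeric(group == levels(group)[2L])
  stopifnot(length(times) == length(values), length(g) == length(values))
  fit_ref <- cosinor_fit(times[g == 0], values[g == 0], period_h)
  fit_trt <- cosinor_fit(times[g == 1], values[g == 1], period_h)

  X <- offset_basis(times, g, period_h)
  qrX <- qr(X)
  if (qrX$rank < 6L) stop("rank-deficient two-group harmonic design")
  n <- length(values)
  df <- n - 6L
  beta <- qr.coef(qrX, values)
  fitv <- drop(X %*% beta)
  res <- values - fitv
  sse <- sum(res^2)
  s2 <- sse / df
  vb <- s2 * chol2inv(qr.R(qrX))

  est6 <- offset_theta(beta, period_h)
  Gfull <- offset_jacobian(beta, period_h)
  vtheta <- if (is.null(Gfull)) matrix(NA_real_, 6, 6)
            else Gfull %*% vb %*% t(Gfull)
  dimnames(vtheta) <- list(names(est6), names(est6))
  se6 <- sqrt(pmax(diag(vtheta), 0))

  if (method == "nls") {
    nl <- offset_nls(times, values, g, period_h, est6)
    if (!is.null(nl)) { est6 <- nl$est; vtheta <- nl$vcov
      se6 <- sqrt(pmax(diag(vtheta), 0)); sse <- nl$sse
      s2 <- sse / df; res <- nl$residuals; fitv <- values - res }
  }

  tq <- stats::qt(1 - (1 - level) / 2, df)
  off_names <- c("d_mesor", "d_amplitude", "d_acrophase")
  unstable_phase <- fit_ref$amplitude_pvalue >= 0.5 ||
    fit_trt$amplitude_pvalue >= 0.5
  offs <- data.frame(
    offset = off_names,
    estimate = est6[off_names],
    se = se6[off_names],
    stringsAsFactors = FALSE)
  if (unstable_phase) offs[offs$offset == "d_acrophase", "se"] <- NA_real_
  offs$lower <- offs$estimate - tq * offs$se
  offs$upper <- offs$estimate + tq * offs$se
  offs$p <- 2 * stats::pt(abs(offs$estimate / offs$se), df,
                          lower.tail = FALSE)
  offs$significant <- !is.na(offs$p) & offs$p <= (1 - level)
  rownames(offs) <- NULL

  structure(list(
    reference = list(estimate = est6[c("mesor", "amplitude", "acrophase")],
                     se = se6[c("mesor", "amplitude", "acrophase")]),
    treatment = list(
      estimate = c(mesor = est6[["mesor"]] + est6[["d_mesor"]],
                   amplitude = est6[["amplitude"]] + est6[["d_amplitude"]],
                   acrophase = (est6[["acrophase"]] + est6[["d_acrophase"]]) %%
                     period_h),
      se = fit_trt$se),
    offsets = offs, vcov = vtheta, beta = beta,
    sse = sse, sigma2 = s2, df = df, n = n,
    n_per_group = c(reference = sum(g == 0), treatment = sum(g == 1)),
    groups = levels(group), period_h = period_h, level = level,
    fitted = fitv, residuals = res,
    fit_reference = fit_ref, fit_treatment = fit_trt,
    acrophase_unstable = unstable_phase,
    times = times, values = values, g = g,
    call = match.call()), class = "cosinor_diff")
}

# (M, A, phi, dM, dA, dphi) from the 6 linear coefficients.
offset_theta <- function(beta, period_h) {
  ref <- beta_to_cosinor(beta[1:3], period_h)
  b2 <- c(beta[1L] + beta[4L], beta[2L] + beta[5L], beta[3L] + beta[6L])
  trt <- beta_to_cosinor(b2, period_h)
  dphi <- if (is.na(ref[["acrophase"]]) || is.na(trt[["acrophase"]]))
    NA_real_ else wrap_phase(trt[["acrophase"]] - ref[["acrophase"]],
                             period_h)
  c(mesor = ref[["mesor"]], amplitude = ref[["amplitude"]],
    acrophase = ref[["acrophase"]],
    d_mesor = unname(beta[4L]),
    d_amplitude = trt[["amplitude"]] - ref[["amplitude"]],
    d_acrophase = dphi)
}

# Jacobian of (M, A, phi, dM, dA, dphi) w.r.t. the 6 linear coefficients.
offset_jacobian <- function(beta, period_h) {
  G1 <- cosinor_grad(beta[1:3], period_h)
  b2 <- c(beta[1L] + beta[4L], beta[2L] + beta[5L], beta[3L] + beta[6L])
  G2 <- cosinor_grad(b2, period_h)
  if (is.null(G1) || is.null(G2)) return(NULL)
  J <- matrix(0, 6, 6)
  J[1:3, 1:3] <- G1
  J[4L, ] <- c(0, 0, 0, 1, 0, 0)
  # treatment amplitude/phase depend on (bc + dc, bs + ds)
  J[5L, 2:3] <- G2[2L, 2:3] - G1[2L, 2:3]
  J[5L, 5:6] <- G2[2L, 2:3]
  J[6L, 2:3] <- G2[3L, 2:3] - G1[3L, 2:3]
  J[6L, 5:6] <- G2[3L, 2:3]
  rownames(J) <- c("mesor", "amplitude", "acrophase",
                   "d_mesor", "d_amplitude", "d_acrophase")
  J
}

# Direct LM fit in the offset parameterization; cross-check route.
offset_nls <- function(times, values, g, period_h, start6) {
  st <- as.list(start6)
  if (!is.finite(st$acrophase)) st$acrophase <- 0
  if (!is.finite(st$d_acrophase)) st$d_acrophase <- 0
  df_ <- data.frame(t = times, y = values, g = g)
  fit <- tryCatch(minpack.lm::nlsLM(
    y ~ (mesor + g * d_mesor) + (amplitude + g * d_amplitude) *
      cos(2 * pi / period_h * (t - acrophase - g * d_acrophase)),
    data = df_, start = st,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit),
                 error = function(e) matrix(NA_real_, 6, 6))
  if (cf[["amplitude"]] < 0) { # canonicalize reference amplitude
    a0 <- cf[["amplitude"]]
    cf[["amplitude"]] <- -a0
    cf[["d_amplitude"]] <- cf[["d_amplitude"]] + 2 * a0
    cf[["acrophase"]] <- cf[["acrophase"]] + period_h / 2
    cf[["d_acrophase"]] <- cf[["d_acrophase"]] - period_h / 2
    vc[] <- NA_real_ # covariance not carried through the re-representation
  }
  cf[["acrophase"]] <- cf[["acrophase"]] %% period_h
  cf[["d_acrophase"]] <- wrap_phase(cf[["d_acrophase"]], period_h)
  est <- cf[c("mesor", "amplitude", "acrophase",
              "d_mesor", "d_amplitude", "d_acrophase")]
  dimnames(vc) <- list(names(est), names(est))
  r <- stats::resid(fit)
  list(est = est, vcov = vc, sse = sum(r^2), residuals = r)
}

#' @export
coef.cosinor_diff <- function(object, ...) {
  c(object$reference$estimate,
    stats::setNames(object$offsets$estimate, object$offsets$offset))
}

#' @export
vcov.cosinor_diff <- function(object, ...) object$vcov

#' @export
fitted.cosinor_diff <- function(object, ...) object$fitted

#' @export
residuals.cosinor_diff <- function(object, ...) object$residuals

#' @export
confint.cosinor_diff <- function(object, parm = object$offsets$offset,
                                 level = object$level, ...) {
  tq <- stats::qt(1 - (1 - level) / 2, object$df)
  o <- object$offsets
  out <- cbind(lower = o$estimate - tq * o$se,
               upper = o$estimate + tq * o$se)
  rownames(out) <- o$offset
  out[parm, , drop = FALSE]
}

#' Predict from a two-group cosinor fit
#' @param object a `cosinor_diff`.
#' @param times times (hours).
#' @param group group labels for the new times.
#' @param ... unused.
#' @export
predict.cosinor_diff <- function(object, times = object$times,
                                 group = NULL, ...) {
  g <- if (is.null(group)) object$g
       else as.numeric(as.character(group) == object$groups[2L])
  th <- c(object$reference$estimate,
          stats::setNames(object$offsets$estimate, object$offsets$offset))
  phi <- ifelse(is.na(th[["acrophase"]]), 0, th[["acrophase"]])
  dphi <- ifelse(is.na(th[["d_acrophase"]]), 0, th[["d_acrophase"]])
  (th[["mesor"]] + g * th[["d_mesor"]]) +
    (th[["amplitude"]] + g * th[["d_amplitude"]]) *
    cos(2 * pi / object$period_h * (times - phi - g * dphi))
}

#' @export
print.cosinor_diff <- function(x, digits = 4, ...) {
  cat("Two-group cosinor offset model (period ", x$period_h, " h)\n",
      "reference: ", x$groups[1L], "  treatment: ", x$groups[2L],
      "  n = ", x$n, "\n", sep = "")
  cat("reference parameters:\n")
  print(round(rbind(estimate = x$reference$estimate,
                    se = x$reference$se), digits))
  cat("treatment offsets (", 100 * x$level, "% CI):\n", sep = "")
  print(cbind(round(x$offsets[2:5], digits),
              p = format.pval(x$offsets$p, digits = 2),
              sig = ifelse(x$offsets$significant, "*", "")),
        row.names = x$offsets$offset)
  if (x$acrophase_unstable)
    cat("note: a group is near-arrhythmic; acrophase offset unstable\n")
  invisible(x)
}

#' @export
summary.cosinor_diff <- function(object, ...) {
  tab <- data.frame(
    parameter = c("mesor", "amplitude", "acrophase"),
    ref_estimate = object$reference$estimate,
    ref_se = object$reference$se,
    trt_estimate = object$treatment$estimate,
    trt_se = object$treatment$se,
    difference = object$offsets$estimate,
    ci_lo = object$offsets$lower,
    ci_hi = object$offsets$upper,
    p = object$offsets$p,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, groups = object$groups, n = object$n,
                 df = object$df, level = object$level,
                 acrophase_unstable = object$acrophase_unstable),
            class = "summary.cosinor_diff")
}

#' @export
print.summary.cosinor_diff <- function(x, digits = 4, ...) {
  cat("Two-group cosinor: ", x$groups[2L], " vs ", x$groups[1L],
      " (reference); n = ", x$n, ", df = ", x$df, "\n", sep = "")
  tab <- x$table
  tab[2:9] <- lapply(tab[2:9], function(z) signif(z, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.cosinor_diff <- function(x, n_grid = 200, ...) {
  grid <- seq(min(x$times), max(x$times), length.out = n_grid)
  cols <- c("steelblue", "firebrick")
  graphics::plot(x$times, x$values, col = cols[x$g + 1],
                 xlab = "time (h)", ylab = "value", ...)
  graphics::lines(grid, predict(x, grid, group = rep(x$groups[1L],
                                                     n_grid)),
                  col = cols[1L], lwd = 2)
  graphics::lines(grid, predict(x, grid, group = rep(x$groups[2L],
                                                     n_grid)),
                  col = cols[2L], lwd = 2)
  graphics::legend("topright", legend = x$groups, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}

# Fit the offset model with a subset of offsets freed. Linear cases are
# solved exactly; mixed cases go through Levenberg-Marquardt.
fit_offset_constrained <- function(times, values, g, period_h,
                                   free = c(d_mesor = TRUE,
                                            d_amplitude = TRUE,
                                            d_acrophase = TRUE)) {
  B <- harmonic_basis(times, period_h)
  lin <- NULL
  if (all(free)) {
    lin <- offset_basis(times, g, period_h)
  } else if (!any(free)) {
    lin <- B
  } else if (free[["d_mesor"]] && !free[["d_amplitude"]] &&
             !free[["d_acrophase"]]) {
    lin <- cbind(B, g = g)
  } else if (!free[["d_mesor"]] && free[["d_amplitude"]] &&
             free[["d_acrophase"]]) {
    lin <- cbind(1, (1 - g) * B[, 2:3], g * B[, 2:3])
  }
  if (!is.null(lin)) {
    qrX <- qr(lin)
    res <- qr.resid(qrX, values)
    return(list(sse = sum(res^2), k = qrX$rank, linear = TRUE))
  }
  # nonlinear constrained fit
  full <- offset_theta(qr.coef(qr(offset_basis(times, g, period_h)),
                               values), period_h)
  st <- as.list(full)
  for (nm in names(free)) if (!free[[nm]]) st[[nm]] <- NULL
  if (!is.finite(st$acrophase)) st$acrophase <- 0
  if (!is.null(st$d_acrophase) && !is.finite(st$d_acrophase))
    st$d_acrophase <- 0
  terms <- c(
    mesor = "mesor", d_mesor = if (free[["d_mesor"]]) "g * d_mesor",
    amp = if (free[["d_amplitude"]]) "(amplitude + g * d_amplitude)"
          else "amplitude",
    phase = if (free[["d_acrophase"]])
      "(t - acrophase - g * d_acrophase)" else "(t - acrophase)")
  rhs <- paste0(terms[["mesor"]],
                if (free[["d_mesor"]]) " + g * d_mesor" else "",
                " + ", terms[["amp"]], " * cos(2 * pi / ", period_h,
                " * ", terms[["phase"]], ")")
  df_ <- data.frame(t = times, y = values, g = g)
  fit <- tryCatch(minpack.lm::nlsLM(
    stats::as.formula(paste("y ~", rhs)), data = df_, start = st,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(sse = NA_real_, k = 3L + sum(free), linear = FALSE))
  list(sse = sum(stats::resid(fit)^2), k = 3L + sum(free),
       linear = FALSE, fit = fit)
}

#' Nested model selection for the two-group cosinor
#'
#' Decides, per parameter, whether the treatment group needs its own
#' mesor, amplitude and acrophase or whether parameters shared with the
#' reference suffice. Each offset is tested by the extra-sum-of-squares F
#' test comparing the full six-parameter offset model against the model
#' with that one offset fixed at zero, at `alpha = 1 - level`. The
#' reported final model keeps only the offsets that are needed.
#'
#' On balanced designs these F decisions agree with the offset
#' confidence-interval calls of [cosinor_diff()] up to the usual
#' equivalence of t and F tests.
#'
#' @inheritParams cosinor_diff
#' @return list with `fit` (the full [cosinor_diff()]), `tests` (per
#'   offset: SSE of the reduced model, F, p, needed), `selected` (logical
#'   vector of retained offsets) and `final_sse`.
#' @export
nested_model_select <- function(times, values, group, period_h = 24,
                                level = 0.95, reference = NULL) {
  full <- cosinor_diff(times, values, group, period_h, level, reference)
  g <- full$g
  alpha <- 1 - level
  df_full <- full$df
  off_names <- c("d_mesor", "d_amplitude", "d_acrophase")
  tests <- data.frame(offset = off_names, sse_reduced = NA_real_,
                      F = NA_real_, p = NA_real_, needed = NA,
                      stringsAsFactors = FALSE)
  for (i in seq_along(off_names)) {
    free <- stats::setNames(off_names[i] != off_names, off_names)
    free[] <- TRUE
    free[off_names[i]] <- FALSE
    red <- fit_offset_constrained(times, values, g, period_h, free)
    Fstat <- ((red$sse - full$sse) / 1) / (full$sse / df_full)
    tests$sse_reduced[i] <- red$sse
    tests$F[i] <- max(Fstat, 0)
    tests$p[i] <- stats::pf(max(Fstat, 0), 1, df_full, lower.tail = FALSE)
    tests$needed[i] <- tests$p[i] <= alpha
  }
  selected <- stats::setNames(tests$needed, off_names)
  final <- fit_offset_constrained(times, values, g, period_h, selected)
  list(fit = full, tests = tests, selected = selected,
       final_sse = final$sse, final_k = final$k)
}

#' Percent change of amplitude and mesor, treatment vs reference
#'
#' Expresses each offset as the percent change the treatment shows
#' relative to the reference: an increase is reported as
#' `100 * (trt/ref - 1)` percent and a decrease as
#' `100 * (1 - trt/ref)` percent (both positive numbers, with a
#' direction label), rounded to the nearest integer as in report prose;
#' unrounded values are retained.
#'
#' @param object a `cosinor_diff`.
#' @return data frame with parameter, reference and treatment estimates,
#'   direction, percent (integer) and percent_exact.
#' @export
percent_offset_summary <- function(object) {
  out <- lapply(c("mesor", "amplitude"), function(p) {
    ref <- object$reference$estimate[[p]]
    trt <- object$treatment$estimate[[p]]
    if (ref == 0) stop("reference ", p, " is 0; percent change undefined")
    if (trt >= ref) {
      pe <- 100 * (trt / ref - 1); dir <- "increase"
    } else {
      pe <- 100 * (1 - trt / ref); dir <- "decrease"
    }
    data.frame(parameter = p, reference = ref, treatment = trt,
               direction = dir, percent = round(pe), percent_exact = pe,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
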