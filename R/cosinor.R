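#' Harmonic regression basis for a fixed-period cosinor
#'
#' Returns the design columns `(1, cos(2*pi*t/T), sin(2*pi*t/T))` that
#' linearize the cosinor model
#' `y = M + A * cos(2*pi/T * (t - phi))`, since
#' `A*cos(w*(t - phi)) = A*cos(w*phi)*cos(w*t) + A*sin(w*phi)*sin(w*t)`.
#'
#' @param times numeric vector of times in hours.
#' @param period_h oscillation period in hours (> 0).
#' @return numeric matrix with columns `intercept`, `cosw`, `sinw`.
#' @export
harmonic_basis <- function(times, period_h = 24) {
  if (period_h <= 0) stop("period_h must be > 0")
  w <- 2 * pi / period_h
  cbind(intercept = 1, cosw = cos(w * times), sinw = sin(w * times))
}

# Map linear harmonic coefficients (b0, bc, bs) to cosinor parameters.
# bc = A*cos(w*phi), bs = A*sin(w*phi); A >= 0, phi in [0, T).
beta_to_cosinor <- function(beta, period_h) {
  A <- sqrt(beta[2L]^2 + beta[3L]^2)
  phi <- if (A > 0) (atan2(beta[3L], beta[2L]) * period_h / (2 * pi)) %% period_h
         else NA_real_
  c(mesor = unname(beta[1L]), amplitude = unname(A), acrophase = unname(phi))
}

# Jacobian of (M, A, phi) w.r.t. (b0, bc, bs); undefined at A = 0.
cosinor_grad <- function(beta, period_h) {
  bc <- beta[2L]; bs <- beta[3L]
  A <- sqrt(bc^2 + bs^2)
  w <- 2 * pi / period_h
  if (A == 0) return(NULL)
  rbind(mesor     = c(1, 0, 0),
        amplitude = c(0, bc / A, bs / A),
        acrophase = c(0, -bs / (w * A^2), bc / (w * A^2)))
}

# Shared OLS core: returns everything a cosinor_fit needs from (times, y).
cosinor_ols_core <- function(times, values, period_h) {
  X <- harmonic_basis(times, period_h)
  qrX <- qr(X)
  if (qrX$rank < 3L)
    stop("rank-deficient harmonic design (times collapse modulo the period)")
  n <- length(values)
  if (n < 4L) stop("need n >= 4 observations")
  beta <- qr.coef(qrX, values)
  fit <- drop(X %*% beta)
  res <- values - fit
  sse <- sum(res^2)
  df <- n - 3L
  s2 <- sse / df
  XtXinv <- chol2inv(qr.R(qrX))
  vb <- s2 * XtXinv
  est <- beta_to_cosinor(beta, period_h)
  G <- cosinor_grad(beta, period_h)
  if (is.null(G)) {
    vcov3 <- matrix(NA_real_, 3, 3,
                    dimnames = list(names(est), names(est)))
    vcov3[1, 1] <- vb[1, 1]
    se <- c(sqrt(vb[1, 1]), NA_real_, NA_real_)
  } else {
    vcov3 <- G %*% vb %*% t(G)
    dimnames(vcov3) <- list(names(est), names(est))
    se <- sqrt(pmax(diag(vcov3), 0))
  }
  names(se) <- names(est)
  # zero-amplitude test: 2-df extra-sum-of-squares F against intercept-only
  sse0 <- sum((values - mean(values))^2)
  num <- max(sse0 - sse, 0)
  p_amp <- if (sse > 0) {
    stats::pf((num / 2) / (sse / df), 2, df, lower.tail = FALSE)
  } else if (est[["amplitude"]] > sqrt(.Machine$double.eps) * max(1, abs(est[["mesor"]]))) {
    0
  } else 1
  list(beta = beta, coefficients = est, se = se, vcov = vcov3,
       sigma2 = s2, sse = sse, df = df, n = n,
       fitted = fit, residuals = res, amplitude_pvalue = p_amp)
}

#' Fit a single-group cosinor model with fixed period
#'
#' Fits `y = M + A * cos(2*pi/T * (t - phi))` for one group of samples,
#' where `M` (mesor) is the rhythm-adjusted mean, `A >= 0` (amplitude) the
#' distance from mesor to peak, and `phi` (acrophase, hours in `[0, T)`)
#' the clock time of the peak. The period `T` is fixed (default 24 h), not
#' estimated.
#'
#' Two estimation routes are provided. `method = "ols"` (default) solves
#' the linearized harmonic regression by ordinary least squares and
#' obtains standard errors for `(M, A, phi)` by the delta method.
#' `method = "nls"` minimizes the same sum of squares directly by
#' Levenberg-Marquardt nonlinear least squares started from the OLS
#' solution; since the model is intrinsically linear both routes agree at
#' the optimum and the nls route exists mainly as a cross-check and for
#' parity with nonlinear extensions.
#'
#' The amplitude p-value is the 2-df extra-sum-of-squares F test of
#' `A = 0` (equivalently `beta_cos = beta_sin = 0`). Because the delta
#' method divides by `A`, the acrophase standard error is unreliable as
#' the rhythm collapses: when the amplitude p-value is >= 0.5 the
#' acrophase is flagged unstable and its confidence interval suppressed.
#'
#' @param times numeric vector of sampling times (hours); at least four
#'   distinct values are required.
#' @param values numeric response vector, same length as `times`.
#' @param period_h fixed period in hours.
#' @param method `"ols"` or `"nls"`.
#' @param init optional named start values `c(mesor=, amplitude=,
#'   acrophase=)` for the nls route; defaults to the OLS solution.
#' @return an object of class `"cosinor_fit"`; see [coef.cosinor_fit()],
#'   [summary.cosinor_fit()], [confint.cosinor_fit()],
#'   [predict.cosinor_fit()].
#' @examples
#' t <- rep(seq(0, 24, by = 4), each = 3)
#' y <- 10 + 3 * cos(2 * pi / 24 * (t - 18)) + rnorm(length(t), sd = 0.5)
#' fit <- cosinor_fit(t, y)
#' coef(fit)
#' confint(fit)
#' @export
cosinor_fit <- function(times, values, period_h = 24,
                        method = c("ols", "nls"), init = NULL) {
  method <- match.arg(method)
  stopifnot(length(times) == length(values))
  keep <- is.finite(times) & is.finite(values)
  if (!all(keep)) stop("non-finite times or values")
  if (length(unique(times %% period_h)) < 4L &&
      length(unique(times)) < 4L)
    stop("need >= 4 distinct time points")
  core <- cosinor_ols_core(times, values, period_h)
  converged <- TRUE
  used <- "ols"
  if (method == "nls") {
    nl <- cosinor_nls_core(times, values, period_h, core, init)
    if (!is.null(nl)) { core <- nl$core; converged <- nl$converged; used <- "nls" }
  }
  structure(c(core, list(times = times, values = values,
                         period_h = period_h, method = used,
                         converged = converged,
                         acrophase_unstable = core$amplitude_pvalue >= 0.5,
                         call = match.call())),
            class = "cosinor_fit")
}

# Levenberg-Marquardt refit; returns NULL if nlsLM is unusable, else a
# core list in the same shape as cosinor_ols_core plus a convergence flag.
cosinor_nls_core <- function(times, values, period_h, ols_core, init) {
  start <- if (is.null(init)) as.list(ols_core$coefficients)
           else as.list(init[c("mesor", "amplitude", "acrophase")])
  if (!is.finite(start$acrophase)) start$acrophase <- 0
  df_ <- data.frame(t = times, y = values)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ mesor + amplitude * cos(2 * pi / period_h * (t - acrophase)),
      data = df_, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e)
    matrix(NA_real_, 3, 3))
  # canonicalize: amplitude >= 0, acrophase in [0, T)
  if (cf[["amplitude"]] < 0) {
    cf[["amplitude"]] <- -cf[["amplitude"]]
    cf[["acrophase"]] <- cf[["acrophase"]] + period_h / 2
    S <- diag(c(1, -1, 1))
    vc <- S %*% vc %*% S
  }
  cf[["acrophase"]] <- cf[["acrophase"]] %% period_h
  est <- c(mesor = cf[["mesor"]], amplitude = cf[["amplitude"]],
           acrophase = cf[["acrophase"]])
  dimnames(vc) <- list(names(est), names(est))
  res <- stats::resid(fit)
  sse <- sum(res^2)
  n <- length(values)
  df <- n - 3L
  core <- list(beta = ols_core$beta, coefficients = est,
               se = sqrt(pmax(diag(vc), 0)), vcov = vc,
               sigma2 = sse / df, sse = sse, df = df, n = n,
               fitted = values - res, residuals = res,
               amplitude_pvalue = ols_core$amplitude_pvalue)
  list(core = core, converged = fit$convInfo$isConv %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
coef.cosinor_fit <- function(object, ...) object$coefficients

#' @export
vcov.cosinor_fit <- function(object, ...) object$vcov

#' @export
fitted.cosinor_fit <- function(object, ...) object$fitted

#' @export
residuals.cosinor_fit <- function(object, ...) object$residuals

#' Predict from a cosinor fit
#' @param object a `cosinor_fit`.
#' @param times times (hours) at which to evaluate the fitted curve;
#'   defaults to the fitting times.
#' @param ... unused.
#' @export
predict.cosinor_fit <- function(object, times = object$times, ...) {
  p <- object$coefficients
  p[["mesor"]] + p[["amplitude"]] *
    cos(2 * pi / object$period_h * (times - ifelse(is.na(p[["acrophase"]]),
                                                   0, p[["acrophase"]])))
}

#' Confidence intervals for cosinor parameters
#'
#' Wald-type intervals using the t distribution with `n - 3` degrees of
#' freedom. The acrophase interval is `NA` when the rhythm is too weak for
#' the delta-method phase uncertainty to be meaningful (amplitude p-value
#' >= 0.5).
#'
#' @param object a `cosinor_fit`.
#' @param parm parameters to include.
#' @param level confidence level.
#' @param ... unused.
#' @export
confint.cosinor_fit <- function(object, parm = names(object$coefficients),
                                level = 0.95, ...) {
  tq <- stats::qt(1 - (1 - level) / 2, object$df)
  se <- object$se
  if (object$acrophase_unstable) se[["acrophase"]] <- NA_real_
  est <- object$coefficients
  out <- cbind(lower = est - tq * se, upper = est + tq * se)
  out[parm, , drop = FALSE]
}

#' Simulate responses from a fitted cosinor model
#' @param object a `cosinor_fit`.
#' @param nsim number of response vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @export
simulate.cosinor_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu),
                                                  sd = sqrt(object$sigma2))))
}

#' @export
print.cosinor_fit <- function(x, digits = 4, ...) {
  cat("Cosinor fit (period ", x$period_h, " h, ", x$method, ", n = ",
      x$n, ")\n", sep = "")
  est <- rbind(estimate = x$coefficients, se = x$se)
  print(round(est, digits))
  cat("zero-amplitude test p = ", format.pval(x$amplitude_pvalue), "\n",
      sep = "")
  if (x$acrophase_unstable)
    cat("note: rhythm weak; acrophase unstable\n")
  invisible(x)
}

#' @export
summary.cosinor_fit <- function(object, level = 0.95, ...) {
  ci <- confint(object, level = level)
  tab <- data.frame(estimate = object$coefficients, se = object$se,
                    lower = ci[, "lower"], upper = ci[, "upper"])
  structure(list(table = tab, amplitude_pvalue = object$amplitude_pvalue,
                 sigma = sqrt(object$sigma2), df = object$df,
                 n = object$n, period_h = object$period_h,
                 level = level, converged = object$converged,
                 acrophase_unstable = object$acrophase_unstable),
            class = "summary.cosinor_fit")
}

#' @export
print.summary.cosinor_fit <- function(x, digits = 4, ...) {
  cat("Cosinor fit, period ", x$period_h, " h; n = ", x$n,
      ", residual df = ", x$df, "\n", sep = "")
  print(round(x$table, digits))
  cat("residual SD ", signif(x$sigma, digits),
      "; zero-amplitude p = ", format.pval(x$amplitude_pvalue), "\n",
      sep = "")
  invisible(x)
}

#' @export
plot.cosinor_fit <- function(x, n_grid = 200, ...) {
  grid <- seq(min(x$times), max(x$times), length.out = n_grid)
  graphics::plot(x$times, x$values, xlab = "time (h)", ylab = "value", ...)
  graphics::lines(grid, predict(x, grid), col = "steelblue", lwd = 2)
  invisible(x)
}

#' Fit a cosinor per feature per group of an expression matrix
#'
#' @param mat expression matrix (features x samples), columns aligned to
#'   `design`.
#' @param design a [sample_design()].
#' @param period_h fixed period in hours.
#' @return data frame: one row per feature x group with mesor, amplitude,
#'   acrophase, their SEs, the zero-amplitude p-value, n and convergence.
#' @export
fit_cosinor_all <- function(mat, design, period_h = 24) {
  rows <- list()
  for (g in levels(design$group)) {
    idx <- design$group == g
    tt <- design$time_h[idx]
    for (f in rownames(mat)) {
      fit <- cosinor_fit(tt, mat[f, idx], period_h)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, group = g,
        mesor = fit$coefficients[["mesor"]],
        mesor_se = fit$se[["mesor"]],
        amplitude = fit$coefficients[["amplitude"]],
        amplitude_se = fit$se[["amplitude"]],
        acrophase = fit$coefficients[["acrophase"]],
        acrophase_se = if (fit$acrophase_unstable) NA_real_
                       else fit$se[["acrophase"]],
        amplitude_pvalue = fit$amplitude_pvalue,
        n = fit$n, converged = fit$converged,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
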