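#' Study-style timecourse design
#'
#' Builds a balanced two-group design sampling both groups at the same
#' Zeitgeber times: by default 2 diet groups x 7 times (0 to 24 h every
#' 4 h) x 5 replicates = 70 samples, mirroring a mouse liver timecourse
#' in which five animals per group are terminated at each time point
#' (ZT 0 and ZT 24 are different animals on consecutive days).
#'
#' @param times Zeitgeber times in hours.
#' @param reps replicates per group per time (>= 1).
#' @param groups two group labels; the first is the reference.
#' @return a [sample_design()].
#' @export
make_study_design <- function(times = seq(0, 24, by = 4), reps = 5,
                              groups = c("AIN93G", "HFD")) {
  if (reps < 1) stop("reps must be >= 1")
  if (length(groups) != 2L) stop("exactly two groups")
  grid <- expand.grid(replicate = seq_len(reps), time_h = times,
                      group = groups, stringsAsFactors = FALSE)
  sample_design(
    sample_id = sprintf("%s_ZT%02g_r%d", grid$group, grid$time_h,
                        grid$replicate),
    group = grid$group, time_h = grid$time_h,
    replicate = grid$replicate, reference = groups[1L])
}

#' Cosinor mean curve
#' @param times hours.
#' @param mesor,amplitude,acrophase cosinor parameters.
#' @param period_h period in hours.
#' @export
cosinor_curve <- function(times, mesor, amplitude, acrophase,
                          period_h = 24) {
  mesor + amplitude * cos(2 * pi / period_h * (times - acrophase))
}

#' Truth table with planted differential-rhythmicity categories
#'
#' Draws per-feature reference and treatment cosinor parameters whose
#' relationship realizes each requested category: SAME shares all
#' parameters, LOSS zeroes the treatment amplitude, GAIN zeroes the
#' reference amplitude, CHANGE perturbs amplitude and phase, ARRHY has
#' zero amplitude in both groups. Amplitudes are expressed through the
#' signal-to-noise ratio `A / sigma`.
#'
#' @param n_per_category named or unnamed counts; unnamed counts recycle
#'   over ARRHY, LOSS, GAIN, SAME, CHANGE.
#' @param sigma noise SD on the analysis scale.
#' @param snr amplitude-to-noise ratio A / sigma of rhythmic features.
#' @param mesor_range range mesors are drawn from (uniform).
#' @return data frame: feature, category, mesor/amplitude/acrophase per
#'   group.
#' @export
plant_categories <- function(n_per_category = 100, sigma = 1, snr = 4,
                             mesor_range = c(6, 10)) {
  if (is.null(names(n_per_category)))
    n_per_category <- stats::setNames(
      rep_len(n_per_category, length(RHYTHM_CATEGORIES)),
      RHYTHM_CATEGORIES)
  A <- snr * sigma
  rows <- lapply(names(n_per_category), function(cat) {
    n <- n_per_category[[cat]]
    if (n == 0L) return(NULL)
    mes <- stats::runif(n, mesor_range[1L], mesor_range[2L])
    phi <- stats::runif(n, 0, 24)
    base <- data.frame(
      category = cat,
      mesor_ref = mes, amplitude_ref = A, acrophase_ref = phi,
      mesor_trt = mes, amplitude_trt = A, acrophase_trt = phi,
      stringsAsFactors = FALSE)
    switch(cat,
      ARRHY = { base$amplitude_ref <- 0; base$amplitude_trt <- 0 },
      LOSS = base$amplitude_trt <- 0,
      GAIN = base$amplitude_ref <- 0,
      SAME = NULL,
      CHANGE = { # clearly different rhythm in both groups
        base$amplitude_trt <- A * stats::runif(n, 1.8, 2.5)
        base$acrophase_trt <- (phi + stats::runif(n, 6, 12)) %% 24
      })
    base
  })
  out <- do.call(rbind, rows)
  out <- cbind(feature = sprintf("feat_%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  out$sigma <- sigma
  out
}

#' Simulate a two-group expression timecourse
#'
#' Generates an expression matrix under group-specific cosinor mean
#' structure. With `noise = "gaussian"` values are the cosinor mean plus
#' Gaussian noise on the given scale (qPCR-fold-change-like or
#' log-expression-like data). With `noise = "nb"` the cosinor structure
#' acts on the log2 scale: counts are negative binomial with mean
#' `2^(cosinor) * library_factor`, library factors lognormal with SD
#' `lib_sd`, giving overdispersed RNA-seq-like integer counts.
#'
#' @param design a [sample_design()].
#' @param truth data frame as from [plant_categories()] (columns
#'   `feature`, `mesor_ref`, `amplitude_ref`, `acrophase_ref`, and the
#'   `_trt` counterparts; optional `sigma`).
#' @param noise `"gaussian"` or `"nb"`.
#' @param sigma Gaussian noise SD; overrides `truth$sigma` if given.
#' @param dispersion NB dispersion (size = 1/dispersion).
#' @param lib_sd SD of log-normal library-size factors.
#' @param period_h period in hours.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return list: `matrix` (features x samples with `scale` attribute),
#'   `design`, `truth`.
#' @export
simulate_expression <- function(design, truth, noise = c("gaussian", "nb"),
                                sigma = NULL, dispersion = 0.05,
                                lib_sd = 0.1, period_h = 24,
                                seed = NULL) {
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sigma)) sigma <- truth$sigma %||% 1
  sigma <- rep_len(sigma, nrow(truth))
  if (noise == "gaussian" && any(sigma <= 0))
    stop("sigma must be > 0")
  if (noise == "nb" && dispersion <= 0) stop("dispersion must be > 0")
  g <- as.numeric(design$group == levels(design$group)[2L])
  n <- nrow(design)
  mu <- matrix(NA_real_, nrow(truth), n,
               dimnames = list(truth$feature, design$sample_id))
  for (i in seq_len(nrow(truth))) {
    mu[i, ] <- ifelse(g == 0,
      cosinor_curve(design$time_h, truth$mesor_ref[i],
                    truth$amplitude_ref[i], truth$acrophase_ref[i],
                    period_h),
      cosinor_curve(design$time_h, truth$mesor_trt[i],
                    truth$amplitude_trt[i], truth$acrophase_trt[i],
                    period_h))
  }
  if (noise == "gaussian") {
    m <- mu + matrix(stats::rnorm(length(mu), sd = rep(sigma, n)),
                     nrow(truth), n)
    attr(m, "scale") <- "normalized"
  } else {
    libf <- exp(stats::rnorm(n, 0, lib_sd))
    lambda <- sweep(2^mu, 2L, libf, `*`)
    m <- matrix(stats::rnbinom(length(lambda), mu = lambda,
                               size = 1 / dispersion),
                nrow(truth), n, dimnames = dimnames(mu))
    storage.mode(m) <- "double"
    attr(m, "scale") <- "counts"
  }
  dimnames(m) <- list(truth$feature, design$sample_id)
  list(matrix = m, design = design, truth = truth)
}

#' Simulate a qPCR Ct table from fold-change truth
#'
#' Encodes a per-sample fold-change truth into target cycle thresholds
#' as `ct_target = reference_gene_ct - log2(truth) + noise`, so the
#' 2^-ddCt pipeline (with a calibrator whose truth is 1) recovers the
#' planted fold changes exactly in the noiseless limit.
#'
#' @param design a [sample_design()].
#' @param truth_fc per-sample true fold changes (> 0), aligned with
#'   `design`; the calibrator samples should have truth 1.
#' @param gene gene label.
#' @param reference_gene_ct reference-gene Ct level (cycles).
#' @param sigma Ct measurement noise SD (cycles); 0 for noiseless.
#' @param seed RNG seed.
#' @return Ct data frame: sample_id, gene, ct_target, ct_reference.
#' @export
simulate_qpcr_ct <- function(design, truth_fc, gene = "gene1",
                             reference_gene_ct = 15, sigma = 0,
                             seed = NULL) {
  if (any(truth_fc <= 0)) stop("fold-change truth must be > 0")
  stopifnot(length(truth_fc) == nrow(design))
  if (!is.null(seed)) set.seed(seed)
  eps <- if (sigma > 0) stats::rnorm(nrow(design), 0, sigma) else 0
  data.frame(sample_id = design$sample_id, gene = gene,
             ct_target = reference_gene_ct - log2(truth_fc) + eps,
             ct_reference = reference_gene_ct,
             stringsAsFactors = FALSE)
}
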