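#' Delta-Ct: target Ct normalized to a reference gene
#'
#' `delta_ct = ct_target - ct_reference` (cycles). Lower values mean more
#' abundant target relative to the reference gene (e.g. 18S rRNA).
#'
#' @param ct_target target-gene cycle thresholds.
#' @param ct_reference reference-gene cycle thresholds, same length.
#' @return numeric vector of delta-Ct values.
#' @export
delta_ct <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("non-finite Ct values")
  ct_target - ct_reference
}

#' Fold change by the 2^-ddCt method
#'
#' `2^-(dct_sample - dct_calibrator)`: the relative quantity of a sample
#' against a calibrator, assuming amplification efficiency 2. The
#' calibrator maps to 1 and the result is strictly positive.
#'
#' @param dct_sample sample delta-Ct (cycles).
#' @param dct_calibrator calibrator delta-Ct (cycles); typically the mean
#'   delta-Ct of a baseline sample set.
#' @return fold-change ratio(s).
#' @export
ddct_fold_change <- function(dct_sample, dct_calibrator) {
  if (any(!is.finite(dct_sample)) || any(!is.finite(dct_calibrator)))
    stop("non-finite delta-Ct values")
  2^(-(dct_sample - dct_calibrator))
}

# TRUE for samples terminated in the light phase; the lights-on moment of
# day 2 (t = light_on + period) counts as light phase.
is_light_phase <- function(time_h, light_on_h = 0, light_off_h = 12,
                           period_h = 24) {
  tt <- (time_h - light_on_h) %% period_h
  tt < (light_off_h - light_on_h) | time_h == light_on_h + period_h
}

#' Phase-specific baseline normalization of fold changes
#'
#' Divides each light-phase value by the reference group's mean at the
#' lights-on baseline time (ZT 0) and each dark-phase value by the
#' reference group's mean at the lights-off baseline time (ZT 12), so the
#' reference-group baseline means map to 1. A sample at ZT 24 is treated
#' as the lights-on moment of day 2, i.e. light phase.
#'
#' @param values numeric vector aligned with `design` rows (one gene).
#' @param design a [sample_design()].
#' @param light_on_h Zeitgeber time of lights-on (baseline of the light
#'   phase).
#' @param light_off_h Zeitgeber time of lights-off (baseline of the dark
#'   phase).
#' @return normalized values, same order as `design`.
#' @export
phase_baseline_normalize <- function(values, design, light_on_h = 0,
                                     light_off_h = 12) {
  stopifnot(length(values) == nrow(design))
  ref <- design$group == reference_group(design)
  light <- is_light_phase(design$time_h, light_on_h, light_off_h)
  base_light <- values[ref & design$time_h == light_on_h]
  base_dark <- values[ref & design$time_h == light_off_h]
  if (!length(base_light))
    stop("reference group has no samples at the light baseline (ZT ",
         light_on_h, ")")
  if (!length(base_dark))
    stop("reference group has no samples at the dark baseline (ZT ",
         light_off_h, ")")
  out <- values
  out[light] <- values[light] / mean(base_light)
  out[!light] <- values[!light] / mean(base_dark)
  out
}

#' Read a qPCR Ct table
#'
#' Expects columns `sample_id`, `gene`, `ct_target`, `ct_reference`
#' (tab or comma delimited). Ct values must be finite and positive.
#'
#' @param path path to the Ct file.
#' @return data frame with the four columns.
#' @export
read_ct_table <- function(path) {
  d <- utils::read.delim(path, sep = sniff_delim(path),
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "gene", "ct_target", "ct_reference")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("Ct file missing column(s): ", paste(miss, collapse = ", "))
  validate_ct(d[need])
}

validate_ct <- function(ct) {
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_reference)))
    stop("Ct values must be finite")
  if (any(ct$ct_target <= 0) || any(ct$ct_reference <= 0))
    stop("Ct values must be > 0")
  ct
}

#' Relative quantification of a Ct table with phase-specific calibrators
#'
#' Runs the full 2^-ddCt pipeline per gene: delta-Ct against the
#' reference gene, calibration against the mean delta-Ct of the reference
#' group at the phase-appropriate baseline time (lights-on for
#' light-phase samples, lights-off for dark-phase samples), and
#' conversion to fold changes.
#'
#' @param ct data frame as from [read_ct_table()].
#' @param design a [sample_design()] covering all `sample_id`s.
#' @param light_on_h,light_off_h baseline Zeitgeber times.
#' @return data frame `sample_id, gene, group, time_h, fold_change`.
#' @export
ddct_quantify <- function(ct, design, light_on_h = 0, light_off_h = 12) {
  ct <- validate_ct(ct)
  idx <- match(ct$sample_id, design$sample_id)
  if (anyNA(idx)) stop("Ct table contains sample_ids absent from design")
  ct$group <- design$group[idx]
  ct$time_h <- design$time_h[idx]
  ct$dct <- delta_ct(ct$ct_target, ct$ct_reference)
  ref <- reference_group(design)
  out <- lapply(split(ct, ct$gene), function(g) {
    light <- is_light_phase(g$time_h, light_on_h, light_off_h)
    cal_light <- mean(g$dct[g$group == ref & g$time_h == light_on_h])
    cal_dark <- mean(g$dct[g$group == ref & g$time_h == light_off_h])
    if (!is.finite(cal_light) || !is.finite(cal_dark))
      stop("gene '", g$gene[1L], "': missing baseline samples in the ",
           "reference group")
    fc <- ifelse(light, ddct_fold_change(g$dct, cal_light),
                 ddct_fold_change(g$dct, cal_dark))
    data.frame(sample_id = g$sample_id, gene = g$gene, group = g$group,
               time_h = g$time_h, fold_change = fc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
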