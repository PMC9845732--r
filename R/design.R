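#' Construct and validate a sample design table
#'
#' A sample design maps each sample of a timecourse experiment to a group,
#' a Zeitgeber time (hours since lights-on) and a replicate index. Exactly
#' two groups are required, one of which is the reference (e.g. a control
#' diet); each group must cover at least four distinct times so that a
#' three-parameter cosinor leaves residual degrees of freedom.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param group character or factor with exactly two levels.
#' @param time_h numeric vector of Zeitgeber times in hours (>= 0).
#' @param replicate positive integer replicate index within group x time.
#' @param reference which group level is the reference; defaults to the
#'   lexicographically first level, with a warning.
#' @return A `data.frame` of class `"sample_design"` whose `group` column is
#'   a factor with the reference level first.
#' @export
sample_design <- function(sample_id, group, time_h, replicate,
                          reference = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  group <- as.character(group)
  lev <- sort(unique(group))
  if (length(lev) != 2L)
    stop("two groups required, found ", length(lev), ": ",
         paste(lev, collapse = ", "))
  if (is.null(reference)) {
    reference <- lev[1L]
    warning("reference group not specified; using lexicographic first: '",
            reference, "'")
  }
  if (!reference %in% lev)
    stop("reference group '", reference, "' not among group levels")
  group <- factor(group, levels = c(reference, setdiff(lev, reference)))
  time_h <- as.numeric(time_h)
  if (anyNA(time_h)) stop("unparseable time_h values")
  if (any(time_h < 0)) stop("time_h must be >= 0")
  replicate <- as.integer(replicate)
  if (anyNA(replicate) || any(replicate < 1L))
    stop("replicate must be a positive integer")
  for (g in levels(group)) {
    nt <- length(unique(time_h[group == g]))
    if (nt < 4L)
      stop("insufficient distinct time points in group '", g, "' (", nt,
           " < 4): a 3-parameter cosinor needs >= 4 distinct times")
  }
  out <- data.frame(sample_id = sample_id, group = group,
                    time_h = time_h, replicate = replicate,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_design", "data.frame")
  out
}

#' @return For `reference_group`, the name of the reference level.
#' @rdname sample_design
#' @param design a `sample_design`.
#' @export
reference_group <- function(design) levels(design$group)[1L]

# Sniff the field delimiter of a delimited text file from its header line:
# tab wins if present, else comma, else whitespace.
sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
}

#' Read a sample design table from delimited text
#'
#' The file must have a header with columns `sample_id`, `group`, `time_h`
#' and `replicate`; tab- and comma-delimited files are auto-detected. An
#' optional logical `reference` column (TRUE for reference-group rows) or
#' the `reference` argument fixes the reference group; otherwise the
#' lexicographically first group is used with a warning.
#'
#' @param path path to the design file.
#' @param reference optional reference group name.
#' @return a validated [sample_design()].
#' @export
read_design <- function(path, reference = NULL) {
  d <- utils::read.delim(path, sep = sniff_delim(path),
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "group", "time_h", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("design file missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(reference) && "reference" %in% names(d)) {
    flagged <- unique(d$group[as.logical(d$reference)])
    if (length(flagged) == 1L) reference <- flagged
  }
  sample_design(d$sample_id, d$group, d$time_h, d$replicate,
                reference = reference)
}

#' Read an expression matrix aligned to a design
#'
#' Reads a features-by-samples delimited text matrix whose first column
#' holds feature ids and whose remaining column names are the design's
#' sample ids. Columns are reordered to the design's sample order. Rows
#' containing missing values are dropped with a message.
#'
#' @param path path to the matrix file (tab or comma delimited).
#' @param design a [sample_design()] the columns must match.
#' @param scale one of `"counts"`, `"normalized"`, `"foldchange"`; counts
#'   must be non-negative integers.
#' @return numeric matrix (features x samples) with attribute `scale`.
#' @export
read_matrix <- function(path, design,
                        scale = c("normalized", "counts", "foldchange")) {
  scale <- match.arg(scale)
  d <- utils::read.delim(path, sep = sniff_delim(path),
                         stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  expression_matrix(m, design, scale = scale)
}

#' Validate (and column-align) an expression matrix against a design
#'
#' @param m numeric matrix with feature row names and sample column names.
#' @inheritParams read_matrix
#' @return the validated matrix, columns in design order, attribute `scale`.
#' @export
expression_matrix <- function(m, design,
                              scale = c("normalized", "counts",
                                        "foldchange")) {
  scale <- match.arg(scale)
  if (is.null(rownames(m)) || anyNA(rownames(m)) || any(rownames(m) == ""))
    stop("missing feature ids")
  if (anyDuplicated(rownames(m)))
    stop("duplicate feature ids")
  if (!setequal(colnames(m), design$sample_id))
    stop("matrix columns do not match design sample_ids")
  m <- m[, design$sample_id, drop = FALSE]
  bad <- rowSums(is.na(m)) > 0L
  if (any(bad)) {
    message("dropping ", sum(bad), " feature(s) with missing values")
    m <- m[!bad, , drop = FALSE]
  }
  if (scale == "counts") {
    if (any(m < 0)) stop("negative values not allowed on counts scale")
    if (any(m != round(m))) stop("non-integral values on counts scale")
  }
  attr(m, "scale") <- scale
  m
}

#' Write a table of records as tab-delimited text
#'
#' Writes with a header, no quoting of numerics, full double precision
#' (round-trips values to at least 12 significant digits), and a stable
#' column order. An empty data frame yields a header-only file.
#'
#' @param records a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the tunable constants of the analysis with validation.
#'
#' @param period_h oscillation period in hours; fixed, not estimated.
#' @param ci_level confidence level for interval-based decisions.
#' @param weight_cutoff minimum BIC weight for a non-fallback category call.
#' @param amplitude_cutoff minimum fitted amplitude (analysis scale) for a
#'   rhythmic category call.
#' @param count_filter_threshold mean-count retention threshold for
#'   RNA-seq features.
#' @param count_filter_stat how the count filter summarizes a feature's
#'   counts: `"mean"`, `"min"` or `"total"`.
#' @param rng_seed integer seed for simulation stages.
#' @return a validated list of class `"rhythm_config"`.
#' @export
rhythm_config <- function(period_h = 24, ci_level = 0.95,
                          weight_cutoff = 0.6, amplitude_cutoff = 0,
                          count_filter_threshold = 25,
                          count_filter_stat = c("mean", "min", "total"),
                          rng_seed = 1L) {
  count_filter_stat <- match.arg(count_filter_stat)
  if (!is.numeric(period_h) || period_h <= 0) stop("period_h must be > 0")
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1)
    stop("ci_level must be in (0, 1)")
  if (weight_cutoff < 0 || weight_cutoff > 1)
    stop("weight_cutoff must be in [0, 1]")
  if (amplitude_cutoff < 0) stop("amplitude_cutoff must be >= 0")
  if (count_filter_threshold < 0) stop("count_filter_threshold must be >= 0")
  structure(list(period_h = period_h, ci_level = ci_level,
                 weight_cutoff = weight_cutoff,
                 amplitude_cutoff = amplitude_cutoff,
                 count_filter_threshold = count_filter_threshold,
                 count_filter_stat = count_filter_stat,
                 rng_seed = as.integer(rng_seed)),
            class = "rhythm_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Unknown keys are rejected so typos fail before any computation.
#'
#' @param path a `.json`, `.yaml` or `.yml` file.
#' @return a [rhythm_config()].
#' @export
read_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(rhythm_config))
  extra <- setdiff(names(lst), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  do.call(rhythm_config, lst)
}
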