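META_COLS <- c("sample_id", "cat_id", "group", "timepoint", "cohort", "censored")

#' Validate a peak matrix
#'
#' A peak matrix is a numeric matrix of non-negative peak heights with samples
#' as rows and metabolites as columns; `NA` marks a missing (undetected) cell.
#' Row and column names must be unique sample and metabolite identifiers.
#'
#' @param x numeric matrix to validate.
#' @return `x`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_peak_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("peak matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("peak matrix must have sample (row) and metabolite (column) names")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate metabolite identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (any(x < 0, na.rm = TRUE))
    stop("peak intensities must be non-negative where not missing")
  invisible(x)
}

#' Read a peak table with sample metadata
#'
#' Reads a TSV (or CSV, by file extension) written by [write_peak_table()]:
#' the first six columns are `sample_id`, `cat_id`, `group`, `timepoint`,
#' `cohort`, `censored`, and the remaining columns are metabolite peak
#' heights. Empty cells become missing values.
#'
#' @param path path to a `.tsv`/`.txt` (tab-delimited) or `.csv` file.
#' @return list with `matrix` (peak matrix, samples x metabolites, `NA` for
#'   missing) and `meta` (data.frame of per-sample metadata).
#' @export
read_peak_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          quote = "\"", comment.char = "")
  missing_meta <- setdiff(META_COLS, names(df))
  if (length(missing_meta) > 0)
    stop("peak table is missing metadata column(s): ",
         paste(missing_meta, collapse = ", "))
  meta <- df[META_COLS]
  meta$censored <- as.logical(meta$censored)
  meta$timepoint <- as.integer(meta$timepoint)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample identifiers: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  if (!all(meta$group %in% c("control", "treated")))
    stop("group must be 'control' or 'treated'")
  mets <- names(df)[!(names(df) %in% META_COLS)]
  if (anyDuplicated(mets))
    stop("duplicate metabolite identifiers: ",
         paste(unique(mets[duplicated(mets)]), collapse = ", "))
  x <- as.matrix(df[mets])
  storage.mode(x) <- "double"
  rownames(x) <- meta$sample_id
  validate_peak_matrix(x)
  list(matrix = x, meta = meta)
}

#' Write a peak table with sample metadata
#'
#' @param x peak matrix (samples x metabolites, `NA` for missing cells).
#' @param meta data.frame with columns `sample_id`, `cat_id`, `group`,
#'   `timepoint`, `cohort`, `censored`, one row per row of `x`.
#' @param path output file; tab-delimited unless the extension is `.csv`.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(x, meta, path) {
  validate_peak_matrix(x)
  stopifnot(nrow(x) == nrow(meta), all(META_COLS %in% names(meta)))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- cbind(meta[META_COLS], as.data.frame(x, check.names = FALSE))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Impute missing peak intensities
#'
#' The `half_min` rule replaces each missing cell with half the minimum
#' observed intensity of that metabolite across all samples, a conventional
#' stand-in for values below the detection limit. Metabolites that are missing
#' in every sample cannot be imputed and are dropped (recorded in the
#' `"dropped"` attribute and reported via `message()`).
#'
#' @param x peak matrix with `NA` for missing cells.
#' @param rule `"half_min"` or `"none"` (leave missing values in place).
#' @return imputed peak matrix; dropped metabolite names in `attr(, "dropped")`.
#' @export
impute_missing <- function(x, rule = c("half_min", "none")) {
  rule <- match.arg(rule)
  validate_peak_matrix(x)
  if (rule == "none") return(x)
  all_missing <- colSums(!is.na(x)) == 0L
  dropped <- colnames(x)[all_missing]
  if (length(dropped) > 0) {
    message("impute_missing: dropping ", length(dropped),
            " metabolite(s) missing in every sample: ",
            paste(dropped, collapse = ", "))
    x <- x[, !all_missing, drop = FALSE]
  }
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- min(x[!miss, j]) / 2
  }
  attr(x, "dropped") <- dropped
  x
}

#' Remove the lowest-variance metabolites
#'
#' Drops the `floor(fraction * p)` metabolites with the smallest sample
#' standard deviation (n-1 denominator), computed on the raw (imputed)
#' intensities. Constant metabolites (SD 0) are by construction removed first.
#' Column order of the survivors is preserved.
#'
#' @param x complete (imputed) peak matrix.
#' @param fraction fraction of metabolites to remove, in `[0, 1)`.
#' @return filtered peak matrix; removed names in `attr(, "removed")`.
#' @export
filter_low_sd <- function(x, fraction) {
  validate_peak_matrix(x)
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1)
    stop("fraction must be in [0, 1)")
  k <- floor(fraction * ncol(x))
  if (k == 0L) {
    attr(x, "removed") <- character(0)
    return(x)
  }
  sds <- apply(x, 2, stats::sd)
  drop_idx <- order(sds, seq_along(sds))[seq_len(k)]
  removed <- colnames(x)[drop_idx]
  out <- x[, -drop_idx, drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Generalized log2 transform
#'
#' Applies `glog2(x) = log2((x + sqrt(x^2 + a^2)) / 2)` elementwise. The
#' transform is strictly increasing, behaves like `log2(x)` for `x >> a` and
#' is defined at zero (`glog2(0) = log2(a/2)`), stabilising the variance of
#' peak-height data without special-casing zeros.
#'
#' @param x complete peak matrix.
#' @param a positive tuning constant (default 1).
#' @return transformed matrix (same dimnames).
#' @export
glog2 <- function(x, a = 1) {
  if (!is.numeric(a) || length(a) != 1 || a <= 0) stop("a must be > 0")
  if (anyNA(x)) stop("glog2 requires a complete matrix; impute first")
  log2((x + sqrt(x^2 + a^2)) / 2)
}

#' Autoscale a matrix (unit-variance scaling)
#'
#' Mean-centres each metabolite and divides by its sample standard deviation
#' (n-1 denominator). Metabolites with zero SD carry no information on this
#' sample set and are dropped (recorded in the returned params).
#'
#' @param x complete matrix with at least two rows.
#' @return list with `matrix` (scaled), and `params`: a list with `center`,
#'   `scale` (named numeric vectors over retained metabolites) and `dropped`
#'   (names of zero-SD metabolites).
#' @export
autoscale <- function(x) {
  if (anyNA(x)) stop("autoscale requires a complete matrix")
  if (nrow(x) < 2) stop("autoscale requires at least 2 samples")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[scl == 0]
  keep <- scl > 0
  x <- x[, keep, drop = FALSE]
  ctr <- ctr[keep]
  scl <- scl[keep]
  scaled <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  list(matrix = scaled,
       params = list(center = ctr, scale = scl, dropped = dropped))
}

#' Apply stored autoscaling parameters to new samples
#'
#' Projects new samples onto the scaling fitted by [autoscale()] without
#' refitting; metabolites dropped at fit time are dropped here too.
#'
#' @param x matrix whose columns include all metabolites retained at fit time.
#' @param params `params` element returned by [autoscale()].
#' @return scaled matrix over the retained metabolites.
#' @export
autoscale_apply <- function(x, params) {
  need <- names(params$center)
  missing_cols <- setdiff(need, colnames(x))
  if (length(missing_cols) > 0)
    stop("matrix lacks metabolite(s) required by scaling params: ",
         paste(missing_cols, collapse = ", "))
  x <- x[, need, drop = FALSE]
  sweep(sweep(x, 2, params$center, "-"), 2, params$scale, "/")
}

#' Preprocessing configuration
#'
#' @param sd_filter_fraction fraction of lowest-SD metabolites to remove;
#'   `NULL` (default) resolves to 0.05 when the table holds at least 250
#'   metabolites and 0 otherwise.
#' @param glog_offset positive constant `a` of the generalized log transform.
#' @param impute `"half_min"` or `"none"`.
#' @param autoscale whether to autoscale after transformation.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(sd_filter_fraction = NULL, glog_offset = 1,
                              impute = "half_min", autoscale = TRUE) {
  if (!is.null(sd_filter_fraction) &&
      (sd_filter_fraction < 0 || sd_filter_fraction >= 1))
    stop("sd_filter_fraction must be in [0, 1)")
  if (glog_offset <= 0) stop("glog_offset must be > 0")
  structure(list(sd_filter_fraction = sd_filter_fraction,
                 glog_offset = glog_offset,
                 impute = match.arg(impute, c("half_min", "none")),
                 autoscale = autoscale),
            class = "preprocess_config")
}

#' Run the fixed preprocessing pipeline
#'
#' Applies, in order: missing-value imputation, SD filtering, generalized log2
#' transform and (optionally) autoscaling. Each stage's metabolite counts are
#' reported via `message()`.
#'
#' @param x peak matrix (`NA` for missing cells).
#' @param config a [preprocess_config()].
#' @return list with `matrix` (processed), `scaling` (autoscale params or
#'   `NULL`), and `log` (data.frame of per-stage metabolite counts).
#' @export
preprocess <- function(x, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  log <- data.frame(stage = character(0), n_in = integer(0), n_out = integer(0))
  note <- function(stage, n_in, n_out) {
    message(sprintf("preprocess/%s: %d -> %d metabolites", stage, n_in, n_out))
    rbind(log, data.frame(stage = stage, n_in = n_in, n_out = n_out))
  }
  p0 <- ncol(x)
  x <- impute_missing(x, config$impute)
  log <- note("impute", p0, ncol(x))
  frac <- config$sd_filter_fraction
  if (is.null(frac)) frac <- if (ncol(x) >= 250) 0.05 else 0
  p0 <- ncol(x)
  x <- filter_low_sd(x, frac)
  log <- note("sd_filter", p0, ncol(x))
  x <- glog2(x, config$glog_offset)
  scaling <- NULL
  if (isTRUE(config$autoscale)) {
    p0 <- ncol(x)
    sc <- autoscale(x)
    x <- sc$matrix
    scaling <- sc$params
    log <- note("autoscale", p0, ncol(x))
  }
  list(matrix = x, scaling = scaling, log = log)
}
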