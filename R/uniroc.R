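#' Univariate ROC AUC for one metabolite
#'
#' Mann-Whitney AUC with ties counted one half: `AUC = (#(t > c) +
#' 0.5 * #(t = c)) / (n_t * n_c)`, computed via midranks. The raw AUC is the
#' probability that a random treated sample scores above a random control; the
#' orientation-free AUC, `max(AUC, 1 - AUC)`, treats a metabolite that
#' decreases under treatment the same as one that increases, and is the
#' quantity used for panel thresholding.
#'
#' @param control_values,treated_values numeric vectors of intensities
#'   (any strictly monotone transform of them yields the same AUC).
#' @return list with `raw` and `orientation_free`.
#' @export
auc_univariate <- function(control_values, treated_values) {
  if (length(control_values) == 0 || length(treated_values) == 0)
    stop("both groups must be non-empty")
  if (anyNA(control_values) || anyNA(treated_values))
    stop("auc_univariate requires complete values")
  nc <- length(control_values); nt <- length(treated_values)
  r <- rank(c(control_values, treated_values))
  u <- sum(r[nc + seq_len(nt)]) - nt * (nt + 1) / 2
  raw <- u / (nt * nc)
  list(raw = raw, orientation_free = max(raw, 1 - raw))
}

#' Univariate AUC for every metabolite of a matrix
#'
#' @param x complete matrix, samples x metabolites.
#' @param y two-class labels (see [fit_plsda()] for accepted codings); the
#'   second level (`treated`) is the positive class.
#' @return data.frame with `metabolite`, `auc_raw`, `auc` (orientation-free).
#' @export
auc_by_metabolite <- function(x, y) {
  x <- as.matrix(x)
  yc <- encode_classes(y)
  ctl <- yc$y01 == 0
  if (!any(ctl) || !any(!ctl)) stop("both groups must be non-empty")
  res <- vapply(seq_len(ncol(x)), function(j) {
    a <- auc_univariate(x[ctl, j], x[!ctl, j])
    c(a$raw, a$orientation_free)
  }, numeric(2))
  data.frame(metabolite = colnames(x), auc_raw = res[1, ], auc = res[2, ],
             stringsAsFactors = FALSE)
}
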