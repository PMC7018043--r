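#' Fit a random-forest classifier with out-of-bag bookkeeping
#'
#' Grows `n_trees` Gini CART trees on bootstrap samples with `mtry` candidate
#' metabolites per split (the `randomForest` implementation), keeping
#' per-tree out-of-bag (OOB) information so that permutation importance can
#' be computed. `mtry` larger than the number of metabolites is clamped with
#' a warning (relevant when refitting on a small selected panel). The fit is
#' reproducible from `seed`.
#'
#' @param x complete matrix, samples x metabolites.
#' @param y two-class labels.
#' @param n_trees number of trees (default 500).
#' @param mtry candidate metabolites per split (default 7).
#' @param seed integer seed.
#' @return object of class `forest_model`: list with the underlying `rf`
#'   fit, `oob_error` (OOB misclassification rate), `levels`, and the
#'   parameters used.
#' @export
fit_forest <- function(x, y, n_trees = 500, mtry = 7, seed = 1) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("fit_forest requires a complete matrix")
  if (n_trees < 1) stop("n_trees must be >= 1")
  yc <- encode_classes(y)
  if (length(unique(yc$y01)) < 2) stop("both classes must be present in y")
  if (mtry > ncol(x)) {
    warning("mtry (", mtry, ") exceeds the number of metabolites (", ncol(x),
            "); clamping")
    mtry <- ncol(x)
  }
  yf <- factor(yc$levels[yc$y01 + 1], levels = yc$levels)
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = x, y = yf, ntree = n_trees,
                                   mtry = mtry, importance = TRUE,
                                   keep.forest = TRUE)
  structure(list(rf = rf, oob_error = unname(rf$err.rate[n_trees, "OOB"]),
                 levels = yc$levels, n_trees = n_trees, mtry = mtry,
                 seed = as.integer(seed), metabolites = colnames(x)),
            class = "forest_model")
}

#' Out-of-bag permutation importance (mean decrease in accuracy)
#'
#' For each tree and metabolite, the accuracy on the tree's OOB samples is
#' compared with the accuracy on the same samples after permuting that
#' metabolite's values; the mean decrease in accuracy (MDA) is the average
#' drop over trees, reported as a raw (unscaled) proportion. A metabolite no
#' split uses has MDA exactly 0; negative values occur by chance and are
#' preserved. Published tables print the same quantity as a percentage
#' (0.004 = 0.4%).
#'
#' @param model fitted `forest_model`.
#' @return data.frame with `metabolite`, `mda` (proportion, in `[-1, 1]`)
#'   and `mda_sd` (between-tree SD of the per-tree decreases).
#' @export
oob_mda <- function(model) {
  if (!inherits(model, "forest_model")) stop("oob_mda requires a forest_model")
  imp <- randomForest::importance(model$rf, type = 1, scale = FALSE)
  sds <- model$rf$importanceSD[, "MeanDecreaseAccuracy"]
  data.frame(metabolite = rownames(imp), mda = unname(imp[, 1]),
             mda_sd = unname(sds), stringsAsFactors = FALSE)
}

#' Class-probability scores from a forest
#'
#' @param object fitted `forest_model`.
#' @param newdata matrix of new samples.
#' @param ... unused.
#' @return numeric vector: fraction of trees voting for the second
#'   (`treated`) class.
#' @export
predict.forest_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$metabolites) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$metabolites, drop = FALSE]
  pr <- stats::predict(object$rf, newdata, type = "prob")
  unname(pr[, object$levels[2]])
}
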