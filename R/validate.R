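#' Classifier specification for panel validation
#'
#' @param kind `"plsda"` or `"rf"`.
#' @param ncomp PLS-DA components (default 2).
#' @param n_trees,mtry random-forest parameters (defaults 500 and 7; `mtry`
#'   is clamped to the panel size when larger).
#' @param threshold decision threshold on the predicted score in `[0, 1]`
#'   (default 0.5; scores above it are called treated).
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("plsda", "rf"), ncomp = 2,
                            n_trees = 500, mtry = 7, threshold = 0.5) {
  kind <- match.arg(kind)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  structure(list(kind = kind, ncomp = ncomp, n_trees = n_trees, mtry = mtry,
                 threshold = threshold),
            class = "classifier_spec")
}

# Fit the configured classifier on an (unscaled) feature matrix; scaling is
# fitted here so held-out samples can be projected with the same params.
fit_panel_classifier <- function(x, y, spec, seed = 1) {
  sc <- autoscale(x)
  model <- if (spec$kind == "plsda") {
    fit_plsda(sc$matrix, y, ncomp = min(spec$ncomp, nrow(x) - 1, ncol(sc$matrix)))
  } else {
    suppressWarnings(fit_forest(sc$matrix, y, n_trees = spec$n_trees,
                                mtry = min(spec$mtry, ncol(sc$matrix)),
                                seed = seed))
  }
  list(model = model, scaling = sc$params, spec = spec)
}

# Continuous treated-class score in [0, 1] for new (unscaled) samples.
score_panel_classifier <- function(fit, x) {
  xs <- autoscale_apply(as.matrix(x), fit$scaling)
  s <- predict(fit$model, xs)
  pmin(pmax(s, 0), 1)
}

#' Sensitivity and specificity from a confusion matrix
#'
#' Treated is the positive class: `sensitivity = 100 * tp / (tp + fn)`,
#' `specificity = 100 * tn / (tn + fp)`, in percent. A zero denominator is an
#' explicit error (the metric is undefined), never a silent zero.
#'
#' @param cm named numeric vector or list with `tp`, `fn`, `tn`, `fp`.
#' @return named numeric vector `c(sensitivity =, specificity =)` in percent.
#' @export
confusion_metrics <- function(cm) {
  cm <- as.list(cm)
  stopifnot(all(c("tp", "fn", "tn", "fp") %in% names(cm)))
  counts <- as.numeric(cm[c("tp", "fn", "tn", "fp")])
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (cm$tp + cm$fn == 0) stop("sensitivity undefined: no positive samples")
  if (cm$tn + cm$fp == 0) stop("specificity undefined: no negative samples")
  c(sensitivity = 100 * cm$tp / (cm$tp + cm$fn),
    specificity = 100 * cm$tn / (cm$tn + cm$fp))
}

confusion_from_scores <- function(score, y01, threshold) {
  call <- as.integer(score > threshold)
  c(tp = sum(call == 1 & y01 == 1), fn = sum(call == 0 & y01 == 1),
    tn = sum(call == 0 & y01 == 0), fp = sum(call == 1 & y01 == 0))
}

roc_curve_points <- function(score, y01) {
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  t(vapply(thr, function(th) {
    c(fpr = mean(score[y01 == 0] >= th), tpr = mean(score[y01 == 1] >= th))
  }, numeric(2)))
}

#' Monte Carlo cross-validated multivariate ROC
#'
#' Repeatedly draws class-stratified train/test splits, fits the configured
#' classifier on the training part (autoscaling refit inside each fold) and
#' scores the held-out part. Each sample's score is averaged over the
#' repetitions in which it was held out; the aggregate confusion matrix
#' thresholds those averaged scores, and the ROC curve sweeps the threshold
#' across them.
#'
#' @param x complete, unscaled (e.g. glog-transformed) matrix restricted to
#'   the panel metabolites.
#' @param y two-class labels (both classes with at least 2 samples).
#' @param spec a [classifier_spec()].
#' @param n_reps number of Monte Carlo repetitions (default 100).
#' @param train_fraction fraction of each class trained on (default 2/3).
#' @param seed integer seed.
#' @return list of class `mccv_result`: `confusion` (aggregate counts),
#'   `sensitivity`, `specificity`, `accuracy` (percent), `scores`
#'   (per-sample mean held-out score), `roc` (FPR/TPR matrix), `importance`
#'   (per-metabolite mean VIP or MDA across reps), `n_reps`,
#'   `rep_confusions`.
#' @export
mccv_roc <- function(x, y, spec = classifier_spec("plsda"), n_reps = 100,
                     train_fraction = 2 / 3, seed = 1) {
  x <- as.matrix(x)
  yc <- encode_classes(y)
  n <- nrow(x)
  idx0 <- which(yc$y01 == 0); idx1 <- which(yc$y01 == 1)
  if (length(idx0) < 2 || length(idx1) < 2)
    stop("each class needs at least 2 samples")
  k0 <- floor(train_fraction * length(idx0))
  k1 <- floor(train_fraction * length(idx1))
  if (k0 < 1 || k1 < 1 || k0 >= length(idx0) || k1 >= length(idx1))
    stop("train_fraction leaves a fold without both classes on each side")
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  score_sum <- numeric(n); score_n <- integer(n)
  imp_sum <- stats::setNames(numeric(ncol(x)), colnames(x))
  rep_cms <- matrix(0L, n_reps, 4, dimnames = list(NULL, c("tp", "fn", "tn", "fp")))
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    tr <- c(sample(idx0, k0), sample(idx1, k1))
    te <- setdiff(seq_len(n), tr)
    fit <- fit_panel_classifier(x[tr, , drop = FALSE], yc$y01[tr], spec,
                                seed = rep_seeds[r])
    s <- score_panel_classifier(fit, x[te, , drop = FALSE])
    score_sum[te] <- score_sum[te] + s
    score_n[te] <- score_n[te] + 1L
    rep_cms[r, ] <- confusion_from_scores(s, yc$y01[te], spec$threshold)
    imp <- if (spec$kind == "plsda") vip_scores(fit$model)
           else stats::setNames(oob_mda(fit$model)$mda, fit$model$metabolites)
    imp_sum[names(imp)] <- imp_sum[names(imp)] + imp
  }
  eval_idx <- score_n > 0
  mean_score <- ifelse(eval_idx, score_sum / pmax(score_n, 1L), NA_real_)
  cm <- confusion_from_scores(mean_score[eval_idx], yc$y01[eval_idx],
                              spec$threshold)
  metrics <- confusion_metrics(cm)
  structure(list(confusion = cm,
                 sensitivity = unname(metrics["sensitivity"]),
                 specificity = unname(metrics["specificity"]),
                 accuracy = 100 * (cm["tp"] + cm["tn"]) / sum(cm),
                 scores = stats::setNames(mean_score, rownames(x)),
                 roc = roc_curve_points(mean_score[eval_idx],
                                        yc$y01[eval_idx]),
                 importance = imp_sum / n_reps,
                 n_reps = n_reps, rep_confusions = rep_cms,
                 spec = spec),
            class = "mccv_result")
}

#' Cross-cohort panel prediction
#'
#' Fits the configured classifier on all training-cohort samples of one time
#' point and predicts every testing-cohort sample of the paired time point.
#' Panel metabolites are matched by name; the two cohorts are expected to
#' have been preprocessed (and are autoscaled here) independently.
#'
#' @param train_x,train_y training-cohort panel matrix (unscaled) and labels.
#' @param test_x,test_y testing-cohort panel matrix and labels.
#' @param panel character vector of panel metabolite names.
#' @param spec a [classifier_spec()].
#' @param seed integer seed (random-forest classifier).
#' @return named integer confusion-count vector (`tp`, `fn`, `tn`, `fp`).
#' @export
cross_cohort_predict <- function(train_x, train_y, test_x, test_y, panel,
                                 spec = classifier_spec("plsda"), seed = 1) {
  for (side in list(c("training", "train_x"), c("testing", "test_x"))) {
    x <- get(side[2])
    miss <- setdiff(panel, colnames(x))
    if (length(miss) > 0)
      stop("panel metabolite(s) absent from the ", side[1], " cohort: ",
           paste(miss, collapse = ", "))
  }
  train_x <- as.matrix(train_x)[, panel, drop = FALSE]
  test_x <- as.matrix(test_x)[, panel, drop = FALSE]
  # independent per-cohort scaling: centre/scale the test cohort on itself
  test_sc <- autoscale(test_x)
  fit <- fit_panel_classifier(train_x, train_y, spec, seed = seed)
  xs <- test_sc$matrix[, names(fit$scaling$center), drop = FALSE]
  s <- pmin(pmax(predict(fit$model, xs), 0), 1)
  confusion_from_scores(s, encode_classes(test_y)$y01, spec$threshold)
}

#' Day-aligned time-point pairing between cohorts
#'
#' The training cohort samples days -1/4/9/13/17 (time points 1-5) and the
#' testing cohort days -1/2/13/17 (time points 1-4); matching by study day
#' pairs training time point 2 with testing 2, 4 with 3, and 5 with 4.
#'
#' @return named integer vector: names are training time points, values the
#'   paired testing time points.
#' @export
timepoint_pairing <- function() {
  c(`2` = 2L, `4` = 3L, `5` = 4L)
}
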