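#' Fit a two-class PLS-DA model (NIPALS PLS1)
#'
#' Partial least squares discriminant analysis with the class dummy-coded
#' 0/1 (control = 0, treated = 1) and centred, fit by NIPALS deflation: for
#' each component `a`, the weight `w_a` is proportional to `X_a' y_c`
#' (normalised to unit length), scores `t_a = X_a w_a`, predictor loadings
#' `p_a = X_a' t_a / (t_a' t_a)`, response loading `q_a = y_c' t_a /
#' (t_a' t_a)`, and `X` is deflated by `t_a p_a'`. `X` is consumed as given
#' and is expected to be autoscaled (see [autoscale()]).
#'
#' @param x complete numeric matrix, samples x metabolites.
#' @param y class labels: a factor with two levels, or a 0/1 vector, or a
#'   character vector of `"control"`/`"treated"`.
#' @param ncomp number of components `A`, with `A <= min(n - 1, p)`.
#' @return object of class `pls_model` with components `weights` (p x A),
#'   `scores` (n x A), `loadings` (p x A), `q` (length A), `y_mean`,
#'   `levels`, `ncomp`, `fitted`.
#' @export
fit_plsda <- function(x, y, ncomp = 2) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("fit_plsda requires a complete matrix")
  yc <- encode_classes(y)
  if (length(unique(yc$y01)) < 2) stop("both classes must be present in y")
  n <- nrow(x); p <- ncol(x)
  if (length(yc$y01) != n) stop("length(y) must match nrow(x)")
  if (ncomp < 1 || ncomp > min(n - 1, p))
    stop("ncomp must satisfy 1 <= ncomp <= min(n - 1, p)")
  y_mean <- mean(yc$y01)
  yres <- yc$y01 - y_mean
  xa <- x
  W <- matrix(0, p, ncomp); TT <- matrix(0, n, ncomp)
  P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(xa, yres))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps^0.5)
      stop("degenerate component ", a, ": X carries no covariance with y")
    w <- w / nw
    tt <- drop(xa %*% w)
    tt2 <- sum(tt^2)
    P[, a] <- drop(crossprod(xa, tt)) / tt2
    q[a] <- sum(yres * tt) / tt2
    W[, a] <- w
    TT[, a] <- tt
    xa <- xa - tcrossprod(tt, P[, a])
  }
  fitted <- y_mean + drop(TT %*% q)
  structure(list(weights = W, scores = TT, loadings = P, q = q,
                 y_mean = y_mean, levels = yc$levels, ncomp = ncomp,
                 fitted = fitted, metabolites = colnames(x)),
            class = "pls_model")
}

encode_classes <- function(y) {
  if (is.factor(y)) {
    if (nlevels(droplevels(y)) > 2) stop("y must have exactly two classes")
    lev <- levels(droplevels(y))
    list(y01 = as.numeric(droplevels(y)) - 1, levels = lev)
  } else if (is.character(y)) {
    lev <- sort(unique(y))
    if (length(lev) > 2) stop("y must have exactly two classes")
    if (all(lev %in% c("control", "treated")))
      lev <- c("control", "treated")[c("control", "treated") %in% lev]
    list(y01 = as.numeric(match(y, lev) - 1), levels = lev)
  } else {
    if (!all(y %in% c(0, 1))) stop("numeric y must be coded 0/1")
    list(y01 = as.numeric(y), levels = c("0", "1"))
  }
}

#' Predict continuous class scores from a PLS-DA model
#'
#' Scores are `y_mean + sum_a q_a t_a*`, with new-sample scores obtained by
#' applying the stored weights and deflating by the stored loadings. New data
#' must be on the same (autoscaled) scale as the training matrix.
#'
#' @param object fitted `pls_model`.
#' @param newdata matrix with the training metabolite columns.
#' @param ... unused.
#' @return numeric vector of continuous scores (near 0 = first class, near 1
#'   = second class).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$metabolites) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$metabolites, drop = FALSE]
  xa <- newdata
  score <- rep(object$y_mean, nrow(newdata))
  for (a in seq_len(object$ncomp)) {
    tt <- drop(xa %*% object$weights[, a])
    score <- score + object$q[a] * tt
    xa <- xa - tcrossprod(tt, object$loadings[, a])
  }
  score
}

#' Variable importance in projection (VIP)
#'
#' The standard Wold VIP: `VIP_j = sqrt(p * sum_a(SS_a * w_aj^2) /
#' sum_a(SS_a))` with `SS_a = q_a^2 * (t_a' t_a)`, the response variance
#' explained by component `a`. Because each `w_a` has unit length, the mean
#' of `VIP^2` over metabolites is exactly 1; VIP > 1 flags metabolites that
#' contribute more than an average share to the model.
#'
#' @param model fitted `pls_model`.
#' @return named numeric vector of VIP scores (one per metabolite).
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "pls_model")) stop("vip_scores requires a fitted pls_model")
  ss <- model$q^2 * colSums(model$scores^2)
  p <- nrow(model$weights)
  vip <- sqrt(p * drop(model$weights^2 %*% ss) / sum(ss))
  names(vip) <- model$metabolites
  vip
}

#' Leave-one-out cross-validated Q2
#'
#' For each sample, the model is refit on the remaining `n - 1` samples (y
#' re-centred within the fold) and the held-out sample predicted. `Q2 = 1 -
#' PRESS / TSS`, where `PRESS = sum((y_i - yhat_(-i))^2)` and `TSS =
#' sum((y_i - mean(y))^2)`. Q2 near 1 indicates high predictive ability; Q2
#' near 0 or negative indicates none (typical of a pre-treatment time point).
#'
#' @param x complete matrix (as for [fit_plsda()]).
#' @param y two-class labels.
#' @param ncomp components per fold.
#' @return list with `q2`, `press`, `tss`, and `predictions` (one per sample).
#' @export
q2_loocv <- function(x, y, ncomp = 2) {
  x <- as.matrix(x)
  yc <- encode_classes(y)
  n <- nrow(x)
  if (n < 3) stop("q2_loocv requires at least 3 samples")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    yi <- yc$y01[-i]
    if (length(unique(yi)) < 2)
      stop("fold ", i, " leaves a single class; cannot cross-validate")
    fit <- fit_plsda(x[-i, , drop = FALSE], yi, ncomp = ncomp)
    pred[i] <- predict(fit, x[i, , drop = FALSE])
  }
  press <- sum((yc$y01 - pred)^2)
  tss <- sum((yc$y01 - mean(yc$y01))^2)
  list(q2 = 1 - press / tss, press = press, tss = tss, predictions = pred)
}
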