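# Independent oracles used to check the implementation.

# Exhaustive Mann-Whitney pair counting (ties count one half).
brute_auc <- function(control, treated) {
  s <- 0
  for (t in treated) for (c in control) s <- s + (t > c) + 0.5 * (t == c)
  raw <- s / (length(treated) * length(control))
  list(raw = raw, orientation_free = max(raw, 1 - raw))
}

# PLS1 fitted values via the Krylov-subspace characterisation: the A-component
# PLS1 prediction equals least squares of centred y on the scores X %*% V,
# where V spans {X'y, (X'X)X'y, ..., (X'X)^(A-1) X'y}. Shares no code with
# the NIPALS implementation.
krylov_pls1_fitted <- function(x, y01, ncomp) {
  yc <- y01 - mean(y01)
  g <- crossprod(x)
  v <- drop(crossprod(x, yc))
  V <- matrix(0, ncol(x), ncomp)
  for (a in seq_len(ncomp)) {
    V[, a] <- v
    v <- drop(g %*% v)
  }
  scores <- x %*% V
  fit <- stats::lm.fit(scores, yc)
  mean(y01) + fit$fitted.values
}

# Small synthetic config for fast tests.
tiny_config <- function(seed = 1, ...) {
  synthetic_config(n_metabolites = 40, seed = seed, ...)
}

# glog + impute convenience used by several tests.
glog_complete <- function(x) glog2(suppressMessages(impute_missing(x)))
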