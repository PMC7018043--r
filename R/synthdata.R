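#' Configuration for the synthetic longitudinal cohort generator
#'
#' Parameterizes a two-cohort, two-group longitudinal metabolomics study
#' emulating a repeated-NSAID urine metabolome design: a training cohort of 6
#' control and 6 treated cats sampled at 5 time points (one treated
#' non-responder flagged as censored), and a testing cohort of 4 + 4 cats
#' sampled at 4 time points. Time point 1 precedes treatment and carries no
#' treatment effect.
#'
#' Peak heights are lognormal. A planted subset of metabolites shifts in the
#' treated group from time point 2 onward, additively on the natural-log scale
#' in units of the metabolite's total log-scale SD (residual, cat and dilution
#' components combined), so "2 SD" is a standardized mean difference of 2; the
#' default direction is a decrease. A configurable
#' fraction of background metabolites receives a small treated-group decrease
#' (`global_drift`), and `baseline_confounders` metabolites receive a group
#' shift at time point 1 only, emulating pre-treatment confounding.
#'
#' @param n_control_train,n_treated_train training-cohort group sizes.
#' @param n_censored_train number of treated training cats flagged censored
#'   (generated with no planted effect, kept in the table).
#' @param n_control_test,n_treated_test testing-cohort group sizes.
#' @param timepoints_train,timepoints_test sampling time points per cohort.
#' @param n_metabolites total metabolite columns.
#' @param n_planted number of planted discriminative metabolites.
#' @param effect_size standardized log-scale shift applied to planted
#'   metabolites at time points >= 2 (signed; negative = decrease).
#' @param effect_profile optional `n_planted x timepoints_train` matrix of
#'   signed standardized shifts overriding `effect_size`; column 1 must be 0.
#' @param global_drift fraction of background metabolites given a small
#'   treated-group shift (`global_drift_shift` SD) from time point 2.
#' @param global_drift_shift standardized shift for drifting background
#'   metabolites.
#' @param baseline_confounders number of metabolites with a group shift at
#'   time point 1 only.
#' @param baseline_confounder_shift standardized shift for the confounders.
#' @param log_mean_range,log_sd_range ranges (natural-log units) from which
#'   per-metabolite lognormal location and residual scale parameters are drawn.
#' @param cat_sd SD (log units) of the per-cat random intercept inducing
#'   repeated-measures correlation.
#' @param dilution_sd SD (log units) of the per-sample urine dilution factor,
#'   a multiplicative effect shared by every metabolite of a sample. Urine
#'   concentration varies several-fold between voids, and unnormalized peak
#'   heights are dominated by it; it is the main source of inter-metabolite
#'   correlation in the generated tables. Standardized shifts are expressed
#'   in units of the total per-metabolite log SD
#'   (`sqrt(log_sd^2 + cat_sd^2 + dilution_sd^2)`).
#' @param missing_rate per-cell missingness probability in `[0, 1)`.
#' @param seed integer seed; all draws derive from it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_control_train = 6, n_treated_train = 6,
                             n_censored_train = 1,
                             n_control_test = 4, n_treated_test = 4,
                             timepoints_train = 5, timepoints_test = 4,
                             n_metabolites = 318, n_planted = 7,
                             effect_size = -2.5, effect_profile = NULL,
                             global_drift = 0.3, global_drift_shift = -0.5,
                             baseline_confounders = 7,
                             baseline_confounder_shift = -5,
                             log_mean_range = c(8, 13),
                             log_sd_range = c(0.2, 0.6),
                             cat_sd = 0.2, dilution_sd = 0.6,
                             missing_rate = 0.02, seed = 1) {
  counts <- c(n_control_train, n_treated_train, n_control_test, n_treated_test,
              timepoints_train, timepoints_test, n_metabolites)
  if (any(counts < 1)) stop("all cohort counts must be positive")
  if (n_planted > n_metabolites) stop("n_planted exceeds n_metabolites")
  if (n_planted < 0 || baseline_confounders < 0 || n_censored_train < 0)
    stop("counts must be non-negative")
  if (n_censored_train >= n_treated_train)
    stop("n_censored_train must leave at least one uncensored treated cat")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (!is.null(effect_profile)) {
    effect_profile <- as.matrix(effect_profile)
    if (nrow(effect_profile) != n_planted ||
        ncol(effect_profile) != timepoints_train)
      stop("effect_profile must be n_planted x timepoints_train")
    if (any(effect_profile[, 1] != 0))
      stop("effect_profile must be 0 at time point 1")
  }
  structure(list(n_control_train = n_control_train,
                 n_treated_train = n_treated_train,
                 n_censored_train = n_censored_train,
                 n_control_test = n_control_test,
                 n_treated_test = n_treated_test,
                 timepoints_train = timepoints_train,
                 timepoints_test = timepoints_test,
                 n_metabolites = n_metabolites, n_planted = n_planted,
                 effect_size = effect_size, effect_profile = effect_profile,
                 global_drift = global_drift,
                 global_drift_shift = global_drift_shift,
                 baseline_confounders = baseline_confounders,
                 baseline_confounder_shift = baseline_confounder_shift,
                 log_mean_range = log_mean_range, log_sd_range = log_sd_range,
                 cat_sd = cat_sd, dilution_sd = dilution_sd,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Metabolite-level (platform) draws shared by both cohorts: names, lognormal
# parameters, planted/confounder/drift identities and the effect profile.
# Named (library-identified) metabolites are drawn from the upper half of the
# abundance range: spectral library matching favours abundant peaks, and the
# planted panel and confounders are drawn from the named set.
platform_params <- function(config) {
  set.seed(config$seed)
  p <- config$n_metabolites
  n_named <- min(114L, p)
  named <- identified_metabolite_names()[seq_len(n_named)]
  mets <- c(named,
            if (p > n_named) sprintf("unknown_%03d", seq_len(p - n_named)))
  lo <- config$log_mean_range[1]; hi <- config$log_mean_range[2]
  mid <- (lo + hi) / 2
  log_mean <- c(stats::runif(n_named, mid, hi),
                if (p > n_named) stats::runif(p - n_named, lo, hi))
  log_sd <- stats::runif(p, config$log_sd_range[1], config$log_sd_range[2])
  named_idx <- seq_len(n_named)
  pool <- if (length(named_idx) >= config$n_planted + config$baseline_confounders)
    named_idx else seq_len(p)
  picks <- sample(pool, config$n_planted + config$baseline_confounders)
  planted <- sort(picks[seq_len(config$n_planted)])
  confounders <- sort(setdiff(picks, picks[seq_len(config$n_planted)]))
  background <- setdiff(seq_len(p), c(planted, confounders))
  n_drift <- round(config$global_drift * length(background))
  drift <- sort(sample(background, n_drift))
  profile <- config$effect_profile
  if (is.null(profile) && config$n_planted > 0)
    profile <- matrix(rep(c(0, rep(config$effect_size,
                                   config$timepoints_train - 1)),
                          each = config$n_planted),
                      nrow = config$n_planted)
  cohort_seeds <- sample.int(.Machine$integer.max - 1L, 2)
  list(metabolites = mets, log_mean = log_mean, log_sd = log_sd,
       planted = planted, confounders = confounders, drift = drift,
       profile = profile, cohort_seeds = cohort_seeds)
}

#' Generate a synthetic cohort
#'
#' Draws one cohort (training or testing) under a [synthetic_config()]. Both
#' cohorts generated from the same config share metabolite-level parameters
#' and ground truth (same analytical platform, independent animals), so a
#' panel discovered on the training cohort is meaningful on the testing one.
#'
#' One row is generated per cat and time point. Log intensities are
#' `log_mean + cat_intercept + N(0, log_sd)` plus, for treated non-censored
#' cats at time points >= 2, the planted standardized shift times `log_sd`
#' (and the drift shift for drifting background metabolites); baseline
#' confounders are shifted in all treated cats at time point 1 only.
#' Intensities are exponentiated, so all generated values are strictly
#' positive; cells are then masked missing independently at `missing_rate`.
#'
#' @param config a [synthetic_config()].
#' @param cohort `"training"` or `"testing"`.
#' @return list with `matrix` (peak matrix, `NA` for missing), `meta`
#'   (sample metadata data.frame), and `truth`: list with `planted_names`,
#'   `confounder_names`, `drift_names` and `shift` (metabolite x time point
#'   matrix of true standardized shifts).
#' @export
generate_cohort <- function(config, cohort = c("training", "testing")) {
  stopifnot(inherits(config, "synthetic_config"))
  cohort <- match.arg(cohort)
  plat <- platform_params(config)
  train <- cohort == "training"
  n_ctl <- if (train) config$n_control_train else config$n_control_test
  n_trt <- if (train) config$n_treated_train else config$n_treated_test
  n_tp <- if (train) config$timepoints_train else config$timepoints_test
  n_cens <- if (train) config$n_censored_train else 0L
  set.seed(plat$cohort_seeds[if (train) 1 else 2])

  p <- config$n_metabolites
  cats <- c(sprintf("%s_C%d", substr(cohort, 1, 2), seq_len(n_ctl)),
            sprintf("%s_M%d", substr(cohort, 1, 2), seq_len(n_trt)))
  group <- rep(c("control", "treated"), c(n_ctl, n_trt))
  censored <- c(rep(FALSE, n_ctl),
                rep(c(FALSE, TRUE), c(n_trt - n_cens, n_cens)))
  intercept <- stats::rnorm(length(cats), 0, config$cat_sd)
  # standardized shifts are in units of the total log-scale SD
  sd_tot <- sqrt(plat$log_sd^2 + config$cat_sd^2 + config$dilution_sd^2)

  # true standardized shift per (metabolite, timepoint) for treated responders
  shift <- matrix(0, p, n_tp, dimnames = list(plat$metabolites, seq_len(n_tp)))
  if (config$n_planted > 0)
    shift[plat$planted, ] <- plat$profile[, seq_len(n_tp), drop = FALSE]
  if (length(plat$drift) > 0 && n_tp >= 2)
    shift[plat$drift, 2:n_tp] <- config$global_drift_shift

  meta <- expand.grid(cat = seq_along(cats), timepoint = seq_len(n_tp))
  meta <- meta[order(meta$cat, meta$timepoint), ]
  n_rows <- nrow(meta)
  x <- matrix(NA_real_, n_rows, p, dimnames = list(NULL, plat$metabolites))
  for (i in seq_len(n_rows)) {
    ci <- meta$cat[i]; tp <- meta$timepoint[i]
    mu <- plat$log_mean + intercept[ci] +
      stats::rnorm(1, 0, config$dilution_sd) +
      stats::rnorm(p, 0, plat$log_sd)
    if (group[ci] == "treated") {
      if (!censored[ci]) mu <- mu + shift[, tp] * sd_tot
      if (tp == 1 && length(plat$confounders) > 0)
        mu[plat$confounders] <- mu[plat$confounders] +
          config$baseline_confounder_shift * sd_tot[plat$confounders]
    }
    x[i, ] <- exp(mu)
  }
  if (config$missing_rate > 0)
    x[matrix(stats::runif(n_rows * p) < config$missing_rate, n_rows, p)] <- NA
  sample_meta <- data.frame(
    sample_id = sprintf("%s_t%d", cats[meta$cat], meta$timepoint),
    cat_id = cats[meta$cat], group = group[meta$cat],
    timepoint = meta$timepoint, cohort = cohort,
    censored = censored[meta$cat], stringsAsFactors = FALSE)
  rownames(x) <- sample_meta$sample_id
  validate_peak_matrix(x)
  truth <- list(planted_names = plat$metabolites[plat$planted],
                confounder_names = plat$metabolites[plat$confounders],
                drift_names = plat$metabolites[plat$drift],
                shift = shift)
  list(matrix = x, meta = sample_meta, truth = truth)
}

#' Write a generated cohort to disk
#'
#' Writes the peak table as TSV (via [write_peak_table()]) and the ground
#' truth as JSON.
#'
#' @param cohort list returned by [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (default: the cohort label).
#' @return named character vector of the paths written, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = cohort$meta$cohort[1]) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(prefix, "_peaks.tsv"))
  js <- file.path(dir, paste0(prefix, "_truth.json"))
  write_peak_table(cohort$matrix, cohort$meta, tsv)
  truth <- cohort$truth
  truth$shift <- as.data.frame(truth$shift)
  jsonlite::write_json(truth, js, auto_unbox = FALSE, digits = NA,
                       dataframe = "columns")
  invisible(c(peaks = tsv, truth = js))
}
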