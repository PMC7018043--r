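#' Run the biomarker discovery pipeline on a training cohort
#'
#' End-to-end discovery: censored animals are dropped; the peak table is
#' imputed, SD-filtered and glog2-transformed; metabolites that already
#' separate the groups at the pre-treatment time point (orientation-free AUC
#' above the baseline threshold) are excluded from all treatment-time-point
#' analyses; then, per treatment time point, samples are autoscaled and each
#' metabolite is ranked by PLS-DA VIP, random-forest MDA and univariate
#' orientation-free AUC; finally the panel is selected with
#' [select_panel()].
#'
#' @param x peak matrix (samples x metabolites, `NA` = missing).
#' @param meta sample metadata data.frame (`sample_id`, `cat_id`, `group`,
#'   `timepoint`, `cohort`, `censored`).
#' @param prep_config a [preprocess_config()]; its `autoscale` flag is
#'   ignored (scaling is refit within each time point).
#' @param criteria a [selection_criteria()].
#' @param ncomp PLS-DA components (default 2).
#' @param n_trees,mtry random-forest parameters (defaults 500 and 7).
#' @param seed integer seed (per-time-point forest seeds derive from it).
#' @return list of class `discovery_result`: `panel` (a `panel_result`),
#'   `metric_table`, `baseline_excluded`, `vip`, `mda`, `auc` (tidy
#'   data.frames over treatment time points), `q2` (per time point,
#'   including the pre-treatment one), `preprocess_log`, `n_censored_dropped`,
#'   `seed`.
#' @export
run_discovery <- function(x, meta, prep_config = preprocess_config(),
                          criteria = selection_criteria(), ncomp = 2,
                          n_trees = 500, mtry = 7, seed = 1) {
  stopifnot(nrow(x) == nrow(meta))
  keep <- !meta$censored
  n_censored <- sum(!keep)
  if (n_censored > 0)
    message("run_discovery: excluding ", n_censored,
            " censored animal-sample row(s)")
  x <- x[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]

  cfg <- prep_config
  cfg$autoscale <- FALSE
  prep <- preprocess(x, cfg)
  xg <- prep$matrix

  tps <- sort(unique(meta$timepoint))
  t1 <- tps[1]
  treat_tps <- tps[-1]
  set.seed(as.integer(seed))
  tp_seeds <- stats::setNames(sample.int(.Machine$integer.max - 1L,
                                         length(tps)), tps)

  rows_t1 <- meta$timepoint == t1
  auc_t1 <- auc_by_metabolite(xg[rows_t1, , drop = FALSE], meta$group[rows_t1])
  excluded <- baseline_exclusions(auc_t1, criteria$baseline_auc_excl)
  if (length(excluded) > 0)
    message("run_discovery: baseline-excluding ", length(excluded),
            " metabolite(s)")

  vip_l <- list(); mda_l <- list(); auc_l <- list(); q2 <- numeric(0)
  for (tp in tps) {
    rows <- meta$timepoint == tp
    xt <- xg[rows, , drop = FALSE]
    if (tp != t1)
      xt <- xt[, setdiff(colnames(xt), excluded), drop = FALSE]
    sc <- autoscale(xt)
    xs <- sc$matrix
    y <- meta$group[rows]
    A <- min(ncomp, nrow(xs) - 1, ncol(xs))
    q2[as.character(tp)] <- tryCatch(q2_loocv(xs, y, ncomp = A)$q2,
                                     error = function(e) NA_real_)
    if (tp == t1) next
    fit <- fit_plsda(xs, y, ncomp = A)
    vip_l[[as.character(tp)]] <- data.frame(
      metabolite = colnames(xs), timepoint = tp, vip = unname(vip_scores(fit)),
      stringsAsFactors = FALSE)
    forest <- suppressWarnings(
      fit_forest(xs, y, n_trees = n_trees, mtry = min(mtry, ncol(xs)),
                 seed = tp_seeds[as.character(tp)]))
    mda_tp <- oob_mda(forest)
    mda_l[[as.character(tp)]] <- data.frame(
      metabolite = mda_tp$metabolite, timepoint = tp, mda = mda_tp$mda,
      stringsAsFactors = FALSE)
    auc_tp <- auc_by_metabolite(xs, y)
    auc_l[[as.character(tp)]] <- data.frame(
      metabolite = auc_tp$metabolite, timepoint = tp, auc = auc_tp$auc,
      stringsAsFactors = FALSE)
  }
  vip <- do.call(rbind, vip_l)
  mda <- do.call(rbind, mda_l)
  auc <- do.call(rbind, auc_l)
  metric_table <- build_metric_table(vip, mda, auc)
  panel <- select_panel(metric_table, criteria, excluded = excluded)
  structure(list(panel = panel, metric_table = metric_table,
                 baseline_excluded = excluded, vip = vip, mda = mda,
                 auc = auc, auc_baseline = auc_t1, q2 = q2,
                 preprocess_log = prep$log,
                 n_censored_dropped = n_censored, seed = as.integer(seed)),
            class = "discovery_result")
}

# Impute + glog a cohort and restrict it to the panel columns (the SD filter
# is a discovery-stage screen and is not applied to a fixed panel).
prepare_panel_matrix <- function(x, panel, glog_offset = 1) {
  x <- impute_missing(x)
  miss <- setdiff(panel, colnames(x))
  if (length(miss) > 0)
    stop("panel metabolite(s) absent from the cohort: ",
         paste(miss, collapse = ", "))
  glog2(x[, panel, drop = FALSE], glog_offset)
}

#' Validate a panel within and across cohorts
#'
#' Produces a binary-classification report for the selected panel: for each
#' classifier and training time point, a Monte Carlo cross-validated row and
#' a resubstitution row (model refit on all samples of the time point and
#' applied back to them -- the two labelled distinctly), and, for each
#' day-aligned time-point pair, a cross-cohort row (model fit on the
#' training cohort, predicting the testing cohort). Censored training
#' animals are dropped. Degenerate rows (a metric with an empty
#' denominator) are reported with `NA` metrics and a note; the run
#' continues.
#'
#' @param train_x,train_meta training-cohort peak matrix and metadata.
#' @param test_x,test_meta testing-cohort peak matrix and metadata (`NULL`
#'   to skip cross-cohort rows).
#' @param panel character vector of panel metabolite names.
#' @param classifiers list of [classifier_spec()]s.
#' @param n_reps,train_fraction MCCV parameters.
#' @param pairing training-to-testing time-point map
#'   (default [timepoint_pairing()]).
#' @param glog_offset generalized-log constant used on both cohorts.
#' @param seed integer seed.
#' @return data.frame of class `validation_report`: `method`,
#'   `train_timepoint`, `test_timepoint`, `evaluation` (`"mccv"`,
#'   `"resubstitution"` or `"cross_cohort"`), `tp`, `fn`, `tn`, `fp`,
#'   `sens_pct`, `spec_pct`, `note`.
#' @export
run_validation <- function(train_x, train_meta, test_x = NULL,
                           test_meta = NULL, panel,
                           classifiers = list(classifier_spec("plsda"),
                                              classifier_spec("rf")),
                           n_reps = 100, train_fraction = 2 / 3,
                           pairing = timepoint_pairing(), glog_offset = 1,
                           seed = 1) {
  if (length(panel) == 0) stop("empty panel")
  keep <- !train_meta$censored
  train_x <- train_x[keep, , drop = FALSE]
  train_meta <- train_meta[keep, , drop = FALSE]
  xtr <- prepare_panel_matrix(train_x, panel, glog_offset)
  xte <- NULL
  if (!is.null(test_x)) {
    keep_te <- !test_meta$censored
    test_x <- test_x[keep_te, , drop = FALSE]
    test_meta <- test_meta[keep_te, , drop = FALSE]
    xte <- prepare_panel_matrix(test_x, panel, glog_offset)
  }
  set.seed(as.integer(seed))
  row_seed <- function() sample.int(.Machine$integer.max - 1L, 1)
  rows <- list()
  add_row <- function(method, tr_tp, te_tp, evaluation, cm_expr) {
    cm <- tryCatch(cm_expr(), error = function(e) e)
    if (inherits(cm, "error")) {
      rows[[length(rows) + 1]] <<- data.frame(
        method = method, train_timepoint = tr_tp, test_timepoint = te_tp,
        evaluation = evaluation, tp = NA_integer_, fn = NA_integer_,
        tn = NA_integer_, fp = NA_integer_, sens_pct = NA_real_,
        spec_pct = NA_real_, note = conditionMessage(cm),
        stringsAsFactors = FALSE)
      return(invisible())
    }
    met <- tryCatch(confusion_metrics(cm), error = function(e) e)
    bad <- inherits(met, "error")
    rows[[length(rows) + 1]] <<- data.frame(
      method = method, train_timepoint = tr_tp, test_timepoint = te_tp,
      evaluation = evaluation, tp = cm[["tp"]], fn = cm[["fn"]],
      tn = cm[["tn"]], fp = cm[["fp"]],
      sens_pct = if (bad) NA_real_ else unname(met["sensitivity"]),
      spec_pct = if (bad) NA_real_ else unname(met["specificity"]),
      note = if (bad) conditionMessage(met) else "",
      stringsAsFactors = FALSE)
  }
  for (spec in classifiers) {
    for (tp in sort(unique(train_meta$timepoint))) {
      sel <- train_meta$timepoint == tp
      xi <- xtr[sel, , drop = FALSE]; yi <- train_meta$group[sel]
      s1 <- row_seed(); s2 <- row_seed()
      add_row(spec$kind, tp, NA_integer_, "mccv", function() {
        mccv_roc(xi, yi, spec, n_reps = n_reps,
                 train_fraction = train_fraction, seed = s1)$confusion
      })
      add_row(spec$kind, tp, NA_integer_, "resubstitution", function() {
        fit <- fit_panel_classifier(xi, yi, spec, seed = s2)
        confusion_from_scores(score_panel_classifier(fit, xi),
                              encode_classes(yi)$y01, spec$threshold)
      })
    }
    if (!is.null(xte)) {
      for (k in seq_along(pairing)) {
        tr_tp <- as.integer(names(pairing)[k]); te_tp <- pairing[[k]]
        sel_tr <- train_meta$timepoint == tr_tp
        sel_te <- test_meta$timepoint == te_tp
        s3 <- row_seed()
        add_row(spec$kind, tr_tp, te_tp, "cross_cohort", function() {
          cross_cohort_predict(xtr[sel_tr, , drop = FALSE],
                               train_meta$group[sel_tr],
                               xte[sel_te, , drop = FALSE],
                               test_meta$group[sel_te],
                               panel, spec, seed = s3)
        })
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("validation_report", "data.frame")
  out
}

#' Write discovery outputs to a directory
#'
#' Writes tidy VIP/MDA/AUC tables, the joined metric table (TSV), and the
#' panel with its audit trail, thresholds and seed (JSON).
#'
#' @param result a `discovery_result` from [run_discovery()].
#' @param dir output directory (created if needed).
#' @return named character vector of paths, invisibly.
#' @export
write_discovery <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vip = file.path(dir, "vip.tsv"), mda = file.path(dir, "mda.tsv"),
             auc = file.path(dir, "auc.tsv"),
             metrics = file.path(dir, "metric_table.tsv"),
             panel = file.path(dir, "panel.json"))
  utils::write.table(result$vip, paths["vip"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(result$mda, paths["mda"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(result$auc, paths["auc"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(result$metric_table, paths["metrics"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(selected = result$panel$selected,
         baseline_excluded = result$panel$baseline_excluded,
         criteria = unclass(result$panel$criteria),
         q2 = as.list(result$q2), seed = result$seed,
         audit = result$panel$audit),
    paths["panel"], auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(paths)
}

#' Write a validation report as TSV
#'
#' @param report a `validation_report` from [run_validation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_validation <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}
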