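#' Panel selection thresholds
#'
#' The triple-threshold intersection rule used to nominate putative
#' biomarkers: a metabolite qualifies at a treatment time point when its
#' PLS-DA VIP exceeds `vip_min` (strict), its random-forest MDA is at least
#' `mda_min`, and its orientation-free ROC AUC exceeds `auc_min` (strict).
#' Metabolites whose orientation-free AUC at the pre-treatment time point
#' exceeds `baseline_auc_excl` are confounders and are excluded up front.
#'
#' @param vip_min VIP threshold (strict `>`), default 1.0.
#' @param mda_min MDA threshold (`>=`), default 0.004 (= 0.4%).
#' @param auc_min AUC threshold (strict `>`), default 0.85.
#' @param baseline_auc_excl pre-treatment AUC above which a metabolite is
#'   excluded as a baseline confounder (strict `>`), default 0.85.
#' @param require_present_all_timepoints require detection at every
#'   treatment time point (default `TRUE`).
#' @param joint if `TRUE` (default) the three thresholds must hold jointly at
#'   a single time point; if `FALSE`, each may be met at a different one.
#' @return list of class `selection_criteria`.
#' @export
selection_criteria <- function(vip_min = 1.0, mda_min = 0.004, auc_min = 0.85,
                               baseline_auc_excl = 0.85,
                               require_present_all_timepoints = TRUE,
                               joint = TRUE) {
  if (vip_min < 0 || mda_min < -1 || mda_min > 1 ||
      auc_min < 0.5 || auc_min > 1 ||
      baseline_auc_excl < 0.5 || baseline_auc_excl > 1)
    stop("selection thresholds out of range")
  structure(list(vip_min = vip_min, mda_min = mda_min, auc_min = auc_min,
                 baseline_auc_excl = baseline_auc_excl,
                 require_present_all_timepoints = require_present_all_timepoints,
                 joint = joint),
            class = "selection_criteria")
}

#' Assemble per-metabolite, per-time-point metrics
#'
#' Outer-joins VIP, MDA and AUC records on (metabolite, time point). A record
#' is marked `present = FALSE` where any metric is absent, i.e. the
#' metabolite was not detected (or was filtered) at that time point.
#'
#' @param vip data.frame with `metabolite`, `timepoint`, `vip`.
#' @param mda data.frame with `metabolite`, `timepoint`, `mda`.
#' @param auc data.frame with `metabolite`, `timepoint`, `auc`
#'   (orientation-free).
#' @return data.frame with `metabolite`, `timepoint`, `vip`, `mda`, `auc`,
#'   `present`.
#' @export
build_metric_table <- function(vip, mda, auc) {
  check <- function(df, value, nm) {
    stopifnot(all(c("metabolite", "timepoint", value) %in% names(df)))
    if (anyDuplicated(df[c("metabolite", "timepoint")])) {
      key <- paste(df$metabolite, df$timepoint)
      dup <- df[key %in% key[duplicated(key)], c("metabolite", "timepoint", value)]
      if (nrow(unique(dup)) > length(unique(paste(dup$metabolite, dup$timepoint))))
        stop("conflicting duplicate ", nm, " records")
      df <- df[!duplicated(key), ]
    }
    df[c("metabolite", "timepoint", value)]
  }
  out <- merge(check(vip, "vip", "VIP"), check(mda, "mda", "MDA"),
               by = c("metabolite", "timepoint"), all = TRUE)
  out <- merge(out, check(auc, "auc", "AUC"),
               by = c("metabolite", "timepoint"), all = TRUE)
  # complete the (metabolite x timepoint) grid so absences are explicit
  if (nrow(out) > 0) {
    grid <- expand.grid(metabolite = unique(out$metabolite),
                        timepoint = unique(out$timepoint),
                        stringsAsFactors = FALSE)
    out <- merge(grid, out, by = c("metabolite", "timepoint"), all.x = TRUE)
  }
  out$present <- !is.na(out$vip) & !is.na(out$mda) & !is.na(out$auc)
  out[order(out$metabolite, out$timepoint), , drop = FALSE]
}

#' Baseline (pre-treatment) confounder exclusion
#'
#' Metabolites that already separate the groups before any treatment cannot
#' be treatment biomarkers. Returns the metabolites whose orientation-free
#' AUC at time point 1 strictly exceeds the threshold; callers must drop
#' these columns before computing treatment-time-point metrics (exclusion
#' precedes ranking).
#'
#' @param auc_t1 data.frame with `metabolite` and `auc` (orientation-free) at
#'   time point 1, as returned by [auc_by_metabolite()].
#' @param threshold exclusion threshold (strict `>`), default 0.85.
#' @return character vector of excluded metabolite names (possibly empty).
#' @export
baseline_exclusions <- function(auc_t1, threshold = 0.85) {
  stopifnot(all(c("metabolite", "auc") %in% names(auc_t1)))
  auc_t1$metabolite[auc_t1$auc > threshold]
}

#' Select the biomarker panel
#'
#' A metabolite is selected iff it (a) is not baseline-excluded, (b) is
#' present at every treatment time point (when required), and (c) meets the
#' three thresholds -- jointly at one treatment time point under the default
#' `joint` rule -- at at least one treatment time point.
#'
#' @param table metric table from [build_metric_table()], covering the
#'   treatment time points.
#' @param criteria a [selection_criteria()].
#' @param excluded metabolite names excluded at baseline
#'   (from [baseline_exclusions()]).
#' @return list of class `panel_result`: `selected` (names),
#'   `baseline_excluded`, `audit` (per metabolite x time point: which
#'   criteria passed), `criteria`.
#' @export
select_panel <- function(table, criteria = selection_criteria(),
                         excluded = character()) {
  stopifnot(inherits(criteria, "selection_criteria"))
  if (nrow(table) == 0) stop("empty metric table")
  tab <- table[!(table$metabolite %in% excluded), , drop = FALSE]
  tab$pass_vip <- !is.na(tab$vip) & tab$vip > criteria$vip_min
  tab$pass_mda <- !is.na(tab$mda) & tab$mda >= criteria$mda_min
  tab$pass_auc <- !is.na(tab$auc) & tab$auc > criteria$auc_min
  tab$pass_joint <- tab$pass_vip & tab$pass_mda & tab$pass_auc
  sel <- vapply(split(tab, tab$metabolite), function(d) {
    if (criteria$require_present_all_timepoints && !all(d$present))
      return(FALSE)
    if (criteria$joint) any(d$pass_joint)
    else any(d$pass_vip) && any(d$pass_mda) && any(d$pass_auc)
  }, logical(1))
  selected <- names(sel)[sel]
  structure(list(selected = selected,
                 baseline_excluded = intersect(excluded,
                                               unique(table$metabolite)),
                 audit = tab[c("metabolite", "timepoint", "vip", "mda", "auc",
                               "present", "pass_vip", "pass_mda", "pass_auc",
                               "pass_joint")],
                 criteria = criteria),
            class = "panel_result")
}

#' @export
print.panel_result <- function(x, ...) {
  cat("Biomarker panel:", length(x$selected), "metabolite(s) selected\n")
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  if (length(x$baseline_excluded))
    cat("Baseline-excluded:", paste(x$baseline_excluded, collapse = ", "), "\n")
  invisible(x)
}
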