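#' Names of the library-identified urinary metabolites
#'
#' The 114 feline urinary metabolites with spectral-library identities in the
#' reference GC-TOF-MS study design this package emulates; the synthetic
#' generator uses them as the named columns (the remainder of a peak table
#' being unidentified compounds).
#'
#' @return character vector of 114 distinct metabolite names.
#' @export
identified_metabolite_names <- function() {
  readLines(system.file("extdata", "identified_metabolites.txt",
                        package = "metabopanel"))
}

#' Published per-time-point metrics for the reference seven-metabolite panel
#'
#' The MDA, VIP and orientation-free ROC AUC values reported for the seven
#' putative urinary biomarkers of repeated meloxicam exposure at treatment
#' time points 2-5, as a tidy table. MDA is converted from the printed
#' percentage to a proportion (1.20% -> 0.012) so it is directly comparable
#' with [selection_criteria()]`$mda_min`.
#'
#' @return data.frame with `metabolite`, `timepoint`, `mda`, `vip`, `auc`.
#' @export
panel_reference_metrics <- function() {
  df <- utils::read.delim(system.file("extdata", "panel_metrics.tsv",
                                      package = "metabopanel"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  data.frame(metabolite = df$metabolite, timepoint = as.integer(df$timepoint),
             mda = df$mda_pct / 100, vip = df$vip, auc = df$auc,
             stringsAsFactors = FALSE)
}

#' Published confusion counts for the reference panel classifiers
#'
#' Confusion-matrix counts (treated = positive class) for PLS-DA and
#' random-forest classifiers built on the reference seven-metabolite panel:
#' within-cohort rows (`test_timepoint` is `NA`) and cross-cohort rows
#' (model fit at a training time point, applied to the paired testing time
#' point), together with the sensitivity/specificity percentages as printed.
#'
#' @return data.frame with `method`, `train_timepoint`, `test_timepoint`,
#'   `tp`, `fn`, `tn`, `fp`, `sens_pct`, `spec_pct`.
#' @export
reference_classification_report <- function() {
  utils::read.delim(system.file("extdata", "classification_report.tsv",
                                package = "metabopanel"),
                    check.names = FALSE, stringsAsFactors = FALSE)
}
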