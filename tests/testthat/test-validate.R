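panel_data <- function(seed, shift = 3, n_ctl = 6, n_trt = 5, p = 7) {
  set.seed(seed)
  x <- matrix(rnorm((n_ctl + n_trt) * p), n_ctl + n_trt, p,
              dimnames = list(NULL, paste0("p", 1:p)))
  y <- rep(c("control", "treated"), c(n_ctl, n_trt))
  x[y == "treated", ] <- x[y == "treated", ] - shift
  list(x = x, y = y)
}

test_that("confusion metrics reproduce the published worked rows", {
  expect_equal(confusion_metrics(c(tp = 5, fn = 0, tn = 6, fp = 0)),
               c(sensitivity = 100, specificity = 100))
  expect_equal(confusion_metrics(c(tp = 4, fn = 1, tn = 6, fp = 0)),
               c(sensitivity = 80, specificity = 100))
  expect_equal(confusion_metrics(c(tp = 0, fn = 4, tn = 3, fp = 1)),
               c(sensitivity = 0, specificity = 75))
  expect_equal(round(confusion_metrics(c(tp = 5, fn = 0, tn = 5, fp = 1)), 2),
               c(sensitivity = 100, specificity = 83.33))
  expect_error(confusion_metrics(c(tp = 0, fn = 0, tn = 3, fp = 1)),
               "sensitivity undefined")
  expect_error(confusion_metrics(c(tp = 2, fn = 1, tn = 0, fp = 0)),
               "specificity undefined")
})

test_that("MCCV is reproducible and its counts sum to the evaluated samples", {
  d <- panel_data(3)
  r1 <- mccv_roc(d$x, d$y, classifier_spec("plsda"), n_reps = 25, seed = 9)
  r2 <- mccv_roc(d$x, d$y, classifier_spec("plsda"), n_reps = 25, seed = 9)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$confusion, r2$confusion)
  expect_equal(sum(r1$confusion), length(d$y))
  expect_equal(r1$confusion[["tp"]] + r1$confusion[["fn"]],
               sum(d$y == "treated"))
  expect_true(all(r1$scores >= 0 & r1$scores <= 1))
  expect_equal(unname(r1$accuracy),
               100 * (r1$confusion[["tp"]] + r1$confusion[["tn"]]) /
                 sum(r1$confusion))
  # ROC endpoints
  expect_equal(unname(r1$roc[1, ]), c(0, 0))
  expect_equal(unname(r1$roc[nrow(r1$roc), ]), c(1, 1))
  expect_error(mccv_roc(d$x, d$y, n_reps = 5, train_fraction = 0.05, seed = 1),
               "train_fraction")
})

test_that("a planted 3-SD panel is recovered with high sensitivity and specificity", {
  ok <- sapply(1:20, function(s) {
    d <- panel_data(s)
    r <- mccv_roc(d$x, d$y, classifier_spec("plsda"), n_reps = 50, seed = s)
    r$sensitivity >= 80 && r$specificity >= 80
  })
  expect_gte(mean(ok), 0.9)
})

test_that("permuted labels give chance-level MCCV accuracy", {
  acc <- sapply(1:10, function(s) {
    set.seed(500 + s)
    x <- matrix(rnorm(12 * 7), 12, 7, dimnames = list(NULL, paste0("p", 1:7)))
    y <- sample(rep(c("control", "treated"), 6))
    mccv_roc(x, y, classifier_spec("plsda"), n_reps = 50, seed = s)$accuracy
  })
  expect_lt(abs(mean(acc) - 50), 20)
})

test_that("swapping class codes flips sensitivity and specificity", {
  d <- panel_data(11, shift = 1.5)
  fit <- metabopanel:::fit_panel_classifier(d$x, d$y, classifier_spec("plsda"))
  s <- metabopanel:::score_panel_classifier(fit, d$x)
  cm <- metabopanel:::confusion_from_scores(s, as.integer(d$y == "treated"), 0.5)
  yflip <- ifelse(d$y == "treated", "a_pos", "z_neg")  # treated becomes class 0
  fit2 <- metabopanel:::fit_panel_classifier(d$x, yflip, classifier_spec("plsda"))
  s2 <- metabopanel:::score_panel_classifier(fit2, d$x)
  cm2 <- metabopanel:::confusion_from_scores(s2, as.integer(yflip == "z_neg"), 0.5)
  m1 <- confusion_metrics(cm); m2 <- confusion_metrics(cm2)
  expect_equal(m1[["sensitivity"]], m2[["specificity"]])
  expect_equal(m1[["specificity"]], m2[["sensitivity"]])
})

test_that("cross-cohort prediction transfers a strong panel", {
  ok <- sapply(1:20, function(s) {
    cfg <- synthetic_config(seed = s, effect_size = -3, global_drift = 0,
                            missing_rate = 0)
    tr <- generate_cohort(cfg, "training")
    te <- generate_cohort(cfg, "testing")
    pan <- tr$truth$planted_names
    rt <- tr$meta$timepoint == 2 & !tr$meta$censored
    rs <- te$meta$timepoint == 2
    cm <- cross_cohort_predict(glog2(tr$matrix)[rt, pan], tr$meta$group[rt],
                               glog2(te$matrix)[rs, pan], te$meta$group[rs],
                               pan, classifier_spec("plsda"), seed = s)
    all(confusion_metrics(cm) >= 75)
  })
  expect_gte(mean(ok), 0.9)
})

test_that("an effect-free test cohort breaks sensitivity but not specificity", {
  cfg <- synthetic_config(seed = 6, effect_size = -3, global_drift = 0,
                          missing_rate = 0)
  tr <- generate_cohort(cfg, "training")
  # regenerate the testing cohort with the same platform but zero effects
  cfg0 <- synthetic_config(seed = 6, effect_size = 0, global_drift = 0,
                           missing_rate = 0)
  te <- generate_cohort(cfg0, "testing")
  pan <- tr$truth$planted_names
  rt <- tr$meta$timepoint == 2 & !tr$meta$censored
  rs <- te$meta$timepoint == 2
  cm <- cross_cohort_predict(glog2(tr$matrix)[rt, pan], tr$meta$group[rt],
                             glog2(te$matrix)[rs, pan], te$meta$group[rs],
                             pan, classifier_spec("plsda"), seed = 6)
  met <- confusion_metrics(cm)
  expect_lte(met[["sensitivity"]], 25)
  expect_gte(met[["specificity"]], 50)
})

test_that("resubstitution on separable data makes no errors; missing panel features are named", {
  d <- panel_data(19, shift = 4)
  cm <- cross_cohort_predict(d$x, d$y, d$x, d$y, colnames(d$x),
                             classifier_spec("plsda"))
  expect_equal(cm[["fn"]] + cm[["fp"]], 0L)
  expect_error(cross_cohort_predict(d$x, d$y, d$x[, 1:5], d$y,
                                    colnames(d$x), classifier_spec("plsda")),
               "p6")
})
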