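mk_metrics <- function(mets, tps, vip = 1.5, mda = 0.01, auc = 0.95) {
  g <- expand.grid(metabolite = mets, timepoint = tps, stringsAsFactors = FALSE)
  list(vip = cbind(g, vip = vip), mda = cbind(g, mda = mda),
       auc = cbind(g, auc = auc))
}

test_that("metric assembly outer-joins and flags absences", {
  m <- mk_metrics(paste0("m", 1:5), 2:4)
  tab <- build_metric_table(m$vip, m$mda, m$auc)
  expect_equal(nrow(tab), 15)
  expect_true(all(tab$present))

  # a metabolite absent from the AUC set at one time point
  m2 <- m
  m2$auc <- m2$auc[!(m2$auc$metabolite == "m3" & m2$auc$timepoint == 3), ]
  tab2 <- build_metric_table(m2$vip, m2$mda, m2$auc)
  expect_false(tab2$present[tab2$metabolite == "m3" & tab2$timepoint == 3])
  expect_equal(sum(!tab2$present), 1)

  # empty inputs give an empty table without error
  empty <- data.frame(metabolite = character(0), timepoint = integer(0),
                      vip = numeric(0), mda = numeric(0), auc = numeric(0))
  expect_equal(nrow(build_metric_table(empty[1:3], empty[c(1, 2, 4)],
                                       empty[c(1, 2, 5)])), 0)

  # conflicting duplicates are an error
  dup <- rbind(m$vip, data.frame(metabolite = "m1", timepoint = 2, vip = 9))
  expect_error(build_metric_table(dup, m$mda, m$auc), "duplicate")
})

test_that("baseline exclusion uses a strict threshold", {
  t1 <- data.frame(metabolite = c("a", "b", "c"), auc = c(0.80, 0.85, 0.86))
  expect_equal(baseline_exclusions(t1, 0.85), "c")
  expect_length(baseline_exclusions(t1, 0.9), 0)
})

test_that("selection enforces the joint triple-threshold and presence rules", {
  m <- mk_metrics(c("hit", "late", "weak"), 2:5)
  fix <- function(l, met, tp, col, val) {
    l[l$metabolite == met & l$timepoint %in% tp, col] <- val; l
  }
  # weak: VIP <= 1 everywhere despite excellent AUC/MDA
  m$vip <- fix(m$vip, "weak", 2:5, "vip", 0.9)
  # late: perfect at tp 3 but absent at tp 5
  m$auc <- m$auc[!(m$auc$metabolite == "late" & m$auc$timepoint == 5), ]
  tab <- build_metric_table(m$vip, m$mda, m$auc)
  res <- select_panel(tab, selection_criteria())
  expect_equal(res$selected, "hit")
  expect_error(select_panel(tab[0, ], selection_criteria()), "empty")

  # baseline exclusion removes a metabolite outright
  res2 <- select_panel(tab, selection_criteria(), excluded = "hit")
  expect_length(res2$selected, 0)
  expect_equal(res2$baseline_excluded, "hit")

  # joint = FALSE allows criteria met at different time points
  m3 <- mk_metrics("split", 2:3)
  m3$vip <- fix(m3$vip, "split", 2, "vip", 0.5)   # vip only passes at tp 3
  m3$mda <- fix(m3$mda, "split", 3, "mda", 0.001) # mda only passes at tp 2
  tab3 <- build_metric_table(m3$vip, m3$mda, m3$auc)
  expect_length(select_panel(tab3, selection_criteria())$selected, 0)
  expect_equal(select_panel(tab3, selection_criteria(joint = FALSE))$selected,
               "split")
})

test_that("selection is monotone in every threshold", {
  set.seed(41)
  g <- expand.grid(metabolite = paste0("m", 1:30), timepoint = 2:5,
                   stringsAsFactors = FALSE)
  tab <- build_metric_table(cbind(g, vip = runif(120, 0.5, 2)),
                            cbind(g, mda = runif(120, -0.01, 0.03)),
                            cbind(g, auc = runif(120, 0.5, 1)))
  base <- select_panel(tab, selection_criteria())$selected
  for (crit in list(selection_criteria(vip_min = 1.3),
                    selection_criteria(mda_min = 0.01),
                    selection_criteria(auc_min = 0.95))) {
    expect_true(all(select_panel(tab, crit)$selected %in% base))
  }
})

test_that("planted baseline confounders are recovered by the exclusion step", {
  # at 20 vs 20 the chance tail of the null AUC is negligible, so the
  # exclusion list equals the confounder set
  exact <- sapply(1:20, function(s) {
    cfg <- synthetic_config(seed = s, n_control_train = 20,
                            n_treated_train = 20, missing_rate = 0,
                            effect_size = 0, global_drift = 0)
    co <- generate_cohort(cfg, "training")
    rows <- co$meta$timepoint == 1 & !co$meta$censored
    a <- auc_by_metabolite(glog_complete(co$matrix)[rows, ],
                           co$meta$group[rows])
    setequal(baseline_exclusions(a, 0.85), co$truth$confounder_names)
  })
  expect_gte(mean(exact), 0.95)

  # at the study's own sizes (5 vs 6) chance exceedances join the list, but
  # the confounders themselves are still caught
  caught <- sapply(1:10, function(s) {
    cfg <- synthetic_config(seed = s, missing_rate = 0, effect_size = 0,
                            global_drift = 0)
    co <- generate_cohort(cfg, "training")
    rows <- co$meta$timepoint == 1 & !co$meta$censored
    a <- auc_by_metabolite(glog_complete(co$matrix)[rows, ],
                           co$meta$group[rows])
    all(co$truth$confounder_names %in% baseline_exclusions(a, 0.85))
  })
  expect_gte(mean(caught), 0.9)
})
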