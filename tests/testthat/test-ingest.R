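test_that("peak table reader enforces the format contract", {
  co <- generate_cohort(tiny_config(seed = 21), "training")
  path <- tempfile(fileext = ".tsv")
  write_peak_table(co$matrix, co$meta, path)
  back <- read_peak_table(path)
  expect_equal(back$matrix, co$matrix)

  # negative intensity rejected
  bad <- co$matrix
  bad[1, 1] <- -5
  p2 <- tempfile(fileext = ".tsv")
  write.table(cbind(co$meta, as.data.frame(bad, check.names = FALSE)), p2,
              sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  expect_error(read_peak_table(p2), "non-negative")

  # duplicated metabolite header rejected (header written verbatim)
  p3 <- tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\tcat_id\tgroup\ttimepoint\tcohort\tcensored\ttryptophan\ttryptophan",
    "s1\tc1\tcontrol\t1\ttraining\tFALSE\t10\t20",
    "s2\tc2\ttreated\t1\ttraining\tFALSE\t11\t21"), p3)
  expect_error(read_peak_table(p3), "duplicate metabolite")

  # duplicated sample identifiers rejected
  p5 <- tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\tcat_id\tgroup\ttimepoint\tcohort\tcensored\ttryptophan",
    "s1\tc1\tcontrol\t1\ttraining\tFALSE\t10",
    "s1\tc2\ttreated\t1\ttraining\tFALSE\t11"), p5)
  expect_error(read_peak_table(p5), "duplicate sample")

  # missing metadata column named in the error
  p4 <- tempfile(fileext = ".tsv")
  write.table(cbind(co$meta[setdiff(names(co$meta), "cohort")],
                    as.data.frame(co$matrix, check.names = FALSE)), p4,
              sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  expect_error(read_peak_table(p4), "cohort")
})

test_that("half-minimum imputation follows the stated rule", {
  x <- matrix(c(2, NA, 4, 1, 2, 3), ncol = 2,
              dimnames = list(c("s1", "s2", "s3"), c("a", "b")))
  out <- impute_missing(x)
  expect_equal(out[, "a"], c(s1 = 2, s2 = 1, s3 = 4))
  expect_equal(out[, "b"], x[, "b"])  # untouched when complete

  # no missing cells: identity
  expect_equal(impute_missing(x[, 2, drop = FALSE]), x[, 2, drop = FALSE],
               ignore_attr = TRUE)

  # a column missing everywhere is dropped and recorded
  x2 <- cbind(x, c(NA, NA, NA))
  colnames(x2)[3] <- "gone"
  expect_message(out2 <- impute_missing(x2), "gone")
  expect_equal(colnames(out2), c("a", "b"))
  expect_equal(attr(out2, "dropped"), "gone")
})

test_that("SD filter removes the stated count, lowest first", {
  set.seed(1)
  x <- matrix(rexp(10 * 100), 10, 100,
              dimnames = list(paste0("s", 1:10), paste0("m", 1:100)))
  expect_equal(filter_low_sd(x, 0), x, ignore_attr = TRUE)
  out <- filter_low_sd(x, 0.05)
  expect_equal(ncol(out), 95)
  expect_length(attr(out, "removed"), 5)
  # a constant column has SD 0 and is removed first
  x[, "m7"] <- 3
  expect_true("m7" %in% attr(filter_low_sd(x, 0.01), "removed"))
  expect_error(filter_low_sd(x, 1), "fraction")
})

test_that("glog2 matches its closed forms and asymptote", {
  expect_equal(glog2(matrix(0), 1), matrix(-1))
  expect_equal(glog2(matrix(3 / 4), 1), matrix(0))
  expect_lt(abs(glog2(matrix(2^20), 1) - 20), 1e-6)
  expect_error(glog2(matrix(1), a = 0), "a must be")
  expect_error(glog2(matrix(c(1, NA))), "complete")
})

test_that("glog2 preserves ranks, so AUC is transform-invariant", {
  set.seed(42)
  x <- matrix(rexp(22 * 30, rate = 1e-4), 22, 30,
              dimnames = list(NULL, paste0("m", 1:30)))
  y <- rep(c("control", "treated"), each = 11)
  before <- auc_by_metabolite(x, y)
  after <- auc_by_metabolite(glog2(x), y)
  expect_equal(before$auc_raw, after$auc_raw)
  expect_equal(before$auc, after$auc)
})

test_that("autoscaling centres and scales with the n-1 convention", {
  x <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "a"))
  expect_equal(unname(autoscale(x)$matrix[, 1]), c(-1, 0, 1))

  set.seed(7)
  x2 <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, letters[1:6]))
  sc <- autoscale(x2)
  expect_lt(max(abs(colMeans(sc$matrix))), 1e-8)
  expect_lt(max(abs(apply(sc$matrix, 2, sd) - 1)), 1e-8)

  # stored params reproduce the fit and project new samples without refitting
  expect_equal(autoscale_apply(x2, sc$params), sc$matrix)
  half <- autoscale_apply(x2[1:5, ], sc$params)
  expect_equal(half, sc$matrix[1:5, ])

  # constant columns are dropped and recorded
  x3 <- cbind(x2, k = 1)
  sc3 <- autoscale(x3)
  expect_equal(sc3$params$dropped, "k")
  expect_false("k" %in% colnames(sc3$matrix))

  expect_error(autoscale(x2[1, , drop = FALSE]), "2 samples")
})

test_that("the preprocessing pipeline runs in the fixed order and logs counts", {
  co <- generate_cohort(synthetic_config(seed = 8), "training")
  res <- suppressMessages(preprocess(co$matrix, preprocess_config()))
  expect_equal(res$log$stage, c("impute", "sd_filter", "autoscale"))
  # default SD filter: 5% of >=250 metabolites
  expect_equal(res$log$n_out[2], 318 - floor(0.05 * 318))
  expect_lt(max(abs(colMeans(res$matrix))), 1e-8)
  # small tables skip the SD filter by default
  tiny <- suppressMessages(preprocess(co$matrix[, 1:60], preprocess_config()))
  expect_equal(tiny$log$n_in[2], tiny$log$n_out[2])
})
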