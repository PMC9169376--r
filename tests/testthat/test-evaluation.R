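test_that("balanced subsetting draws m per class and flags shortfalls", {
  set.seed(51)
  segs <- c(lapply(1:30, function(i) make_segment(rnorm(50), 0)),
            lapply(1:25, function(i) make_segment(rnorm(50), 1)),
            lapply(1:40, function(i) make_segment(rnorm(50), 2)))
  sub <- pick_balanced_subset(segs, m = 20, seed = 1)
  expect_length(sub, 60L)
  labs <- vapply(sub, function(s) s$label, integer(1))
  expect_equal(unname(table(labs)), rep(20L, 3), ignore_attr = TRUE)

  # m equal to the smallest class count includes that class fully
  sub2 <- pick_balanced_subset(segs, m = 25, seed = 1)
  expect_identical(sum(vapply(sub2, function(s) s$label, integer(1)) == 1L), 25L)

  expect_error(pick_balanced_subset(segs, m = 26), "Stone has only 25")

  # different seeds give different subsets (collision vanishingly unlikely)
  big <- lapply(1:300, function(i) make_segment(rnorm(50), (i - 1) %% 3))
  s1 <- pick_balanced_subset(big, 20, seed = 1)
  s2 <- pick_balanced_subset(big, 20, seed = 2)
  key <- function(s) paste(vapply(s, function(g) g$values[1], numeric(1)),
                           collapse = ",")
  expect_false(key(s1) == key(s2))
})

test_that("normalized confusion matches a hand tally and flags empty rows", {
  expect_equal(unclass(normalized_confusion(0:2, 0:2)), diag(3),
               ignore_attr = TRUE)
  m <- normalized_confusion(rep(0:2, each = 3), rep(0L, 9))
  expect_equal(unname(m[, 1]), rep(1, 3))

  # 9-sample example tallied by hand
  truth <- c(0, 0, 0, 1, 1, 1, 2, 2, 2)
  pred  <- c(0, 1, 0, 1, 1, 2, 2, 2, 0)
  m2 <- normalized_confusion(truth, pred)
  expect_equal(unclass(m2),
               rbind(c(2, 1, 0), c(0, 2, 1), c(1, 0, 2)) / 3,
               ignore_attr = TRUE)
  expect_identical(attr(m2, "zero_support"), character(0))

  m3 <- normalized_confusion(c(0, 0), c(1, 1))
  expect_identical(attr(m3, "zero_support"), c("Stone", "Tissue"))
  expect_true(all(m3[2:3, ] == 0))

  expect_error(normalized_confusion(integer(0), integer(0)), "empty")
  expect_error(normalized_confusion(0:1, 0:2), "equal length")
})

test_that("ROC handles the textbook extremes and equals the U-statistic", {
  perfect <- ovr_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 1)
  expect_equal(perfect$auc, 1.0)
  inverted <- ovr_roc(1 - c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 1)
  expect_equal(inverted$auc, 0.0)
  expect_error(ovr_roc(runif(4), rep(1, 4), 1), "undefined")

  # hand-sized score sets, with ties, against the exhaustive pairwise oracle
  set.seed(52)
  for (i in 1:20) {
    scores <- sample(seq(0, 1, by = 0.25), 6, replace = TRUE)
    truth <- c(0, 0, 0, 1, 1, 1)[sample.int(6)]
    expect_equal(ovr_roc(scores, truth, 1)$auc,
                 auc_u_statistic(scores, truth, 1), tolerance = 1e-12)
  }

  # cross-check against an established ROC implementation
  scores <- runif(40)
  truth <- rbinom(40, 1, 0.5)
  expect_equal(ovr_roc(scores, truth, 1)$auc,
               as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("repeated CV bookkeeping, disjointness and aggregation are sound", {
  segs <- default_sim_segments()
  vc <- validation_config(m = 15, n = 4, k = 5, seed = 99)
  rep <- run_repeated_cv(segs, "haar", forest_config(n_trees = 50, seed = 1),
                         vc, keep_folds = TRUE)

  expect_identical(rep$combination_count, 15 * 4 * 5)
  expect_identical(dim(rep$fold_accuracies), c(4L, 5L))
  expect_equal(rep$mean_accuracy, mean(rep$fold_accuracies))
  expect_equal(rep$rep_mean_accuracies, rowMeans(rep$fold_accuracies))
  expect_lt(max(abs(rowSums(rep$confusion) - 1)), 1e-9)

  # equal fold sizes: mean fold accuracy == pooled accuracy from counts
  expect_equal(rep$mean_accuracy,
               sum(diag(rep$confusion_counts)) / sum(rep$confusion_counts))

  for (fl in rep$folds) {
    labs <- vapply(segs[fl$subset], function(s) s$label, integer(1))
    expect_equal(unname(table(labs)), rep(15L, 3), ignore_attr = TRUE)
    for (f in unique(fl$fold)) {
      train_idx <- fl$subset[fl$fold != f]
      test_idx <- fl$subset[fl$fold == f]
      expect_length(intersect(train_idx, test_idx), 0L)
      # stratification: each fold holds m/k segments per class
      expect_equal(unname(table(labs[fl$fold == f])), rep(3L, 3),
                   ignore_attr = TRUE)
    }
  }

  for (cc in rep$roc) {
    expect_true(all(cc$auc_mean >= 0 & cc$auc_mean <= 1))
    expect_length(cc$fpr_grid, 101L)
    expect_false(is.unsorted(cc$tpr_mean))
  }

  expect_error(validation_config(k = 1), "config error")
  expect_error(validation_config(m = 2, k = 10), "config error")
})

test_that("disjoint constant classes give perfect accuracy and confusion", {
  segs <- c(lapply(1:12, function(i) make_segment(rep(0, 50), 0)),
            lapply(1:12, function(i) make_segment(rep(5, 50), 1)),
            lapply(1:12, function(i) make_segment(rep(-7, 50), 2)))
  rep <- run_repeated_cv(segs, "haar",
                         forest_config(n_trees = 20, seed = 1),
                         validation_config(m = 10, n = 2, k = 5, seed = 1))
  expect_equal(rep$mean_accuracy, 1.0)
  expect_equal(unclass(rep$confusion), diag(3), ignore_attr = TRUE)
  for (cc in rep$roc) expect_equal(cc$auc_mean, 1.0)
})

test_that("dummy-data accuracy distribution covers chance level", {
  set.seed(53)
  means <- vapply(1:30, function(s) {
    run_dummy_null(validation_config(m = 8, n = 2, k = 4, seed = s),
                   forest_config(n_trees = 30, seed = s),
                   segment_shape = list(n_per_class = 16),
                   seed = s, wavelet = "haar")$mean_accuracy
  }, numeric(1))
  # one-sample t-test: chance level 1/3 must not be rejected at alpha = 0.01
  expect_gt(stats::t.test(means, mu = 1 / 3)$p.value, 0.01)
})

test_that("dummy pipeline stays honest on a separable control", {
  vc <- validation_config(m = 8, n = 2, k = 4, seed = 7)
  fc <- forest_config(n_trees = 30, seed = 7)
  # constant per-class segments (separable) must hit accuracy 1
  segs <- unlist(lapply(0:2, function(code) {
    lapply(1:16, function(i) make_segment(rep(code * 3 - 1, 50), code))
  }), recursive = FALSE)
  rep <- run_repeated_cv(segs, "haar", fc, vc)
  expect_equal(rep$mean_accuracy, 1.0)
})

test_that("wavelet choice barely moves accuracy on separable data", {
  segs <- default_sim_segments()
  sweep <- run_wavelet_sweep(segs,
                             forest_cfg = forest_config(seed = 1),
                             val_cfg = validation_config(m = 20, n = 10,
                                                         k = 10, seed = 5))
  accs <- sweep$table$mean_accuracy
  expect_identical(sweep$table$wavelet, supported_wavelets())
  expect_true(all(accs > 0.9))
  expect_lte(max(accs) - min(accs), 0.05)
})
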