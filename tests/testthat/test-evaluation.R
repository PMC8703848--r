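test_that("confusion/accuracy arithmetic on hand-built cases", {
  # perfect predictor
  labs <- rep(c("BBB_plus", "BBB_minus"), 5)
  rep0 <- confusion_and_accuracy(labs, labs)
  expect_equal(rep0$accuracy, 1)
  expect_equal(rep0$class_error_plus, 0)
  expect_equal(rep0$class_error_minus, 0)
  # hand-built 2x2: TP=8, FN=2, FP=3, TN=7
  truth <- c(rep("BBB_plus", 10), rep("BBB_minus", 10))
  pred <- c(rep("BBB_plus", 8), rep("BBB_minus", 2),
            rep("BBB_plus", 3), rep("BBB_minus", 7))
  r <- confusion_and_accuracy(pred, truth)
  expect_equal(r$accuracy, 0.75)
  expect_equal(r$class_error_plus, 0.2)
  expect_equal(r$class_error_minus, 0.3)
  expect_equal(sum(r$confusion), r$n_classified)
})

test_that("all-positive predictor: accuracy r/(r+1), minus error 1", {
  ratio <- 4
  truth <- c(rep("BBB_plus", 40), rep("BBB_minus", 10))
  r <- confusion_and_accuracy(rep("BBB_plus", 50), truth)
  expect_equal(r$accuracy, ratio / (ratio + 1))
  expect_equal(r$class_error_minus, 1)
})

test_that("unclassifiable and unknown-label records are excluded but counted", {
  truth <- c("BBB_plus", "BBB_minus", "BBB_plus", "unknown")
  pred <- c("BBB_plus", NA, "BBB_minus", "BBB_plus")
  r <- confusion_and_accuracy(pred, truth)
  expect_equal(r$n_classified, 2L)
  expect_equal(r$n_unclassifiable, 1L)
  expect_error(confusion_and_accuracy(NA_character_, "BBB_plus"),
               "undefined|no classified")
})

test_that("z-score normalization: hand value, idempotence, affine invariance", {
  z <- zscore_normalize(c(1, 2, 3))
  expect_equal(z, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(mean(z), 0)
  expect_equal(sqrt(mean(z^2)), 1)          # population SD
  expect_equal(zscore_normalize(z), z)       # already standardized
  x <- rnorm(50)
  expect_equal(zscore_normalize(3.7 * x - 11), zscore_normalize(x))
  expect_error(zscore_normalize(rep(2, 5)), "degenerate")
})

test_that("rf_importance ranks the sole informative descriptor first", {
  ds <- signal_only_ccs(n_per_class = 120, seed = 5)
  rep1 <- rf_importance(ds, descriptors = setdiff(descriptor_names(), "xlogp3"),
                        cfg = validation_config(rf_trees = 150))
  expect_equal(rep1$ranking[1], "ccs")
  expect_true(all(rep1$scores[setdiff(names(rep1$scores), "ccs")] <
                    rep1$scores["ccs"]))
})

test_that("all-noise descriptors give near-zero importance and base-rate OOB error", {
  set.seed(8)
  n <- 300
  df <- data.frame(id = seq_len(n),
                   bbb_label = rep(c("BBB_plus", "BBB_minus"), c(240, 60)))
  for (d in c("ccs", "mw", "psa", "pka")) df[[d]] <- abs(rnorm(n, 100, 10))
  ds <- compound_dataset(df)
  rep0 <- rf_importance(ds, c("ccs", "mw", "psa", "pka"),
                        validation_config(rf_trees = 200))
  expect_lt(max(abs(rep0$scores)), 0.05)
  # OOB error near the minority base rate (0.2), within simulation noise
  expect_lt(abs(rep0$fit$oob_error - 0.2), 0.08)
})

test_that("rf_importance is deterministic under a fixed seed", {
  ds <- signal_only_ccs(60, seed = 2)
  cfg <- validation_config(rf_trees = 50)
  r1 <- rf_importance(ds, c("ccs", "mw", "psa", "pka"), cfg)
  r2 <- rf_importance(ds, c("ccs", "mw", "psa", "pka"), cfg)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$oob_report$confusion, r2$oob_report$confusion)
})

test_that("single-class data raise a degenerate-label error", {
  df <- data.frame(id = 1:20, bbb_label = "BBB_plus", ccs = rnorm(20, 170))
  expect_error(rf_importance(compound_dataset(df), "ccs"),
               "degenerate|single class")
})

test_that("stepwise reduction follows the 8->6->4 ladder and keeps signal carriers", {
  # exactly 4 informative descriptors + 4 pure-noise ones
  set.seed(13)
  n <- 150
  informative <- c("ccs", "psa", "mw", "logd74")
  noise <- c("h_acceptors", "h_donors", "rotatable_bonds", "pka")
  df <- data.frame(id = seq_len(2 * n),
                   bbb_label = rep(c("BBB_plus", "BBB_minus"), each = n))
  for (d in informative) {
    df[[d]] <- abs(c(rnorm(n, 100, 15), rnorm(n, 160, 15)))
  }
  for (d in noise) df[[d]] <- rnorm(2 * n)
  ds <- compound_dataset(df)
  ladder <- stepwise_reduction(ds, descriptors = c(informative, noise),
                               cfg = validation_config(rf_trees = 150))
  expect_equal(vapply(ladder, function(r) r$subset_size, integer(1)),
               c(size_8 = 8L, size_6 = 6L, size_4 = 4L))
  expect_setequal(ladder$size_4$descriptors, informative)
  # reruns with the same seed give the identical drop sequence
  ladder2 <- stepwise_reduction(ds, descriptors = c(informative, noise),
                                cfg = validation_config(rf_trees = 150))
  expect_identical(lapply(ladder, `[[`, "descriptors"),
                   lapply(ladder2, `[[`, "descriptors"))
  expect_error(stepwise_reduction(ds, descriptors = informative,
                                  steps = c(8, 6, 4)), "must match")
})

test_that("split_and_validate: deterministic rule equals brute-force on test rows", {
  ds <- simulate_dataset(synthetic_config(n_total = 500, seed = 21))
  cfg <- validation_config(n_folds = 10)
  sv <- split_and_validate(ds, ccs200_rule(), cfg)
  brute <- mean((ds$ccs < 200) ==
                  (ds$bbb_label == "BBB_plus"))
  test_rows <- sv$test_idx
  brute_test <- mean((ds$ccs[test_rows] < 200) ==
                       (ds$bbb_label[test_rows] == "BBB_plus"))
  expect_equal(sv$test_report$accuracy, brute_test)
  # stratification: test fraction ~0.3 in each class
  expect_equal(length(test_rows) / nrow(ds), 0.3, tolerance = 0.02)
  # same seed twice -> identical folds and accuracies
  sv2 <- split_and_validate(ds, ccs200_rule(), cfg)
  expect_identical(sv$fold_accuracies, sv2$fold_accuracies)
  expect_identical(sv$test_idx, sv2$test_idx)
})

test_that("leave-one-out folds on a toy set give 0/1 fold accuracies", {
  ds <- tiny_dataset(ccs = c(150, 160, 170, 180, 190, 210, 220, 230, 240, 250),
                     labels = rep(c("BBB+", "BBB-"), each = 5))
  sv <- split_and_validate(ds, ccs200_rule(),
                           validation_config(n_folds = 5, test_fraction = 0.4))
  expect_true(all(sv$fold_accuracies %in% c(0, 1)))
  expect_equal(sv$cv_mean, 1)
})

test_that("fold counts beyond the smallest class are a configuration error", {
  ds <- tiny_dataset()
  expect_error(split_and_validate(ds, ccs200_rule(),
                                  validation_config(n_folds = 50)),
               "configuration error")
})

test_that("an rf model can be validated through the same splitter", {
  ds <- signal_only_ccs(80, seed = 31)
  sv <- split_and_validate(ds, rule = NULL,
                           cfg = validation_config(n_folds = 5,
                                                   rf_trees = 60),
                           model = "rf",
                           descriptors = c("ccs", "mw", "psa", "pka"))
  expect_gt(sv$test_report$accuracy, 0.8)   # strong signal, easy task
})
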