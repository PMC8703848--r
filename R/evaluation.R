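# Accuracy evaluation against literature labels, Z-score normalization,
# descriptor-importance analysis with stepwise reduction, and train/test
# plus k-fold validation.

#' Validation configuration
#'
#' Bundles the knobs of the evaluation stage. Defaults follow the
#' conventions of BBB descriptor studies: a 0.3 test fraction with split
#' seed 42, 100-fold cross validation, and 1000-tree forests fitted under
#' the fixed seed 123456.
#'
#' @param test_fraction held-out fraction, strictly between 0 and 1.
#' @param split_seed integer seed for the train/test split and folds.
#' @param n_folds number of cross-validation folds, >= 2.
#' @param rf_trees trees per forest.
#' @param rf_seed seed for forest fitting.
#' @param rf_mtry features tried per node (`NULL` = `floor(sqrt(p))`).
#' @param cv_repeats repeats of the whole k-fold procedure (default 1).
#' @return Object of class `validation_config`.
#' @export
validation_config <- function(test_fraction = 0.3, split_seed = 42L,
                              n_folds = 100L, rf_trees = 1000L,
                              rf_seed = 123456L, rf_mtry = NULL,
                              cv_repeats = 1L) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (n_folds < 2L) stop("n_folds must be at least 2", call. = FALSE)
  structure(list(test_fraction = test_fraction,
                 split_seed = as.integer(split_seed),
                 n_folds = as.integer(n_folds),
                 rf_trees = as.integer(rf_trees),
                 rf_seed = as.integer(rf_seed),
                 rf_mtry = rf_mtry,
                 cv_repeats = as.integer(cv_repeats)),
            class = "validation_config")
}

#' Confusion matrix and accuracy of BBB predictions
#'
#' Compares predicted labels with reference (literature) labels. Records
#' with an `NA` prediction are excluded from the confusion matrix but
#' counted as unclassifiable; records with an unknown reference label are
#' ignored.
#'
#' @param predictions character/factor vector of `"BBB_plus"`,
#'   `"BBB_minus"` or `NA`.
#' @param labels reference labels, same length and ordering.
#' @return Object of class `classification_report`: `confusion` (2x2 counts,
#'   truth x prediction), `accuracy`, `class_error_plus`,
#'   `class_error_minus`, `n_classified`, `n_unclassifiable`.
#' @examples
#' confusion_and_accuracy(
#'   predictions = c("BBB_plus", "BBB_plus", "BBB_minus"),
#'   labels = c("BBB_plus", "BBB_minus", "BBB_minus"))
#' @export
confusion_and_accuracy <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    stop("predictions and labels must align", call. = FALSE)
  }
  labels <- as.character(labels)
  predictions <- as.character(predictions)
  known <- labels %in% c("BBB_plus", "BBB_minus")
  n_unclassifiable <- sum(known & is.na(predictions))
  use <- known & !is.na(predictions)
  if (!any(use)) {
    stop("no classified records with known labels; metrics undefined",
         call. = FALSE)
  }
  lv <- c("BBB_plus", "BBB_minus")
  conf <- table(truth = factor(labels[use], lv),
                predicted = factor(predictions[use], lv))
  n <- sum(conf)
  acc <- sum(diag(conf)) / n
  cls_err <- function(lv1) {
    tot <- sum(conf[lv1, ])
    if (tot == 0) NA_real_ else (tot - conf[lv1, lv1]) / tot
  }
  structure(list(confusion = conf, accuracy = acc,
                 class_error_plus = cls_err("BBB_plus"),
                 class_error_minus = cls_err("BBB_minus"),
                 n_classified = n,
                 n_unclassifiable = n_unclassifiable),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification report: accuracy %.1f%% on %d records (%d unclassifiable)>\n",
    100 * x$accuracy, x$n_classified, x$n_unclassifiable))
  cat(sprintf("  class error BBB+: %.1f%%   BBB-: %.1f%%\n",
              100 * x$class_error_plus, 100 * x$class_error_minus))
  print(x$confusion)
  invisible(x)
}

#' Z-score normalization
#'
#' Centres and scales a numeric vector by its population mean and
#' population standard deviation (divisor `n`, not `n - 1`), the
#' normalization conventionally used to overlay descriptor distributions of
#' BBB-permeant and non-permeant compounds on a common scale.
#'
#' @param values numeric vector with at least two distinct finite values.
#' @return Vector of the same length with mean 0 and population SD 1.
#' @examples
#' zscore_normalize(c(1, 2, 3))   # -1.2247, 0, 1.2247
#' @export
zscore_normalize <- function(values) {
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2L) {
    stop("degenerate input: need at least two distinct values", call. = FALSE)
  }
  mu <- mean(v)
  sd_pop <- sqrt(mean((v - mu)^2))
  (values - mu) / sd_pop
}

# descriptor matrix for labelled records; drops gap rows with a message
.descriptor_matrix <- function(ds, descriptors) {
  missing_cols <- setdiff(descriptors, names(ds))
  if (length(missing_cols)) {
    stop("descriptors absent from dataset: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  labelled <- ds$bbb_label %in% c("BBB_plus", "BBB_minus")
  x <- as.matrix(as.data.frame(ds)[labelled, descriptors, drop = FALSE])
  storage.mode(x) <- "double"
  y <- factor(ds$bbb_label[labelled], c("BBB_plus", "BBB_minus"))
  complete <- stats::complete.cases(x)
  if (any(!complete)) {
    message(sum(!complete), " record(s) with descriptor gaps dropped")
  }
  list(x = x[complete, , drop = FALSE], y = droplevels(y[complete]))
}

#' Random-forest descriptor importance
#'
#' Fits a forest of classification trees on the requested descriptor
#' subset and reports permutation-based mean decrease accuracy estimated on
#' out-of-bag samples, together with the out-of-bag error and per-class
#' errors. No normalization, scaling or filtering is applied beyond
#' dropping records with descriptor gaps.
#'
#' @param ds a [compound_dataset()] with known BBB labels.
#' @param descriptors character vector of descriptor columns to use.
#' @param cfg a [validation_config()]; `rf_trees`, `rf_seed` and `rf_mtry`
#'   are consumed.
#' @return Object of class `importance_report`: `descriptors`, `scores`
#'   (mean decrease accuracy, same order as `descriptors`), `ranking`
#'   (descriptor names, best first), `n_trees`, `seed`,
#'   `subset_size`, `oob_report` (a `classification_report` built from the
#'   out-of-bag predictions), and the underlying `fit`.
#' @export
rf_importance <- function(ds, descriptors = descriptor_names(),
                          cfg = validation_config()) {
  stopifnot(inherits(ds, "compound_dataset"),
            inherits(cfg, "validation_config"))
  dm <- .descriptor_matrix(ds, descriptors)
  if (nlevels(dm$y) < 2L) {
    stop("degenerate labels: dataset has a single class", call. = FALSE)
  }
  fit <- rf_fit(dm$x, dm$y, ntree = cfg$rf_trees, mtry = cfg$rf_mtry,
                seed = cfg$rf_seed)
  oob_ok <- !is.na(fit$oob_pred)
  oob_report <- confusion_and_accuracy(as.character(fit$oob_pred[oob_ok]),
                                       as.character(dm$y[oob_ok]))
  scores <- fit$importance[descriptors]
  structure(list(
    descriptors = descriptors,
    scores = scores,
    ranking = names(sort(scores, decreasing = TRUE)),
    n_trees = cfg$rf_trees, seed = cfg$rf_seed,
    subset_size = length(descriptors),
    oob_report = oob_report,
    fit = fit
  ), class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf(
    "<importance report: %d descriptors, %d trees, seed %d, OOB error %.1f%%>\n",
    x$subset_size, x$n_trees, x$seed, 100 * x$fit$oob_error))
  print(round(sort(x$scores, decreasing = TRUE), 4))
  invisible(x)
}

#' Stepwise descriptor reduction
#'
#' Refits the importance analysis on shrinking descriptor subsets,
#' dropping the lowest-ranked descriptors at each step (default ladder
#' 8 -> 6 -> 4).
#'
#' @param ds a [compound_dataset()].
#' @param descriptors the full starting subset (default the first 8
#'   descriptor names present, conventionally PSA, CCS, logD, MW, H-bond
#'   counts, rotatable bonds and pKa).
#' @param cfg a [validation_config()].
#' @param steps decreasing subset sizes; the first must equal
#'   `length(descriptors)`.
#' @return List of [rf_importance()] reports, one per step size.
#' @export
stepwise_reduction <- function(ds,
                               descriptors = setdiff(descriptor_names(),
                                                     "xlogp3"),
                               cfg = validation_config(),
                               steps = c(8L, 6L, 4L)) {
  steps <- as.integer(steps)
  if (steps[1] != length(descriptors)) {
    stop("first step size must match the number of starting descriptors",
         call. = FALSE)
  }
  if (is.unsorted(rev(steps), strictly = TRUE)) {
    stop("steps must be strictly decreasing", call. = FALSE)
  }
  current <- descriptors
  reports <- vector("list", length(steps))
  for (k in seq_along(steps)) {
    if (k > 1L) {
      keep <- steps[k]
      current <- reports[[k - 1L]]$ranking[seq_len(keep)]
    }
    reports[[k]] <- rf_importance(ds, current, cfg)
  }
  names(reports) <- paste0("size_", steps)
  reports
}

# stratified index split: returns test indices
.stratified_test_idx <- function(y, fraction, seed) {
  set.seed(seed)
  idx <- unlist(lapply(split(seq_along(y), y), function(ix) {
    n_test <- round(length(ix) * fraction)
    sample(ix, n_test)
  }), use.names = FALSE)
  sort(idx)
}

# stratified fold assignment, 1..k per record
.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (ix in split(seq_along(y), y)) {
    fold[sample(ix)] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

#' Train/test split and k-fold validation of a rule or model
#'
#' Splits the labelled records into a stratified train/test partition
#' (class ratio preserved, the datasets being heavily imbalanced) and
#' evaluates the classifier on the test set; additionally runs stratified
#' k-fold cross validation over all labelled records and reports the
#' fold-wise accuracy distribution.
#'
#' For a [threshold_rule()]/[combined_rule()] the classifier is
#' deterministic and needs no training; with `model = "rf"` a forest is
#' fitted on each training portion and evaluated on the held-out part.
#'
#' @param ds a [compound_dataset()] with known labels.
#' @param rule a threshold/combined rule, or `NULL` when `model = "rf"`.
#' @param cfg a [validation_config()].
#' @param model `"rule"` (default) or `"rf"`.
#' @param descriptors descriptor columns for the `"rf"` model.
#' @return List: `test_report` (a `classification_report`),
#'   `fold_accuracies`, `cv_mean`, `cv_sd`, `test_idx`.
#' @export
split_and_validate <- function(ds, rule = ccs200_rule(),
                               cfg = validation_config(),
                               model = c("rule", "rf"),
                               descriptors = descriptor_names()) {
  model <- match.arg(model)
  stopifnot(inherits(ds, "compound_dataset"))
  labelled <- which(ds$bbb_label %in% c("BBB_plus", "BBB_minus"))
  y <- ds$bbb_label[labelled]
  counts <- table(y)
  if (cfg$n_folds > min(counts)) {
    stop(sprintf(
      "configuration error: %d folds exceed the smallest class (%d records)",
      cfg$n_folds, min(counts)), call. = FALSE)
  }
  sub <- compound_dataset(as.data.frame(ds)[labelled, , drop = FALSE],
                          name = attr(ds, "name"))
  predict_subset <- function(train_idx, eval_idx) {
    if (model == "rule") {
      preds <- classify_dataset(sub, rule)$predicted
      preds[eval_idx]
    } else {
      dtrain <- .descriptor_matrix(
        compound_dataset(as.data.frame(sub)[train_idx, , drop = FALSE]),
        descriptors)
      fit <- rf_fit(dtrain$x, dtrain$y, ntree = cfg$rf_trees,
                    mtry = cfg$rf_mtry, seed = cfg$rf_seed)
      x_eval <- as.matrix(as.data.frame(sub)[eval_idx, descriptors,
                                             drop = FALSE])
      as.character(predict(fit, x_eval))
    }
  }
  test_idx <- .stratified_test_idx(y, cfg$test_fraction, cfg$split_seed)
  train_idx <- setdiff(seq_along(y), test_idx)
  test_report <- confusion_and_accuracy(predict_subset(train_idx, test_idx),
                                        y[test_idx])
  fold_acc <- numeric(0)
  for (rep_i in seq_len(cfg$cv_repeats)) {
    fold <- .stratified_folds(y, cfg$n_folds, cfg$split_seed + rep_i - 1L)
    for (f in seq_len(cfg$n_folds)) {
      eval_idx <- which(fold == f)
      rep_train <- which(fold != f)
      preds <- predict_subset(rep_train, eval_idx)
      known <- !is.na(preds)
      if (!any(known)) next
      fold_acc <- c(fold_acc, mean(preds[known] == y[eval_idx][known]))
    }
  }
  list(test_report = test_report,
       fold_accuracies = fold_acc,
       cv_mean = mean(fold_acc),
       cv_sd = stats::sd(fold_acc),
       test_idx = labelled[test_idx])
}
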