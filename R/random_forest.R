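# R-level interface to the bagged-tree ensemble in src/rf.cpp. The forest
# follows the classic classification random-forest recipe: bootstrap
# resampling per tree, Gini splits on mtry randomly drawn features per
# node, unpruned trees, majority-vote aggregation; importance is the
# out-of-bag permutation estimate of mean decrease accuracy.

#' Fit a random forest of classification trees
#'
#' @param x numeric matrix or data.frame of predictors (no missing values).
#' @param y factor (or coercible) of class labels, at least two classes
#'   present.
#' @param ntree number of trees (default 500).
#' @param mtry features tried per node; default `floor(sqrt(p))`.
#' @param min_node minimum records per leaf (default 1, fully grown trees).
#' @param importance compute out-of-bag permutation importance
#'   (default `TRUE`).
#' @param seed optional integer; when given, `set.seed(seed)` is applied so
#'   the fit is reproducible.
#' @return Object of class `ccs_rf`: `forest` (opaque tree list),
#'   `levels`, `oob_pred` (factor, `NA` where a record was never
#'   out-of-bag), `oob_error`, `class_errors`, `confusion`,
#'   `importance` (named mean-decrease-accuracy vector), `ntree`, `mtry`.
#' @export
rf_fit <- function(x, y, ntree = 500, mtry = NULL, min_node = 1,
                   importance = TRUE, seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("predictor matrix contains missing values", call. = FALSE)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) {
    stop("degenerate labels: need at least two classes to fit a forest",
         call. = FALSE)
  }
  if (length(y) != nrow(x)) stop("x and y lengths differ", call. = FALSE)
  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  if (!is.null(seed)) set.seed(seed)
  fit <- .rf_fit_cpp(x, as.integer(y) - 1L, nlevels(y), as.integer(ntree),
                     as.integer(mtry), as.integer(min_node),
                     isTRUE(importance))
  votes <- fit$oob_votes
  oob_idx <- rowSums(votes) > 0
  oob_pred <- rep(NA_integer_, nrow(x))
  oob_pred[oob_idx] <- max.col(votes[oob_idx, , drop = FALSE],
                               ties.method = "first")
  oob_pred <- factor(levels(y)[oob_pred], levels = levels(y))
  conf <- table(truth = y[oob_idx], predicted = oob_pred[oob_idx])
  oob_error <- mean(oob_pred[oob_idx] != y[oob_idx])
  class_errors <- vapply(levels(y), function(lv) {
    in_class <- oob_idx & y == lv
    if (!any(in_class)) return(NA_real_)
    mean(oob_pred[in_class] != lv)
  }, numeric(1))
  imp <- as.numeric(fit$importance)
  names(imp) <- colnames(x) %||% paste0("x", seq_len(p))
  structure(list(
    forest = fit$trees, levels = levels(y), oob_pred = oob_pred,
    oob_error = oob_error, class_errors = class_errors, confusion = conf,
    importance = if (isTRUE(importance)) imp else NULL,
    ntree = ntree, mtry = mtry
  ), class = "ccs_rf")
}

#' @export
print.ccs_rf <- function(x, ...) {
  cat(sprintf("<random forest: %d trees, mtry %d, OOB error %.1f%%>\n",
              x$ntree, x$mtry, 100 * x$oob_error))
  if (!is.null(x$importance)) {
    cat("importance (mean decrease accuracy):\n")
    print(round(sort(x$importance, decreasing = TRUE), 4))
  }
  invisible(x)
}

#' Predict classes with a fitted forest
#'
#' @param object a `ccs_rf` fit.
#' @param newdata numeric matrix/data.frame with the training columns.
#' @param ... unused.
#' @return Factor of predicted labels (majority vote over trees).
#' @export
predict.ccs_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  votes <- .rf_predict_cpp(object$forest, newdata, length(object$levels))
  factor(object$levels[max.col(votes, ties.method = "first")],
         levels = object$levels)
}
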