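# Random-forest symptom detector: an ensemble of 50 trees on the 56-feature
# representation, class-weighted for the imbalanced symptom labels, with the
# out-of-bag error exposed for tuning checks.

#' Fit a random-forest symptom classifier
#'
#' @param x numeric feature matrix (clips x features) with column names.
#' @param y binary labels (0 = symptom absent, 1 = present); both classes
#'   must be present.
#' @param n_trees number of trees (default 50).
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @param seed integer seed; the fit is deterministic given the seed.
#' @return An object of class `pd_rf` with the fitted forest, the out-of-bag
#'   error estimate (`oob_error`) and the training feature schema.
#' @export
pd_rf <- function(x, y, n_trees = 50, mtry = NULL, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab < 2)) {
    stop("training requires at least 2 examples of each class", call. = FALSE)
  }
  if (!is_count(n_trees, min = 1)) stop("`n_trees` must be >= 1", call. = FALSE)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  cw <- as.numeric(1 / tab)
  cw <- cw / sum(cw)
  fit <- with_seed(seed, randomForest::randomForest(
    x = x, y = factor(y, levels = c(0, 1)), ntree = n_trees, mtry = mtry,
    classwt = cw
  ))
  structure(list(
    forest = fit,
    n_trees = as.integer(n_trees),
    mtry = mtry,
    seed = as.integer(seed),
    feature_names = colnames(x),
    class_counts = as.integer(tab),
    oob_error = unname(fit$err.rate[n_trees, "OOB"])
  ), class = "pd_rf")
}

#' Predict symptom probabilities from a fitted random forest
#'
#' @param object a [pd_rf()] fit.
#' @param newdata feature matrix with the training schema (same column
#'   names in the same order).
#' @param ... ignored.
#' @return Numeric vector in `[0, 1]`: per-clip probability that the symptom
#'   is present, in input order.
#' @export
predict.pd_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) colnames(newdata) <- object$feature_names
  if (!identical(colnames(newdata), object$feature_names)) {
    stop("feature schema mismatch between model and new data", call. = FALSE)
  }
  unname(predict(object$forest, newdata, type = "prob")[, "1"])
}

#' @export
print.pd_rf <- function(x, ...) {
  cat(sprintf("<pd_rf> %d trees, mtry %d, %d features | OOB error %.3f | n = %d/%d (neg/pos)\n",
              x$n_trees, x$mtry, length(x$feature_names), x$oob_error,
              x$class_counts[1], x$class_counts[2]))
  invisible(x)
}
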