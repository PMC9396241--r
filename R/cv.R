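#' Random forest hyperparameters
#'
#' The fixed configuration of the outcome classifier: 2,000 trees, minimum
#' node size 1 and 7 candidate features per split.
#'
#' @param n_trees Number of trees.
#' @param min_node_size Minimum terminal node size.
#' @param mtry Candidate features per split.
#' @param seed Integer seed for forest growing.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 2000, min_node_size = 1, mtry = 7, seed = 1) {
  assert_scalar_number(n_trees, "n_trees", lo = 1)
  assert_scalar_number(min_node_size, "min_node_size", lo = 1)
  assert_scalar_number(mtry, "mtry", lo = 1)
  structure(
    list(n_trees = as.integer(n_trees),
         min_node_size = as.integer(min_node_size),
         mtry = as.integer(mtry), seed = as.integer(seed)),
    class = "rf_config"
  )
}

#' Stratified k-fold assignment
#'
#' Deterministic stratified folds: within each class the (seeded) shuffled
#' members are dealt cyclically onto the folds, the cycle position
#' carrying over between classes. Fold sizes therefore differ by at most
#' one and each fold's class counts are within one of proportional
#' allocation.
#'
#' @param labels Vector of class labels (any type; each class must have at
#'   least `k` members).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, aligned with `labels`.
#' @export
stratified_kfold <- function(labels, k = 10, seed = 1) {
  counts <- table(labels)
  if (any(counts < k)) {
    stop_contract("every class needs at least k = %d members (smallest has %d)",
                  k, min(counts))
  }
  fold <- integer(length(labels))
  pos <- 0L
  with_eye_rng(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
      pos <- pos + length(idx)
    }
  })
  fold
}

rf_matrix <- function(features, feature_set) {
  cols <- feature_set_columns(feature_set)
  x <- as.matrix(features[cols])
  if (any(!is.finite(x))) {
    stop_missing_data("feature table contains missing or non-finite values")
  }
  x
}

#' Cross-validated random-forest class probabilities
#'
#' Stratified k-fold cross-validation of a random forest with the pinned
#' hyperparameters: at each fold 90% of the eyes grow the forest (its
#' out-of-bag error is recorded as the validation error) and the held-out
#' 10% receive class probabilities, so every eye's probability comes from
#' a forest never trained on it. The probability of the positive class is
#' the fraction of trees voting for it.
#'
#' @param features Wide feature tibble from [assemble_features()] with an
#'   `eye_id` column.
#' @param labels Logical or 0/1 vector aligned with `features` (positive
#'   class = `TRUE`).
#' @param rf An [rf_config()].
#' @param k Number of folds.
#' @param feature_set Predictor subset, see [feature_set_columns()].
#' @param seed Seed for the fold assignment.
#' @return Object of class `cv_prediction`: tibble `predictions`
#'   `(eye_id, fold, label, prob)`, per-fold `oob_error`, plus the fold
#'   assignment and configuration. The fitted fold forests are retained
#'   for permutation importance.
#' @export
cv_predict <- function(features, labels, rf = rf_config(), k = 10,
                       feature_set = "all", seed = 1) {
  labels <- as.logical(labels)
  if (any(is.na(labels))) stop_contract("`labels` must be binary without NA")
  if (length(labels) != nrow(features)) {
    stop_contract("`labels` must align with `features`")
  }
  x <- rf_matrix(features, feature_set)
  y <- factor(labels, levels = c(FALSE, TRUE))
  fold <- stratified_kfold(labels, k = k, seed = seed)

  fits <- vector("list", k)
  prob <- numeric(length(labels))
  oob <- numeric(k)
  mtry <- min(rf$mtry, ncol(x))
  for (f in seq_len(k)) {
    tr <- fold != f
    set.seed(rf$seed + f)
    fit <- randomForest::randomForest(
      x = x[tr, , drop = FALSE], y = y[tr],
      ntree = rf$n_trees, mtry = mtry, nodesize = rf$min_node_size
    )
    fits[[f]] <- fit
    oob[f] <- fit$err.rate[rf$n_trees, "OOB"]
    prob[!tr] <- predict(fit, x[!tr, , drop = FALSE], type = "prob")[, "TRUE"]
  }

  structure(
    list(
      predictions = tibble::tibble(
        eye_id = features$eye_id, fold = fold, label = labels, prob = prob
      ),
      oob_error = oob, fold = fold, feature_set = feature_set,
      feature_cols = colnames(x), rf = rf, k = k, seed = seed,
      fits = fits, x = x
    ),
    class = "cv_prediction"
  )
}

#' @export
print.cv_prediction <- function(x, ...) {
  cat(sprintf("<cv_prediction> %d eyes, %d folds, feature set '%s' (%d predictors)\n",
              nrow(x$predictions), x$k, x$feature_set, length(x$feature_cols)))
  cat(sprintf("  mean fold OOB error %.3f\n", mean(x$oob_error)))
  invisible(x)
}
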