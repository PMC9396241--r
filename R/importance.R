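#' Out-of-fold permutation feature importance
#'
#' For each feature, its column is permuted (whole-cohort permutations,
#' `n_perm` of them, seeded) and the out-of-fold accuracy of the
#' cross-validated forests is recomputed; the importance is the mean
#' decrease in out-of-fold accuracy relative to the unpermuted
#' predictions. Computing the decrease out-of-fold rather than from the
#' forests' internal out-of-bag samples makes the measure independent of
#' the forest implementation.
#'
#' @param cv A `cv_prediction` from [cv_predict()].
#' @param n_perm Permutations per feature.
#' @param seed Integer seed.
#' @return Tibble `(feature, importance)` ranked by decreasing
#'   importance.
#' @export
permutation_importance <- function(cv, n_perm = 10, seed = 1) {
  x <- cv$x
  n <- nrow(x)
  labels <- cv$predictions$label
  base_acc <- mean((cv$predictions$prob >= 0.5) == labels)

  perms <- with_eye_rng(seed, {
    lapply(seq_len(n_perm), function(r) sample.int(n))
  })
  p <- ncol(x)
  acc <- matrix(0, p, n_perm, dimnames = list(colnames(x), NULL))

  for (f in seq_len(cv$k)) {
    te <- which(cv$fold == f)
    # one prediction call per fold over all (feature, permutation) variants
    big <- do.call(rbind, lapply(seq_len(p), function(j) {
      do.call(rbind, lapply(perms, function(pr) {
        xt <- x[te, , drop = FALSE]
        xt[, j] <- x[pr[te], j]
        xt
      }))
    }))
    pred <- predict(cv$fits[[f]], big, type = "prob")[, "TRUE"] >= 0.5
    hit <- pred == rep(labels[te], times = p * n_perm)
    dim(hit) <- c(length(te), n_perm, p)
    acc <- acc + t(colSums(hit))  # p x n_perm matrix of correct counts
  }
  acc <- acc / n
  tibble::tibble(
    feature = colnames(x),
    importance = base_acc - rowMeans(acc)
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}
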