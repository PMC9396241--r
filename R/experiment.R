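#' Evaluate cross-validated predictions
#'
#' Wraps a [cv_predict()] result with the full evaluation: pooled
#' out-of-fold ROC/AUC, the per-fold mean AUC, a 1000-resample percentile
#' bootstrap 95% CI, the Youden-optimal and 80%-specificity operating
#' points, and (optionally) out-of-fold permutation importances.
#'
#' @param cv A `cv_prediction`.
#' @param n_boot Bootstrap resamples for the AUC CI.
#' @param seed Seed for the bootstrap and the permutations.
#' @param importance Compute permutation feature importance.
#' @param n_perm Permutations per feature.
#' @return Object of class `cv_evaluation`.
#' @export
evaluate_cv <- function(cv, n_boot = 1000, seed = 1, importance = FALSE,
                        n_perm = 10) {
  pr <- cv$predictions
  roc <- roc_auc(pr$prob, pr$label)
  fold_auc <- pr |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(auc = tryCatch(roc_auc(.data$prob, .data$label)$auc,
                                    error = function(e) NA_real_),
                     .groups = "drop")
  structure(
    list(
      feature_set = cv$feature_set,
      predictions = pr,
      roc = roc,
      auc = roc$auc,
      auc_fold_mean = mean(fold_auc$auc, na.rm = TRUE),
      auc_ci = bootstrap_auc_ci(pr$prob, pr$label, n_boot = n_boot, seed = seed),
      auc_se = auc_se(roc$auc, roc$n_pos, roc$n_neg),
      operating_points = operating_points(roc),
      oob_error = cv$oob_error,
      importances = if (importance) permutation_importance(cv, n_perm, seed)
    ),
    class = "cv_evaluation"
  )
}

#' @export
print.cv_evaluation <- function(x, ...) {
  cat(sprintf("<cv_evaluation> feature set '%s': AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$feature_set, x$auc, x$auc_ci[["lo"]], x$auc_ci[["hi"]]))
  print(x$operating_points)
  invisible(x)
}

#' Glance at a cross-validation evaluation
#'
#' @param x A `cv_evaluation`.
#' @param ... Unused.
#' @return One-row tibble with AUC, CI, operating points and mean OOB
#'   error.
#' @export
glance.cv_evaluation <- function(x, ...) {
  op <- x$operating_points
  tibble::tibble(
    feature_set = x$feature_set,
    auc = x$auc, auc_lo = x$auc_ci[["lo"]], auc_hi = x$auc_ci[["hi"]],
    auc_fold_mean = x$auc_fold_mean,
    youden_sens = op$sensitivity[op$point == "youden"],
    youden_spec = op$specificity[op$point == "youden"],
    sens_at_spec80 = if (any(op$point == "spec80")) op$sensitivity[op$point == "spec80"] else NA_real_,
    oob_error = mean(x$oob_error)
  )
}

#' Tidy a cross-validation evaluation
#'
#' @param x A `cv_evaluation`.
#' @param ... Unused.
#' @return The ROC points tibble.
#' @export
tidy.cv_evaluation <- function(x, ...) {
  dplyr::mutate(x$roc$roc_points, feature_set = x$feature_set)
}

#' Run a full prediction experiment
#'
#' Joins the feature table to the outcome labels and evaluates the random
#' forest over the requested predictor subsets, mirroring the trial
#' analysis layout: `all` (baseline + follow-up, 50 predictors),
#' `baseline_only` (18) and `imaging_only` (45). Permutation importance
#' is computed for `importance_set` (default the imaging features, where
#' the SRF-vs-IRF ordering is read off).
#'
#' @param features Wide feature tibble with `eye_id`.
#' @param labels Tibble with `eye_id` and the logical target column.
#' @param target Name of the label column (`"responder"` or
#'   `"extendable"`).
#' @param feature_sets Character vector of predictor subsets.
#' @param rf An [rf_config()].
#' @param k Folds.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for folds/bootstrap/permutations.
#' @param importance_set Feature set on which to compute importances
#'   (`NULL` to skip).
#' @param n_perm Permutations per feature.
#' @return Object of class `te_experiment`: one `cv_evaluation` per
#'   feature set plus the importance ranking.
#' @export
run_experiment <- function(features, labels, target,
                           feature_sets = c("all", "baseline_only", "imaging_only"),
                           rf = rf_config(), k = 10, n_boot = 1000, seed = 1,
                           importance_set = "imaging_only", n_perm = 10) {
  if (!target %in% names(labels)) {
    stop_contract("`labels` has no column `%s`", target)
  }
  orphans <- c(setdiff(features$eye_id, labels$eye_id),
               setdiff(labels$eye_id, features$eye_id))
  if (length(orphans) > 0) {
    stop_contract("features and labels do not join; orphan eye_ids: %s",
                  paste(head(sort(unique(orphans)), 8), collapse = ", "))
  }
  joined <- dplyr::inner_join(features, labels[c("eye_id", target)], by = "eye_id")
  y <- as.logical(joined[[target]])

  evals <- purrr::map(feature_sets, function(fs) {
    cv <- cv_predict(joined, y, rf = rf, k = k, feature_set = fs, seed = seed)
    evaluate_cv(cv, n_boot = n_boot, seed = seed,
                importance = identical(fs, importance_set), n_perm = n_perm)
  })
  names(evals) <- feature_sets

  imp <- purrr::compact(purrr::map(evals, "importances"))
  structure(
    list(target = target, evaluations = evals,
         importances = if (length(imp) > 0) imp[[1]] else NULL,
         n_eyes = nrow(joined), n_pos = sum(y), seed = seed),
    class = "te_experiment"
  )
}

#' @export
print.te_experiment <- function(x, ...) {
  cat(sprintf("<te_experiment> target '%s', %d eyes (%d positive)\n",
              x$target, x$n_eyes, x$n_pos))
  print(glance(x))
  invisible(x)
}

#' Glance at an experiment
#'
#' @param x A `te_experiment`.
#' @param ... Unused.
#' @return One row per feature set.
#' @export
glance.te_experiment <- function(x, ...) {
  purrr::map_dfr(x$evaluations, glance) |>
    dplyr::mutate(target = x$target, .before = 1)
}

#' Mean permutation importance of a biomarker's feature block
#'
#' Averages the permutation importance over every feature whose name
#' starts with the biomarker prefix (all zones and time blocks), used to
#' compare e.g. the SRF block against the IRF block.
#'
#' @param experiment A `te_experiment` with importances.
#' @param biomarker Biomarker prefix, e.g. `"srf"`.
#' @return Mean importance (numeric scalar).
#' @export
block_importance <- function(experiment, biomarker) {
  imp <- experiment$importances
  if (is.null(imp)) stop_contract("experiment carries no importances")
  mean(imp$importance[startsWith(imp$feature, paste0(biomarker, "_"))])
}

#' Plot ROC curves of an experiment
#'
#' @param object A `te_experiment`.
#' @param ... Unused.
#' @return A ggplot of one ROC curve per feature set.
#' @export
autoplot.te_experiment <- function(object, ...) {
  df <- purrr::map_dfr(object$evaluations, tidy)
  labs <- purrr::map_chr(object$evaluations, function(e)
    sprintf("%s (AUC %.2f)", e$feature_set, e$auc))
  df$feature_set <- factor(df$feature_set, names(labs), labs)
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr,
                                   colour = .data$feature_set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  colour = NULL, title = sprintf("Target: %s", object$target)) +
    ggplot2::theme_minimal()
}

#' Bar chart of the top permutation importances
#'
#' @param experiment A `te_experiment` with importances.
#' @param top_n Number of features to show.
#' @return A ggplot.
#' @export
plot_importance <- function(experiment, top_n = 10) {
  imp <- experiment$importances
  if (is.null(imp)) stop_contract("experiment carries no importances")
  df <- head(imp, top_n)
  ggplot2::ggplot(df, ggplot2::aes(.data$importance,
                                   stats::reorder(.data$feature, .data$importance))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Mean decrease in out-of-fold accuracy", y = NULL) +
    ggplot2::theme_minimal()
}
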