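test_that("stratified folds balance sizes and class counts", {
  labels <- rep(c(TRUE, FALSE), each = 50)
  fold <- stratified_kfold(labels, k = 10, seed = 1)
  tab <- table(fold, labels)
  expect_true(all(tab == 5))

  labels228 <- rep(c(TRUE, FALSE), c(120, 108))
  fold228 <- stratified_kfold(labels228, k = 10, seed = 2)
  expect_true(all(table(fold228) %in% c(22, 23)))
  per_class <- table(fold228, labels228)
  expect_true(all(apply(per_class, 2, function(x) diff(range(x))) <= 1))

  expect_identical(fold228, stratified_kfold(labels228, k = 10, seed = 2))
  # permuting the samples leaves the per-class fold counts unchanged
  perm <- sample(length(labels228))
  fold_perm <- stratified_kfold(labels228[perm], k = 10, seed = 2)
  expect_equal(table(fold_perm, labels228[perm]), per_class,
               ignore_attr = TRUE)

  expect_error(stratified_kfold(rep(c(TRUE, FALSE), c(5, 95)), k = 10),
               class = "tepredict_contract_error")
})

test_that("AUC equals all-pairs concordance with ties at one half", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(c(0.6, 0.4, 0.6, 0.4), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.5)

  withr::with_seed(11, {
    for (r in 1:25) {
      n <- sample(10:200, 1)
      probs <- round(runif(n), 2)  # rounded so ties occur
      labels <- runif(n) < 0.5
      if (!any(labels) || all(labels)) next
      got <- roc_auc(probs, labels)
      expect_equal(got$auc, brute_force_auc(probs, labels))
      expect_equal(got$auc, 1 - roc_auc(probs, !labels)$auc)
      expect_true(!is.unsorted(got$roc_points$fpr))
      expect_true(!is.unsorted(got$roc_points$tpr))
    }
  })
  expect_error(roc_auc(c(0.1, 0.2), c(TRUE, TRUE)),
               class = "tepredict_contract_error")
})

test_that("AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(3, {
    probs <- runif(150)
    labels <- runif(150) < 0.4
    ours <- roc_auc(probs, labels)$auc
    theirs <- as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE,
                                             direction = "<")))
    expect_equal(ours, theirs)
  })
})

test_that("bootstrap CIs are percentile-based, ordered and seeded", {
  probs <- c(rep(0.9, 60), rep(0.1, 60))
  labels <- rep(c(TRUE, FALSE), each = 60)
  ci <- bootstrap_auc_ci(probs, labels, n_boot = 200, seed = 1)
  expect_equal(unname(ci), c(1, 1))

  withr::with_seed(5, {
    probs2 <- runif(120); labels2 <- runif(120) < 0.5
  })
  ci2 <- bootstrap_auc_ci(probs2, labels2, n_boot = 300, seed = 2)
  expect_lte(ci2[["lo"]], ci2[["hi"]])
  expect_identical(ci2, bootstrap_auc_ci(probs2, labels2, n_boot = 300, seed = 2))
})

test_that("operating points maximize Youden and honour the 80% specificity floor", {
  perfect <- roc_auc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  op <- operating_points(perfect)
  expect_equal(op$sensitivity[op$point == "youden"], 1)
  expect_equal(op$specificity[op$point == "youden"], 1)

  withr::with_seed(17, {
    probs <- round(runif(60), 2)
    labels <- runif(60) < 0.5
  })
  roc <- roc_auc(probs, labels)
  op2 <- operating_points(roc)
  # brute-force oracle: enumerate every threshold
  thr <- c(Inf, sort(unique(probs), decreasing = TRUE))
  j_best <- max(vapply(thr, function(t) {
    sens <- sum(probs >= t & labels) / sum(labels)
    spec <- 1 - sum(probs >= t & !labels) / sum(!labels)
    sens + spec - 1
  }, numeric(1)))
  got_j <- op2$sensitivity[op2$point == "youden"] +
    op2$specificity[op2$point == "youden"] - 1
  expect_equal(got_j, j_best)
  expect_gte(op2$specificity[op2$point == "spec80"], 0.80)
  expect_lte(op2$sensitivity[op2$point == "spec80"], max(roc$roc_points$sensitivity))
})

test_that("cross-validation predicts each sample out-of-fold exactly once", {
  withr::with_seed(2, {
    n <- 120
    y <- rep(c(TRUE, FALSE), each = n / 2)
    ft <- tibble::tibble(eye_id = sprintf("e%03d", 1:n))
    for (nm in feature_names()) ft[[nm]] <- rnorm(n)
    ft$irf_central_m1 <- as.numeric(y)  # perfectly separating feature
  })
  cv <- cv_predict(ft, y, rf = rf_config(n_trees = 150, seed = 4), k = 5,
                   feature_set = "all", seed = 3)
  expect_equal(nrow(cv$predictions), n)
  expect_equal(sort(cv$predictions$eye_id), sort(ft$eye_id))
  expect_equal(mean((cv$predictions$prob >= 0.5) == cv$predictions$label), 1)
  expect_true(all(cv$predictions$prob >= 0 & cv$predictions$prob <= 1))
  expect_length(cv$oob_error, 5)

  ft_bad <- ft; ft_bad$age[3] <- NA
  expect_error(cv_predict(ft_bad, y, rf_config(n_trees = 50), k = 5),
               class = "tepredict_missing_data_error")
})

test_that("permuted labels yield chance-level AUC", {
  withr::with_seed(8, {
    n <- 200
    ft <- tibble::tibble(eye_id = sprintf("e%03d", 1:n))
    for (nm in feature_names()) ft[[nm]] <- rnorm(n)
    y <- sample(rep(c(TRUE, FALSE), each = n / 2))
  })
  cv <- cv_predict(ft, y, rf = rf_config(n_trees = 200, seed = 1), k = 10,
                   seed = 5)
  auc <- roc_auc(cv$predictions$prob, cv$predictions$label)$auc
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.6)
})

test_that("permutation importance isolates the informative feature", {
  withr::with_seed(13, {
    n <- 500
    ft <- tibble::tibble(eye_id = sprintf("e%03d", 1:n))
    for (nm in feature_names()) ft[[nm]] <- rnorm(n)
    y <- rep(c(TRUE, FALSE), each = n / 2)
    ft$srf_central_m1 <- as.numeric(y) + rnorm(n, 0, 0.1)
  })
  cv <- cv_predict(ft, y, rf = rf_config(n_trees = 100, seed = 2), k = 5,
                   seed = 7)
  imp <- permutation_importance(cv, n_perm = 5, seed = 9)
  expect_equal(imp$feature[1], "srf_central_m1")
  noise <- imp$importance[imp$feature == "age"]
  expect_lt(abs(noise), 0.02)
  expect_identical(imp, permutation_importance(cv, n_perm = 5, seed = 9))
})

test_that("experiments evaluate every requested feature subset", {
  withr::with_seed(21, {
    n <- 80
    ft <- tibble::tibble(eye_id = sprintf("e%03d", 1:n))
    for (nm in feature_names()) ft[[nm]] <- rnorm(n)
    y <- rep(c(TRUE, FALSE), each = n / 2)
    ft$irf_central_change <- as.numeric(y) + rnorm(n, 0, 0.3)
  })
  labels <- tibble::tibble(eye_id = ft$eye_id, responder = y)
  ex <- run_experiment(ft, labels, "responder",
                       feature_sets = c("all", "baseline_only"),
                       rf = rf_config(n_trees = 100, seed = 1), k = 5,
                       n_boot = 50, seed = 2, importance_set = NULL)
  expect_length(ex$evaluations, 2)
  expect_named(ex$evaluations, c("all", "baseline_only"))
  gl <- glance(ex)
  expect_equal(nrow(gl), 2)
  expect_true(all(gl$auc >= 0 & gl$auc <= 1))
  expect_s3_class(autoplot(ex), "ggplot")

  bad_labels <- labels[-(1:3), ]
  expect_error(run_experiment(ft, bad_labels, "responder"),
               class = "tepredict_contract_error")
})
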