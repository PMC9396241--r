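test_that("single-class fit reduces to the generalized least squares oracle", {
  dat <- balanced_bcva_data(matrix(c(55, 1.2, -0.05), 1), 20, seed = 42)
  fit <- fit_lcmm(dat, lcmm_spec(k_classes = 1, seed = 5))
  # balanced design with an intercept: GLS coincides with pooled OLS
  oracle <- unname(coef(lm(bcva ~ month + I(month^2), data = dat)))
  expect_lt(max(abs(fit$class_coeffs[1, ] - oracle) / abs(oracle)), 1e-6)
  expect_true(fit$converged)
})

test_that("fit agrees with an independent mixed-model ML fit", {
  skip_if_not_installed("lme4")
  dat <- balanced_bcva_data(matrix(c(60, 0.8, -0.03), 1), 30, seed = 9)
  fit <- fit_lcmm(dat, lcmm_spec(k_classes = 1, seed = 2))
  ml <- lme4::lmer(bcva ~ month + I(month^2) + (1 | eye_id), data = dat,
                   REML = FALSE)
  expect_equal(unname(fit$class_coeffs[1, ]), unname(lme4::fixef(ml)),
               tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ml)), tolerance = 1e-5)
  expect_equal(fit$sigma2, stats::sigma(ml)^2, tolerance = 1e-2)
  expect_equal(fit$tau2,
               as.numeric(lme4::VarCorr(ml)$eye_id), tolerance = 1e-2)
})

test_that("the EM log-likelihood is monotone non-decreasing on any input", {
  betas <- rbind(c(65, 1, -0.04), c(45, -0.3, 0.01), c(55, 2, -0.08))
  for (seed in c(1, 2, 3)) {
    dat <- balanced_bcva_data(betas, c(30, 25, 20), seed = seed)
    fit <- fit_lcmm(dat, lcmm_spec(k_classes = 3, n_starts = 3, seed = seed,
                                   max_iter = 100))
    expect_true(all(diff(fit$loglik_trace) >= -1e-7 * abs(fit$loglik)))
    expect_equal(sum(fit$class_proportions), 1, tolerance = 1e-8)
    expect_equal(rowSums(fit$posterior), rep(1, fit$n_eyes), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_gt(fit$sigma2, 0)
  }
})

test_that("well-separated two-class cohorts are recovered almost perfectly", {
  betas <- rbind(c(70, -0.5, 0.01), c(40, 2.0, -0.06))
  dat <- balanced_bcva_data(betas, c(135, 135), sigma_b = 3, sigma_e = 2.5,
                            seed = 7)
  fit <- fit_lcmm(dat, lcmm_spec(k_classes = 2, n_starts = 5, seed = 3))
  truth <- dat |> dplyr::distinct(eye_id, true_class)
  agree <- posterior_assign(fit) |>
    dplyr::inner_join(truth, by = "eye_id") |>
    dplyr::summarise(a = mean(latent_class == true_class)) |>
    dplyr::pull(a)
  expect_gte(max(agree, 1 - agree), 0.95)
})

test_that("parameters of a six-class model are recovered across replicates", {
  # well-separated six-class design at the fitter's own noise structure
  betas <- rbind(
    c(80, -1.0, 0.02), c(68, 1.5, -0.06), c(55, -0.8, 0.01),
    c(44, 2.2, -0.07), c(30, 0.2, -0.01), c(18, 1.0, -0.03)
  )
  prop_err <- numeric(10)
  se_units <- numeric(10)
  n_per <- c(15, 110, 40, 20, 60, 25)  # two dominant classes
  for (r in 1:10) {
    dat <- balanced_bcva_data(betas, n_per, sigma_b = 2.5, sigma_e = 2.5,
                              seed = 100 + r)
    fit <- fit_lcmm(dat, lcmm_spec(k_classes = 6, n_starts = 6, seed = r))
    # canonical order (b0 descending) matches the construction order
    prop_err[r] <- sqrt(mean((fit$class_proportions - n_per / sum(n_per))^2))
    se <- lcmm_beta_se(fit)
    big <- order(n_per, decreasing = TRUE)[1:2]
    se_units[r] <- max(abs(fit$class_coeffs[big, ] - betas[big, ]) / se[big, ])
  }
  expect_lt(sqrt(mean(prop_err^2)), 0.05)
  # the two largest classes' coefficients sit within ~2 SE of truth on average
  expect_lt(mean(se_units), 2)
})

test_that("noise-free single-class data drives sigma2 to the numerical floor", {
  months <- seq(0, 12, 2)
  dat <- purrr::map_dfr(1:20, function(i) {
    tibble::tibble(eye_id = sprintf("e%02d", i), month = months,
                   bcva = 50 + 1.5 * months - 0.05 * months^2 + i / 10)
  })
  fit <- fit_lcmm(dat, lcmm_spec(k_classes = 1, seed = 1, max_iter = 2000))
  expect_lt(fit$sigma2, 1e-6)
  expect_gte(fit$sigma2, 1e-8)
})

test_that("modal assignment breaks ties toward the lower class index", {
  fit <- structure(list(posterior = matrix(c(0.9, 0.5, 0.1, 0.5), 2, 2,
                                           dimnames = list(c("a", "b"), NULL))),
                   class = "lcmm_fit")
  asg <- posterior_assign(fit)
  expect_equal(asg$latent_class, c(1L, 1L))
  expect_equal(asg$posterior_prob, c(0.9, 0.5))
})

test_that("responder merging thresholds the model-implied 12-month gain", {
  fit <- structure(list(class_coeffs = rbind(
    class1 = c(b0 = 70, b1 = 0, b2 = 0),
    class2 = c(b0 = 60, b1 = 1.5, b2 = -0.05)  # gain 18 - 7.2 = 10.8...
  )), class = "lcmm_fit")
  fit$class_coeffs[2, ] <- c(60, 1.1, -0.04)   # gain 13.2 - 5.76 = 7.44
  mr <- merge_to_responder(fit, threshold = 5)
  expect_false(mr$responder[1])  # zero gain
  expect_true(mr$responder[2])   # gain > threshold
  expect_equal(mr$gain_12m[2], 1.1 * 12 - 0.04 * 144)
  # raising the threshold never creates a responder
  stricter <- merge_to_responder(fit, threshold = 10)
  expect_true(all(!stricter$responder | mr$responder))
})

test_that("the baseline cross-tab reproduces one-decimal percentages", {
  labels <- tibble::tibble(
    responder = rep(c(TRUE, FALSE, TRUE, FALSE), c(173, 16, 15, 66)),
    baseline_bcva = rep(c(60, 65, 40, 35), c(173, 16, 15, 66))
  )
  ct <- crosstab_by_baseline(labels, cut = 50)
  get <- function(b, r) ct$pct[ct$baseline == b & ct$responder == r]
  expect_equal(get("high", TRUE), 64.1)
  expect_equal(get("high", FALSE), 5.9)
  expect_equal(get("low", TRUE), 5.6)
  expect_equal(get("low", FALSE), 24.4)
  expect_lt(abs(sum(ct$pct) - 100), 0.2)

  all_resp <- tibble::tibble(responder = rep(TRUE, 10),
                             baseline_bcva = c(rep(60, 6), rep(40, 4)))
  ct2 <- crosstab_by_baseline(all_resp)
  expect_equal(ct2$n[!ct2$responder], c(0L, 0L))
})

test_that("fits carry tidy, glance and trajectory plots", {
  dat <- balanced_bcva_data(rbind(c(65, 1, -0.04), c(40, 0, 0)), c(30, 30),
                            seed = 4)
  fit <- fit_lcmm(dat, lcmm_spec(k_classes = 2, n_starts = 3, seed = 1))
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_true(all(c("proportion", "b0", "gain_12m") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$k_classes, 2)
  expect_s3_class(autoplot(fit), "ggplot")
})
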