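#' Specify a latent class mixed model
#'
#' Mixture of linear mixed models for longitudinal BCVA: each latent class
#' has its own quadratic fixed-effect trajectory in time (months), all
#' classes share a per-eye random intercept variance `tau2` and a residual
#' variance `sigma2`, and no baseline covariates enter the model. Fitted
#' by EM with multiple k-means-initialized starts.
#'
#' @param k_classes Number of latent classes (default 6).
#' @param max_iter Maximum EM iterations per start.
#' @param tol Convergence tolerance on the relative log-likelihood change.
#' @param n_starts Number of random starts; the best final log-likelihood
#'   wins (ties resolved toward the lowest start seed).
#' @param seed Integer seed for the starts.
#' @return A list of class `lcmm_spec`.
#' @export
lcmm_spec <- function(k_classes = 6, max_iter = 500, tol = 1e-6,
                      n_starts = 10, seed = 1) {
  assert_scalar_number(k_classes, "k_classes", lo = 1)
  assert_scalar_number(max_iter, "max_iter", lo = 1)
  if (!is.numeric(tol) || tol <= 0) stop_config("`tol` must be positive")
  assert_scalar_number(n_starts, "n_starts", lo = 1)
  structure(
    list(k_classes = as.integer(k_classes), max_iter = as.integer(max_iter),
         tol = tol, n_starts = as.integer(n_starts), seed = as.integer(seed)),
    class = "lcmm_spec"
  )
}

VAR_FLOOR <- 1e-8

# Per-eye sufficient statistics for the quadratic mixed model; everything
# the EM needs is linear in these, so they are computed once.
lcmm_suffstats <- function(data) {
  split_idx <- split(seq_len(nrow(data)), data$eye_id)
  ids <- names(split_idx)
  n_eyes <- length(ids)
  nn <- integer(n_eyes); yy <- numeric(n_eyes); sy <- numeric(n_eyes)
  Xy <- matrix(0, 3, n_eyes); X1 <- matrix(0, 3, n_eyes)
  XXf <- matrix(0, 9, n_eyes)
  for (i in seq_len(n_eyes)) {
    idx <- split_idx[[i]]
    t <- data$month[idx]; y <- data$bcva[idx]
    X <- cbind(1, t, t^2)
    nn[i] <- length(y); yy[i] <- sum(y^2); sy[i] <- sum(y)
    Xy[, i] <- crossprod(X, y); X1[, i] <- colSums(X)
    XXf[, i] <- as.vector(crossprod(X))
  }
  list(ids = ids, n = nn, yy = yy, sy = sy, Xy = Xy, X1 = X1, XXf = XXf,
       n_eyes = n_eyes, n_obs = sum(nn))
}

# E-step quantities for all eyes under one class's coefficients,
# vectorized across eyes. Returns the per-eye marginal log-density and the
# conditional random-intercept moments.
lcmm_estep_class <- function(ss, beta, tau2, sigma2) {
  rr <- ss$yy - 2 * colSums(ss$Xy * beta) +
    colSums(ss$XXf * as.vector(outer(beta, beta)))
  zr <- ss$sy - colSums(ss$X1 * beta)      # 1' r
  A <- sigma2 / tau2 + ss$n                # scalar Woodbury factor
  quad <- (rr - zr^2 / A) / sigma2
  logdet <- ss$n * log(sigma2) + log1p(tau2 * ss$n / sigma2)
  ll <- -0.5 * (ss$n * log(2 * pi) + logdet + quad)
  bhat <- zr / A
  vb <- sigma2 / A
  list(ll = ll, bhat = bhat, vb = vb)
}

# Posterior class probabilities for all eyes given the current parameters.
lcmm_posteriors <- function(ss, pi_g, beta, tau2, sigma2) {
  K <- length(pi_g)
  est <- lapply(seq_len(K), function(g)
    lcmm_estep_class(ss, beta[g, ], tau2, sigma2))
  llmat <- matrix(vapply(est, function(e) e$ll, numeric(ss$n_eyes)), ncol = K)
  lw <- sweep(llmat, 2, log(pi_g), `+`)
  m <- apply(lw, 1, max)
  ll <- sum(m + log(rowSums(exp(lw - m))))
  w <- exp(lw - m)
  list(w = w / rowSums(w), loglik = ll, est = est)
}

# Multicycle ECM: (1) E-step and class-coefficient update by
# posterior-weighted generalized least squares (the exact conditional
# maximizer given the variance components), (2) fresh E-step, then
# proportion and variance-component updates from the conditional
# random-intercept moments. Every cycle increases the observed-data
# log-likelihood.
lcmm_em <- function(ss, pi0, beta0, tau2, sigma2, max_iter, tol) {
  K <- length(pi0)
  pi_g <- pi0; beta <- beta0
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  e1 <- NULL

  for (iter in seq_len(max_iter)) {
    e1 <- lcmm_posteriors(ss, pi_g, beta, tau2, sigma2)
    trace <- c(trace, e1$loglik)
    if (is.finite(ll_old) &&
        abs(e1$loglik - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- e1$loglik

    # CM-1: weighted GLS for each class's coefficients. With
    # V^{-1} = (I - sh * J) / sigma2 and sh_i = tau2 / (sigma2 + n_i tau2),
    # the common 1/sigma2 cancels from the normal equations.
    sh <- tau2 / (sigma2 + ss$n * tau2)
    for (g in seq_len(K)) {
      wg <- e1$w[, g]
      A <- matrix(ss$XXf %*% wg, 3, 3) -
        sweep(ss$X1, 2, wg * sh, `*`) %*% t(ss$X1)
      rhs <- ss$Xy %*% wg - ss$X1 %*% (wg * sh * ss$sy)
      beta[g, ] <- as.numeric(solve(A, rhs))
    }

    # CM-2 after a fresh E-step at the new coefficients.
    e2 <- lcmm_posteriors(ss, pi_g, beta, tau2, sigma2)
    w <- e2$w
    pi_g <- colMeans(w)
    bhat <- vapply(e2$est, function(e) e$bhat, numeric(ss$n_eyes))
    vb <- vapply(e2$est, function(e) rep(e$vb, length.out = ss$n_eyes),
                 numeric(ss$n_eyes))
    tau2 <- max(sum(w * (bhat^2 + vb)) / ss$n_eyes, VAR_FLOOR)
    res <- 0
    for (g in seq_len(K)) {
      b <- beta[g, ]
      rr <- ss$yy - 2 * colSums(ss$Xy * b) +
        colSums(ss$XXf * as.vector(outer(b, b)))
      zr <- ss$sy - colSums(ss$X1 * b)
      sq <- rr - 2 * bhat[, g] * zr + ss$n * bhat[, g]^2 + ss$n * vb[, g]
      res <- res + sum(w[, g] * sq)
    }
    sigma2 <- max(res / ss$n_obs, VAR_FLOOR)
  }
  final <- lcmm_posteriors(ss, pi_g, beta, tau2, sigma2)
  list(pi = pi_g, beta = beta, tau2 = tau2, sigma2 = sigma2,
       posterior = final$w, loglik = final$loglik, loglik_trace = trace,
       converged = converged, n_iter = iter)
}

# k-means-initialized start values from per-eye OLS quadratic coefficients.
lcmm_init <- function(data, ss, K, start_seed) {
  coefs <- t(vapply(split(data, data$eye_id), function(df) {
    X <- cbind(1, df$month, df$month^2)
    as.numeric(qr.coef(qr(X), df$bcva))
  }, numeric(3)))
  coefs[!is.finite(coefs)] <- 0
  with_eye_rng(start_seed, {
    if (K == 1L) {
      centers <- matrix(colMeans(coefs), 1, 3)
      sizes <- nrow(coefs)
    } else {
      km <- suppressWarnings(kmeans(coefs, centers = K, nstart = 10))
      centers <- km$centers
      sizes <- tabulate(km$cluster, K)
    }
    # jitter keeps coincident centers apart across restarts
    centers <- centers + rnorm(length(centers), 0, 0.1)
    list(pi = pmax(sizes, 1) / sum(pmax(sizes, 1)), beta = unname(centers))
  })
}

#' Fit a latent class mixed model by EM
#'
#' Fits the mixture of quadratic mixed models of [lcmm_spec()] to
#' longitudinal BCVA series. The E-step computes posterior class
#' probabilities from the Gaussian marginal likelihood with the random
#' intercept integrated out in closed form; the M-step performs
#' posterior-weighted updates of the class proportions, class
#' coefficients and the two variance components. The observed-data
#' log-likelihood is non-decreasing over iterations. Starts whose
#' solution collapses a class (proportion below `1/(10 n)`) are discarded
#' and restarted with the next seed; if every start collapses an error is
#' raised. Classes are reported sorted by intercept `b0` descending.
#'
#' @param data Tibble with columns `eye_id`, `bcva`, and `month` (or
#'   `week`, converted as one month = 4 weeks).
#' @param spec An [lcmm_spec()].
#' @return An object of class `lcmm_fit`.
#' @export
fit_lcmm <- function(data, spec = lcmm_spec()) {
  if (!inherits(spec, "lcmm_spec")) stop_config("`spec` must be an lcmm_spec()")
  if (!"month" %in% names(data)) {
    if (!"week" %in% names(data)) stop_contract("`data` needs a month or week column")
    data$month <- data$week / 4
  }
  if (!all(c("eye_id", "bcva") %in% names(data))) {
    stop_contract("`data` needs eye_id and bcva columns")
  }
  obs_per_eye <- table(data$eye_id)
  if (any(obs_per_eye < 3)) {
    stop_contract("every eye needs at least 3 observations")
  }
  K <- spec$k_classes
  if (length(obs_per_eye) < 5 * K) {
    stop_contract("need at least 5 eyes per class (%d eyes for K = %d)",
                  5 * K, K)
  }

  ss <- lcmm_suffstats(data)
  pooled <- lm(bcva ~ month + I(month^2), data = data)
  s2 <- max(summary(pooled)$sigma^2, 2 * VAR_FLOOR)

  best <- NULL
  for (s in seq_len(spec$n_starts)) {
    init <- lcmm_init(data, ss, K, spec$seed + s - 1L)
    fit <- lcmm_em(ss, init$pi, init$beta, tau2 = s2 / 2, sigma2 = s2 / 2,
                   max_iter = spec$max_iter, tol = spec$tol)
    if (any(fit$pi < 1 / (10 * ss$n_eyes))) next  # collapsed class: restart
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
    if (K == 1L) break
  }
  if (is.null(best)) {
    rlang::abort("all EM starts collapsed a latent class; increase n_starts or reduce k_classes",
                 class = "tepredict_fit_error")
  }
  if (!best$converged) {
    rlang::warn("EM did not converge within max_iter; returning best fit with converged = FALSE")
  }

  ord <- order(best$beta[, 1], decreasing = TRUE)
  beta <- best$beta[ord, , drop = FALSE]
  dimnames(beta) <- list(paste0("class", seq_len(K)), c("b0", "b1", "b2"))
  posterior <- best$posterior[, ord, drop = FALSE]
  dimnames(posterior) <- list(ss$ids, paste0("class", seq_len(K)))
  n_par <- (K - 1) + 3 * K + 2

  structure(
    list(
      class_proportions = best$pi[ord], class_coeffs = beta,
      tau2 = best$tau2, sigma2 = best$sigma2,
      posterior = posterior,
      loglik = best$loglik, loglik_trace = best$loglik_trace,
      converged = best$converged, n_iter = best$n_iter,
      n_eyes = ss$n_eyes, n_obs = ss$n_obs, n_par = n_par,
      bic = -2 * best$loglik + n_par * log(ss$n_eyes),
      spec = spec, suffstats = ss
    ),
    class = "lcmm_fit"
  )
}

#' Wald standard errors of the class coefficients
#'
#' Posterior-weighted generalized-least-squares information
#' `sum_i w_ig X_i' V_i^{-1} X_i` inverted per class; an SE-equivalent
#' used by parameter-recovery checks.
#'
#' @param fit An `lcmm_fit`.
#' @return K x 3 matrix of standard errors.
#' @export
lcmm_beta_se <- function(fit) {
  ss <- fit$suffstats
  K <- length(fit$class_proportions)
  se <- matrix(NA_real_, K, 3, dimnames = dimnames(fit$class_coeffs))
  shrink <- fit$tau2 / (fit$sigma2 + ss$n * fit$tau2)
  for (g in seq_len(K)) {
    info <- matrix(0, 3, 3)
    w <- fit$posterior[, g]
    XX <- matrix(ss$XXf %*% w, 3, 3)
    X1w <- sweep(ss$X1, 2, sqrt(w * shrink), `*`)
    info <- (XX - X1w %*% t(X1w)) / fit$sigma2
    se[g, ] <- sqrt(diag(solve(info)))
  }
  se
}

#' Modal class assignment
#'
#' Argmax over each eye's posterior row, ties broken toward the lower
#' class index.
#'
#' @param fit An `lcmm_fit`.
#' @return Tibble `(eye_id, latent_class, posterior_prob)`.
#' @export
posterior_assign <- function(fit) {
  cls <- max.col(fit$posterior, ties.method = "first")
  tibble::tibble(
    eye_id = rownames(fit$posterior),
    latent_class = cls,
    posterior_prob = fit$posterior[cbind(seq_along(cls), cls)]
  )
}

#' Merge latent classes into responder / non-responder
#'
#' A class is a responder class iff its model-implied BCVA gain from
#' baseline to month 12, `b1 * 12 + b2 * 144`, is at least `threshold`
#' letters (default +5).
#'
#' @param fit An `lcmm_fit`.
#' @param threshold Letters gained by month 12.
#' @return Tibble `(latent_class, gain_12m, responder)` covering all
#'   classes.
#' @export
merge_to_responder <- function(fit, threshold = 5) {
  gain <- fit$class_coeffs[, "b1"] * 12 + fit$class_coeffs[, "b2"] * 144
  tibble::tibble(
    latent_class = seq_along(gain),
    gain_12m = unname(gain),
    responder = unname(gain >= threshold)
  )
}

#' Responder cross-tabulation by baseline visual acuity
#'
#' Stratifies eyes into high (`>= cut`) and low (`< cut`) baseline BCVA
#' and cross-tabulates against responder status, reporting counts and
#' percentages of the total rounded to one decimal.
#'
#' @param labels Tibble with logical `responder` and numeric
#'   `baseline_bcva` per eye.
#' @param cut Baseline BCVA cut in letters (default 50).
#' @return Tibble `(baseline, responder, n, pct)` with four rows.
#' @export
crosstab_by_baseline <- function(labels, cut = 50) {
  if (!all(c("responder", "baseline_bcva") %in% names(labels))) {
    stop_contract("`labels` needs responder and baseline_bcva columns")
  }
  total <- nrow(labels)
  grid <- tidyr::expand_grid(
    baseline = c("high", "low"),
    responder = c(TRUE, FALSE)
  )
  counts <- labels |>
    dplyr::mutate(baseline = ifelse(.data$baseline_bcva >= cut, "high", "low")) |>
    dplyr::count(.data$baseline, .data$responder)
  grid |>
    dplyr::left_join(counts, by = c("baseline", "responder")) |>
    dplyr::mutate(
      n = tidyr::replace_na(.data$n, 0L),
      pct = round(100 * .data$n / total, 1)
    )
}
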