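#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @export
print.lcmm_fit <- function(x, ...) {
  K <- length(x$class_proportions)
  cat(sprintf("<lcmm_fit> %d latent classes, %d eyes, %d observations\n",
              K, x$n_eyes, x$n_obs))
  cat(sprintf("  log-likelihood %.2f (BIC %.1f), %s in %d iterations\n",
              x$loglik, x$bic,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat(sprintf("  sigma2 %.3f, tau2 %.3f\n", x$sigma2, x$tau2))
  print(round(cbind(pi = x$class_proportions, x$class_coeffs), 3))
  invisible(x)
}

#' Tidy a latent class mixed model fit
#'
#' One row per class with its mixture proportion, quadratic coefficients
#' and the model-implied 12-month BCVA gain.
#'
#' @param x An `lcmm_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lcmm_fit <- function(x, ...) {
  tibble::tibble(
    latent_class = seq_along(x$class_proportions),
    proportion = x$class_proportions,
    b0 = x$class_coeffs[, "b0"],
    b1 = x$class_coeffs[, "b1"],
    b2 = x$class_coeffs[, "b2"],
    gain_12m = x$class_coeffs[, "b1"] * 12 + x$class_coeffs[, "b2"] * 144
  )
}

#' Glance at a latent class mixed model fit
#'
#' @param x An `lcmm_fit`.
#' @param ... Unused.
#' @return A one-row tibble with fit statistics.
#' @export
glance.lcmm_fit <- function(x, ...) {
  tibble::tibble(
    k_classes = length(x$class_proportions),
    n_eyes = x$n_eyes, n_obs = x$n_obs,
    logLik = x$loglik, BIC = x$bic,
    sigma2 = x$sigma2, tau2 = x$tau2,
    converged = x$converged, n_iter = x$n_iter
  )
}

#' Plot latent-class mean BCVA trajectories
#'
#' Mean model-implied trajectory of each latent class over the follow-up,
#' line width proportional to class prevalence.
#'
#' @param object An `lcmm_fit`.
#' @param months Time grid in months.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lcmm_fit <- function(object, months = seq(0, 13, by = 0.25), ...) {
  td <- tidy(object)
  df <- purrr::map_dfr(seq_len(nrow(td)), function(g) {
    tibble::tibble(
      latent_class = td$latent_class[g],
      proportion = td$proportion[g],
      month = months,
      bcva = td$b0[g] + td$b1[g] * months + td$b2[g] * months^2
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$month, .data$bcva,
                                   colour = factor(.data$latent_class),
                                   linewidth = .data$proportion)) +
    ggplot2::geom_line() +
    ggplot2::scale_linewidth(range = c(0.4, 1.6), guide = "none") +
    ggplot2::labs(x = "Month", y = "BCVA (letters)", colour = "Latent class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
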