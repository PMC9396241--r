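#' Simulate BCVA trajectories
#'
#' Evaluates each eye's latent quadratic trajectory
#' `bcva(t) = b0 + b1 * t + b2 * t^2 + random_intercept + noise` at the
#' requested visit weeks (time in months, one month = 4 weeks), truncating
#' to the 0-100 ETDRS letter range. Measurement noise is drawn from a
#' per-eye random stream derived from `(seed, eye_id)`.
#'
#' @param eyes Eye tibble from [generate_cohort()].
#' @param visit_weeks Numeric vector of visit weeks in `[0, horizon]`.
#' @param config Optional [cohort_config()] supplying `sigma_noise` and
#'   `seed` defaults.
#' @param sigma_noise Measurement noise SD in letters (overrides config).
#' @param seed Integer stream seed (overrides config).
#' @param use_outcome_state If `TRUE`, evaluate the outcome-driving
#'   (`out_*`) trajectory coefficients instead of the feature-side ones;
#'   the two coincide unless the cohort was generated with
#'   `coupling = FALSE`.
#' @return A tibble `(eye_id, week, month, bcva)` in long format.
#' @export
simulate_bcva <- function(eyes, visit_weeks, config = NULL,
                          sigma_noise = NULL, seed = NULL,
                          use_outcome_state = FALSE) {
  sigma_noise <- sigma_noise %||% config$sigma_noise %||% 3
  seed <- seed %||% config$seed %||% 1L
  if (any(visit_weeks < 0)) {
    stop_contract("`visit_weeks` must be non-negative")
  }
  pre <- if (use_outcome_state) "out_" else ""
  col <- function(nm) eyes[[paste0(pre, nm)]]
  months <- visit_weeks / 4

  purrr::map_dfr(seq_len(nrow(eyes)), function(i) {
    noise <- if (sigma_noise > 0) {
      with_eye_rng(eye_seed(seed, paste0(eyes$eye_id[i], ":bcva")),
                   rnorm(length(months), 0, sigma_noise))
    } else {
      numeric(length(months))
    }
    y <- col("b0")[i] + col("b1")[i] * months + col("b2")[i] * months^2 +
      col("random_intercept")[i] + noise
    tibble::tibble(
      eye_id = eyes$eye_id[i],
      week = visit_weeks,
      month = months,
      bcva = pmin(pmax(y, 0), 100)
    )
  })
}
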