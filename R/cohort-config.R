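#' Default latent-class BCVA trajectory coefficients
#'
#' Six latent classes of best-corrected visual acuity (BCVA) trajectories,
#' quadratic in time (letters as a function of months, one month = 4 weeks):
#' `bcva(t) = b0 + b1 * t + b2 * t^2`. The default classes form a 2x2
#' responder/non-responder by high/low baseline structure plus two small
#' declining classes, with class weights matching the composition of a
#' treat-and-extend trial arm of 270 eyes (class sizes 4, 173, 58, 12, 15, 8).
#' Classes 2 and 5 are responders (model-implied 12-month gain of at least
#' +5 letters); the others are not.
#'
#' @return A 6 x 3 numeric matrix with columns `b0`, `b1`, `b2`.
#' @export
default_class_coeffs <- function() {
  m <- rbind(
    c(72, -1.0,  0.030), # high baseline, declining
    c(62,  1.5, -0.070), # high baseline, responder (largest class)
    c(42,  0.3, -0.020), # low baseline, flat
    c(67,  0.0, -0.010), # high baseline, flat
    c(38,  2.2, -0.080), # low baseline, responder
    c(34, -0.5,  0.010)  # low baseline, declining
  )
  dimnames(m) <- list(paste0("class", 1:6), c("b0", "b1", "b2"))
  m
}

#' Default latent-class proportions
#'
#' Class weights 4/270, 173/270, 58/270, 12/270, 15/270, 8/270, mirroring the
#' latent-class sizes of a 270-eye treat-and-extend cohort.
#'
#' @return A numeric simplex vector of length 6.
#' @export
default_class_proportions <- function() {
  c(4, 173, 58, 12, 15, 8) / 270
}

default_zone_shares <- function() {
  # Fraction of each biomarker's volume located in the central 1 mm disc,
  # the 1-3 mm parafoveal ring and the 3-6 mm perifoveal ring. IRF is
  # fovea-dominant; SRF sits predominantly outside the central millimetre.
  m <- rbind(
    irf = c(0.45, 0.40, 0.15),
    srf = c(0.15, 0.45, 0.40),
    ped = c(0.25, 0.45, 0.30),
    hrf = c(0.20, 0.45, 0.35)
  )
  colnames(m) <- zones_all()
  m
}

#' Configure a synthetic treat-and-extend cohort
#'
#' Bundles every knob of the synthetic cohort generator: cohort size, latent
#' BCVA class structure, fluid kinetics priors, scanner mix, attrition
#' counts and the feature/label coupling switch. Defaults emulate the
#' treat-and-extend arm of a 52-week anti-VEGF trial: 270 treatment-naive
#' eyes, six latent BCVA classes, a 65/35 split between a 49 x 768 and a
#' 128 x 512 en-face grid, and attrition of 10 (missing baseline/follow-up
#' scan) + 22 (lost to follow-up) + 5 (bad scan quality) + 5 (protocol
#' deviation) eyes, leaving 228 evaluable.
#'
#' @param n_eyes Number of eyes.
#' @param k_classes Number of latent BCVA classes.
#' @param class_proportions Simplex vector of length `k_classes`.
#' @param class_coeffs `k_classes` x 3 matrix of quadratic trajectory
#'   coefficients (letters vs. months).
#' @param sigma_intercept SD (letters) of the per-eye random intercept.
#' @param sigma_noise SD (letters) of per-visit BCVA measurement noise.
#' @param scanner_mix Named proportions over `grid_49x768` and
#'   `grid_128x512`.
#' @param seed Integer seed; the cohort is bit-reproducible given the seed.
#' @param horizon_weeks Follow-up horizon in weeks.
#' @param coupling If `TRUE` (default) the latent state that drives maps and
#'   early BCVA also drives the treatment course and outcome trajectories,
#'   so imaging features are genuinely predictive. If `FALSE` the
#'   outcome-driving state is a seeded permutation of the eye states,
#'   making outcome labels independent of the features (a null control).
#' @param attrition Named integer counts of eyes affected by, in order,
#'   `missing_scan`, `lost_followup`, `bad_quality`, `protocol_deviation`.
#' @param activity_thresholds Named nl thresholds (`irf`, `srf`) above which
#'   fluid counts as disease activity.
#' @param recurrence_frac Fraction of an eye's baseline fluid volume added
#'   by one recurrence event.
#' @param ped_floor_frac PED never drops below this fraction of its
#'   baseline (PED responds partially and persists).
#' @param zone_shares 4 x 3 matrix of per-biomarker zonal volume shares.
#'
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_eyes = 270,
                          k_classes = 6,
                          class_proportions = default_class_proportions(),
                          class_coeffs = default_class_coeffs(),
                          sigma_intercept = 5,
                          sigma_noise = 3,
                          scanner_mix = c(grid_49x768 = 0.65, grid_128x512 = 0.35),
                          seed = 1,
                          horizon_weeks = 52,
                          coupling = TRUE,
                          attrition = c(missing_scan = 10, lost_followup = 22,
                                        bad_quality = 5, protocol_deviation = 5),
                          activity_thresholds = c(irf = 1, srf = 1),
                          recurrence_frac = 0.18,
                          ped_floor_frac = 0.35,
                          zone_shares = default_zone_shares()) {
  assert_scalar_number(n_eyes, "n_eyes", lo = 2)
  assert_scalar_number(k_classes, "k_classes", lo = 1)
  assert_scalar_number(seed, "seed")
  assert_scalar_number(horizon_weeks, "horizon_weeks", lo = 4)
  assert_scalar_number(sigma_intercept, "sigma_intercept", lo = 0)
  assert_scalar_number(sigma_noise, "sigma_noise", lo = 0)
  assert_scalar_number(recurrence_frac, "recurrence_frac", lo = 0, hi = 1)
  assert_scalar_number(ped_floor_frac, "ped_floor_frac", lo = 0, hi = 1)

  if (length(class_proportions) != k_classes || any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-9) {
    stop_config("`class_proportions` must be a length-%d simplex (sum 1 within 1e-9)",
                k_classes)
  }
  if (!is.matrix(class_coeffs) || nrow(class_coeffs) != k_classes ||
      ncol(class_coeffs) != 3 || any(!is.finite(class_coeffs))) {
    stop_config("`class_coeffs` must be a finite %d x 3 matrix", k_classes)
  }
  if (n_eyes < 2 * k_classes) {
    stop_config("`n_eyes` must be at least 2 * k_classes")
  }
  if (!setequal(names(scanner_mix), c("grid_49x768", "grid_128x512")) ||
      any(scanner_mix < 0) || abs(sum(scanner_mix) - 1) > 1e-9) {
    stop_config("`scanner_mix` must be proportions over grid_49x768 and grid_128x512")
  }
  need <- c("missing_scan", "lost_followup", "bad_quality", "protocol_deviation")
  if (!all(need %in% names(attrition)) || any(attrition < 0)) {
    stop_config("`attrition` must have non-negative counts named %s",
                paste(need, collapse = ", "))
  }
  attrition <- attrition[need]
  if (sum(attrition) >= n_eyes) {
    stop_config("attrition counts must leave at least one evaluable eye")
  }
  if (any(activity_thresholds[c("irf", "srf")] < 0) ||
      any(is.na(activity_thresholds[c("irf", "srf")]))) {
    stop_config("`activity_thresholds` must give non-negative irf and srf values")
  }

  structure(
    list(
      n_eyes = as.integer(n_eyes), k_classes = as.integer(k_classes),
      class_proportions = as.numeric(class_proportions),
      class_coeffs = class_coeffs,
      sigma_intercept = sigma_intercept, sigma_noise = sigma_noise,
      scanner_mix = scanner_mix, seed = as.integer(seed),
      horizon_weeks = as.integer(horizon_weeks), coupling = isTRUE(coupling),
      attrition = as.integer(attrition) |> setNames(need),
      activity_thresholds = activity_thresholds,
      recurrence_frac = recurrence_frac, ped_floor_frac = ped_floor_frac,
      zone_shares = zone_shares
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d eyes, %d latent classes, %d-week horizon, seed %d\n",
              x$n_eyes, x$k_classes, x$horizon_weeks, x$seed))
  cat(sprintf("  coupling %s; attrition %s\n",
              if (x$coupling) "on" else "off (null control)",
              paste(names(x$attrition), x$attrition, sep = "=", collapse = ", ")))
  invisible(x)
}

# Model-implied BCVA gain from baseline to month 12 for each class.
implied_gain_12m <- function(class_coeffs) {
  class_coeffs[, 2] * 12 + class_coeffs[, 3] * 144
}
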