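# Shared fixtures: everything is generated in code at test time.

no_attrition <- c(missing_scan = 0, lost_followup = 0, bad_quality = 0,
                  protocol_deviation = 0)

small_config <- function(n = 24, seed = 101, ...) {
  cohort_config(n_eyes = n, seed = seed, attrition = no_attrition, ...)
}

# A fully specified one-row eye state with controllable kinetics, the
# outcome-side columns mirroring the feature-side ones.
toy_eye <- function(eye_id = "toy01", b = c(60, 0, 0), random_intercept = 0,
                    baseline = c(irf = 200, srf = 150, ped = 250, hrf = 10),
                    retention = c(irf = 0.2, srf = 0.4, ped = 0.9, hrf = 0.5),
                    hazard = 0, pr_0 = 32, age = 75, sex = "female",
                    latent_class = 1L, scanner = "grid_128x512") {
  eye <- tibble::tibble(
    eye_id = eye_id, scanner = scanner, attrition = "none",
    latent_class = latent_class, response_type = "intermediate",
    sex = sex, b0 = b[1], b1 = b[2], b2 = b[3],
    random_intercept = random_intercept,
    baseline_bcva = min(max(b[1] + random_intercept, 0), 100),
    age = age,
    irf_0 = baseline[["irf"]], srf_0 = baseline[["srf"]],
    ped_0 = baseline[["ped"]], hrf_0 = baseline[["hrf"]], pr_0 = pr_0,
    ret_irf = retention[["irf"]], ret_srf = retention[["srf"]],
    ret_ped = retention[["ped"]], ret_hrf = retention[["hrf"]],
    hazard = hazard
  )
  out_cols <- c("latent_class", "response_type", "b0", "b1", "b2",
                "random_intercept", "irf_0", "srf_0", "ped_0", "hrf_0",
                "ret_irf", "ret_srf", "ret_ped", "ret_hrf", "hazard")
  for (nm in out_cols) eye[[paste0("out_", nm)]] <- eye[[nm]]
  eye
}

# Independent brute-force oracle for the ETDRS zone geometry: plain loops
# over pixel centers, no shared code with the implementation.
brute_force_masks <- function(rows, cols, extent = c(6, 6)) {
  central <- para <- peri <- matrix(FALSE, rows, cols)
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      cy <- (i - 0.5) * extent[1] / rows - extent[1] / 2
      cx <- (j - 0.5) * extent[2] / cols - extent[2] / 2
      d <- sqrt(cx^2 + cy^2)
      if (d < 0.5) central[i, j] <- TRUE
      else if (d < 1.5) para[i, j] <- TRUE
      else if (d < 3.0) peri[i, j] <- TRUE
    }
  }
  list(central = central, para = para, peri = peri)
}

# All-pairs Mann-Whitney concordance, ties at one half.
brute_force_auc <- function(probs, labels) {
  pos <- probs[as.logical(labels)]
  neg <- probs[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Balanced longitudinal fixture around known class quadratics.
balanced_bcva_data <- function(betas, n_per_class, months = seq(0, 12, 2),
                               sigma_b = 3, sigma_e = 2.5, seed = 1) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(betas)), function(g) {
      purrr::map_dfr(seq_len(n_per_class[g]), function(i) {
        b <- rnorm(1, 0, sigma_b)
        tibble::tibble(
          eye_id = sprintf("c%d_%03d", g, i),
          true_class = g,
          month = months,
          bcva = betas[g, 1] + betas[g, 2] * months + betas[g, 3] * months^2 +
            b + rnorm(length(months), 0, sigma_e)
        )
      })
    })
  })
}
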