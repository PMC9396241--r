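test_that("cohort generation honours size, mixture and determinism", {
  cc <- small_config(n = 40, seed = 7)
  eyes <- generate_cohort(cc)
  expect_equal(nrow(eyes), 40)
  expect_identical(eyes, generate_cohort(cc))

  degenerate <- small_config(
    n = 20, seed = 3, k_classes = 6,
    class_proportions = c(1, 0, 0, 0, 0, 0)
  )
  expect_true(all(generate_cohort(degenerate)$latent_class == 1))

  expect_error(
    cohort_config(n_eyes = 50, class_proportions = c(0.5, 0.4)),
    class = "tepredict_config_error"
  )
  expect_error(
    cohort_config(n_eyes = 8, k_classes = 6),
    class = "tepredict_config_error"
  )
})

test_that("empirical class frequencies satisfy the binomial sampling bound", {
  n <- 10000
  cc <- small_config(n = n, seed = 4)
  eyes <- generate_cohort(cc)
  p <- cc$class_proportions
  emp <- as.numeric(table(factor(eyes$latent_class, seq_along(p)))) / n
  expect_true(all(abs(emp - p) <= 3 * sqrt(p * (1 - p) / n)))
})

test_that("retention factors are ordered IRF <= SRF <= PED with valid ranges", {
  eyes <- generate_cohort(small_config(n = 500, seed = 12))
  expect_true(all(eyes$ret_irf <= eyes$ret_srf))
  expect_true(all(eyes$ret_srf <= eyes$ret_ped))
  ret <- as.matrix(eyes[c("ret_irf", "ret_srf", "ret_ped", "ret_hrf")])
  expect_true(all(ret >= 0 & ret <= 1))
  expect_true(all(eyes[c("irf_0", "srf_0", "ped_0", "hrf_0")] >= 0))
  expect_true(all(is.finite(as.matrix(eyes[c("b0", "b1", "b2")]))))
})

test_that("BCVA simulation evaluates the latent quadratic and truncates", {
  eye <- toy_eye(b = c(60, 0, 0))
  const <- simulate_bcva(eye, c(0, 4, 24, 48), sigma_noise = 0, seed = 1)
  expect_equal(const$bcva, rep(60, 4))

  eye2 <- toy_eye(b = c(50, 2, -0.1))
  at12 <- simulate_bcva(eye2, 48, sigma_noise = 0, seed = 1)  # month 12
  expect_equal(at12$bcva, 50 + 24 - 14.4)

  high <- toy_eye(b = c(98, 2, 0))
  capped <- simulate_bcva(high, c(0, 24, 48), sigma_noise = 4, seed = 2)
  expect_true(all(capped$bcva >= 0 & capped$bcva <= 100))
})

test_that("per-visit BCVA sample means track the class quadratic", {
  b <- c(55, 1.5, -0.05)
  eyes <- purrr::map_dfr(1:400, function(i) {
    e <- toy_eye(eye_id = sprintf("mc%03d", i), b = b)
    e$random_intercept <- 0
    e
  })
  weeks <- c(0, 16, 48)
  sim <- simulate_bcva(eyes, weeks, sigma_noise = 3, seed = 5)
  for (w in weeks) {
    t <- w / 4
    truth <- b[1] + b[2] * t + b[3] * t^2
    obs <- sim$bcva[sim$week == w]
    # 4 SE keeps the familywise false-failure rate negligible across the
    # three visits while still catching any systematic bias
    expect_lt(abs(mean(obs) - truth), 4 * 3 / sqrt(length(obs)))
  }
})

test_that("fluid kinetics follow exponential per-injection decay", {
  cc <- small_config(n = 12, seed = 1)
  eye <- toy_eye(baseline = c(irf = 200, srf = 150, ped = 250, hrf = 10),
                 retention = c(irf = 0.2, srf = 0.4, ped = 0.9, hrf = 0.5),
                 hazard = 0)
  fc <- simulate_fluid_course(eye, c(0, 4, 8), c(TRUE, TRUE, TRUE), cc)
  expect_equal(fc$irf, c(200, 40, 8))

  zero_ret <- toy_eye(retention = c(irf = 0, srf = 0.4, ped = 0.9, hrf = 0.5),
                      hazard = 0)
  fc0 <- simulate_fluid_course(zero_ret, c(0, 4, 8, 12), rep(TRUE, 4), cc)
  expect_equal(fc0$irf, c(200, 0, 0, 0))

  still <- simulate_fluid_course(eye, c(0, 6, 20), rep(FALSE, 3), cc)
  expect_true(all(still$irf == 200 & still$srf == 150))

  expect_error(simulate_fluid_course(eye, c(0, 4), c(TRUE), cc),
               class = "tepredict_contract_error")
})

test_that("PED keeps a strictly positive floor and volumes stay non-negative", {
  cc <- small_config(n = 12, seed = 1)
  eye <- toy_eye(retention = c(irf = 0.1, srf = 0.2, ped = 0.3, hrf = 0.5),
                 hazard = 0)
  fc <- simulate_fluid_course(eye, seq(0, 40, 4), rep(TRUE, 11), cc)
  expect_true(all(fc$ped >= cc$ped_floor_frac * eye$ped_0 - 1e-9))
  expect_true(all(fc[c("irf", "srf", "ped", "hrf")] >= 0))
})

test_that("post-injection fractional reduction orders IRF >= SRF >= PED cohort-wide", {
  cc <- small_config(n = 500, seed = 21)
  eyes <- generate_cohort(cc)
  fc <- simulate_fluid_course(eyes, c(0, 4), c(TRUE, TRUE), cc)
  red <- fc |>
    dplyr::group_by(eye_id) |>
    dplyr::summarise(dplyr::across(c(irf, srf, ped), function(v) {
      if (v[1] > 0) 1 - v[2] / v[1] else NA_real_
    }), .groups = "drop")
  expect_gte(mean(red$irf, na.rm = TRUE), mean(red$srf, na.rm = TRUE))
  expect_gte(mean(red$srf, na.rm = TRUE), mean(red$ped, na.rm = TRUE))
})

test_that("rendered maps round-trip their zonal volume targets", {
  cc <- small_config(n = 12, seed = 2)
  eye <- generate_cohort(cc)[1, ]
  vols <- list(irf = 120, srf = 180, ped = 260, hrf = 12)

  for (grid in c("grid_49x768", "grid_128x512")) {
    ms <- render_maps(eye, vols, "M0", grid, cc)
    dims <- c(ms$grid_rows, ms$grid_cols)
    masks <- etdrs_zone_masks(dims[1], dims[2])
    px <- 36 / prod(dims)
    for (bm in c("irf", "srf", "ped", "hrf")) {
      target <- vols[[bm]] * cc$zone_shares[bm, ]
      got <- vapply(masks, function(m) zonal_volume(ms$maps[[bm]], m, px),
                    numeric(1))
      expect_true(all(abs(got - target) <= 0.01 * pmax(target, 1)))
      full <- zonal_volume(ms$maps[[bm]], matrix(TRUE, dims[1], dims[2]), px)
      expect_lt(abs(full - vols[[bm]]), 0.01 * vols[[bm]])
    }
  }
})

test_that("the two scanner grids agree after the canonical reduction", {
  cc <- small_config(n = 12, seed = 2)
  eye <- generate_cohort(cc)[1, ]
  vols <- list(irf = 100, srf = 150, ped = 220, hrf = 10)
  z1 <- zonal_features(render_maps(eye, vols, "M0", "grid_49x768", cc))
  z2 <- zonal_features(render_maps(eye, vols, "M0", "grid_128x512", cc))
  fluids <- z1$biomarker != "pr"
  rel <- abs(z1$value[fluids] - z2$value[fluids]) / pmax(abs(z1$value[fluids]), 1)
  expect_lt(max(rel), 0.02)
})

test_that("degenerate targets render as empty maps and bad targets error", {
  cc <- small_config(n = 12, seed = 2)
  eye <- generate_cohort(cc)[1, ]
  ms <- render_maps(eye, list(irf = 0, srf = 0, ped = 0, hrf = 0),
                    "M0", "grid_128x512", cc)
  for (bm in c("irf", "srf", "ped", "hrf")) {
    expect_true(all(ms$maps[[bm]] == 0))
  }
  expect_true(all(ms$maps$pr >= 0))
  expect_error(
    render_maps(eye, list(irf = -5, srf = 0, ped = 0, hrf = 0),
                "M0", "grid_128x512", cc),
    class = "tepredict_contract_error"
  )
})
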