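# Fluid kinetics: exponential per-injection decay plus Bernoulli weekly
# recurrence. At an injected visit each compartment volume is multiplied by
# its retention factor; between visits each week adds `recurrence_frac` of
# the baseline volume with probability `hazard` (IRF and SRF only — PED and
# HRF neither recur nor fully clear). PED is floored at
# `ped_floor_frac * baseline` so it persists whenever present at baseline.

# One visit-to-visit transition. `state` and `baseline` are named vectors
# over irf/srf/ped/hrf; `recur_draws` is a logical matrix (weeks x 2) of
# pre-drawn recurrence events for irf and srf.
advance_fluid <- function(state, baseline, retention, inject, gap_weeks,
                          recur_draws, recurrence_frac, ped_floor_frac) {
  if (inject) {
    state <- state * retention
    if (baseline[["ped"]] > 0) {
      state[["ped"]] <- max(state[["ped"]], ped_floor_frac * baseline[["ped"]])
    }
  }
  if (gap_weeks > 0) {
    for (fl in c("irf", "srf")) {
      hits <- sum(recur_draws[seq_len(gap_weeks), fl])
      state[[fl]] <- state[[fl]] + hits * recurrence_frac * baseline[[fl]]
    }
  }
  pmax(state, 0)
}

eye_kinetics <- function(eyes, i, use_outcome_state) {
  pre <- if (use_outcome_state) "out_" else ""
  col <- function(nm) eyes[[paste0(pre, nm)]][i]
  list(
    baseline = c(irf = col("irf_0"), srf = col("srf_0"),
                 ped = col("ped_0"), hrf = col("hrf_0")),
    retention = c(irf = col("ret_irf"), srf = col("ret_srf"),
                  ped = col("ret_ped"), hrf = col("ret_hrf")),
    hazard = col("hazard")
  )
}

# Draw the full weekly recurrence event table for one eye up front from its
# private stream, so courses are reproducible no matter how many visits end
# up being scheduled.
draw_recurrence <- function(seed, eye_id, hazard, n_weeks, stream) {
  with_eye_rng(eye_seed(seed, paste0(eye_id, ":", stream)), {
    matrix(runif(n_weeks * 2) < hazard, ncol = 2,
           dimnames = list(NULL, c("irf", "srf")))
  })
}

#' Simulate fluid volumes along a fixed visit schedule
#'
#' Open-loop fluid kinetics: volumes are recorded at each visit before any
#' injection, injections multiply each compartment by its retention factor,
#' and recurrence can add fluid between visits. The closed-loop
#' treat-and-extend schedule (where the visit times depend on the measured
#' fluid) lives in [simulate_course()]; both share the same transition
#' kernel.
#'
#' @param eyes Eye tibble from [generate_cohort()].
#' @param course_weeks Increasing numeric vector of visit weeks.
#' @param injections Logical vector aligned with `course_weeks`.
#' @param config A [cohort_config()].
#' @param use_outcome_state Use the `out_*` kinetics columns (see
#'   [generate_cohort()]).
#' @param stream Suffix of the per-eye random stream, so the observation
#'   window and the full course use independent recurrence draws.
#' @return Long tibble `(eye_id, week, injected, irf, srf, ped, hrf)`,
#'   volumes in nl as measured at each visit (pre-injection).
#' @export
simulate_fluid_course <- function(eyes, course_weeks, injections, config,
                                  use_outcome_state = FALSE,
                                  stream = "fluid") {
  if (length(course_weeks) != length(injections)) {
    stop_contract("`course_weeks` and `injections` must be aligned")
  }
  if (is.unsorted(course_weeks, strictly = TRUE)) {
    stop_contract("`course_weeks` must be strictly increasing")
  }
  gaps <- diff(c(course_weeks, course_weeks[length(course_weeks)]))

  purrr::map_dfr(seq_len(nrow(eyes)), function(i) {
    kin <- eye_kinetics(eyes, i, use_outcome_state)
    total_weeks <- max(1L, as.integer(ceiling(max(course_weeks))) + 1L)
    recur <- draw_recurrence(config$seed, eyes$eye_id[i], kin$hazard,
                             total_weeks, stream)
    state <- kin$baseline
    out <- matrix(NA_real_, nrow = length(course_weeks), ncol = 4,
                  dimnames = list(NULL, biomarkers_fluid()))
    wk_ptr <- 0L
    for (j in seq_along(course_weeks)) {
      out[j, ] <- state
      gap <- as.integer(gaps[j])
      draws <- if (gap > 0) recur[wk_ptr + seq_len(gap), , drop = FALSE] else recur[0, , drop = FALSE]
      state <- advance_fluid(state, kin$baseline, kin$retention,
                             injections[j], gap, draws,
                             config$recurrence_frac, config$ped_floor_frac)
      wk_ptr <- wk_ptr + gap
    }
    tibble::tibble(
      eye_id = eyes$eye_id[i],
      week = course_weeks,
      injected = injections,
      irf = out[, "irf"], srf = out[, "srf"],
      ped = out[, "ped"], hrf = out[, "hrf"]
    )
  })
}
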