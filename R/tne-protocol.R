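#' Disease activity from fluid volumes
#'
#' Disease activity under the treat-and-extend protocol is defined by the
#' presence of intraretinal or subretinal fluid: active iff IRF or SRF
#' exceeds its threshold. PED and HRF never trigger activity.
#'
#' @param volumes Named numeric vector or one-row data frame with at least
#'   `irf` and `srf` (nl).
#' @param thresholds Named non-negative thresholds for `irf` and `srf`
#'   (nl); the default 1 nl operationalizes "presence" of fluid.
#' @return Logical.
#' @export
assess_activity <- function(volumes, thresholds = c(irf = 1, srf = 1)) {
  if (any(thresholds[c("irf", "srf")] < 0, na.rm = TRUE) ||
      any(is.na(thresholds[c("irf", "srf")]))) {
    stop_config("`thresholds` must give non-negative irf and srf values")
  }
  if (!all(c("irf", "srf") %in% names(volumes))) {
    stop_contract("`volumes` must contain irf and srf")
  }
  isTRUE(as.numeric(volumes[["irf"]]) > thresholds[["irf"]] ||
         as.numeric(volumes[["srf"]]) > thresholds[["srf"]])
}

#' Next treat-and-extend interval
#'
#' One decision of the interval state machine: if the retina is dry the
#' interval is extended by 2 weeks up to 12, if fluid is present it is
#' shortened by 2 weeks down to 4. The opportunity to extend is limited to
#' two attempts: an attempt is consumed when an extension episode is
#' revoked, i.e. when a shortening follows a prior extension; after the
#' second revocation the interval may shorten but never re-extend.
#'
#' @param current Current interval in weeks, one of 4, 6, 8, 10, 12.
#' @param active Disease activity at this visit.
#' @param attempts_used Extension attempts consumed so far (0-2).
#' @param in_extension Whether an extension episode is open (an extension
#'   was granted and not yet revoked).
#' @return List with the new `interval`, `attempts_used` and
#'   `in_extension`.
#' @export
next_interval <- function(current, active, attempts_used = 0L,
                          in_extension = FALSE) {
  if (!current %in% c(4, 6, 8, 10, 12)) {
    stop_contract("`current` must be one of 4, 6, 8, 10, 12 weeks")
  }
  if (active) {
    if (in_extension) {
      attempts_used <- attempts_used + 1L
      in_extension <- FALSE
    }
    interval <- max(current - 2, 4)
  } else if (attempts_used < 2L) {
    interval <- min(current + 2, 12)
    if (interval > current) in_extension <- TRUE
  } else {
    interval <- current
  }
  list(interval = interval, attempts_used = attempts_used,
       in_extension = in_extension)
}

#' Simulate a 52-week treat-and-extend course
#'
#' Closed-loop simulation: every visit injects (the regimen is proactive),
#' the first two visits form the loading phase (weeks 0 and 4, both
#' injected unconditionally), and from the first follow-up onward the
#' interval follows [next_interval()] driven by the measured fluid
#' activity. Fluid evolves by the kinetics of [simulate_fluid_course()]
#' and BCVA follows the eye's latent trajectory; both use the
#' outcome-driving (`out_*`) state, which equals the feature state unless
#' the cohort was generated with `coupling = FALSE`. Courses are
#' deterministic given the config seed.
#'
#' @param eyes Eye tibble from [generate_cohort()].
#' @param config A [cohort_config()].
#' @param horizon_weeks Follow-up horizon (defaults to the config value).
#' @return Tibble of visits: `eye_id`, `visit` (1-based index), `week`,
#'   `interval_weeks` (interval assigned at this visit, equal to the gap
#'   preceding the next injection), `injected`, `disease_active`, `bcva`,
#'   the four fluid volumes (nl) and `attempts_used`.
#' @export
simulate_course <- function(eyes, config, horizon_weeks = NULL) {
  horizon <- horizon_weeks %||% config$horizon_weeks
  thr <- config$activity_thresholds

  purrr::map_dfr(seq_len(nrow(eyes)), function(i) {
    kin <- eye_kinetics(eyes, i, use_outcome_state = TRUE)
    recur <- draw_recurrence(config$seed, eyes$eye_id[i], kin$hazard,
                             horizon + 16L, "course")
    state <- kin$baseline
    week <- 0L
    interval <- 4L
    attempts <- 0L
    in_ext <- FALSE
    rows <- list()
    v <- 0L
    while (week <= horizon) {
      v <- v + 1L
      active <- assess_activity(state, thr)
      if (v >= 2L) {
        dec <- next_interval(interval, active, attempts, in_ext)
        interval <- dec$interval
        attempts <- dec$attempts_used
        in_ext <- dec$in_extension
      }
      rows[[v]] <- tibble::tibble(
        eye_id = eyes$eye_id[i], visit = v, week = week,
        interval_weeks = interval, injected = TRUE,
        disease_active = active,
        irf = state[["irf"]], srf = state[["srf"]],
        ped = state[["ped"]], hrf = state[["hrf"]],
        attempts_used = attempts
      )
      gap <- if (v == 1L) 4L else as.integer(interval)
      draws <- recur[week + seq_len(gap), , drop = FALSE]
      state <- advance_fluid(state, kin$baseline, kin$retention, TRUE, gap,
                             draws, config$recurrence_frac,
                             config$ped_floor_frac)
      week <- week + gap
    }
    course <- dplyr::bind_rows(rows)
    bcva <- simulate_bcva(eyes[i, ], course$week, config,
                          use_outcome_state = TRUE)
    course$bcva <- bcva$bcva
    course
  })
}

# Interval sequence of a course: the gaps preceding injections 2..m, which
# equal the intervals assigned at visits 1..(m-1).
course_intervals <- function(course) {
  if (is.numeric(course)) return(as.numeric(course))
  course <- dplyr::arrange(course, .data$visit)
  diff(course$week)
}

#' Extendability label of a treatment course
#'
#' An eye is extendable if it reached and maintained an interval of at
#' least 8 weeks: the course ends with a run of two or more injections
#' given at intervals >= 8 weeks and does not fall back below 8 weeks
#' afterwards. With `maintained = FALSE` the fall-back requirement is
#' dropped and any two >= 8-week injections qualify.
#'
#' @param course A course tibble from [simulate_course()] or a numeric
#'   vector of between-injection intervals (weeks).
#' @param maintained Require the extended interval to be kept through the
#'   end of follow-up (default).
#' @return Logical.
#' @export
label_extendable <- function(course, maintained = TRUE) {
  g <- course_intervals(course)
  if (length(g) == 0) return(FALSE)
  if (!maintained) return(sum(g >= 8) >= 2)
  run <- rev(cumprod(rev(g >= 8)))  # terminal run of >=8-week gaps
  sum(run) >= 2
}

#' Treatment-pattern grouping of a course
#'
#' Three mutually exclusive, exhaustive patterns: `monthly_intensive`
#' (every interval stayed at 4 weeks), `continually_extended` (intervals
#' never shortened and extension began by the 4th injection, i.e. after
#' 2-4 initial injections), and `individualized` otherwise.
#'
#' @inheritParams label_extendable
#' @return Character scalar.
#' @export
classify_pattern <- function(course) {
  g <- course_intervals(course)
  if (all(g == 4)) return("monthly_intensive")
  first_ext <- which(g > 4)[1]
  if (!is.unsorted(g) && !is.na(first_ext) && first_ext <= 3) {
    return("continually_extended")
  }
  "individualized"
}

#' Outcome labels for a set of courses
#'
#' @param courses Visit tibble from [simulate_course()] (multiple eyes).
#' @param maintained Passed to [label_extendable()].
#' @return Tibble `(eye_id, extendable, pattern)`.
#' @export
label_courses <- function(courses, maintained = TRUE) {
  courses |>
    dplyr::group_by(.data$eye_id) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(
        extendable = label_extendable(df, maintained),
        pattern = classify_pattern(df)
      )
    }) |>
    dplyr::ungroup()
}

#' Per-visit cohort summary
#'
#' Mean fluid volumes and mean BCVA change from baseline by visit index,
#' the cohort-level view of the fluid resolution kinetics (IRF clears
#' fastest, SRF more slowly, PED persists) and of the visual response.
#'
#' @param courses Visit tibble from [simulate_course()].
#' @return Tibble with one row per visit index: `visit`, `n_eyes`, mean
#'   volumes `irf`, `srf`, `ped`, `hrf` and `bcva_change`.
#' @export
cohort_summary <- function(courses) {
  if (nrow(courses) == 0) stop_contract("`courses` must contain at least one visit")
  courses |>
    dplyr::group_by(.data$eye_id) |>
    dplyr::mutate(bcva_change = .data$bcva - .data$bcva[.data$visit == 1]) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$visit) |>
    dplyr::summarise(
      n_eyes = dplyr::n(),
      dplyr::across(c("irf", "srf", "ped", "hrf", "bcva_change"), mean),
      .groups = "drop"
    )
}
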