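#' Compute the per-eye feature table of a cohort
#'
#' Runs the observation window for each eye: fluid volumes at baseline
#' (week 0, pre-injection) and at the first follow-up (week 4, after one
#' injection), en-face maps rendered on the eye's native scanner grid,
#' zonal reduction on the canonical analysis grid, change features, and
#' the clinical/demographic block. Features always derive from the
#' feature-side latent state (see [generate_cohort()] on coupling).
#'
#' @param eyes Eye tibble (typically the evaluable subset).
#' @param config A [cohort_config()].
#' @param canonical Canonical analysis grid side (pixels).
#' @return Wide tibble: `eye_id` plus the 50 canonical predictors.
#' @export
compute_feature_table <- function(eyes, config, canonical = 128L) {
  vols <- simulate_fluid_course(eyes, c(0, 4), c(TRUE, TRUE), config,
                                stream = "obs")
  bcva <- simulate_bcva(eyes, c(0, 4), config)

  zonal <- purrr::map_dfr(seq_len(nrow(eyes)), function(i) {
    eye <- eyes[i, ]
    v <- dplyr::filter(vols, .data$eye_id == eye$eye_id)
    purrr::map_dfr(c(1, 2), function(j) {
      ms <- render_maps(eye, v[j, c("irf", "srf", "ped", "hrf")],
                        visit = c("M0", "M1")[j], grid = eye$scanner,
                        config = config)
      zonal_features(ms, canonical = canonical)
    })
  })
  m0 <- dplyr::filter(zonal, .data$visit == "M0")
  m1 <- dplyr::filter(zonal, .data$visit == "M1")
  zonal_all <- dplyr::bind_rows(m0, m1, change_features(m0, m1))

  clinical <- bcva |>
    tidyr::pivot_wider(id_cols = "eye_id", names_from = "week",
                       values_from = "bcva", names_prefix = "w") |>
    dplyr::rename(bcva_m0 = "w0", bcva_m1 = "w4") |>
    dplyr::left_join(eyes[c("eye_id", "age", "sex")], by = "eye_id")

  assemble_features(zonal_all, clinical)
}

# Materialize the per-visit trial record, injecting the data defects that
# the generator assigned to attrition eyes: a missing baseline/follow-up
# scan, truncated follow-up, bad scan quality at an early visit, or a
# protocol deviation (two visits without injection).
realize_visits <- function(eyes, courses, config) {
  visits <- courses |>
    dplyr::left_join(eyes[c("eye_id", "attrition", "age", "sex")], by = "eye_id") |>
    dplyr::mutate(scan_available = TRUE, scan_quality_ok = TRUE)

  fix <- function(df, id) {
    a <- df$attrition[1]
    if (a == "missing_scan") {
      drop_visit <- 1L + eye_seed(config$seed, paste0(id, ":ms")) %% 2L
      df$scan_available[df$visit == drop_visit] <- FALSE
    } else if (a == "lost_followup") {
      df <- df[df$visit <= 3L, ]
    } else if (a == "bad_quality") {
      df$scan_quality_ok[df$visit <= 2L] <- FALSE
    } else if (a == "protocol_deviation") {
      df$injected[df$visit %in% c(3L, 5L)] <- FALSE
    }
    df
  }
  visits |>
    dplyr::group_by(.data$eye_id) |>
    dplyr::group_modify(function(df, key) fix(df, key$eye_id)) |>
    dplyr::ungroup() |>
    dplyr::select(-"attrition")
}

#' Apply the evaluability exclusion rules
#'
#' Sequentially excludes eyes with a missing scan at one of the first two
#' visits, eyes lost to follow-up (fewer than `min_visits` visits), eyes
#' with bad scan quality at an early visit, and protocol deviators (two
#' or more visits without injection, or an interval beyond
#' `max_interval` weeks). Rules are applied in that order and each eye is
#' tallied only under the first rule it matches.
#'
#' @param visits Per-visit tibble (from [realize_visits()] or equivalent)
#'   with at least `eye_id`, `visit`, `week`, `injected`; optional
#'   `scan_available` and `scan_quality_ok` default to `TRUE`.
#' @param min_visits Minimum visit count to be evaluable.
#' @param max_interval Maximum protocol-conforming interval (weeks).
#' @return List with `visits` (evaluable subset), `eye_ids` and a `tally`
#'   tibble (one row per rule plus the evaluable count).
#' @export
exclusion_filter <- function(visits, min_visits = 6, max_interval = 12) {
  if (!all(c("eye_id", "visit", "week", "injected") %in% names(visits))) {
    stop_contract("`visits` must have eye_id, visit, week, injected")
  }
  if (!"scan_available" %in% names(visits)) visits$scan_available <- TRUE
  if (!"scan_quality_ok" %in% names(visits)) visits$scan_quality_ok <- TRUE

  per_eye <- visits |>
    dplyr::group_by(.data$eye_id) |>
    dplyr::summarise(
      missing_scan = any(!.data$scan_available[.data$visit <= 2]),
      lost_followup = dplyr::n() < min_visits,
      bad_quality = any(!.data$scan_quality_ok[.data$visit <= 2]),
      protocol_deviation = sum(!.data$injected) >= 2 ||
        any(diff(sort(.data$week)) > max_interval),
      .groups = "drop"
    )

  rules <- c("missing_scan", "lost_followup", "bad_quality", "protocol_deviation")
  excluded <- character(0)
  tally <- integer(length(rules)) |> setNames(rules)
  for (rule in rules) {
    hit <- per_eye$eye_id[per_eye[[rule]] & !per_eye$eye_id %in% excluded]
    tally[[rule]] <- length(hit)
    excluded <- c(excluded, hit)
  }
  keep <- setdiff(per_eye$eye_id, excluded)
  list(
    visits = dplyr::filter(visits, .data$eye_id %in% keep),
    eye_ids = keep,
    tally = tibble::tibble(
      rule = c(rules, "evaluable"),
      n = c(unname(tally), length(keep))
    )
  )
}

#' Configure the end-to-end pipeline
#'
#' @param cohort A [cohort_config()].
#' @param lcmm An [lcmm_spec()].
#' @param rf An [rf_config()].
#' @param responder_threshold Letters gained by month 12 defining a
#'   responder class.
#' @param k_folds Cross-validation folds.
#' @param n_boot Bootstrap resamples for AUC CIs.
#' @param min_visits Evaluability threshold on visit count.
#' @param global_seed If given, overrides the seeds of every sub-config.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), lcmm = lcmm_spec(),
                            rf = rf_config(), responder_threshold = 5,
                            k_folds = 10, n_boot = 1000, min_visits = 6,
                            global_seed = NULL) {
  if (!is.null(global_seed)) {
    assert_scalar_number(global_seed, "global_seed")
    cohort$seed <- as.integer(global_seed)
    lcmm$seed <- as.integer(global_seed)
    rf$seed <- as.integer(global_seed)
  }
  structure(
    list(cohort = cohort, lcmm = lcmm, rf = rf,
         responder_threshold = responder_threshold,
         k_folds = as.integer(k_folds), n_boot = as.integer(n_boot),
         min_visits = as.integer(min_visits),
         seed = cohort$seed),
    class = "pipeline_config"
  )
}

#' Run the full synthetic-cohort experiment
#'
#' Orchestrates all stages: cohort generation, treat-and-extend course
#' simulation, attrition and exclusion, zonal feature extraction, latent
#' class modelling with responder merging, and the two random-forest
#' prediction experiments (responder and extendable). With an
#' `output_dir` every stage's table is written as CSV/JSON and a manifest
#' of MD5 hashes is returned; reruns with the same configuration
#' reproduce identical hashes.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory for artifacts, or `NULL` to skip writing.
#' @param feature_sets Predictor subsets to evaluate per target.
#' @return List of class `te_pipeline` with every stage's result and, if
#'   written, the artifact `manifest`.
#' @export
run_pipeline <- function(config, output_dir = NULL,
                         feature_sets = c("all", "baseline_only", "imaging_only")) {
  stopifnot(inherits(config, "pipeline_config"))
  cc <- config$cohort

  eyes <- generate_cohort(cc)
  courses <- simulate_course(eyes, cc)
  visits <- realize_visits(eyes, courses, cc)
  excl <- exclusion_filter(visits, min_visits = config$min_visits)
  evaluable <- dplyr::filter(eyes, .data$eye_id %in% excl$eye_ids)

  features <- compute_feature_table(evaluable, cc)

  lcmm_fit <- fit_lcmm(
    dplyr::select(excl$visits, "eye_id", "week", "bcva"),
    config$lcmm
  )
  class_map <- merge_to_responder(lcmm_fit, config$responder_threshold)
  assign <- posterior_assign(lcmm_fit)
  responder <- assign |>
    dplyr::left_join(class_map, by = "latent_class") |>
    dplyr::select("eye_id", "latent_class", "responder")

  labels <- label_courses(dplyr::filter(courses, .data$eye_id %in% excl$eye_ids)) |>
    dplyr::left_join(responder, by = "eye_id")

  experiments <- list(
    responder = run_experiment(features, labels, "responder",
                               feature_sets = feature_sets, rf = config$rf,
                               k = config$k_folds, n_boot = config$n_boot,
                               seed = config$seed),
    extendable = run_experiment(features, labels, "extendable",
                                feature_sets = feature_sets, rf = config$rf,
                                k = config$k_folds, n_boot = config$n_boot,
                                seed = config$seed)
  )

  baseline_bcva <- excl$visits |>
    dplyr::filter(.data$visit == 1) |>
    dplyr::select("eye_id", baseline_bcva = "bcva")
  crosstab <- crosstab_by_baseline(
    dplyr::left_join(responder, baseline_bcva, by = "eye_id")
  )

  result <- structure(
    list(config = config, eyes = eyes, courses = courses, visits = visits,
         exclusions = excl$tally, evaluable_ids = excl$eye_ids,
         features = features, lcmm = lcmm_fit, labels = labels,
         crosstab = crosstab, experiments = experiments,
         summary = cohort_summary(dplyr::filter(courses, .data$eye_id %in% excl$eye_ids))),
    class = "te_pipeline"
  )
  if (!is.null(output_dir)) {
    result$manifest <- write_pipeline_artifacts(result, output_dir)
  }
  result
}

write_pipeline_artifacts <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(output_dir, f)

  readr::write_csv(result$eyes, p("eyes_ground_truth.csv"))
  readr::write_csv(result$visits, p("visits.csv"))
  readr::write_csv(result$features, p("features.csv"))
  readr::write_csv(result$labels, p("labels.csv"))
  readr::write_csv(result$exclusions, p("exclusion_tally.csv"))
  posterior <- result$lcmm$posterior
  colnames(posterior) <- paste0("class", seq_len(ncol(posterior)))
  readr::write_csv(
    tibble::as_tibble(posterior) |>
      dplyr::mutate(eye_id = rownames(result$lcmm$posterior), .before = 1),
    p("lcmm_posterior.csv")
  )
  jsonlite::write_json(
    list(
      feature_names = feature_names(),
      units = c(rep("nl (um for pr)", 45), "letters", "letters", "letters",
                "years", "female=1")
    ),
    p("feature_schema.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    list(
      class_proportions = result$lcmm$class_proportions,
      class_coeffs = result$lcmm$class_coeffs,
      sigma2 = result$lcmm$sigma2, tau2 = result$lcmm$tau2,
      loglik = result$lcmm$loglik, converged = result$lcmm$converged,
      n_iter = result$lcmm$n_iter
    ),
    p("lcmm_fit.json"), auto_unbox = TRUE, digits = NA
  )
  for (target in names(result$experiments)) {
    jsonlite::write_json(
      glance(result$experiments[[target]]),
      p(sprintf("report_%s.json", target)), auto_unbox = TRUE, digits = NA
    )
  }
  files <- sort(list.files(output_dir, full.names = TRUE))
  tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = file.size(files)
  )
}

#' @export
print.te_pipeline <- function(x, ...) {
  cat(sprintf("<te_pipeline> %d eyes, %d evaluable\n",
              nrow(x$eyes), length(x$evaluable_ids)))
  print(x$exclusions)
  for (target in names(x$experiments)) print(glance(x$experiments[[target]]))
  invisible(x)
}
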