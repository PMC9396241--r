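#' Plot mean fluid volumes and BCVA change over the course
#'
#' Cohort-level fluid resolution kinetics (IRF clears fastest, SRF more
#' slowly, PED persists) alongside the mean BCVA change from baseline,
#' by visit index.
#'
#' @param summary Tibble from [cohort_summary()].
#' @return A ggplot.
#' @export
plot_cohort_summary <- function(summary) {
  long <- tidyr::pivot_longer(summary, c("irf", "srf", "ped"),
                              names_to = "fluid", values_to = "volume")
  scale <- max(long$volume) / max(abs(summary$bcva_change), 1)
  ggplot2::ggplot(long, ggplot2::aes(.data$visit)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$volume,
                                    colour = toupper(.data$fluid))) +
    ggplot2::geom_line(data = summary,
                       ggplot2::aes(y = .data$bcva_change * scale),
                       linetype = 2, colour = "grey30") +
    ggplot2::scale_y_continuous(
      "Mean fluid volume (nl)",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "Mean BCVA change (letters)")
    ) +
    ggplot2::labs(x = "Visit", colour = "Fluid") +
    ggplot2::theme_minimal()
}

#' Plot per-eye treatment interval patterns
#'
#' One column per eye, one tile per visit, filled by the interval
#' assigned at that visit; eyes ordered by treatment pattern and final
#' interval, making the monthly-intensive, continually-extended and
#' individualized groups visible.
#'
#' @param courses Visit tibble from [simulate_course()].
#' @return A ggplot.
#' @export
plot_treatment_patterns <- function(courses) {
  last_iv <- courses |>
    dplyr::group_by(.data$eye_id) |>
    dplyr::summarise(last = dplyr::last(.data$interval_weeks), .groups = "drop")
  ord <- label_courses(courses) |>
    dplyr::left_join(last_iv, by = "eye_id") |>
    dplyr::arrange(.data$pattern, .data$last)
  df <- dplyr::mutate(courses,
                      eye = factor(.data$eye_id, levels = ord$eye_id))
  ggplot2::ggplot(df, ggplot2::aes(.data$eye, .data$visit,
                                   fill = factor(.data$interval_weeks))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", name = "Interval (weeks)") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "Visit") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
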