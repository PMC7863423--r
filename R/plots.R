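# ggplot2 views of the result objects.

#' Plot age-specific incidence rates
#'
#' Point estimates with exact Poisson confidence intervals per five-year
#' age band (the crude row is dropped).
#'
#' @param object An `incidence_estimates` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot incidence_estimates
#' @export
autoplot.incidence_estimates <- function(object, ...) {
  df <- object |>
    filter(.data$band != "CRUDE", !is.na(.data$rate)) |>
    mutate(band = factor(.data$band, levels = age_band_levels()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$band, y = .data$rate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = "Age band", y = "Incidence per 100,000 person-years") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a feasibility report
#'
#' Incident cases by recruitment status, split by pre-existing dementia.
#'
#' @param object A `feasibility_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot feasibility_report
#' @export
autoplot.feasibility_report <- function(object, ...) {
  df <- object$by_status |>
    mutate(no_dementia = .data$n - .data$dementia_n) |>
    select("status", dementia = "dementia_n", "no_dementia") |>
    tidyr::pivot_longer(c("dementia", "no_dementia"),
                        names_to = "group", values_to = "count") |>
    mutate(group = ifelse(.data$group == "dementia",
                          "With dementia", "Without dementia"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data$count,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Recruitment status", y = "Incident cases",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-condition caution frequencies
#'
#' The caution-summary table as a horizontal bar chart, coloured by
#' consensus recruitment status.
#'
#' @param caution_table Output of [caution_summary()].
#' @return A ggplot.
#' @export
plot_caution_summary <- function(caution_table) {
  df <- caution_table |>
    mutate(condition = stats::reorder(.data$condition, .data$n))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$condition,
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Incident cases with a record", y = NULL,
                  fill = "Recruitment status") +
    ggplot2::theme_minimal()
}
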