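#' Annual prevalence trend chart
#'
#' One line per region (plus the pooled cohort) of annual P_IAD with Wilson
#' confidence ribbons.
#'
#' @param prevalence A prevalence table from [prevalence_table()].
#' @return A ggplot object.
#' @export
plot_prevalence_trend <- function(prevalence) {
  ggplot2::ggplot(prevalence,
                  ggplot2::aes(x = .data$year, y = 100 * .data$p_iad,
                               colour = .data$region, fill = .data$region)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = 100 * .data$ci_low,
                                      ymax = 100 * .data$ci_high),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = "Year", y = "Annual prevalence of intermittency (%)",
                  colour = "Region", fill = "Region") +
    ggplot2::theme_minimal()
}

#' Cost-by-year chart
#'
#' Total expenditure per year, one line per drug (LHRH analogues and
#' antiandrogens), in millions of euros.
#'
#' @param costs A cost table from [annual_costs()] grouped at least by
#'   `year` and `drug`.
#' @return A ggplot object.
#' @export
plot_cost_trend <- function(costs) {
  by_drug <- costs %>%
    dplyr::group_by(.data$year, .data$drug) %>%
    dplyr::summarise(total_eur = sum(.data$total_eur), .groups = "drop")
  ggplot2::ggplot(by_drug,
                  ggplot2::aes(x = .data$year, y = .data$total_eur / 1e6,
                               colour = .data$drug)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = "Year", y = "Total cost (million €)",
                  colour = "Drug") +
    ggplot2::theme_minimal()
}

#' Age distribution by regimen
#'
#' Decade-binned age distribution of patients under continuous versus
#' intermittent deprivation.
#'
#' @param patients A patient table with `age` and `regimen` columns (as
#'   produced by [adt_run()]).
#' @return A ggplot object.
#' @export
plot_age_distribution <- function(patients) {
  patients <- patients %>%
    dplyr::mutate(age_decade = cut(.data$age,
                                   breaks = seq(10, 110, by = 10),
                                   right = FALSE,
                                   labels = paste(seq(10, 100, 10),
                                                  seq(19, 109, 10), sep = "-")))
  ggplot2::ggplot(patients, ggplot2::aes(x = .data$age_decade,
                                         fill = .data$regimen)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = "Age (years)", y = "Patients", fill = "Regimen") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.adt_results <- function(object, ...) {
  plot_prevalence_trend(object$prevalence)
}
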