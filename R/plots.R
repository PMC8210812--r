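#' Bar chart of identification metrics across fragment lengths
#'
#' Plots the replicate mean of one metric per fragment length, faceted by
#' dataset, colored by tool x cutoff, with error bars spanning the
#' replicate standard deviation — the usual panel layout for comparing
#' identification tools across fragment sizes.
#'
#' @param report tibble from [evaluate_run()]
#' @param metric metric column to plot (default `"mcc"`)
#' @return a ggplot object
#' @export
plot_id_metrics <- function(report, metric = "mcc") {
  stopifnot(metric %in% names(report))
  means <- filter(report, .data$stat == "mean") |>
    mutate(value = .data[[metric]],
           tool_cutoff = paste(.data$tool, .data$cutoff, sep = " / "))
  sds <- filter(report, .data$stat == "sd") |>
    select("tool", "cutoff", "dataset", "length_class",
           sd_value = all_of(metric))
  means <- left_join(means, sds, by = c("tool", "cutoff", "dataset", "length_class"))
  ggplot2::ggplot(means,
                  ggplot2::aes(x = factor(.data$length_class),
                               y = .data$value, fill = .data$tool_cutoff)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$value,
                   ymax = .data$value + dplyr::coalesce(.data$sd_value, 0)),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$dataset)) +
    ggplot2::labs(x = "fragment length (bp)", y = metric, fill = "tool / cutoff") +
    ggplot2::theme_minimal()
}

#' Bar chart of clustering statuses
#'
#' @param summary the result of [clustering_status_summary()]
#' @return a ggplot object
#' @export
plot_status_summary <- function(summary) {
  ggplot2::ggplot(summary$status,
                  ggplot2::aes(x = .data$status, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of input sequences") +
    ggplot2::theme_minimal()
}

#' Histogram of pairwise distance degradation
#'
#' @param degradation the result of [distance_degradation()]
#' @return a ggplot object
#' @export
plot_distance_degradation <- function(degradation) {
  ggplot2::ggplot(degradation$pairs, ggplot2::aes(x = .data$delta_pct)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "% difference vs complete genomes", y = "pairs") +
    ggplot2::theme_minimal()
}
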