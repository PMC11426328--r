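# ggplot2 displays of the main result types.

#' Plot a Kaplan-Meier curve
#'
#' @param object An `eein_km` object from [km_curve()].
#' @param ... Unused.
#' @return A ggplot step plot of the survival estimate.
#' @method autoplot eein_km
#' @export
autoplot.eein_km <- function(object, ...) {
  df <- bind_rows(tibble(time = 0, survival = 1),
                  tibble(time = object$time, survival = object$survival))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Compare Kaplan-Meier curves of an edge split
#'
#' @param split Tibble from [split_by_edge()].
#' @return A ggplot with one step curve per group (edge present /
#'   absent).
#' @export
plot_km_split <- function(split) {
  df <- split |>
    group_by(.data$present) |>
    dplyr::group_modify(function(d, g) {
      km <- km_curve(d)
      bind_rows(tibble(time = 0, survival = 1),
                tibble(time = km$time, survival = km$survival))
    }) |>
    ungroup() |>
    mutate(group = ifelse(.data$present, "present", "absent"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  colour = "Edge") +
    ggplot2::theme_minimal()
}

#' Plot pathway enrichment results
#'
#' @param object An `eein_enrichment` tibble from [enrich_pathways()].
#' @param top Number of top pathways shown (default 20).
#' @param ... Unused.
#' @return A ggplot bar chart of -log10 q by pathway.
#' @method autoplot eein_enrichment
#' @export
autoplot.eein_enrichment <- function(object, top = 20, ...) {
  df <- head(arrange(object, .data$q), top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$pathway_id, -.data$q),
    y = -log10(.data$q), fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "-log10 q-value") +
    ggplot2::theme_minimal()
}

#' Plot a CPM threshold sweep
#'
#' @param sweep Tibble from [threshold_sweep()].
#' @return A ggplot of per-sample mean edge counts and perturbed-edge
#'   counts against the expression threshold (log scale).
#' @export
plot_threshold_sweep <- function(sweep) {
  df <- tidyr::pivot_longer(
    sweep, -"threshold", names_to = "quantity", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$count,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "CPM threshold", y = "Count") +
    ggplot2::theme_minimal()
}
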