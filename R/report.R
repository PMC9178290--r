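# Figures: influence-rating heatmaps and per-parameter summaries.

#' Heatmap of combined influence ratings
#'
#' One tile per (parameter of interest, outcome metric), colored on the
#' 0 (no influence) to 3 (large influence) scale, faceted by model when
#' several models are rated. Partial ratings (only one direction
#' available) are marked with an asterisk.
#'
#' @param ratings Output of [rate_study()].
#' @param category Optional category filter (e.g. `"contact"`).
#' @return A ggplot object.
#' @export
plot_rating_heatmap <- function(ratings, category = NULL) {
  stopifnot(nrow(ratings) > 0)
  if (!is.null(category)) {
    ratings <- ratings[ratings$category %in% category, , drop = FALSE]
    if (nrow(ratings) == 0) stop("no ratings in that category",
                                 call. = FALSE)
  }
  ratings$metric_kind <- factor(ratings$metric_kind, levels = METRIC_KINDS)
  ratings$label <- ifelse(
    is.na(ratings$combined_score), "n/a",
    paste0(format(ratings$combined_score, drop0trailing = TRUE),
           ifelse(ratings$partial, "*", "")))
  p <- ggplot2::ggplot(
    ratings,
    ggplot2::aes(x = .data$metric_kind, y = .data$parameter,
                 fill = .data$combined_score)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient(
      low = "#f7fbff", high = "#b2182b", limits = c(0, 3),
      na.value = "grey80", name = "influence\n(0-3)") +
    ggplot2::labs(x = "outcome metric", y = "parameter of interest") +
    ggplot2::theme_minimal()
  if (length(unique(ratings$model_id)) > 1) {
    p <- p + ggplot2::facet_wrap(~model_id)
  }
  p
}

#' Bar chart of an aggregated metric per parameter
#'
#' @param aggregates Output of [aggregate_study()].
#' @param metric One of the aggregate metric columns (default
#'   `"pressure_pct_diff"`).
#' @return A ggplot object; excluded-run counts are annotated above bars.
#' @export
plot_aggregate_bars <- function(aggregates, metric = "pressure_pct_diff") {
  stopifnot(metric %in% names(aggregates))
  aggregates$excl_lab <- ifelse(
    aggregates$n_excluded > 0,
    sprintf("%d excl.", aggregates$n_excluded), "")
  ggplot2::ggplot(
    aggregates,
    ggplot2::aes(x = .data$parameter, y = .data[[metric]],
                 fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(ggplot2::aes(label = .data$excl_lab),
                       position = ggplot2::position_dodge(width = 0.9),
                       vjust = -0.3, size = 2.5) +
    ggplot2::labs(x = "parameter of interest", y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Render the report figures of a pipeline run
#'
#' Writes one rating heatmap per category plus a pressure-difference bar
#' chart. Figure files are deterministic given a fixed rating matrix.
#'
#' @param ratings Output of [rate_study()].
#' @param aggregates Output of [aggregate_study()].
#' @param out_dir Output directory.
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#' @return Invisibly, the files written.
#' @export
render_report <- function(ratings, aggregates, out_dir, width = 8,
                          height = 6, dpi = 150) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (cat in unique(ratings$category[!is.na(ratings$category)])) {
    f <- file.path(out_dir, sprintf("ratings_%s.png", cat))
    ggplot2::ggsave(f, plot_rating_heatmap(ratings, cat), width = width,
                    height = height, dpi = dpi)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "pressure_pct_diff.png")
  ggplot2::ggsave(f, plot_aggregate_bars(aggregates), width = width,
                  height = height, dpi = dpi)
  files <- c(files, f)
  invisible(files)
}
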