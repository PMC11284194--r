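#' Plot matched-pair distances by stratum
#'
#' Dot plot of each matched pair's dissimilarity, grouped by matching
#' stratum; conflict-resolved pairs (matched at neighbour rank 2 or 3) are
#' highlighted.
#'
#' @param object A `matched_cohort` from [sequential_match()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot matched_cohort
#' @export
autoplot.matched_cohort <- function(object, ...) {
  d <- object$pairs |>
    mutate(via = ifelse(.data$rank == 1, "nearest neighbour",
                        "conflict fallback"))
  ggplot(d, aes(x = .data$distance, y = .data$aoi_id, colour = .data$via)) +
    geom_point(size = 2) +
    facet_grid(rows = vars(.data$stratum), scales = "free_y", space = "free_y") +
    labs(x = "weighted Euclidean distance (z-scored features)",
         y = NULL, colour = NULL,
         title = sprintf("Matched pairs (%d), variant %s, k = %d",
                         nrow(d), object$variant, object$k)) +
    theme_minimal()
}

#' Heat map of the AOI-by-reference distance matrix
#'
#' Static tile rendering of the within-stratum dissimilarity matrix, with
#' the selected match outlined. Cross-stratum cells are absent: distances
#' are only defined within a matching stratum.
#'
#' @param match A `matched_cohort`.
#' @return A ggplot object.
#' @export
plot_distance_matrix <- function(match) {
  d <- match$distances |>
    left_join(match$pairs |> select("aoi_id", "reference_id") |>
                mutate(selected = TRUE),
              by = c("aoi_id", "reference_id")) |>
    mutate(selected = !is.na(.data$selected))
  ggplot(d, aes(x = .data$reference_id, y = .data$aoi_id, fill = .data$distance)) +
    geom_tile() +
    geom_tile(data = filter(d, .data$selected), fill = NA,
              colour = "black", linewidth = 0.8) +
    facet_wrap(vars(.data$stratum), scales = "free") +
    scale_fill_viridis_c(direction = -1) +
    labs(x = "reference case", y = "AOI",
         fill = "distance") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Plot a comparison table's p-values
#'
#' Lollipop chart of per-variable p-values from [baseline_table()] or
#' [outcome_analysis()], with the screening level marked; skipped
#' (no-contrast) variables are omitted.
#'
#' @param object An `aneumatch_comparison` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot aneumatch_comparison
#' @export
autoplot.aneumatch_comparison <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  d <- filter(as_tibble(object), !is.na(.data$p_value))
  ggplot(d, aes(x = .data$p_value,
                y = stats::reorder(.data$variable, .data$p_value),
                colour = .data$test)) +
    geom_segment(aes(xend = 0, yend = stats::reorder(.data$variable, .data$p_value))) +
    geom_point(size = 2) +
    geom_vline(xintercept = alpha, linetype = "dashed") +
    scale_x_continuous(limits = c(0, 1)) +
    labs(x = "two-sided p-value", y = NULL, colour = "test") +
    theme_minimal()
}
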