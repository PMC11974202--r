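#' Plot a reliability grid
#'
#' Line plot of the averaged single-day ICC against the minimum-hours
#' criterion, one panel per outcome and one line per day count, with the
#' Spearman-Brown target reliability context in the subtitle.
#'
#' @param object A `reliability_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reliability_grid
#' @export
autoplot.reliability_grid <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$min_hours, y = .data$icc,
                 colour = factor(.data$n_days))
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(
      x = "minimum reported hours/day", y = "single-day ICC",
      colour = "days",
      title = "Day-to-day reliability by inclusion criterion",
      subtitle = sprintf("ICC (%s), averaged over %d random day selections",
                         attr(object, "icc_type"), attr(object, "reps"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a hypothesis consistency ledger
#'
#' Tile display of the `+` / `±` / `-` verdicts for the enumerated
#' sub-hypotheses, grouped by hypothesis family.
#'
#' @param object A `hypothesis_ledger`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hypothesis_ledger
#' @export
autoplot.hypothesis_ledger <- function(object, ...) {
  df <- dplyr::mutate(
    object,
    family = dplyr::case_when(
      .data$kind == "similarity" & .data$left %in% sb_activity_groups &
        .data$right %in% sb_activity_groups ~ "SB similarity",
      .data$kind == "similarity" ~ "PA similarity",
      .data$left == "sleeping" ~ "sleep differences",
      TRUE ~ "PA vs SB differences"
    ),
    label = paste(.data$left,
                  ifelse(.data$expected == "left=right", "=", "<"),
                  .data$right)
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = 1, y = stats::reorder(.data$label, -.data$id),
                 fill = .data$verdict)
  ) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$verdict), size = 3) +
    ggplot2::facet_wrap(~family, scales = "free_y") +
    ggplot2::scale_fill_manual(
      values = c("+" = "#74c476", "±" = "#fdae6b", "-" = "#fb6a4a")
    ) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Hypothesis support across metrics and placements") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   legend.position = "none")
}

#' Plot entry-level acceleration by activity grouping
#'
#' Box plots of per-entry median acceleration on a log scale, by activity
#' grouping, faceted by metric and placement -- the synthetic analog of
#' the descriptive acceleration-by-category display.
#'
#' @param entry_acc Entry accelerations from [summarize_entries()].
#' @param eps Offset added before the log scale.
#' @return A ggplot object.
#' @export
plot_entry_accelerations <- function(entry_acc, eps = 0.001) {
  df <- entry_acc |>
    dplyr::filter(!.data$excluded) |>
    tidyr::pivot_longer(c("median_enmo", "median_mad"),
                        names_to = "metric", values_to = "median_g") |>
    dplyr::mutate(metric = toupper(sub("median_", "", .data$metric)))
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = stats::reorder(.data$group, .data$median_g,
                                    FUN = stats::median),
                 y = .data$median_g + eps, fill = .data$behavior)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(metric ~ placement) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = sprintf("median acceleration + %g (g)", eps),
                  fill = "behavior") +
    ggplot2::theme_minimal()
}
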