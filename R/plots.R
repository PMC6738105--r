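#' Enrichment running-sum plot
#'
#' The classic pre-ranked enrichment picture: the running sum along the
#' ranked list with the member positions marked in a rug and the enrichment
#' score highlighted at the peak.
#'
#' @param ranked a [ranked_list()].
#' @param gene_set member genes.
#' @param weight metric weight exponent.
#' @return a ggplot object.
#' @export
plot_running_sum <- function(ranked, gene_set, weight = 1) {
  es <- enrichment_score(ranked, gene_set, weight = weight)
  df <- tibble(rank = seq_along(es$running_sum), running = es$running_sum)
  peak <- which.max(abs(df$running))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$running)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_rug(
      data = tibble(rank = es$hit_positions),
      ggplot2::aes(x = .data$rank), inherit.aes = FALSE, sides = "b",
      length = ggplot2::unit(0.03, "npc")
    ) +
    ggplot2::annotate("point", x = peak, y = df$running[peak], colour = "#d95f02") +
    ggplot2::labs(
      x = "rank in list", y = "running enrichment score",
      subtitle = sprintf("ES = %.3f, %d members in list", es$es, es$n_hits)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn km_estimate Kaplan-Meier step-curve plot with censoring marks.
#' @param object a `km_curve`.
#' @param ... unused.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- as_tibble(object)
  if (!"group" %in% names(df)) df$group <- "all"
  # prepend S(0) = 1 per group
  start <- distinct(df, .data$group) |>
    mutate(time = 0, survival = 1, n_censor = 0L)
  df2 <- bind_rows(start, df)
  p <- ggplot2::ggplot(df2, ggplot2::aes(
    x = .data$time, y = .data$survival, colour = .data$group
  )) +
    ggplot2::geom_step() +
    ggplot2::geom_point(
      data = filter(df, .data$n_censor > 0), shape = 3, show.legend = FALSE
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability", colour = NULL) +
    ggplot2::theme_minimal()
  if (all(df2$group == "all")) p <- p + ggplot2::guides(colour = "none")
  p
}

#' Knockout differential-expression volcano plot
#'
#' @param de_table tibble with `gene`, `logFC`, `fdr`.
#' @param fdr_max,min_abs_logfc the (strict) filter thresholds to display.
#' @return a ggplot object.
#' @export
plot_volcano <- function(de_table, fdr_max = 0.1, min_abs_logfc = 1.0) {
  df <- de_table |>
    mutate(status = dplyr::case_when(
      .data$fdr < fdr_max & .data$logFC > min_abs_logfc ~ "up",
      .data$fdr < fdr_max & .data$logFC < -min_abs_logfc ~ "down",
      TRUE ~ "ns"
    ))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$logFC, y = -log10(.data$fdr), colour = .data$status
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::scale_colour_manual(values = c(up = "#d7301f", down = "#0570b0", ns = "grey75")) +
    ggplot2::geom_vline(xintercept = c(-min_abs_logfc, min_abs_logfc), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(fdr_max), linetype = 2) +
    ggplot2::labs(x = "log2 fold-change", y = "-log10 FDR", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Binding-fraction bar plot
#'
#' Shows, per ChIP dataset, the fraction of query genes with at least one
#' peak in their regulatory window.
#'
#' @param summary output of [binding_summary()].
#' @return a ggplot object.
#' @export
plot_binding_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(
    x = stats::reorder(.data$dataset, -.data$fraction), y = .data$fraction
  )) +
    ggplot2::geom_col(fill = "#fc8d59") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d/%d", .data$n_bound, .data$n_query)),
                       vjust = -0.4, size = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "fraction of query genes bound") +
    ggplot2::theme_minimal()
}
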