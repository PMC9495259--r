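#' Volcano plot of a differential-expression comparison
#'
#' @param de `de_test()` result tibble.
#' @param p_threshold,lfc_threshold Thresholds drawn as guide lines.
#' @return A ggplot.
#' @export
plot_volcano <- function(de, p_threshold = 0.05, lfc_threshold = 1) {
  ggplot2::ggplot(de, ggplot2::aes(.data$log2fc, -log10(.data$p_value),
                                   colour = .data$is_deg)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold), linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * lfc_threshold, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = "DEG", title = unique(de$comparison)) +
    ggplot2::theme_minimal()
}

#' Plot the pathway crosstalk network
#'
#' Nodes are pathways (those containing variant-mapped genes highlighted),
#' edges weighted by the JC/OC average score. Layout is a deterministic
#' circle so reruns give identical figures.
#'
#' @param edges Crosstalk edge tibble from [build_crosstalk()].
#' @param snp_pathways Character vector of pathway ids containing
#'   variant-mapped genes.
#' @return A ggplot.
#' @export
plot_crosstalk <- function(edges, snp_pathways = character()) {
  nodes <- sort(unique(c(edges$pathway_a, edges$pathway_b)))
  if (length(nodes) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "Empty crosstalk network") +
             ggplot2::theme_void())
  }
  angle <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
  layout <- tibble(
    pathway = nodes, x = cos(angle), y = sin(angle),
    snp = nodes %in% snp_pathways
  )
  seg <- edges %>%
    left_join(layout, by = c(pathway_a = "pathway")) %>%
    rename(xa = "x", ya = "y") %>%
    left_join(layout[1:3], by = c(pathway_b = "pathway"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$x,
                   yend = .data$y, linewidth = .data$score),
      colour = "grey70"
    ) +
    ggplot2::geom_point(
      data = layout,
      ggplot2::aes(.data$x, .data$y, colour = .data$snp), size = 5
    ) +
    ggplot2::geom_text(
      data = layout,
      ggplot2::aes(.data$x * 1.12, .data$y * 1.12, label = .data$pathway),
      size = 3
    ) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "steelblue", `FALSE` = "darkseagreen"),
      labels = c(`TRUE` = "contains SNP gene", `FALSE` = "DEG only"),
      name = NULL
    ) +
    ggplot2::scale_linewidth(range = c(0.3, 2), name = "score") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
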