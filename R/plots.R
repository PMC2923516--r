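#' Plot allelic divergence along the chromosome
#'
#' dS per pair along the layout, with the mat locus and centromere marked:
#' the visual signature of a suppressed central region is a plateau of
#' elevated dS flanked by zeros.
#'
#' @param object A [divergence_table()] tibble.
#' @param layout A `tet_layout` (for gene order and landmarks).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.tet_divergence <- function(object, layout, ...) {
  df <- left_join(as_tibble(object), layout[, c("gene", "order")], by = "gene")
  marks <- bind_rows(
    if (any(layout$mat_locus_follows))
      tibble(x = layout$order[layout$mat_locus_follows] + 0.5, label = "mat"),
    if (any(layout$centromere_follows))
      tibble(x = layout$order[layout$centromere_follows] + 0.5, label = "centromere")
  )
  if (nrow(marks) == 0) marks <- tibble(x = numeric(0), label = character(0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$order, y = .data$dS,
                                   group = .data$pair_id, colour = .data$pair_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(data = marks, ggplot2::aes(xintercept = .data$x),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_continuous(breaks = layout$order, labels = layout$gene) +
    ggplot2::labs(x = NULL, y = "allelic dS", colour = "pair") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot the phase matrix
#'
#' Gene-by-pair tile map of allele phase calls; supported separation is shown
#' darker. Conversion candidates appear as isolated "together" tiles inside a
#' separated block.
#'
#' @param object A [phase_matrix()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.tet_phases <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(state = dplyr::case_when(
      .data$phase == "separated" & .data$separation_supported ~ "separated (supported)",
      .data$phase == "separated" ~ "separated",
      .data$phase == "together" ~ "together",
      TRUE ~ "unresolved"
    ))
  genes <- df |> distinct(.data$gene, .data$order) |> arrange(.data$order)
  df$gene <- factor(df$gene, levels = genes$gene)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$pair_id,
                                   fill = .data$state)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(
      "separated (supported)" = "#74301C", "separated" = "#C86A4A",
      "together" = "#3C7DC4", "unresolved" = "grey85"
    )) +
    ggplot2::labs(x = NULL, y = NULL, fill = "allele phase") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
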