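#' Heatmap of per-cell pathway enrichment
#'
#' Tiles cells by pathways, coloured by -log10 of the one-tailed
#' enrichment p-value.
#'
#' @param tbl Output of [per_cell_pathway_test()].
#' @param cap Upper cap on -log10(p) for the colour scale.
#' @return A ggplot object.
#' @export
plot_cell_pathway <- function(tbl, cap = 10) {
  stopifnot(all(c("cell", "pathway", "p") %in% names(tbl)))
  dat <- dplyr::mutate(
    tbl, neglogp = pmin(-log10(pmax(.data$p, 1e-300)), cap)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cell, y = .data$pathway,
                                    fill = .data$neglogp)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10] * p)) +
    ggplot2::labs(x = "cell", y = "pathway") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Cumulative gain/loss frequency profile plot
#'
#' Per-group genome-wide track: gain percentages plotted upwards, loss
#' percentages downwards, bins in genomic order faceted by chromosome.
#'
#' @param profile Output of [cumulative_frequency()].
#' @return A ggplot object.
#' @export
plot_frequency_profile <- function(profile) {
  stopifnot(all(c("group", "chrom", "start", "gain_pct", "loss_pct") %in%
                  names(profile)))
  dat <- profile |>
    dplyr::mutate(mid = (.data$start + .data$end) / 2) |>
    tidyr::pivot_longer(c("gain_pct", "loss_pct"), names_to = "type",
                        values_to = "pct") |>
    dplyr::mutate(
      type = sub("_pct", "", .data$type),
      signed = ifelse(.data$type == "gain", .data$pct, -.data$pct)
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mid, y = .data$signed,
                                    fill = .data$type)) +
    ggplot2::geom_col(width = NA) +
    ggplot2::facet_grid(group ~ chrom, scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_fill_manual(values = c(gain = "#c0392b",
                                          loss = "#2980b9")) +
    ggplot2::labs(x = "genomic position", y = "% cells with aberration") +
    ggplot2::theme_minimal()
}

#' Concordance grid plot
#'
#' Tile plot of the non-centered fold-change correlation for every
#' (stimulation, lineage) signature pair, annotated with the number of
#' common differential genes.
#'
#' @param grid Output of [concordance_grid()].
#' @return A ggplot object.
#' @export
plot_concordance_grid <- function(grid) {
  stopifnot(all(c("stim", "lineage", "nc_cor", "num") %in% names(grid)))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$lineage, y = .data$stim,
                                     fill = .data$nc_cor)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$num), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "Nc cor") +
    ggplot2::labs(x = "lineage contrast", y = "stimulation contrast") +
    ggplot2::theme_minimal()
}
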