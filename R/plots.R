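#' Plot a linear gene-order map
#'
#' Draws the linearized gene order as a row of tiles, heavy-strand
#' features above the axis and light-strand features below, coloured by
#' feature class — the usual linear mitogenome-map style.
#'
#' @param order A `gene_order`.
#' @param title Optional plot title.
#' @return A `ggplot` object.
#' @export
plot_gene_order <- function(order, title = NULL) {
  df <- dplyr::mutate(
    tibble::as_tibble(order),
    y = ifelse(.data$orientation == "+", 1, -1)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$y / 2,
                                   fill = .data$feature_class)) +
    ggplot2::geom_tile(height = 0.9, width = 0.92, colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), angle = 90,
                       size = 2.6) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_y_continuous(breaks = c(-0.5, 0.5),
                                labels = c("L strand", "H strand"),
                                limits = c(-1.1, 1.1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "class", title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' @rdname plot_gene_order
#' @param object A `gene_order` (autoplot method).
#' @param ... Unused.
#' @method autoplot gene_order
#' @export
autoplot.gene_order <- function(object, ...) plot_gene_order(object)

#' Plot a control-region annotation
#'
#' Domains as background bands, motif hits as labelled ticks, repeat
#' arrays and any embedded tRNA-Pro as segments — a compact one-line map
#' of the control region's structural features.
#'
#' @param annotation A `cr_annotation` from [cr_profile()].
#' @return A `ggplot` object.
#' @export
plot_cr_annotation <- function(annotation) {
  dom <- dplyr::mutate(annotation$domains,
                       label = paste0("Domain ", .data$domain))
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = dom,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -0.5, ymax = 0.5, fill = .data$label),
      alpha = 0.25) +
    ggplot2::labs(x = "position (bp)", y = NULL, fill = NULL) +
    ggplot2::scale_y_continuous(limits = c(-1.5, 1.6), breaks = NULL) +
    ggplot2::theme_minimal()
  if (nrow(annotation$motifs) > 0) {
    p <- p + ggplot2::geom_segment(
      data = annotation$motifs,
      ggplot2::aes(x = .data$start, xend = .data$end, y = 0.7, yend = 0.7),
      linewidth = 2) +
      ggplot2::geom_text(
        data = annotation$motifs,
        ggplot2::aes(x = (.data$start + .data$end) / 2, y = 1,
                     label = .data$motif),
        size = 2.6, angle = 45)
  }
  if (nrow(annotation$repeats) > 0) {
    p <- p + ggplot2::geom_segment(
      data = annotation$repeats,
      ggplot2::aes(x = .data$start, xend = .data$end, y = -0.8, yend = -0.8,
                   colour = .data$kind),
      linewidth = 2.5) +
      ggplot2::labs(colour = "repeat")
  }
  if (!is.null(annotation$trnp)) {
    p <- p + ggplot2::annotate("segment", x = annotation$trnp[1],
                               xend = annotation$trnp[2], y = -1.2,
                               yend = -1.2, linewidth = 3) +
      ggplot2::annotate("text", x = mean(annotation$trnp), y = -1.45,
                        label = "trnP", size = 3)
  }
  p
}

#' @rdname plot_cr_annotation
#' @param object A `cr_annotation` (autoplot method).
#' @param ... Unused.
#' @method autoplot cr_annotation
#' @export
autoplot.cr_annotation <- function(object, ...) plot_cr_annotation(object)

#' Plot rearrangement events on the tree
#'
#' Draws the rooted tree and marks branches carrying mapped events with
#' the character and state transition.
#'
#' @param events An `event_map` from [map_events()].
#' @param cex Tip-label size passed to the tree plot.
#' @return Invisibly, the event tibble drawn.
#' @export
plot_event_map <- function(events, cex = 0.7) {
  ape::plot.phylo(events$tree, cex = cex, no.margin = TRUE)
  ev <- events$events
  if (nrow(ev) > 0) {
    lab <- paste0(ev$character, ": ", ev$from, ">", ev$to)
    ape::edgelabels(text = lab,
                    edge = match(ev$node, events$tree$edge[, 2]),
                    frame = "rect", cex = cex * 0.85, bg = "lightyellow")
  }
  invisible(ev)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
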