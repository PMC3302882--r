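#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Dendrogram segments from an hclust-style merge tree
#' @noRd
dendrogram_segments <- function(hc) {
  n <- length(hc$labels)
  xpos <- numeric(n - 1L)
  leaf_x <- match(seq_len(n), hc$order)
  segs <- vector("list", n - 1L)
  for (r in seq_len(n - 1L)) {
    child_xy <- vapply(hc$merge[r, ], function(id) {
      if (id < 0L) c(leaf_x[-id], 0) else c(xpos[id], hc$height[id])
    }, numeric(2))
    xpos[r] <- mean(child_xy[1L, ])
    segs[[r]] <- tibble::tibble(
      x = c(child_xy[1L, 1L], child_xy[1L, 1L], child_xy[1L, 2L]),
      xend = c(child_xy[1L, 1L], child_xy[1L, 2L], child_xy[1L, 2L]),
      y = c(child_xy[2L, 1L], hc$height[r], hc$height[r]),
      yend = c(hc$height[r], hc$height[r], child_xy[2L, 2L]),
      level = attr(hc, "merge_level")[r] %||% "merge"
    )
  }
  dplyr::bind_rows(segs)
}

#' Plot a DBHT dendrogram coloured by hierarchy level
#'
#' Draws the three-level merge tree: intra-bubble merges at the bottom,
#' then intra-cluster, then inter-cluster, each in its own colour.
#'
#' @param object A `dbht` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dbht
#' @export
autoplot.dbht <- function(object, ...) {
  segs <- dendrogram_segments(object$hierarchy)
  segs$level <- factor(
    segs$level,
    levels = c("intra_bubble", "intra_cluster", "inter_cluster")
  )
  ggplot2::ggplot(segs, ggplot2::aes(
    x = .data$x, xend = .data$xend,
    y = .data$y, yend = .data$yend,
    colour = .data$level
  )) +
    ggplot2::geom_segment(linewidth = 0.3) +
    ggplot2::labs(
      x = NULL, y = "merge height (offset by level)",
      colour = "hierarchy level"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      panel.grid.major.x = ggplot2::element_blank()
    )
}

#' Plot the PMFG with cluster colours
#'
#' Force-directed layout of the planar graph, vertices coloured by discrete
#' DBHT cluster.
#'
#' @param fit A `dbht` fit.
#' @param seed Layout seed (layout only; the fit is deterministic).
#' @return A ggplot object.
#' @export
plot_pmfg <- function(fit, seed = 1L) {
  stopifnot(inherits(fit, "dbht"))
  ig <- pmfg_igraph(fit$pmfg)
  xy <- with_seed(seed, igraph::layout_with_fr(ig))
  nodes <- tibble::tibble(
    x = xy[, 1L], y = xy[, 2L],
    cluster = factor(fit$clusters$labels)
  )
  edges <- tibble::tibble(
    x = xy[fit$pmfg$edges$i, 1L], y = xy[fit$pmfg$edges$i, 2L],
    xend = xy[fit$pmfg$edges$j, 1L], yend = xy[fit$pmfg$edges$j, 2L]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      colour = "grey75", linewidth = 0.2
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$cluster),
      size = 2
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "cluster")
}

#' @importFrom rlang .data
NULL
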