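#' Plot the landscape as a filled height map
#'
#' Renders the pseudo-potential over developmental time (vertical) and the
#' angular cell-state coordinate (horizontal), with optional cell balls.
#'
#' @param object A [build_landscape()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.landscape_surface <- function(object, ...) {
  p <- ggplot2::ggplot(object$surface,
                       ggplot2::aes(x = .data$x, y = .data$t,
                                    fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "cividis", direction = -1,
                                  name = "pseudo-potential U") +
    ggplot2::labs(x = "angular coordinate (radians)",
                  y = "developmental time log2(stage)")
  if (!is.null(object$cells)) {
    p <- p + ggplot2::geom_point(
      data = object$cells,
      ggplot2::aes(x = .data$x, y = .data$t), inherit.aes = FALSE,
      shape = 21, fill = "white", size = 1.2, alpha = 0.7)
  }
  p
}

#' Plot a phase-space force field
#'
#' Arrows show the direction of motion in TF (or cluster-total)
#' concentration space; short red arrows mark slow, stable regions and long
#' violet arrows fast transient ones.
#'
#' @param object A [force_field()] result.
#' @param arrow_scale Multiplier applied to the (normalised) arrows.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.force_field <- function(object, arrow_scale = 0.08, ...) {
  two_tf <- "u" %in% names(object)
  df <- as_tibble(object)
  if (two_tf) {
    df$a <- df$u; df$b <- df$v; df$da <- df$du; df$db <- df$dv
    labs <- c("u (TF 1)", "v (TF 2)")
  } else {
    df$a <- df$x; df$b <- df$y; df$da <- df$dx; df$db <- df$dy
    labs <- c("x = u1 + u2 (cluster 1 total)", "y = v1 + v2 (cluster 2 total)")
  }
  len <- sqrt(df$da^2 + df$db^2)
  len[len == 0] <- 1
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$a + arrow_scale * .data$da / len,
                   yend = .data$b + arrow_scale * .data$db / len,
                   colour = .data$speed),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.02, "npc"))) +
    ggplot2::scale_colour_viridis_c(option = "plasma", name = "speed") +
    ggplot2::labs(x = labs[1], y = labs[2])
}

#' Plot a gene coexpression heatmap
#'
#' Tiles the Spearman correlation matrix with genes in dendrogram leaf
#' order, reproducing the clustered-heatmap view of the TF modules.
#'
#' @param object A [spearman_matrix()] result.
#' @param clusters Optional [cluster_genes()] result providing the leaf
#'   ordering; without it genes keep input order.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_matrix <- function(object, clusters = NULL, ...) {
  ord <- if (!is.null(clusters)) attr(clusters, "ordering")
         else seq_along(object$genes)
  lv <- object$genes[ord]
  df <- tidy(object)
  df$gene1 <- factor(df$gene1, levels = lv)
  df$gene2 <- factor(df$gene2, levels = lv)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene1, y = .data$gene2,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1),
                                  name = "Spearman rho") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1,
                                                       size = 6),
                   axis.text.y = ggplot2::element_text(size = 6)) +
    ggplot2::labs(x = NULL, y = NULL)
}
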