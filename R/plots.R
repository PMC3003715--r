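#' Plot an eBURST graph
#'
#' SLV edges solid, DLV edges dotted; founders highlighted; node size
#' proportional to isolate count.
#'
#' @param object An [eburst()] result.
#' @param seed Layout seed (Fruchterman-Reingold).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eburst <- function(object, seed = 1L, ...) {
  nodes <- object$nodes
  g <- igraph::graph_from_data_frame(
    object$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = as.character(nodes$ST)))
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  edges <- object$edges %>%
    dplyr::mutate(
      x = nodes$x[match(.data$from, nodes$ST)],
      y = nodes$y[match(.data$from, nodes$ST)],
      xend = nodes$x[match(.data$to, nodes$ST)],
      yend = nodes$y[match(.data$to, nodes$ST)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$type),
      colour = "grey40") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$n_isolates,
                   colour = factor(.data$complex))) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y,
                   label = paste0("ST", .data$ST,
                                  ifelse(.data$founder, "*", ""))),
      vjust = -1, size = 3) +
    ggplot2::scale_linetype_manual(values = c(slv = "solid", dlv = "dotted")) +
    ggplot2::labs(colour = "complex", size = "isolates",
                  caption = "* founder") +
    ggplot2::theme_void()
}

#' Plot the null distribution of an I_A^S permutation test
#'
#' @param object An [ias_test()] result.
#' @param ... Unused.
#' @return A ggplot: histogram of permuted V_D with the observed value.
#' @export
autoplot.ias_test <- function(object, ...) {
  ggplot2::ggplot(tibble(V_D = object$null_V_D),
                  ggplot2::aes(x = .data$V_D)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed$V_D,
                        colour = "red", linewidth = 1) +
    ggplot2::labs(x = "permuted V_D",
                  title = sprintf("I_A^S = %.3f, p = %.3g",
                                  object$observed$ias, object$p_value))
}

#' Heatmap of pairwise Dice similarities
#'
#' @param object A [dice_matrix()] result.
#' @param ... Unused.
#' @return A ggplot tile heatmap of S_D.
#' @export
autoplot.dice_matrix <- function(object, ...) {
  s <- object$similarity
  long <- as_tibble(s, rownames = "strain_a") %>%
    tidyr::pivot_longer(-"strain_a", names_to = "strain_b",
                        values_to = "S_D")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$strain_a, y = .data$strain_b,
                                     fill = .data$S_D)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 0.6, low = "white",
                                  mid = "steelblue1", high = "navy",
                                  limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(S[D])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Per-locus diversity plot
#'
#' Bars of per-locus nucleotide diversity with pi_MAX markers, from a
#' [neutrality_scan()] table.
#'
#' @param scan A tibble from [neutrality_scan()].
#' @return A ggplot object.
#' @export
plot_locus_diversity <- function(scan) {
  d <- scan[scan$sequence != "concatenate", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sequence)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$pi), fill = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$pi - .data$pi_sd, 0),
                                        ymax = .data$pi + .data$pi_sd),
                           width = 0.2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$pi_max), shape = 17, size = 3) +
    ggplot2::labs(x = "locus", y = "% diversity",
                  caption = "bars: pi (+/- SD); triangles: pi_MAX") +
    ggplot2::theme_minimal()
}
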