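#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_tile
#'   geom_text labs theme_minimal scale_fill_gradient2 facet_wrap
#'   geom_abline coord_equal
#' @export
ggplot2::autoplot

#' Scatter plot of the first two shape principal components
#'
#' @param object a [shape_pca()] model
#' @param groups optional named vector taxon -> group used for colour
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.shape_pc_model <- function(object, groups = NULL, ...) {
  df <- tibble::tibble(
    taxon = rownames(object$scores),
    PC1 = object$scores[, 1],
    PC2 = if (ncol(object$scores) >= 2) object$scores[, 2] else 0
  )
  pct <- 100 * object$eigenvalues / sum(object$eigenvalues)
  if (!is.null(groups)) df$group <- unname(groups[df$taxon])
  p <- ggplot(df, if (is.null(groups)) aes(.data$PC1, .data$PC2) else
    aes(.data$PC1, .data$PC2, colour = .data$group)) +
    geom_point(size = 2) +
    ggplot2::geom_text(aes(label = .data$taxon), vjust = -0.8, size = 2.7,
                       show.legend = FALSE) +
    labs(x = sprintf("PC1 (%.1f%%)", pct[1]),
         y = if (length(pct) >= 2) sprintf("PC2 (%.1f%%)", pct[2]) else "PC2") +
    theme_minimal()
  p
}

#' Branch excess-change rates
#'
#' Dot plot of per-branch rates `R`, coloured by clade, with the neutral
#' reference line at `R = 1`.
#'
#' @param object a `branch_rate_table`
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.branch_rate_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$child_label <- stats::reorder(df$child_label, df$R)
  ggplot(df, aes(.data$R, .data$child_label, colour = .data$clade,
                 shape = .data$terminal)) +
    geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    labs(x = "excess change (observed / expected distance)", y = NULL,
         shape = "terminal branch") +
    theme_minimal()
}

#' Rate-correlation heatmap
#'
#' Tile plot of Pearson correlations between regional branch rates,
#' faceted by stratum (combined sample and each clade), with significance
#' stars.
#'
#' @param object a [rate_correlations()] table
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.rate_correlations <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot(df, aes(.data$region_a, .data$region_b, fill = .data$r)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f%s", .data$r, .data$stars)), size = 3) +
    scale_fill_gradient2(limits = c(-1, 1)) +
    facet_wrap(~stratum) +
    labs(x = NULL, y = NULL, fill = "r") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Allometry fit plot
#'
#' Shape score along the fitted allometric axis against log centroid size.
#'
#' @param object an [phylo_allometry_fit()] object
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.allometry_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(.data$log_size, .data$allometric_score)) +
    geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::geom_text(aes(label = .data$taxon), vjust = -0.8, size = 2.7) +
    labs(x = "log centroid size", y = "allometric shape score",
         subtitle = sprintf("lambda = %g, R^2 = %.2f, p = %.3g",
                            object$lambda, object$r_squared, object$p_value)) +
    theme_minimal()
}

#' Rate-annotated phylogeny
#'
#' Plots the time tree with branch thickness and colour proportional to
#' the excess-change rate (base-graphics, via ape).
#'
#' @param tree an [ape::phylo] tree
#' @param rates a `branch_rate_table` for that tree
#' @param ... passed to [ape::plot.phylo()]
#' @return invisibly, the rate vector in edge order
#' @export
plot_rate_tree <- function(tree, rates, ...) {
  r <- rates$R[match(seq_len(nrow(tree$edge)), rates$edge)]
  cols <- ifelse(r > 1, "#2166ac", ifelse(r < 0.9, "#d9a441", "grey50"))
  ape::plot.phylo(tree, edge.width = pmax(0.5, 2.5 * r), edge.color = cols, ...)
  ape::edgelabels(sprintf("%.2f", r), frame = "none", cex = 0.6, adj = c(0.5, 1.3))
  invisible(r)
}
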