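#' Ordination plot for a PCoA result
#'
#' @param object [pcoa()] result.
#' @param groups optional grouping vector (one per sample) used for color.
#' @param axes which two axes to draw.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.netstab_pcoa <- function(object, groups = NULL, axes = c(1, 2),
                                  ...) {
  stopifnot(length(axes) == 2, max(axes) <= ncol(object$coordinates))
  df <- tibble(
    sample_id = object$sample_ids,
    x = object$coordinates[, axes[1]],
    y = object$coordinates[, axes[2]]
  )
  if (!is.null(groups)) df$group <- resolve_groups(groups, df$sample_id)
  lab <- function(i) sprintf("PCo%d (%.1f%%)", i,
                             100 * object$prop_explained[i])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::labs(x = lab(axes[1]), y = lab(axes[2])) +
    ggplot2::theme_minimal()
  if (is.null(groups)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
      ggplot2::stat_ellipse(ggplot2::aes(colour = .data$group),
                            show.legend = FALSE)
  }
}

#' Stacked-bar plot of assembly process fractions
#'
#' @param object [partition_processes()] result (or a named list of them, one
#'   per group).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.assembly_partition <- function(object, ...) {
  df <- object$fractions
  df$group <- "all"
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$fraction,
                                   fill = .data$process)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "fraction of sample pairs") +
    ggplot2::theme_minimal()
}

#' Zi-Pi scatter plot of node roles
#'
#' @param object [zipi()] table.
#' @param zi_threshold,pi_threshold guide lines (the role thresholds).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.node_roles <- function(object, zi_threshold = 2.5,
                                pi_threshold = 0.62, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$pi, .data$zi,
                                       colour = .data$role)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = zi_threshold, linetype = 2) +
    ggplot2::geom_vline(xintercept = pi_threshold, linetype = 2) +
    ggplot2::labs(x = "among-module connectivity (Pi)",
                  y = "within-module degree (Zi)") +
    ggplot2::theme_minimal()
}

#' Histogram of robustness replicates
#'
#' @param object [robustness()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.robustness_sim <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$proportion_remaining)) +
    ggplot2::geom_histogram(bins = 20) +
    ggplot2::geom_vline(xintercept = object$mean, linetype = 2) +
    ggplot2::labs(x = "proportion of taxa remaining", y = "replicates") +
    ggplot2::theme_minimal()
}
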