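# ggplot2 views of the main result types.

#' Plot an interaction profile
#'
#' Per-fragment values against the fragment midpoint, one panel per
#' chromosome. Differential profiles (and mean profiles carrying an `se`
#' column) get a +/- 1 SE ribbon.
#'
#' @param object An `interaction_profile`.
#' @param chrom Optional chromosome(s) to restrict to.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.interaction_profile <- function(object, chrom = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(chrom)) df <- df[df$chrom %in% chrom, ]
  df$mid <- (df$start + df$end) / 2
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$value))
  if ("se" %in% names(df)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$value - .data$se, ymax = .data$value + .data$se),
      fill = "grey70")
  }
  p +
    ggplot2::geom_step(colour = "#b2182b") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = sprintf("interactions per fragment (%s)", attr(object, "kind")),
                  title = attr(object, "viewpoint")) +
    ggplot2::theme_minimal()
}

#' Plot a dedup cluster-size histogram
#'
#' @param object A `dedup_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dedup_result <- function(object, ...) {
  ggplot2::ggplot(object$report$cluster_sizes,
                  ggplot2::aes(x = factor(.data$size), y = .data$n_clusters)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "reads per UMI cluster", y = "clusters",
                  title = sprintf("duplicate clusters (max wobble %d)",
                                  object$report$max_wobble)) +
    ggplot2::theme_minimal()
}

#' Plot counts against input mass
#'
#' Total probe counts per sample against input library mass, with the fitted
#' least-squares line per tissue; a quantitative assay is linear.
#'
#' @param object A `cstring_linearity` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cstring_linearity <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$input_mass, y = .data$count,
                               colour = .data$tissue)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "input mass", y = "total probe counts") +
    ggplot2::theme_minimal()
}
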