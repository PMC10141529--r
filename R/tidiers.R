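#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a deconvolution result into long format
#'
#' @param x A [tree_deconvolve()] result.
#' @param ... Unused.
#' @return Tibble with one row per (sample, cluster): `sample`, `cluster`,
#'   `proportion`.
#' @export
tidy.decon_result <- function(x, ...) {
  P <- x$proportions
  tibble::tibble(
    sample = rep(colnames(P), each = nrow(P)),
    cluster = rep(rownames(P), times = ncol(P)),
    proportion = as.numeric(P))
}

#' One-row summary of a deconvolution result
#'
#' @param x A [tree_deconvolve()] result.
#' @param ... Unused.
#' @return Tibble: `n_samples`, `n_clusters`, `n_markers_used`,
#'   `residual_sum`, `total_deviance`, `mean_deviance`, `n_zero_fits`.
#' @export
glance.decon_result <- function(x, ...) {
  tibble::tibble(
    n_samples = ncol(x$proportions),
    n_clusters = nrow(x$proportions),
    n_markers_used = x$gene_overlap$n_used,
    residual_sum = sum(x$diagnostics$residual_ss),
    total_deviance = sum(x$diagnostics$deviance),
    mean_deviance = mean(x$diagnostics$deviance),
    n_zero_fits = sum(x$diagnostics$zero_fit))
}

#' Stacked-bar plot of estimated cell-type proportions
#'
#' @param object A [tree_deconvolve()] result.
#' @param ... Unused.
#' @return A ggplot: one bar per sample, filled by cluster proportion.
#' @export
autoplot.decon_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$proportion,
                                  fill = .data$cluster)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "estimated proportion", fill = "cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Marker-score profile plot
#'
#' Scores of the selected markers per cluster, on a log10 axis — a quick
#' visual check that selected markers separate cleanly from the background.
#'
#' @param object A [select_all_markers()] result.
#' @param ... Unused.
#' @return A ggplot of score vs within-cluster rank, one facet per cluster.
#' @export
autoplot.marker_set <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "marker rank", y = "aggregated bootstrap score") +
    ggplot2::theme_minimal()
}

#' Tuning-grid recovery plot
#'
#' @param object A [tune_parameters()] result.
#' @param ... Unused.
#' @return A ggplot of Pearson recovery per grid point.
#' @export
autoplot.tuning_result <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$label <- sprintf("n_b=%d n_bs=%d [%d,%d]", d$n_b, d$n_bs, d$n_min,
                     d$n_max)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$label,
                                                     .data$pearson_r),
                                  y = .data$pearson_r)) +
    ggplot2::geom_point() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Pearson r (true vs estimated)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
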