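#' @importFrom ggplot2 autoplot
NULL

#' Plot a t-SNE embedding
#'
#' @param object a `meth_embedding`.
#' @param labels optional per-sample grouping (cluster labels, classes, ...).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.meth_embedding <- function(object, labels = NULL, ...) {
  df <- object$coords
  df$group <- if (is.null(labels)) "sample" else as.factor(labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a binned CNV profile
#'
#' Per-bin log2 copy-number ratios along the genome, colored by gain/loss
#' beyond the alteration threshold.
#'
#' @param profile tibble from [bin_profile()].
#' @param thresh |log2R| threshold used for coloring.
#' @return a ggplot object.
#' @export
plot_cnv_profile <- function(profile, thresh = 0.1) {
  df <- profile
  df$idx <- seq_len(nrow(df))
  df$state <- ifelse(df$log2r > thresh, "gain",
                     ifelse(df$log2r < -thresh, "loss", "neutral"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$log2r,
                                   colour = .data$state)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(values = c(gain = "firebrick",
                                            loss = "steelblue",
                                            neutral = "grey60")) +
    ggplot2::labs(x = "genomic bin", y = "log2R",
                  title = profile$sample_id[1]) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot stratified fidelity category counts
#'
#' @param report list from [fidelity_report()].
#' @return a ggplot object.
#' @export
plot_fidelity_summary <- function(report) {
  ggplot2::ggplot(report$counts,
                  ggplot2::aes(x = .data$stratum, y = .data$n,
                               fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~stratum_var, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(faithful = "#1b7837",
                                          useful = "#fdb863",
                                          unfaithful = "#762a83")) +
    ggplot2::labs(x = NULL, y = "cell lines", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Coordinates of an embedding as a tibble
#' @param x a `meth_embedding`.
#' @param ... unused.
#' @return the coordinate tibble.
#' @importFrom tibble as_tibble
#' @export
as_tibble.meth_embedding <- function(x, ...) x$coords

#' Labels of a cluster assignment as a tibble
#' @param x a `cluster_assignment`.
#' @param ... unused.
#' @return the label tibble.
#' @export
as_tibble.cluster_assignment <- function(x, ...) x$labels
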