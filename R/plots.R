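# ggplot2 views of the main result types.

#' Scatter plot of a 2-D gene embedding
#'
#' @param embedding Tibble `gene_id`, `dim1`, `dim2`.
#' @param colour_by Optional tibble `gene_id` + one value column (e.g. tsp
#'   or archetype) used to colour points.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, colour_by = NULL) {
  df <- embedding
  mapping <- ggplot2::aes(x = .data$dim1, y = .data$dim2)
  if (!is.null(colour_by)) {
    val <- setdiff(names(colour_by), "gene_id")[1]
    df <- dplyr::left_join(df, colour_by[c("gene_id", val)], by = "gene_id")
    mapping <- ggplot2::aes(x = .data$dim1, y = .data$dim2,
                            colour = .data[[val]])
  }
  ggplot2::ggplot(df, mapping) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "dimension 1", y = "dimension 2")
}

#' @describeIn plot_embedding Autoplot of a clustered embedding, coloured
#'   by DBSCAN group (noise in grey).
#' @param object A `gene_clusters` tibble.
#' @param ... Unused.
#' @export
autoplot.gene_clusters <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      group = factor(.data$cluster))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_discrete(na.value = "grey70") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "dimension 1", y = "dimension 2",
                  colour = "DBSCAN group")
}

#' ROC curve of a fitted classifier
#' @param object A `testis_gbt`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.testis_gbt <- function(object, ...) {
  ggplot2::ggplot(object$roc_curve,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("%s (AUC = %.4f)", object$rule, object$auc))
}

#' Positional distribution of motif hits around the TSS
#'
#' Two panels in one plot: the overall histogram and the strand-resolved
#' breakdown (sense vs antisense), as counts per bin.
#'
#' @param dist Tibble from [positional_distribution()].
#' @return A ggplot object.
#' @export
plot_positional_distribution <- function(dist) {
  long <- tidyr::pivot_longer(dist, c("total", "sense", "antisense"),
                              names_to = "strand", values_to = "count")
  long$panel <- ifelse(long$strand == "total", "overall", "by strand")
  long$panel <- factor(long$panel, levels = c("overall", "by strand"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin_mid, y = .data$count,
                                     fill = .data$strand)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "offset from TSS (nt)", y = "hits")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
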