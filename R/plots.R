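# ggplot2 visualizations of the result objects

#' Consensus-matrix heat map
#'
#' @param object An `sdt_consensus` object.
#' @param ... Unused.
#' @return A ggplot; samples ordered by the consensus dendrogram.
#' @method autoplot sdt_consensus
#' @export
autoplot.sdt_consensus <- function(object, ...) {
  ord <- object$hclust$labels[object$hclust$order]
  df <- tidy(object)
  df2 <- dplyr::bind_rows(
    df,
    dplyr::rename(df, sample_1 = "sample_2", sample_2 = "sample_1"),
    tibble::tibble(sample_1 = ord, sample_2 = ord, consensus = 1)
  )
  df2$sample_1 <- factor(df2$sample_1, levels = ord)
  df2$sample_2 <- factor(df2$sample_2, levels = ord)
  ggplot2::ggplot(df2, ggplot2::aes(.data$sample_1, .data$sample_2,
                                    fill = .data$consensus)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "consensus",
                  title = sprintf("Consensus (rank %d, %d runs)",
                                  object$rank, object$n_runs)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Rank-diagnostics profile
#'
#' PAC (to minimize) and cophenetic correlation (to maximize) against the
#' candidate rank, with the selected rank marked.
#'
#' @param object An `sdt_rank` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sdt_rank
#' @export
autoplot.sdt_rank <- function(object, ...) {
  df <- tidyr::pivot_longer(object$diagnostics, c("pac", "cophenetic"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$value,
                                   color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$rank, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = object$diagnostics$rank) +
    ggplot2::labs(x = "NMF rank", y = NULL,
                  title = sprintf("Rank diagnostics (selected: %d)",
                                  object$rank)) +
    ggplot2::theme_minimal()
}

#' Silhouette plot of a classification
#'
#' Per-sample silhouette bars by cluster, colored by final label, with
#' the per-cluster acceptance thresholds drawn as dashed lines.
#'
#' @param object An `sdt_classification` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sdt_classification
#' @export
autoplot.sdt_classification <- function(object, ...) {
  df <- tidy(object)
  df <- dplyr::arrange(df, .data$cluster, dplyr::desc(.data$silhouette))
  df$sample_id <- factor(df$sample_id, levels = df$sample_id)
  thr <- attr(object, "thresholds")
  thr_df <- tibble::tibble(cluster = names(thr), threshold = unname(thr))
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$silhouette,
                                   fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(data = thr_df,
                        ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::facet_grid(. ~ cluster, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "silhouette") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}
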