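#' Plot the training loss history
#'
#' @param object a `mmd_autoencoder`.
#' @param ... unused.
#' @return a ggplot: reconstruction, transfer and total loss per epoch.
#' @export
autoplot.mmd_autoencoder <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("recon", "transfer", "total"),
                           names_to = "loss", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (log scale)",
                  title = "Autoencoder training history")
}

#' Heatmap of cross-batch cluster similarities
#'
#' @param object a `cluster_similarity` at any stage.
#' @param ... unused.
#' @return a ggplot tile map of the similarity matrix.
#' @export
autoplot.cluster_similarity <- function(object, ...) {
  tab <- tidy(object)
  if (object$stage == "binary") tab$score <- as.numeric(tab$aligned)
  tab$from <- paste(tab$batch_a, tab$cluster_a, sep = "|")
  tab$to <- paste(tab$batch_b, tab$cluster_b, sep = "|")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$from, y = .data$to,
                                    fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(title = sprintf("Cluster similarity (stage %s)",
                                  object$stage),
                  x = NULL, y = NULL, fill = "score") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Scatter plot of a 2D embedding colored by batch and cell type
#'
#' @param embedding tibble with columns z1, z2, batch, cell_type (e.g. from
#'   [code_table()]), or an `mmd_run`.
#' @param colour `"cell_type"` (default) or `"batch"`.
#' @return a ggplot.
#' @export
plot_embedding <- function(embedding, colour = c("cell_type", "batch")) {
  colour <- match.arg(colour)
  if (inherits(embedding, "mmd_run")) embedding <- embedding$embedding
  stopifnot(all(c("z1", "z2", "batch") %in% names(embedding)))
  ggplot2::ggplot(embedding,
                  ggplot2::aes(x = .data$z1, y = .data$z2,
                               colour = .data[[colour]],
                               shape = .data$batch)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::labs(x = "code 1", y = "code 2", colour = colour)
}
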