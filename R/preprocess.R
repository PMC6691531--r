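#' Preprocessing configuration
#'
#' @param n_hvg number of highly variable genes to keep (default 2000).
#' @param n_bins number of equal-count mean-expression bins used when
#'   z-scoring gene dispersions (default 20).
#' @param sd_convention `"sample"` (divisor n-1, default) or `"population"`.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(n_hvg = 2000, n_bins = 20,
                              sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  if (n_hvg < 1) stop("n_hvg must be >= 1", call. = FALSE)
  structure(list(n_hvg = as.integer(n_hvg), n_bins = as.integer(n_bins),
                 sd_convention = sd_convention),
            class = "preprocess_config")
}

#' Library-size normalization to counts-per-million
#'
#' Rescales every cell (column) to sum to 1e6. With UMI-style or simulated
#' data there are no gene lengths, so CPM stands in for TPM; the downstream
#' log/standardize/scale steps are invariant to this distinction gene-wise.
#'
#' @param batch an `expression_batch` at stage `"counts"`.
#' @return the batch at stage `"tpm"`.
#' @export
to_tpm <- function(batch) {
  stopifnot_stage(batch, "counts", "to_tpm")
  tot <- colSums(batch$values)
  zero <- tot == 0
  if (any(zero)) {
    warning(sprintf("%d all-zero cell(s) left unnormalized", sum(zero)),
            call. = FALSE)
    tot[zero] <- 1
  }
  batch$values <- sweep(batch$values, 2, tot / 1e6, "/")
  batch$stage <- "tpm"
  batch
}

#' Log transform: G = log2(TPM + 1)
#'
#' @param batch an `expression_batch` at stage `"tpm"` with nonnegative values.
#' @return the batch at stage `"log"`.
#' @export
log_transform <- function(batch) {
  stopifnot_stage(batch, "tpm", "log_transform")
  if (any(batch$values < 0))
    stop("log_transform requires nonnegative values", call. = FALSE)
  batch$values <- log2(batch$values + 1)
  batch$stage <- "log"
  batch
}

# dispersion z-scores for one batch: bin genes by mean expression into
# equal-count bins, z-score var/mean dispersion within each bin
dispersion_z <- function(values, n_bins) {
  mu <- rowMeans(values)
  v <- apply(values, 1, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  n_bins <- max(1L, min(n_bins, length(mu)))
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = n_bins, labels = FALSE, include.lowest = TRUE)
  z <- numeric(length(mu))
  for (b in unique(bins)) {
    idx <- bins == b
    m <- mean(disp[idx]); s <- stats::sd(disp[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - m) / s
  }
  z
}

#' Select highly variable genes across batches
#'
#' Per batch, genes are binned into `n_bins` equal-count bins by mean
#' log-expression and the variance/mean dispersion is z-scored within each
#' bin; genes are ranked by the mean z-score across batches and the top
#' `n_hvg` returned (in ranked order).
#'
#' @param batches list of `expression_batch` at stage `"log"` sharing genes.
#' @param config a [preprocess_config()].
#' @return character vector of selected gene IDs.
#' @export
select_hvg <- function(batches, config = preprocess_config()) {
  check_batch_list(batches)
  for (b in batches) stopifnot_stage(b, "log", "select_hvg")
  z <- rowMeans(vapply(batches, function(b) dispersion_z(b$values, config$n_bins),
                       numeric(length(batches[[1]]$gene_ids))))
  genes <- batches[[1]]$gene_ids
  if (config$n_hvg >= length(genes)) {
    if (config$n_hvg > length(genes))
      warning("n_hvg exceeds the number of genes; returning all genes",
              call. = FALSE)
    return(genes[order(-z)])
  }
  genes[order(-z)][seq_len(config$n_hvg)]
}

#' Restrict batches to a gene list
#'
#' @param batches list of `expression_batch`.
#' @param genes character vector of gene IDs to keep, in order.
#' @return list of batches restricted to `genes`.
#' @export
restrict_genes <- function(batches, genes) {
  check_batch_list(batches)
  missing <- setdiff(genes, batches[[1]]$gene_ids)
  if (length(missing))
    stop(sprintf("gene(s) not present: %s", paste(utils::head(missing, 3),
                                                  collapse = ", ")),
         call. = FALSE)
  lapply(batches, function(b) {
    b$values <- b$values[match(genes, b$gene_ids), , drop = FALSE]
    b$gene_ids <- genes
    b
  })
}

#' Standardize each gene within a batch
#'
#' G' = (G - mean) / sd, computed gene-wise within the batch. Constant genes
#' (sd = 0) map to 0.
#'
#' @param batch an `expression_batch` at stage `"log"`.
#' @param sd_convention `"sample"` (n-1 divisor, default) or `"population"`.
#' @return list with elements `batch` (stage `"standardized"`) and `stats`
#'   (tibble: batch, gene_id, mean, sd).
#' @export
standardize <- function(batch, sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  stopifnot_stage(batch, "log", "standardize")
  n <- ncol(batch$values)
  if (n < 2)
    stop("standardize requires at least 2 cells per batch", call. = FALSE)
  mu <- rowMeans(batch$values)
  ss <- rowSums((batch$values - mu)^2)
  sdv <- sqrt(ss / if (sd_convention == "sample") n - 1 else n)
  denom <- ifelse(sdv > 0, sdv, 1)
  batch$values <- (batch$values - mu) / denom
  batch$values[sdv == 0, ] <- 0
  batch$stage <- "standardized"
  bid <- batch$batch_id
  gid <- batch$gene_ids
  list(batch = batch,
       stats = tibble::tibble(batch = bid, gene_id = gid,
                              mean = unname(mu), sd = unname(sdv)))
}

#' Min-max scale genes to [0, 1] pooled across batches
#'
#' Per gene, the min and max are taken over all cells of all batches, so the
#' batches end on one common scale for a single autoencoder. Constant genes
#' map to 0.
#'
#' @param batches list of `expression_batch` at stage `"standardized"`.
#' @return list of batches at stage `"scaled"`.
#' @export
minmax_scale <- function(batches) {
  check_batch_list(batches)
  for (b in batches) stopifnot_stage(b, "standardized", "minmax_scale")
  pooled <- do.call(cbind, lapply(batches, function(b) b$values))
  lo <- apply(pooled, 1, min)
  hi <- apply(pooled, 1, max)
  rng <- hi - lo
  denom <- ifelse(rng > 0, rng, 1)
  lapply(batches, function(b) {
    b$values <- (b$values - lo) / denom
    b$values[rng == 0, ] <- 0
    b$stage <- "scaled"
    b
  })
}

#' Full preprocessing pipeline
#'
#' Composes CPM normalization (if the input is counts), log2(x+1),
#' highly-variable-gene selection, restriction to those genes, per-batch
#' standardization and pooled [0,1] scaling.
#'
#' @param batches list of `expression_batch` at stage `"counts"` or `"tpm"`.
#' @param config a [preprocess_config()].
#' @return list with `batches` (stage `"scaled"`, HVG rows), `log_batches`
#'   (stage `"log"`, same HVG rows; used for the rank-correlation similarity
#'   network, which must not see the per-batch standardization), `genes`
#'   (selected gene IDs) and `gene_stats` (standardization audit tibble).
#' @export
preprocess_pipeline <- function(batches, config = preprocess_config()) {
  check_batch_list(batches)
  batches <- lapply(batches, function(b)
    if (b$stage == "counts") to_tpm(b) else b)
  for (b in batches) stopifnot_stage(b, "tpm", "preprocess_pipeline")
  batches <- lapply(batches, log_transform)
  genes <- select_hvg(batches, config)
  batches <- restrict_genes(batches, genes)
  std <- lapply(batches, standardize, sd_convention = config$sd_convention)
  scaled <- minmax_scale(lapply(std, `[[`, "batch"))
  names(scaled) <- names(batches) <- vapply(batches, `[[`, character(1),
                                            "batch_id")
  list(batches = scaled, log_batches = batches, genes = genes,
       gene_stats = dplyr::bind_rows(lapply(std, `[[`, "stats")))
}
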