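#' Configuration for the projected 2D Gaussian simulator
#'
#' Cells live in a two-dimensional biological subspace where each cell type is
#' a bivariate normal; all batches share one random linear projection to
#' `ambient_dim` "genes", and batch effects are added in the ambient space as
#' gene-specific offsets plus per-entry noise.
#'
#' @param n_batches number of batches (default 2).
#' @param cells_per_batch cells per batch; scalar or one value per batch
#'   (default 2000).
#' @param n_types number of cell types (default 4).
#' @param type_means list of 2-vectors, one per type. The default (0,5),
#'   (5,0), (-5,0), (-4,-6) makes every type a distinct correlation archetype
#'   after projection (no two types share a direction from the origin), puts
#'   the extreme labels Type1/Type4 in near-opposite directions, and is
#'   deliberately asymmetric: no isometry of the subspace fixes two types
#'   while swapping the other two, so an encoder cannot satisfy alignment
#'   constraints on two types by mirroring the plane and collapsing the rest.
#'   Further types go on a ring of radius 10.
#' @param type_covs list of 2x2 positive-definite matrices (default identity).
#' @param composition_mode `"random"` (per-batch Dirichlet(1,...,1) type
#'   proportions) or `"fixed"`.
#' @param proportions type proportions used when `composition_mode = "fixed"`:
#'   a single vector shared by all batches or a list with one vector per
#'   batch; each must sum to 1.
#' @param ambient_dim ambient ("gene") dimension after projection (default 100).
#' @param batch_offset_sd sd of the gene-specific per-batch offsets (default 1).
#' @param batch_noise_sd sd of the per-entry Gaussian noise (default 0.1).
#' @param seed integer RNG seed.
#' @return list of class `gaussian_sim_config`.
#' @export
gaussian_sim_config <- function(n_batches = 2, cells_per_batch = 2000,
                                n_types = 4, type_means = NULL,
                                type_covs = NULL,
                                composition_mode = c("random", "fixed"),
                                proportions = NULL, ambient_dim = 100,
                                batch_offset_sd = 1, batch_noise_sd = 0.1,
                                seed = 1L) {
  composition_mode <- match.arg(composition_mode)
  if (ambient_dim < 2) stop("ambient_dim must be >= 2", call. = FALSE)
  if (batch_noise_sd < 0 || batch_offset_sd < 0)
    stop("noise sds must be nonnegative", call. = FALSE)
  if (is.null(type_means)) {
    base <- list(c(0, 5), c(5, 0), c(-5, 0), c(-4, -6))
    type_means <- lapply(seq_len(n_types), function(i) {
      if (i <= 4) base[[i]]
      else 10 * c(cos(2 * pi * (i - 4) / 7), sin(2 * pi * (i - 4) / 7))
    })
  }
  if (is.null(type_covs)) type_covs <- rep(list(diag(2)), n_types)
  if (length(type_means) != n_types || length(type_covs) != n_types)
    stop("type_means/type_covs must have one entry per type", call. = FALSE)
  for (S in type_covs) {
    S <- as.matrix(S)
    if (!all(dim(S) == 2) || any(abs(S - t(S)) > 1e-12) ||
        any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("every type covariance must be 2x2 positive definite", call. = FALSE)
  }
  if (composition_mode == "fixed") {
    if (is.null(proportions)) proportions <- rep(1 / n_types, n_types)
    if (!is.list(proportions)) proportions <- rep(list(proportions), n_batches)
    if (length(proportions) != n_batches)
      stop("need one proportion vector per batch", call. = FALSE)
    for (pv in proportions)
      if (length(pv) != n_types || abs(sum(pv) - 1) > 1e-8)
        stop("fixed proportions must be length n_types and sum to 1",
             call. = FALSE)
  }
  cells_per_batch <- rep_len(as.integer(cells_per_batch), n_batches)
  structure(list(n_batches = as.integer(n_batches),
                 cells_per_batch = cells_per_batch,
                 n_types = as.integer(n_types), type_means = type_means,
                 type_covs = lapply(type_covs, as.matrix),
                 composition_mode = composition_mode,
                 proportions = proportions,
                 ambient_dim = as.integer(ambient_dim),
                 batch_offset_sd = batch_offset_sd,
                 batch_noise_sd = batch_noise_sd, seed = as.integer(seed)),
            class = "gaussian_sim_config")
}

rmvnorm2 <- function(n, mean, sigma) {
  L <- chol(sigma)
  matrix(stats::rnorm(2 * n), n, 2) %*% L + rep(mean, each = n)
}

#' Simulate batches from a projected 2D Gaussian mixture
#'
#' Draws per-type cell counts (Dirichlet-multinomial when the composition is
#' random), samples each cell's 2D coordinate from its type's bivariate
#' normal, applies one shared random linear projection (entries N(0,1)) to the
#' ambient dimension, then adds batch-specific gene offsets and per-entry
#' noise and shifts all values to be nonnegative (TPM-like continuous data,
#' stage `"tpm"`). True 2D coordinates are returned for oracle checks.
#'
#' @param config a [gaussian_sim_config()].
#' @return list of class `sim_dataset`: `batches` (list of
#'   `expression_batch`), `true_subspace` (per-batch cells x 2 matrices),
#'   `config`.
#' @export
simulate_gaussian <- function(config = gaussian_sim_config()) {
  stopifnot(inherits(config, "gaussian_sim_config"))
  set.seed(config$seed)
  P <- matrix(stats::rnorm(2 * config$ambient_dim), 2, config$ambient_dim)
  genes <- sprintf("gene%03d", seq_len(config$ambient_dim))
  types <- paste0("Type", seq_len(config$n_types))
  batches <- vector("list", config$n_batches)
  subspace <- vector("list", config$n_batches)
  for (b in seq_len(config$n_batches)) {
    n <- config$cells_per_batch[b]
    prop <- if (config$composition_mode == "random") {
      g <- stats::rgamma(config$n_types, shape = 1)
      g / sum(g)
    } else config$proportions[[b]]
    counts <- as.vector(stats::rmultinom(1, n, prop))
    lab <- rep(types, counts)
    Y <- do.call(rbind, lapply(seq_len(config$n_types), function(t)
      if (counts[t] > 0)
        rmvnorm2(counts[t], config$type_means[[t]], config$type_covs[[t]])
      else matrix(0, 0, 2)))
    X <- Y %*% P
    offset <- stats::rnorm(config$ambient_dim, 0, config$batch_offset_sd)
    X <- X + rep(offset, each = n) +
      matrix(stats::rnorm(n * config$ambient_dim, 0, config$batch_noise_sd),
             n, config$ambient_dim)
    cells <- sprintf("b%d_c%04d", b, seq_len(n))
    batches[[b]] <- expression_batch(t(X), batch_id = paste0("Batch", b),
                                     gene_ids = genes, cell_ids = cells,
                                     stage = "tpm", cell_type_labels = lab)
    subspace[[b]] <- Y
  }
  # one shared shift so all batches stay on a common nonnegative scale
  lo <- min(vapply(batches, function(b) min(b$values), numeric(1)))
  batches <- lapply(batches, function(b) { b$values <- b$values - lo; b })
  names(batches) <- vapply(batches, `[[`, character(1), "batch_id")
  names(subspace) <- names(batches)
  structure(list(batches = batches, true_subspace = subspace, config = config),
            class = "sim_dataset")
}

#' Configuration for the gamma-Poisson count simulator
#'
#' A reduced Splatter-style hierarchy: gene base means are Gamma, a fraction
#' `de_prob` of genes gets a lognormal differential-expression factor per cell
#' group, every gene gets a lognormal factor per batch, cells get lognormal
#' library sizes, and counts are Poisson around the library-size-normalized
#' mean.
#'
#' @param n_batches number of batches (default 2).
#' @param cells_per_batch cells per batch (default `c(2000, 1000)`).
#' @param n_genes number of genes (default 1000).
#' @param group_proportions cell-group proportions (default 0.4/0.3/0.2/0.1).
#' @param gene_mean_shape,gene_mean_rate Gamma hyperparameters for gene base
#'   means (defaults 0.6, 0.3).
#' @param libsize_logmean,libsize_logsd lognormal library-size hyperparameters
#'   (defaults 11, 0.2).
#' @param de_prob probability a gene is differentially expressed per group
#'   (default 0.1).
#' @param de_factor_logsd lognormal scale of DE factors (default 0.4).
#' @param batch_factor_logsd lognormal scale of batch factors (default 0.2).
#' @param seed integer RNG seed.
#' @return list of class `count_sim_config`.
#' @export
count_sim_config <- function(n_batches = 2, cells_per_batch = c(2000, 1000),
                             n_genes = 1000,
                             group_proportions = c(0.4, 0.3, 0.2, 0.1),
                             gene_mean_shape = 0.6, gene_mean_rate = 0.3,
                             libsize_logmean = 11, libsize_logsd = 0.2,
                             de_prob = 0.1, de_factor_logsd = 0.4,
                             batch_factor_logsd = 0.2, seed = 1L) {
  if (n_genes < 1 || any(cells_per_batch < 1))
    stop("need at least one gene and one cell per batch", call. = FALSE)
  if (abs(sum(group_proportions) - 1) > 1e-12)
    stop("group_proportions must sum to 1", call. = FALSE)
  if (de_prob < 0 || de_prob > 1) stop("de_prob must be in [0,1]", call. = FALSE)
  if (gene_mean_shape <= 0 || gene_mean_rate <= 0 || libsize_logsd < 0 ||
      de_factor_logsd < 0 || batch_factor_logsd < 0)
    stop("scale parameters must be positive", call. = FALSE)
  cells_per_batch <- rep_len(as.integer(cells_per_batch), n_batches)
  structure(list(n_batches = as.integer(n_batches),
                 cells_per_batch = cells_per_batch,
                 n_genes = as.integer(n_genes),
                 group_proportions = group_proportions,
                 gene_mean_shape = gene_mean_shape,
                 gene_mean_rate = gene_mean_rate,
                 libsize_logmean = libsize_logmean,
                 libsize_logsd = libsize_logsd, de_prob = de_prob,
                 de_factor_logsd = de_factor_logsd,
                 batch_factor_logsd = batch_factor_logsd,
                 seed = as.integer(seed)),
            class = "count_sim_config")
}

#' Simulate multi-batch scRNA-seq counts (gamma-Poisson)
#'
#' @param config a [count_sim_config()].
#' @return A `sim_dataset` whose batches are at stage `"counts"`.
#' @export
simulate_counts <- function(config = count_sim_config()) {
  stopifnot(inherits(config, "count_sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  K <- length(config$group_proportions)
  genes <- sprintf("gene%04d", seq_len(G))
  types <- paste0("Type", seq_len(K))
  base_mean <- stats::rgamma(G, shape = config$gene_mean_shape,
                             rate = config$gene_mean_rate)
  de_factor <- matrix(1, G, K)
  for (k in seq_len(K)) {
    is_de <- stats::runif(G) < config$de_prob
    de_factor[is_de, k] <- stats::rlnorm(sum(is_de), 0, config$de_factor_logsd)
  }
  batch_factor <- matrix(stats::rlnorm(G * config$n_batches, 0,
                                       config$batch_factor_logsd),
                         G, config$n_batches)
  batches <- vector("list", config$n_batches)
  for (b in seq_len(config$n_batches)) {
    n <- config$cells_per_batch[b]
    grp <- sample.int(K, n, replace = TRUE, prob = config$group_proportions)
    lib <- stats::rlnorm(n, config$libsize_logmean, config$libsize_logsd)
    counts <- matrix(0L, G, n)
    for (k in seq_len(K)) {
      idx <- which(grp == k)
      if (!length(idx)) next
      lam <- base_mean * de_factor[, k] * batch_factor[, b]
      lam <- lam / sum(lam)
      mu <- outer(lam, lib[idx])
      counts[, idx] <- stats::rpois(length(mu), mu)
    }
    ord <- order(grp)  # group cells by type for readability
    cells <- sprintf("b%d_c%04d", b, seq_len(n))
    batches[[b]] <- expression_batch(counts[, ord, drop = FALSE],
                                     batch_id = paste0("Batch", b),
                                     gene_ids = genes, cell_ids = cells,
                                     stage = "counts",
                                     cell_type_labels = types[grp[ord]])
  }
  names(batches) <- vapply(batches, `[[`, character(1), "batch_id")
  structure(list(batches = batches, true_subspace = NULL, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d batches (%s), %d genes\n", length(x$batches),
              paste(vapply(x$batches, n_cells, integer(1)), collapse = "+"),
              length(x$batches[[1]]$gene_ids)))
  invisible(x)
}

#' Remove one cell type from one batch
#'
#' Used to build the removal experiment designs in which only a subset of the
#' cell populations is shared across batches.
#'
#' @param dataset a `sim_dataset` (or any named list of `expression_batch`
#'   wrapped the same way).
#' @param batch_id name of the batch to edit.
#' @param type_label the cell type to drop from that batch.
#' @return the dataset with those cells removed; other batches untouched.
#' @export
remove_cell_type <- function(dataset, batch_id, type_label) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (!batch_id %in% names(dataset$batches))
    stop(sprintf("unknown batch '%s'", batch_id), call. = FALSE)
  b <- dataset$batches[[batch_id]]
  if (is.null(b$cell_type_labels))
    stop("batch carries no cell-type labels", call. = FALSE)
  keep <- b$cell_type_labels != type_label
  if (all(keep)) {
    warning(sprintf("type '%s' not present in batch '%s'; nothing removed",
                    type_label, batch_id), call. = FALSE)
    return(dataset)
  }
  b$values <- b$values[, keep, drop = FALSE]
  b$cell_ids <- b$cell_ids[keep]
  b$cell_type_labels <- b$cell_type_labels[keep]
  dataset$batches[[batch_id]] <- b
  if (!is.null(dataset$true_subspace))
    dataset$true_subspace[[batch_id]] <-
      dataset$true_subspace[[batch_id]][keep, , drop = FALSE]
  dataset
}
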