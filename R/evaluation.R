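#' Evaluation configuration
#'
#' @param nn neighborhood size for local entropy (default 100).
#' @param k_div k for the kNN divergence estimator (default 5).
#' @param umap_seed seed for the UMAP embedding (default 42).
#' @param umap_neighbors,umap_min_dist UMAP knobs (defaults 15, 0.1).
#' @return list of class `eval_config`.
#' @export
eval_config <- function(nn = 100, k_div = 5, umap_seed = 42L,
                        umap_neighbors = 15, umap_min_dist = 0.1) {
  if (nn < 2 || k_div < 1) stop("nn >= 2 and k_div >= 1 required", call. = FALSE)
  structure(list(nn = as.integer(nn), k_div = as.integer(k_div),
                 umap_seed = as.integer(umap_seed),
                 umap_neighbors = as.integer(umap_neighbors),
                 umap_min_dist = umap_min_dist),
            class = "eval_config")
}

#' 2D UMAP of an embedding (pass-through when already 2D)
#'
#' All three evaluation metrics are computed on these coordinates. A
#' two-column input is returned unchanged, so a 2D bottleneck code is
#' evaluated directly in its own space.
#'
#' @param x cells x d numeric matrix, d >= 2.
#' @param config an [eval_config()].
#' @return cells x 2 matrix.
#' @export
umap2d <- function(x, config = eval_config()) {
  x <- as.matrix(x)
  if (nrow(x) < 10) stop("need at least 10 cells", call. = FALSE)
  if (ncol(x) < 2) stop("embedding must have >= 2 columns", call. = FALSE)
  if (ncol(x) == 2) return(x)
  set.seed(config$umap_seed)
  uwot::umap(x, n_neighbors = config$umap_neighbors,
             min_dist = config$umap_min_dist, n_components = 2,
             n_threads = 1, n_sgd_threads = 1, batch = FALSE)
}

#' kNN Kullback-Leibler divergence estimate between two samples
#'
#' Nearest-neighbor estimator of D(P || Q):
#' (d/n) sum_i log(nu_k(i) / rho_k(i)) + log(m / (n - 1)), where rho_k(i) is
#' the k-th NN distance of x_i within P (excluding itself) and nu_k(i) its
#' k-th NN distance within Q. Distances are floored at 1e-12 so duplicated
#' points do not produce infinities.
#'
#' @param p,q sample matrices (rows = observations) of equal dimension.
#' @param k neighbor order (default 5).
#' @return scalar divergence estimate (can be negative for finite samples).
#' @export
knn_kl_divergence <- function(p, q, k = 5) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (ncol(p) != ncol(q)) stop("dimension mismatch", call. = FALSE)
  n <- nrow(p); m <- nrow(q)
  if (n < k + 1 || m < k)
    stop("too few points for the requested k", call. = FALSE)
  rho <- FNN::get.knn(p, k = k)$nn.dist[, k]
  nu <- FNN::get.knnx(q, p, k = k)$nn.dist[, k]
  rho <- pmax(rho, 1e-12); nu <- pmax(nu, 1e-12)
  (ncol(p) / n) * sum(log(nu / rho)) + log(m / (n - 1))
}

eval_label_check <- function(coords, batch, type) {
  coords <- as.matrix(coords)
  if (length(batch) != nrow(coords) || length(type) != nrow(coords))
    stop("labels must align with embedding rows", call. = FALSE)
  coords
}

#' Divergence score: mixing of shared populations
#'
#' For every ordered batch pair with a nonempty shared set of cell types, the
#' kNN divergence between the two batches' shared-type cells (both restricted
#' to the common types) is estimated on the 2D coordinates and averaged.
#' Smaller is better: well-corrected batches are homogeneously mixed.
#'
#' @param coords cells x 2 matrix (UMAP or 2D code).
#' @param batch,type per-cell batch and cell-type labels.
#' @param k_div neighbor order for the estimator.
#' @return list: `score` (mean divergence), `n_pairs` (ordered pairs used).
#' @export
divergence_score <- function(coords, batch, type, k_div = 5) {
  coords <- eval_label_check(coords, batch, type)
  bs <- unique(batch)
  if (length(bs) < 2) stop("need at least 2 batches", call. = FALSE)
  vals <- c()
  for (i in bs) for (j in bs) {
    if (i == j) next
    shared <- intersect(unique(type[batch == i]), unique(type[batch == j]))
    if (!length(shared)) next
    pi_ <- coords[batch == i & type %in% shared, , drop = FALSE]
    qj <- coords[batch == j & type %in% shared, , drop = FALSE]
    vals <- c(vals, knn_kl_divergence(pi_, qj, k = k_div))
  }
  if (!length(vals)) stop("no shared populations between any batch pair",
                          call. = FALSE)
  list(score = mean(vals), n_pairs = length(vals))
}

#' Local batch entropy of a neighborhood
#'
#' Standard nonnegative Shannon entropy (natural log) of the batch
#' proportions among a cell's nearest neighbors: 0 for a pure batch-specific
#' neighborhood, log(n_batches) for uniform mixing.
#'
#' @param neighborhood_batches batch labels of the neighbors.
#' @return entropy in [0, log(number of batches present)].
#' @export
local_entropy <- function(neighborhood_batches) {
  if (!length(neighborhood_batches)) stop("empty neighborhood", call. = FALSE)
  p <- table(neighborhood_batches) / length(neighborhood_batches)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Entropy score: purity of batch-specific populations
#'
#' For every ordered batch pair (i, j) such that batch i contains cell types
#' absent from batch j, the local batch entropy around each such
#' distinct-type cell (over its `nn` nearest neighbors among all cells) is
#' averaged; the score is the mean over those pairs. Smaller is better:
#' populations private to a batch should not be mixed with other batches.
#' NULL when every type is shared by all batches.
#'
#' @param coords cells x 2 matrix.
#' @param batch,type per-cell labels.
#' @param nn neighborhood size (default 100).
#' @return list: `score` (or NULL), `n_pairs`.
#' @export
entropy_score <- function(coords, batch, type, nn = 100) {
  coords <- eval_label_check(coords, batch, type)
  bs <- unique(batch)
  nn <- min(nn, nrow(coords) - 1)
  nn_idx <- NULL
  vals <- c()
  for (i in bs) for (j in bs) {
    if (i == j) next
    distinct <- setdiff(unique(type[batch == i]), unique(type[batch == j]))
    if (!length(distinct)) next
    if (is.null(nn_idx)) nn_idx <- FNN::get.knn(coords, k = nn)$nn.index
    cells <- which(batch == i & type %in% distinct)
    e <- vapply(cells, function(cc) local_entropy(batch[nn_idx[cc, ]]),
                numeric(1))
    vals <- c(vals, mean(e))
  }
  if (!length(vals)) return(list(score = NULL, n_pairs = 0L))
  list(score = mean(vals), n_pairs = length(vals))
}

#' Cell-type silhouette score on 2D coordinates
#'
#' Mean silhouette coefficient over all cells with clusters defined by cell
#' types and Euclidean distance on the 2D embedding; cells in singleton
#' clusters score 0. Larger is better: cell types stay compact and separate.
#'
#' @param coords cells x 2 matrix.
#' @param type per-cell cell-type labels (>= 2 distinct types).
#' @return scalar in [-1, 1].
#' @export
silhouette_score <- function(coords, type) {
  coords <- as.matrix(coords)
  if (length(unique(type)) < 2)
    stop("silhouette requires at least 2 cell types", call. = FALSE)
  sil <- cluster::silhouette(as.integer(factor(type)), stats::dist(coords))
  mean(sil[, "sil_width"])
}

#' Evaluate a batch-correction result
#'
#' Runs [umap2d()] once (pass-through when the embedding is already 2D) and
#' computes the three metrics on the same coordinates.
#'
#' @param embedding cells x d matrix (e.g. stacked bottleneck codes).
#' @param batch,type per-cell labels aligned with the rows.
#' @param config an [eval_config()].
#' @return one-row tibble of class `eval_report`: divergence_score,
#'   entropy_score (NA when all types are shared), silhouette_score, n_div,
#'   n_ent.
#' @export
evaluate_correction <- function(embedding, batch, type,
                                config = eval_config()) {
  coords <- umap2d(embedding, config)
  coords <- eval_label_check(coords, batch, type)
  dv <- divergence_score(coords, batch, type, k_div = config$k_div)
  en <- entropy_score(coords, batch, type, nn = config$nn)
  out <- tibble::tibble(
    divergence_score = dv$score,
    entropy_score = if (is.null(en$score)) NA_real_ else en$score,
    silhouette_score = silhouette_score(coords, type),
    n_div = dv$n_pairs, n_ent = en$n_pairs)
  class(out) <- c("eval_report", class(out))
  out
}
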