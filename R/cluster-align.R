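#' Shared-nearest-neighbor graph of one batch
#'
#' Cells are reduced by PCA to `n_pcs` components, connected to their `k`
#' Euclidean nearest neighbors, and the union of directed kNN edges is
#' weighted by the Jaccard overlap of the two endpoints' neighbor sets.
#'
#' @param x numeric matrix, cells in rows (e.g. the transposed scaled
#'   expression of one batch), or an `expression_batch` (columns become rows).
#' @param k number of nearest neighbors (default 15).
#' @param n_pcs number of principal components (default 30; capped at the
#'   data's rank).
#' @return an undirected weighted `igraph` graph with one vertex per cell.
#' @export
knn_graph <- function(x, k = 15, n_pcs = 30) {
  if (inherits(x, "expression_batch")) x <- t(x$values)
  x <- as.matrix(x)
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of cells", call. = FALSE)
  n_pcs <- min(n_pcs, ncol(x), n - 1)
  if (ncol(x) > n_pcs) {
    x <- stats::prcomp(x, rank. = n_pcs, center = TRUE, scale. = FALSE)$x
  }
  nn <- FNN::get.knn(x, k = k)$nn.index
  nbr <- lapply(seq_len(n), function(i) nn[i, ])
  # union of directed kNN edges
  ei <- rep(seq_len(n), each = k)
  ej <- as.vector(t(nn))
  und <- unique(cbind(pmin(ei, ej), pmax(ei, ej)))
  w <- vapply(seq_len(nrow(und)), function(r) {
    a <- nbr[[und[r, 1]]]; b <- nbr[[und[r, 2]]]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  g <- igraph::graph_from_edgelist(und, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w + 1e-6  # keep zero-overlap kNN edges in the graph
  g
}

#' Modularity-based community detection
#'
#' Louvain modularity optimization on a weighted graph at a given resolution;
#' labels are deterministic given the seed.
#'
#' @param graph an `igraph` graph (weights used when present).
#' @param resolution modularity resolution (default 1).
#' @param seed integer RNG seed.
#' @return integer vector of community labels, contiguous from 1.
#' @export
modularity_cluster <- function(graph, resolution = 1, seed = 1L) {
  if (igraph::vcount(graph) == 0) stop("empty graph", call. = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph, resolution = resolution)
  labels <- igraph::membership(cl)
  as.integer(factor(labels, levels = sort(unique(labels))))
}

#' Cluster every batch independently
#'
#' @param batches list of `expression_batch` at stage `"scaled"`.
#' @param k,n_pcs,resolution see [knn_graph()] and [modularity_cluster()].
#' @param seed integer RNG seed.
#' @return list of class `cluster_assignment`: per-batch integer label
#'   vectors (`labels`), cluster counts (`n_clusters`).
#' @export
cluster_batches <- function(batches, k = 15, n_pcs = 30, resolution = 1,
                            seed = 1L) {
  check_batch_list(batches)
  labels <- lapply(batches, function(b)
    modularity_cluster(knn_graph(b, k = k, n_pcs = n_pcs),
                       resolution = resolution, seed = seed))
  names(labels) <- vapply(batches, `[[`, character(1), "batch_id")
  structure(list(labels = labels,
                 n_clusters = vapply(labels, max, integer(1))),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment>",
      paste(sprintf("%s: %d clusters", names(x$labels), x$n_clusters),
            collapse = ", "), "\n")
  invisible(x)
}

# rank-based AUROC of `positive` under `score` (Mann-Whitney form)
auroc <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

cluster_index <- function(assignment) {
  tibble::tibble(
    batch = rep(names(assignment$labels), assignment$n_clusters),
    cluster = unlist(lapply(assignment$n_clusters, seq_len), use.names = FALSE))
}

new_similarity <- function(M, clusters, stage, s_thr = NA_real_) {
  rownames(M) <- colnames(M) <- paste(clusters$batch, clusters$cluster,
                                      sep = "|")
  structure(list(M = M, clusters = clusters, stage = stage, s_thr = s_thr),
            class = "cluster_similarity")
}

#' @export
print.cluster_similarity <- function(x, ...) {
  cat(sprintf("<cluster_similarity> %d clusters, stage = %s%s\n",
              nrow(x$M), x$stage,
              if (is.na(x$s_thr)) "" else sprintf(", S_thr = %g", x$s_thr)))
  invisible(x)
}

#' Neighbor-voting AUROC similarity between clusters of different batches
#'
#' For each batch pair a cell-cell Spearman correlation network is built over
#' the HVG expression profiles and rank-normalized to [0, 1] jointly over the
#' whole cross-batch block; cells of the target batch are scored by their mean
#' normalized edge weight to a source cluster (neighbor voting,
#' leave-one-batch-out), and the similarity of a cluster pair is the AUROC of
#' the target cluster's cells under that score, averaged over the two voting
#' directions. Within-batch entries are 0.
#'
#' @param batches list of `expression_batch` at stage `"scaled"` on a common
#'   gene list.
#' @param assignment a `cluster_assignment` from [cluster_batches()].
#' @return `cluster_similarity` at stage `"raw"`; entries in [0, 1].
#' @export
metaneighbor_similarity <- function(batches, assignment) {
  check_batch_list(batches)
  if (length(batches) < 2) stop("need at least 2 batches", call. = FALSE)
  stopifnot(inherits(assignment, "cluster_assignment"))
  idx <- cluster_index(assignment)
  p <- nrow(idx)
  M <- matrix(0, p, p)
  bn <- names(assignment$labels)
  small <- FALSE
  row_of <- function(b, j) which(idx$batch == b & idx$cluster == j)
  for (a in seq_along(batches)) for (b in seq_along(batches)) {
    if (a >= b) next
    # Spearman correlations between all cells of batch a and batch b
    cors <- stats::cor(batches[[a]]$values, batches[[b]]$values,
                       method = "spearman")
    la <- assignment$labels[[bn[a]]]; lb <- assignment$labels[[bn[b]]]
    # rank-normalize the whole cross-batch block jointly (network weights)
    net <- matrix(rank(cors) / length(cors), nrow(cors), ncol(cors))
    for (ja in seq_len(assignment$n_clusters[a])) {
      # votes a -> b: each b-cell's mean weight to the a-cells of cluster ja
      score_b <- colMeans(net[la == ja, , drop = FALSE])
      for (jb in seq_len(assignment$n_clusters[b])) {
        score_a <- rowMeans(net[, lb == jb, drop = FALSE])
        if (sum(la == ja) < 2 || sum(lb == jb) < 2) small <- TRUE
        s <- mean(c(auroc(score_b, lb == jb), auroc(score_a, la == ja)))
        M[row_of(bn[a], ja), row_of(bn[b], jb)] <- s
        M[row_of(bn[b], jb), row_of(bn[a], ja)] <- s
      }
    }
  }
  if (small)
    warning("cluster(s) with < 2 cells: AUROC is low-confidence",
            call. = FALSE)
  new_similarity(M, idx, "raw")
}

#' Keep only each cluster's best hit per other batch
#'
#' For every source cluster and every other batch, only the maximal
#' similarity entry toward that batch survives (ties keep all maxima); the
#' rest are zeroed.
#'
#' @param sim a `cluster_similarity` at stage `"raw"`.
#' @return `cluster_similarity` at stage `"best-hit"`.
#' @export
best_hit_filter <- function(sim) {
  stopifnot(inherits(sim, "cluster_similarity"))
  if (sim$stage != "raw") stop("expected stage 'raw'", call. = FALSE)
  M <- sim$M
  out <- matrix(0, nrow(M), ncol(M))
  for (r in seq_len(nrow(M))) {
    for (b in unique(sim$clusters$batch)) {
      if (b == sim$clusters$batch[r]) next
      cols <- which(sim$clusters$batch == b)
      mx <- max(M[r, cols])
      keep <- cols[M[r, cols] == mx]
      out[r, keep] <- M[r, keep]
    }
  }
  new_similarity(out, sim$clusters, "best-hit")
}

#' Symmetrize cluster similarities
#'
#' Each unordered cluster pair takes the larger of its two directional
#' scores, so a cluster can stay aligned to several clusters of another batch
#' when the clustering over-split one population.
#'
#' @param sim a `cluster_similarity` at stage `"best-hit"`.
#' @return `cluster_similarity` at stage `"symmetric"`.
#' @export
symmetrize_similarity <- function(sim) {
  stopifnot(inherits(sim, "cluster_similarity"))
  if (sim$stage != "best-hit") stop("expected stage 'best-hit'", call. = FALSE)
  new_similarity(pmax(sim$M, t(sim$M)), sim$clusters, "symmetric")
}

#' Binarize cluster similarities at a threshold
#'
#' Entries at or above `s_thr` become 1, the rest 0. Clusters whose every
#' score falls below the threshold end up with an all-zero row/column and are
#' never aligned, which protects batch-specific populations.
#'
#' @param sim a `cluster_similarity` at stage `"symmetric"`.
#' @param s_thr threshold in (0, 1); the documented working range is
#'   0.85-0.90 (default 0.90).
#' @return `cluster_similarity` at stage `"binary"`.
#' @export
binarize_similarity <- function(sim, s_thr = 0.90) {
  stopifnot(inherits(sim, "cluster_similarity"))
  if (sim$stage != "symmetric") stop("expected stage 'symmetric'", call. = FALSE)
  if (s_thr <= 0 || s_thr >= 1) stop("s_thr must be in (0,1)", call. = FALSE)
  new_similarity((sim$M >= s_thr) * 1, sim$clusters, "binary", s_thr)
}

#' Full similarity chain: raw scores to binary alignment mask
#'
#' @param batches,assignment passed to [metaneighbor_similarity()].
#' @param s_thr passed to [binarize_similarity()].
#' @return `cluster_similarity` at stage `"binary"`.
#' @export
similarity_mask <- function(batches, assignment, s_thr = 0.90) {
  binarize_similarity(
    symmetrize_similarity(
      best_hit_filter(metaneighbor_similarity(batches, assignment))),
    s_thr = s_thr)
}

#' Long-format similarity table
#'
#' @param x a `cluster_similarity`.
#' @param ... unused.
#' @return tibble with columns batch_a, cluster_a, batch_b, cluster_b, score
#'   and (at stage `"binary"`) aligned.
#' @export
tidy.cluster_similarity <- function(x, ...) {
  idx <- x$clusters
  grid <- tidyr::expand_grid(a = seq_len(nrow(idx)), b = seq_len(nrow(idx)))
  grid <- grid[grid$a < grid$b & idx$batch[grid$a] != idx$batch[grid$b], ]
  out <- tibble::tibble(
    batch_a = idx$batch[grid$a], cluster_a = idx$cluster[grid$a],
    batch_b = idx$batch[grid$b], cluster_b = idx$cluster[grid$b],
    score = x$M[cbind(grid$a, grid$b)])
  if (x$stage == "binary") {
    out$score <- NULL
    out$aligned <- x$M[cbind(grid$a, grid$b)] == 1
  }
  out
}
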