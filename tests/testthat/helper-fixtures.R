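# shared fixture builders for the test suite

# a small expression batch with the given matrix (genes x cells)
tiny_batch <- function(m, id = "B1", stage = "tpm", types = NULL) {
  expression_batch(m, batch_id = id, stage = stage, cell_type_labels = types)
}

# batch of `per` cells per cluster drawn around well-separated centers
# (rows of `centers` in gene space); returns scaled-stage-compatible values
blob_batch <- function(centers, per = 40, id = "A", sd = 0.3, seed = 1,
                       stage = "tpm") {
  set.seed(seed)
  k <- nrow(centers); d <- ncol(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    centers[rep(i, per), , drop = FALSE] + matrix(rnorm(per * d, sd = sd),
                                                  per, d)))
  expression_batch(t(x - min(x)), batch_id = id, stage = stage,
                   cell_type_labels = rep(paste0("T", seq_len(k)), each = per))
}

# hand-built cluster assignment
manual_assignment <- function(labels) {
  labels <- lapply(labels, as.integer)
  structure(list(labels = labels,
                 n_clusters = vapply(labels, max, integer(1))),
            class = "cluster_assignment")
}

# hand-built similarity object at a given stage from a square matrix and a
# clusters tibble (columns batch, cluster)
manual_similarity <- function(M, clusters, stage = "raw", s_thr = NA_real_) {
  rownames(M) <- colnames(M) <- paste(clusters$batch, clusters$cluster,
                                      sep = "|")
  structure(list(M = M, clusters = clusters, stage = stage, s_thr = s_thr),
            class = "cluster_similarity")
}

# the worked two-batch scenario: clusters j1 (batch i1), j2 and j3 (batch i2)
# with raw scores 0.99 between (i1,j1)-(i2,j2) and 0.98 between (i1,j1)-(i2,j3)
worked_example_similarity <- function() {
  cl <- tibble::tibble(batch = c("i1", "i2", "i2"), cluster = c(1L, 1L, 2L))
  M <- matrix(0, 3, 3)
  M[1, 2] <- M[2, 1] <- 0.99
  M[1, 3] <- M[3, 1] <- 0.98
  manual_similarity(M, cl, stage = "raw")
}

# reference per-batch type compositions of the simulated two-batch design
ref_compositions <- function() {
  list(c(855, 237, 373, 535) / 2000, c(379, 656, 102, 863) / 2000)
}
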