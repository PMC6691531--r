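test_that("umap2d passes 2D through and is seeded otherwise", {
  set.seed(1)
  x2 <- matrix(rnorm(60), 30, 2)
  expect_identical(umap2d(x2), x2)
  x5 <- matrix(rnorm(300), 60, 5)
  u1 <- umap2d(x5, eval_config(umap_seed = 7))
  u2 <- umap2d(x5, eval_config(umap_seed = 7))
  expect_equal(u1, u2)
  expect_equal(dim(u1), c(60, 2))
  expect_error(umap2d(matrix(rnorm(30), 30, 1)), ">= 2")
  expect_error(umap2d(matrix(rnorm(8), 4, 2)), "at least 10")
})

test_that("umap2d keeps far-separated blobs separated", {
  set.seed(2)
  a <- matrix(rnorm(50 * 6, 0, 0.5), 50, 6)
  b <- matrix(rnorm(50 * 6, 20, 0.5), 50, 6)
  u <- umap2d(rbind(a, b), eval_config(umap_seed = 3))
  ca <- colMeans(u[1:50, ]); cb <- colMeans(u[51:100, ])
  spread <- mean(c(sqrt(rowSums((u[1:50, ] - rep(ca, each = 50))^2)),
                   sqrt(rowSums((u[51:100, ] - rep(cb, each = 50))^2))))
  expect_gt(sqrt(sum((ca - cb)^2)), 5 * spread)
})

test_that("kNN distances used by the divergence estimator match brute force", {
  p <- cbind(c(0, 1, 3, 6, 10), 0)
  d <- as.matrix(dist(p)); diag(d) <- Inf
  rho1 <- apply(d, 1, min)
  expect_equal(FNN::get.knn(p, k = 1)$nn.dist[, 1], rho1, ignore_attr = TRUE)
  q <- cbind(c(0.5, 2, 7), 0)
  nu <- apply(as.matrix(dist(rbind(p, q)))[1:5, 6:8], 1, min)
  expect_equal(FNN::get.knnx(q, p, k = 1)$nn.dist[, 1], nu,
               ignore_attr = TRUE)
  # estimator formula on the tiny fixture (k = 1, dim = 2)
  got <- knn_kl_divergence(p, q, k = 1)
  expect_equal(got, (2 / 5) * sum(log(nu / rho1)) + log(3 / 4),
               tolerance = 1e-12)
})

test_that("kNN divergence is calibrated on 1D Gaussians", {
  vals0 <- numeric(10); vals1 <- numeric(10)
  for (s in 1:10) {
    set.seed(s)
    p <- matrix(rnorm(2000), ncol = 1)
    q <- matrix(rnorm(2000), ncol = 1)
    q1 <- matrix(rnorm(2000, mean = 1), ncol = 1)
    vals0[s] <- knn_kl_divergence(p, q, k = 5)
    vals1[s] <- knn_kl_divergence(p, q1, k = 5)
  }
  expect_lt(abs(mean(vals0)), 0.1)          # true KL = 0
  expect_gt(mean(vals1), 0.35)              # true KL = 0.5
  expect_lt(mean(vals1), 0.65)
  expect_error(knn_kl_divergence(matrix(1:3), matrix(1:3), k = 5), "too few")
})

test_that("divergence_score averages shared-population divergences over ordered pairs", {
  set.seed(9)
  n <- 1000
  mix <- function(seed) {
    set.seed(seed)
    g <- sample(1:2, n, replace = TRUE)
    cbind(rnorm(n, c(0, 6)[g]), rnorm(n, c(0, 6)[g]))
  }
  co <- rbind(mix(1), mix(2))
  batch <- rep(c("A", "B"), each = n)
  type <- rep("shared", 2 * n)
  null_case <- divergence_score(co, batch, type)
  expect_equal(null_case$n_pairs, 2)
  expect_lt(null_case$score, 0.2)
  # translating one batch away increases the divergence in every seed
  worse <- vapply(1:10, function(s) {
    set.seed(s)
    co2 <- rbind(mix(s * 11), mix(s * 13) + 12)
    divergence_score(co2, batch, type)$score
  }, numeric(1))
  expect_true(all(worse > null_case$score))
  expect_error(divergence_score(co, batch, rep(c("x", "y"), each = n)),
               "no shared populations")
})

test_that("divergence_score decreases as the batch offset shrinks", {
  n <- 600
  batch <- rep(c("A", "B"), each = n)
  type <- rep("t", 2 * n)
  trend <- sapply(1:10, function(s) {
    set.seed(s)
    scores <- sapply(c(10, 5, 2, 0), function(off) {
      a <- matrix(rnorm(2 * n), n, 2)
      b <- matrix(rnorm(2 * n), n, 2) + off
      divergence_score(rbind(a, b), batch, type)$score
    })
    cor(scores, c(10, 5, 2, 0), method = "spearman")
  })
  expect_true(all(trend > 0))  # larger offset, larger divergence
})

test_that("local entropy matches closed forms and its bounds", {
  expect_equal(local_entropy(rep("A", 100)), 0)
  expect_equal(local_entropy(rep(c("A", "B"), 50)), log(2), tolerance = 1e-12)
  expect_equal(local_entropy(rep(c("A", "B"), c(75, 25))),
               -(0.75 * log(0.75) + 0.25 * log(0.25)), tolerance = 1e-12)
  # maximized by uniform mixing over a proportion grid
  for (k in 2:4) {
    ent_uniform <- local_entropy(rep(letters[1:k], 12))
    expect_equal(ent_uniform, log(k), tolerance = 1e-12)
    for (i in 1:5) {
      set.seed(i)
      p <- table(sample(letters[1:k], 60, replace = TRUE))
      expect_lte(local_entropy(rep(names(p), p)), log(k) + 1e-12)
    }
  }
  expect_error(local_entropy(character(0)), "empty")
})

test_that("entropy_score isolates batch-specific populations", {
  set.seed(3)
  n <- 150
  # batch A: shared blob + private blob far away; batch B: shared blob only
  shared_a <- matrix(rnorm(2 * n, sd = 0.5), n, 2)
  shared_b <- matrix(rnorm(2 * n, sd = 0.5), n, 2)
  private <- matrix(rnorm(2 * n, sd = 0.5), n, 2) + 50
  co <- rbind(shared_a, private, shared_b)
  batch <- rep(c("A", "A", "B"), each = n)
  type <- rep(c("s", "p", "s"), each = n)
  es <- entropy_score(co, batch, type, nn = 100)
  expect_equal(es$n_pairs, 1)
  expect_equal(es$score, 0)
  # forcibly interleaving the private type with batch B cells gives ~log 2
  co2 <- co
  co2[type == "p", ] <- shared_b[sample(n), ] + rnorm(2 * n, sd = 1e-3)
  es2 <- entropy_score(co2, batch, type, nn = 100)
  expect_gt(es2$score, log(2) * 0.8)
  # all types shared -> NULL score
  es3 <- entropy_score(co, batch, rep("s", 3 * n), nn = 100)
  expect_null(es3$score)
  expect_equal(es3$n_pairs, 0L)
})

test_that("silhouette matches the hand-computed 1D toy and its invariances", {
  co <- cbind(c(0, 1, 5), 0)
  type <- c("A", "A", "B")
  # a(0)=1, b(0)=5 -> 0.8; a(1)=1, b(1)=4 -> 0.75; singleton -> 0
  expect_equal(silhouette_score(co, type), (0.8 + 0.75 + 0) / 3,
               tolerance = 1e-6)
  set.seed(8)
  blob1 <- matrix(rnorm(60, sd = 0.01), 30, 2)
  blob2 <- matrix(rnorm(60, sd = 0.01), 30, 2) + 100
  co2 <- rbind(blob1, blob2)
  ty2 <- rep(c("A", "B"), each = 30)
  expect_gt(silhouette_score(co2, ty2), 0.99)
  # invariant to rotation, translation, isotropic scaling
  th <- 0.77
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(silhouette_score(co2, ty2),
               silhouette_score(3 * co2 %*% rot + 5, ty2), tolerance = 1e-9)
  # random labels give ~0
  shuffles <- replicate(20, silhouette_score(co2, sample(ty2)))
  expect_lt(abs(mean(shuffles)), 0.05)
  expect_error(silhouette_score(co2, rep("A", 60)), "at least 2")
})

test_that("ideal correction (true subspace) has a near-zero entropy floor under balanced removal2", {
  ds <- simulate_gaussian(gaussian_sim_config(
    cells_per_batch = 500, composition_mode = "fixed",
    proportions = rep(0.25, 4), seed = 13))
  ds <- remove_cell_type(ds, "Batch1", "Type1")
  ds <- remove_cell_type(ds, "Batch2", "Type4")
  labs <- batch_labels(ds$batches)
  tsub <- do.call(rbind, ds$true_subspace)
  oracle <- evaluate_correction(tsub, labs$batch, labs$cell_type)
  expect_lt(oracle$entropy_score, 0.1)
  expect_lt(oracle$divergence_score, 0.3)
  expect_gt(oracle$silhouette_score, 0.6)
})

test_that("evaluate_correction combines the metrics coherently", {
  set.seed(5)
  n <- 120
  a1 <- matrix(rnorm(2 * n, sd = 0.4), n, 2)            # shared, batch A
  b1 <- matrix(rnorm(2 * n, sd = 0.4), n, 2)            # shared, batch B
  a2 <- matrix(rnorm(2 * n, sd = 0.4), n, 2) + 30       # private to A
  emb <- rbind(a1, a2, b1)
  batch <- rep(c("A", "A", "B"), each = n)
  type <- rep(c("s", "p", "s"), each = n)
  rep1 <- evaluate_correction(emb, batch, type)
  expect_s3_class(rep1, "eval_report")
  expect_equal(rep1$n_div, 2)
  expect_equal(rep1$n_ent, 1)
  expect_true(is.finite(rep1$divergence_score))
  expect_lt(rep1$entropy_score, 0.05)
  expect_gt(rep1$silhouette_score, 0.5)
  # 2D embedding: metrics equal direct computation (UMAP pass-through)
  expect_equal(rep1$divergence_score,
               divergence_score(emb, batch, type)$score)
  expect_equal(rep1$silhouette_score, silhouette_score(emb, type))
  # entropy NA iff no batch-specific types (both batches share both types)
  emb_sh <- rbind(a1, a2, b1, a2 + rnorm(2 * n, sd = 0.1))
  batch_sh <- rep(c("A", "A", "B", "B"), each = n)
  type_sh <- rep(c("s", "p", "s", "p"), each = n)
  rep2 <- evaluate_correction(emb_sh, batch_sh, type_sh)
  expect_true(is.na(rep2$entropy_score))
  expect_equal(rep2$n_ent, 0L)
  # determinism under a fixed umap seed for d > 2
  emb5 <- cbind(emb, matrix(rnorm(3 * n * 3, sd = 0.1), 3 * n, 3))
  r1 <- evaluate_correction(emb5, batch, type, eval_config(umap_seed = 11))
  r2 <- evaluate_correction(emb5, batch, type, eval_config(umap_seed = 11))
  expect_equal(r1, r2)
})
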