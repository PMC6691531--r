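test_that("lambda schedule matches the printed formula", {
  expect_identical(lambda_schedule(0, 2000), 0)
  expect_equal(lambda_schedule(2000, 2000), 2 / (1 + exp(-10)) - 1,
               tolerance = 1e-12)
  expect_equal(lambda_schedule(1000, 2000), 2 / (1 + exp(-5)) - 1,
               tolerance = 1e-12)
  lam <- lambda_schedule(0:500, 500)
  expect_true(all(diff(lam) > 0))
  expect_true(all(lam >= 0 & lam < 1))
})

test_that("reconstruction and total loss follow their definitions", {
  x <- rbind(c(0, 0))
  expect_equal(reconstruction_loss(x, rbind(c(1, 1))), 2)
  expect_equal(reconstruction_loss(x, x), 0)
  y <- matrix(runif(12), 3, 4)
  expect_equal(reconstruction_loss(rbind(y, y), rbind(y * 0, y * 0)),
               2 * reconstruction_loss(y, y * 0))
  expect_error(reconstruction_loss(y, y[, 1:2]), "shape")
  expect_equal(total_loss(1, 2, 0.5), 2)
  expect_equal(total_loss(3, 100, 0), 3)
  expect_equal(total_loss(3, 0, 0.9), 3)
})

test_that("mini-batch sampling gives n_mb rows per cluster block", {
  set.seed(1)
  centers <- matrix(rnorm(2 * 10, sd = 3), 2, 10)
  b1 <- blob_batch(centers, per = 30, id = "A", seed = 1)
  b2 <- blob_batch(centers, per = 60, id = "B", seed = 2)
  b1$stage <- b2$stage <- "scaled"
  b1$values <- b1$values / max(b1$values)
  b2$values <- b2$values / max(b2$values)
  asn <- manual_assignment(list(A = rep(1:2, each = 30),
                                B = rep(1:2, each = 60)))
  mb <- sample_minibatch(list(b1, b2), asn, n_mb = 50, seed = 2)
  expect_equal(nrow(mb$x), 50 * 4)  # B = n_mb * sum(c_i)
  expect_equal(unname(table(paste(mb$batch, mb$cluster))), rep(50L, 4),
               ignore_attr = TRUE)
  # cluster of size 30 sampled with replacement
  rows_a1 <- mb$x[mb$batch == "A" & mb$cluster == 1, ]
  expect_equal(nrow(rows_a1), 50)
  expect_true(any(duplicated(rows_a1)))
  # n_mb = 1 gives one row per cluster
  mb1 <- sample_minibatch(list(b1, b2), asn, n_mb = 1, seed = 3)
  expect_equal(nrow(mb1$x), 4)
})

test_that("transfer loss sums mmd2 over aligned pairs exactly once", {
  cl <- tibble::tibble(batch = rep(c("A", "B"), each = 2),
                       cluster = rep(1:2, 2))
  M <- matrix(0, 4, 4)
  M[1, 3] <- M[3, 1] <- 1   # A1-B1 aligned
  M[2, 4] <- M[4, 2] <- 1   # A2-B2 aligned
  mask <- manual_similarity(M, cl, "binary", s_thr = 0.9)
  set.seed(4)
  codes <- matrix(rnorm(40), 20, 2)
  batch <- rep(c("A", "B"), each = 10)
  cluster <- rep(rep(1:2, each = 5), 2)
  bw <- c(1, 2)
  got <- transfer_loss(codes, batch, cluster, mask, bw)
  z <- function(b, j) codes[batch == b & cluster == j, ]
  expect_equal(got, mmd2(z("A", 1), z("B", 1), bw) +
                 mmd2(z("A", 2), z("B", 2), bw), tolerance = 1e-12)
  # empty mask gives zero; single pair equals its own mmd2
  m0 <- mask; m0$M[] <- 0
  expect_equal(transfer_loss(codes, batch, cluster, m0, bw), 0)
  m1 <- mask; m1$M[2, 4] <- m1$M[4, 2] <- 0
  expect_equal(transfer_loss(codes, batch, cluster, m1, bw),
               mmd2(z("A", 1), z("B", 1), bw))
  # aligned pair with an empty block errors
  expect_error(transfer_loss(codes[batch == "A", ], batch[batch == "A"],
                             cluster[batch == "A"], mask, bw),
               "empty code block")
})

test_that("network gradients agree with finite differences", {
  set.seed(3)
  sizes <- c(6, 4, 2, 4, 6)
  params <- mmdbatch:::init_params(sizes)
  x <- matrix(runif(5 * 6), 5, 6)
  cg <- matrix(rnorm(10), 5, 2)
  loss_fn <- function(p) {
    fwd <- mmdbatch:::ae_forward(p, x, 2)
    sum((x - fwd$a[[5]])^2) + sum(fwd$a[[3]] * cg)
  }
  fwd <- mmdbatch:::ae_forward(params, x, 2)
  gr <- mmdbatch:::ae_backward(params, fwd, 2 * (fwd$a[[5]] - x), 2, cg)
  eps <- 1e-6
  for (l in 1:4) {
    i <- sample(length(params$w[[l]]), 3)
    for (ii in i) {
      pp <- params; pp$w[[l]][ii] <- pp$w[[l]][ii] + eps
      pm <- params; pm$w[[l]][ii] <- pm$w[[l]][ii] - eps
      expect_equal(gr$w[[l]][ii], (loss_fn(pp) - loss_fn(pm)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("a plain autoencoder learns to reconstruct", {
  set.seed(11)
  centers <- matrix(rnorm(3 * 15, sd = 3), 3, 15)
  b1 <- blob_batch(centers, per = 30, id = "A", seed = 1)
  b2 <- blob_batch(centers, per = 30, id = "B", seed = 2)
  pp <- preprocess_pipeline(list(b1, b2), preprocess_config(n_hvg = 15))
  asn <- manual_assignment(list(A = rep(1:3, each = 30),
                                B = rep(1:3, each = 30)))
  cl <- tibble::tibble(batch = rep(c("A", "B"), each = 3), cluster = rep(1:3, 2))
  mask0 <- manual_similarity(matrix(0, 6, 6), cl, "binary", 0.9)
  improved <- vapply(1:10, function(s) {
    cfg <- ae_config(hidden_sizes = c(8, 2, 8), epochs = 60, n_mb = 10,
                     seed = s)
    fit <- train_correction(pp$batches, asn, mask0, cfg)
    x <- t(do.call(cbind, lapply(pp$batches, function(b) b$values)))
    set.seed(s)
    untrained <- mmdbatch:::init_params(c(15, 8, 2, 8, 15))
    before <- reconstruction_loss(
      x, mmdbatch:::ae_forward(untrained, x, 2)$a[[5]])
    after <- reconstruction_loss(x, reconstruct(fit, x))
    after < before
  }, logical(1))
  expect_gte(sum(improved), 9)
})

test_that("training with alignment reduces MMD between matched code blocks", {
  set.seed(21)
  centers <- matrix(rnorm(3 * 20, sd = 3), 3, 20)
  b1 <- blob_batch(centers, per = 40, id = "A", seed = 3)
  # batch B: same blobs, shifted (batch effect)
  b2 <- blob_batch(centers + 1.5, per = 40, id = "B", seed = 4)
  pp <- preprocess_pipeline(list(b1, b2), preprocess_config(n_hvg = 20))
  asn <- manual_assignment(list(A = rep(1:3, each = 40),
                                B = rep(1:3, each = 40)))
  mask <- similarity_mask(pp$log_batches, asn, s_thr = 0.9)
  wins <- vapply(1:10, function(s) {
    cfg <- ae_config(hidden_sizes = c(10, 2, 10), epochs = 80, n_mb = 20,
                     recon_mean = TRUE, seed = s)
    fit <- train_correction(pp$batches, asn, mask, cfg)
    pair_mmd <- function(codes) {
      bw <- median_bandwidths(do.call(rbind, codes))
      mean(vapply(1:3, function(j) {
        mmd2(codes$A[asn$labels$A == j, ], codes$B[asn$labels$B == j, ], bw)
      }, numeric(1)))
    }
    set.seed(s)
    p0 <- mmdbatch:::init_params(c(20, 10, 2, 10, 20))
    m0 <- structure(list(params = p0, code_layer = 2,
                         gene_ids = pp$batches[[1]]$gene_ids),
                    class = "mmd_autoencoder")
    before <- pair_mmd(lapply(pp$batches, function(b) embed(m0, b)))
    after <- pair_mmd(fit$codes)
    after < before
  }, logical(1))
  expect_gte(sum(wins), 8)
})

test_that("embedding is deterministic, shape-correct and oracle-checked", {
  set.seed(2)
  centers <- matrix(rnorm(2 * 12, sd = 3), 2, 12)
  b1 <- blob_batch(centers, per = 20, id = "A", seed = 5)
  b2 <- blob_batch(centers, per = 20, id = "B", seed = 6)
  pp <- preprocess_pipeline(list(b1, b2), preprocess_config(n_hvg = 12))
  asn <- manual_assignment(list(A = rep(1:2, each = 20),
                                B = rep(1:2, each = 20)))
  cl <- tibble::tibble(batch = rep(c("A", "B"), each = 2), cluster = rep(1:2, 2))
  mask0 <- manual_similarity(matrix(0, 4, 4), cl, "binary", 0.9)
  fit <- train_correction(pp$batches, asn, mask0,
                          ae_config(hidden_sizes = c(6, 2, 6), epochs = 20,
                                    n_mb = 10, seed = 1))
  z1 <- embed(fit, pp$batches[[1]])
  expect_identical(z1, embed(fit, pp$batches[[1]]))
  expect_equal(ncol(z1), 2)
  expect_equal(nrow(z1), 40)
  # hand-set linear toy: identity-like encoder reproduces a matrix product
  toy <- fit
  toy$params$w[[1]] <- diag(1, 12, 6)
  toy$params$b[[1]] <- rep(0, 6)
  toy$params$w[[2]] <- matrix(1:12 / 10, 6, 2)
  toy$params$b[[2]] <- c(0.1, -0.2)
  x <- matrix(runif(36), 3, 12)
  manual <- pmax(x %*% diag(1, 12, 6), 0) %*% matrix(1:12 / 10, 6, 2)
  manual <- sweep(manual, 2, c(0.1, -0.2), "+")
  expect_equal(embed(toy, x), manual, tolerance = 1e-10)
  expect_error(embed(fit, x[, 1:5]), "dimension")
  # history bookkeeping and broom-style accessors
  expect_equal(nrow(tidy(fit)), 20)
  expect_named(tidy(fit), c("epoch", "recon", "transfer", "lambda", "total"))
  g <- glance(fit)
  expect_equal(g$code_dim, 2)
  expect_equal(g$epochs, 20)
})
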