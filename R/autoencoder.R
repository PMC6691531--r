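#' Autoencoder / training configuration
#'
#' The network is a symmetric fully connected autoencoder with an odd number
#' of hidden layers; the middle layer is the bottleneck whose activations (the
#' "code") are the batch-corrected representation. Hidden layers use the
#' rectifier except the bottleneck, which is linear (a rectified low-dim
#' bottleneck confines codes to the nonnegative quadrant and can collapse);
#' the output layer uses the logistic function so reconstructions live in
#' [0, 1] like the scaled input.
#'
#' @param hidden_sizes hidden layer sizes, odd length, middle = bottleneck.
#'   Default `c(200, 20, 200)`; use `c(20, 2, 20)` for data simulated from a
#'   2D biological subspace so the plane can be read off the code directly.
#' @param epochs total training epochs `np` (default 2000).
#' @param learning_rate Adam step size (default 1e-3).
#' @param n_mb cells sampled per (batch, cluster) block per mini-batch
#'   (default 50), so a mini-batch holds `B = n_mb * sum(c_i)` cells.
#' @param kernel_mults multipliers of the median-heuristic MMD bandwidth.
#' @param recon_mean if TRUE, use mean- instead of sum-squared reconstruction
#'   error (default FALSE: plain sum over the mini-batch).
#' @param lr_decay if TRUE, anneal the step size with a cosine schedule to ~0
#'   by the final epoch; reduces late-training jitter so code clusters end
#'   tight (default FALSE: constant step size).
#' @param seed master seed for parameter init and mini-batch sampling.
#' @return list of class `ae_config`.
#' @export
ae_config <- function(hidden_sizes = c(200, 20, 200), epochs = 2000,
                      learning_rate = 1e-3, n_mb = 50,
                      kernel_mults = c(1, 2, 4, 8, 16), recon_mean = FALSE,
                      lr_decay = FALSE, seed = 1L) {
  if (length(hidden_sizes) %% 2 != 1)
    stop("hidden_sizes must have an odd number of layers", call. = FALSE)
  if (epochs < 1 || n_mb < 1) stop("epochs and n_mb must be >= 1", call. = FALSE)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 n_mb = as.integer(n_mb), kernel_mults = kernel_mults,
                 recon_mean = recon_mean, lr_decay = lr_decay,
                 seed = as.integer(seed)),
            class = "ae_config")
}

#' Transfer-loss ramp schedule
#'
#' lambda_p = 2 / (1 + exp(-10 p / np)) - 1: zero at epoch 0 and saturating
#' toward 1, so the autoencoder first learns a faithful low-dimensional
#' representation and only then aligns similar clusters.
#'
#' @param p epoch index, 0 <= p <= np.
#' @param np total number of epochs.
#' @return lambda in [0, 1).
#' @export
lambda_schedule <- function(p, np) {
  stopifnot(np >= 1, all(p >= 0), all(p <= np))
  2 / (1 + exp(-10 * p / np)) - 1
}

#' Sum-of-squares reconstruction loss
#'
#' @param x,x_hat matrices of identical shape (rows = cells).
#' @param mean_per_cell divide by the number of rows (default FALSE).
#' @return nonnegative scalar, `sum((x - x_hat)^2)`.
#' @export
reconstruction_loss <- function(x, x_hat, mean_per_cell = FALSE) {
  if (!all(dim(x) == dim(x_hat))) stop("shape mismatch", call. = FALSE)
  v <- sum((x - x_hat)^2)
  if (mean_per_cell) v / nrow(x) else v
}

#' Total training loss
#'
#' @param l1 reconstruction loss.
#' @param l2 transfer (MMD) loss.
#' @param lambda_p schedule weight.
#' @return `l1 + lambda_p * l2`.
#' @export
total_loss <- function(l1, l2, lambda_p) l1 + lambda_p * l2

#' Sample one mini-batch
#'
#' Draws `n_mb` cells from every cluster of every batch — without replacement
#' when the cluster has at least `n_mb` cells, with replacement otherwise —
#' so each (batch, cluster) block is equally represented.
#'
#' @param batches list of `expression_batch` at stage `"scaled"`.
#' @param assignment a `cluster_assignment`.
#' @param n_mb cells per cluster block.
#' @param seed optional seed (omit inside a seeded training loop).
#' @return list: `x` (B x genes matrix), `batch`, `cluster` (row tags).
#' @export
sample_minibatch <- function(batches, assignment, n_mb = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bn <- names(assignment$labels)
  xs <- list(); tb <- character(0); tc <- integer(0)
  for (i in seq_along(batches)) {
    lab <- assignment$labels[[bn[i]]]
    xi <- t(batches[[i]]$values)
    for (j in seq_len(assignment$n_clusters[i])) {
      idx <- which(lab == j)
      if (!length(idx)) stop("empty cluster", call. = FALSE)
      pick <- if (length(idx) >= n_mb) sample(idx, n_mb)
              else sample(idx, n_mb, replace = TRUE)
      xs[[length(xs) + 1]] <- xi[pick, , drop = FALSE]
      tb <- c(tb, rep(bn[i], n_mb)); tc <- c(tc, rep(j, n_mb))
    }
  }
  list(x = do.call(rbind, xs), batch = tb, cluster = tc)
}

#' MMD transfer loss over aligned cluster pairs
#'
#' Sums `mmd2` between the code blocks of every unordered cluster pair marked
#' aligned in the binary similarity mask (each pair counted once).
#'
#' @param codes matrix of bottleneck codes for the mini-batch (rows = cells).
#' @param batch,cluster row tags of `codes`.
#' @param mask a `cluster_similarity` at stage `"binary"`.
#' @param bandwidths kernel bandwidths for [mmd2()].
#' @return nonnegative scalar.
#' @export
transfer_loss <- function(codes, batch, cluster, mask,
                          bandwidths = c(1, 2, 4, 8, 16)) {
  pairs <- aligned_pairs(mask)
  if (nrow(pairs) == 0) return(0)
  total <- 0
  for (r in seq_len(nrow(pairs))) {
    ia <- batch == pairs$batch_a[r] & cluster == pairs$cluster_a[r]
    ib <- batch == pairs$batch_b[r] & cluster == pairs$cluster_b[r]
    if (!any(ia) || !any(ib))
      stop("aligned pair with an empty code block", call. = FALSE)
    total <- total + mmd2(codes[ia, , drop = FALSE],
                          codes[ib, , drop = FALSE], bandwidths)
  }
  total
}

aligned_pairs <- function(mask) {
  stopifnot(inherits(mask, "cluster_similarity"))
  if (mask$stage != "binary") stop("mask must be at stage 'binary'", call. = FALSE)
  idx <- mask$clusters
  w <- which(upper.tri(mask$M) & mask$M == 1, arr.ind = TRUE)
  tibble::tibble(batch_a = idx$batch[w[, 1]], cluster_a = idx$cluster[w[, 1]],
                 batch_b = idx$batch[w[, 2]], cluster_b = idx$cluster[w[, 2]])
}

relu <- function(x) (x > 0) * x
sigmoid <- function(x) 1 / (1 + exp(-x))

init_params <- function(sizes) {
  L <- length(sizes) - 1
  w <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    sd <- if (l < L) sqrt(2 / sizes[l]) else sqrt(1 / sizes[l])
    w[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0, sd),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(w = w, b = b, sizes = sizes)
}

# forward pass; returns activations a (a[[1]] = x) and pre-activations z.
# Hidden layers are rectified except the bottleneck, which is linear so the
# code is not confined to the nonnegative quadrant (a rectified low-dim
# bottleneck is prone to collapse); the output layer is logistic.
ae_forward <- function(params, x, code_layer) {
  L <- length(params$w)
  a <- vector("list", L + 1); z <- vector("list", L)
  a[[1]] <- x
  for (l in seq_len(L)) {
    z[[l]] <- sweep(a[[l]] %*% params$w[[l]], 2, params$b[[l]], "+")
    a[[l + 1]] <- if (l == L) sigmoid(z[[l]])
                  else if (l == code_layer) z[[l]]
                  else relu(z[[l]])
  }
  list(a = a, z = z)
}

# one backward pass; code_grad (B x code_dim) is added at the bottleneck
ae_backward <- function(params, fwd, d_out, code_layer, code_grad = NULL) {
  L <- length(params$w)
  gw <- vector("list", L); gb <- vector("list", L)
  delta <- d_out * fwd$a[[L + 1]] * (1 - fwd$a[[L + 1]])  # sigmoid output
  for (l in L:1) {
    gw[[l]] <- crossprod(fwd$a[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      da <- delta %*% t(params$w[[l]])
      if (!is.null(code_grad) && l - 1 == code_layer)
        da <- da + code_grad
      delta <- if (l - 1 == code_layer) da
               else da * (fwd$z[[l - 1]] > 0)  # relu hidden layers
    }
  }
  list(w = gw, b = gb)
}

adam_init <- function(params) {
  zero <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
                      else numeric(length(x))
  list(mw = lapply(params$w, zero), vw = lapply(params$w, zero),
       mb = lapply(params$b, zero), vb = lapply(params$b, zero), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (l in seq_along(params$w)) {
    state$mw[[l]] <- beta1 * state$mw[[l]] + (1 - beta1) * grads$w[[l]]
    state$vw[[l]] <- beta2 * state$vw[[l]] + (1 - beta2) * grads$w[[l]]^2
    params$w[[l]] <- params$w[[l]] -
      lr * (state$mw[[l]] / c1) / (sqrt(state$vw[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    params$b[[l]] <- params$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Train the batch-correcting autoencoder
#'
#' Mini-batch gradient training of the autoencoder under the combined loss
#' `L = L1 + lambda_p * L2`: sum-of-squares reconstruction error plus the
#' ramped MMD transfer loss between bottleneck-code blocks of aligned cluster
#' pairs. Each epoch runs enough mini-batches to cover all cells; MMD kernel
#' bandwidths follow the median heuristic on each mini-batch's codes.
#'
#' @param batches list of `expression_batch` at stage `"scaled"` on a common
#'   gene list.
#' @param assignment a `cluster_assignment` for those batches.
#' @param mask a binary `cluster_similarity` alignment mask.
#' @param config an [ae_config()].
#' @return object of class `mmd_autoencoder`: network parameters, config,
#'   gene list, per-epoch loss `history` tibble, and `codes` — the bottleneck
#'   embedding of every cell (list of per-batch cells x code_dim matrices).
#' @export
train_correction <- function(batches, assignment, mask,
                             config = ae_config()) {
  check_batch_list(batches)
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(config, "ae_config"))
  d <- length(batches[[1]]$gene_ids)
  sizes <- c(d, config$hidden_sizes, d)
  code_layer <- (length(config$hidden_sizes) + 1) %/% 2
  set.seed(config$seed)
  params <- init_params(sizes)
  state <- adam_init(params)
  n_total <- sum(vapply(batches, n_cells, integer(1)))
  b_size <- config$n_mb * sum(assignment$n_clusters)
  iters <- max(1L, ceiling(n_total / b_size))
  pairs_exist <- nrow(aligned_pairs(mask)) > 0
  hist <- matrix(0, config$epochs, 4,
                 dimnames = list(NULL, c("recon", "transfer", "lambda", "total")))
  for (p in seq_len(config$epochs)) {
    lam <- lambda_schedule(p, config$epochs)
    lr <- if (isTRUE(config$lr_decay))
      config$learning_rate * 0.5 * (1 + cos(pi * (p - 1) / config$epochs))
    else config$learning_rate
    acc <- c(0, 0, 0)
    for (it in seq_len(iters)) {
      mb <- sample_minibatch(batches, assignment, config$n_mb)
      fwd <- ae_forward(params, mb$x, code_layer)
      x_hat <- fwd$a[[length(fwd$a)]]
      l1 <- reconstruction_loss(mb$x, x_hat, config$recon_mean)
      d_out <- 2 * (x_hat - mb$x)
      if (config$recon_mean) d_out <- d_out / nrow(mb$x)
      codes <- fwd$a[[code_layer + 1]]
      l2 <- 0; code_grad <- NULL
      if (pairs_exist && lam > 0) {
        bw <- median_bandwidths(codes, config$kernel_mults)
        pr <- aligned_pairs(mask)
        code_grad <- matrix(0, nrow(codes), ncol(codes))
        for (r in seq_len(nrow(pr))) {
          ia <- which(mb$batch == pr$batch_a[r] & mb$cluster == pr$cluster_a[r])
          ib <- which(mb$batch == pr$batch_b[r] & mb$cluster == pr$cluster_b[r])
          za <- codes[ia, , drop = FALSE]; zb <- codes[ib, , drop = FALSE]
          l2 <- l2 + mmd2(za, zb, bw)
          g <- mmd2_grad(za, zb, bw)
          code_grad[ia, ] <- code_grad[ia, ] + lam * g$a
          code_grad[ib, ] <- code_grad[ib, ] + lam * g$b
        }
      }
      loss <- total_loss(l1, l2, lam)
      if (!is.finite(loss)) {
        stop(sprintf(paste0("non-finite loss at epoch %d iteration %d ",
                            "(recon %.4g, transfer %.4g)"), p, it, l1, l2),
             call. = FALSE)
      }
      grads <- ae_backward(params, fwd, d_out, code_layer, code_grad)
      upd <- adam_step(params, grads, state, lr)
      params <- upd$params; state <- upd$state
      acc <- acc + c(l1, l2, loss)
    }
    hist[p, ] <- c(acc[1] / iters, acc[2] / iters, lam, acc[3] / iters)
  }
  model <- structure(
    list(params = params, config = config, code_layer = code_layer,
         gene_ids = batches[[1]]$gene_ids,
         history = tibble::tibble(epoch = seq_len(config$epochs),
                                  recon = hist[, "recon"],
                                  transfer = hist[, "transfer"],
                                  lambda = hist[, "lambda"],
                                  total = hist[, "total"])),
    class = "mmd_autoencoder")
  model$codes <- lapply(batches, function(b) embed(model, b))
  names(model$codes) <- vapply(batches, `[[`, character(1), "batch_id")
  model
}

#' @export
print.mmd_autoencoder <- function(x, ...) {
  cat(sprintf("<mmd_autoencoder> layers %s, %d epochs, final loss %.4g\n",
              paste(x$params$sizes, collapse = "-"), x$config$epochs,
              utils::tail(x$history$total, 1)))
  invisible(x)
}

#' Bottleneck embedding of expression profiles
#'
#' Deterministic encoder pass: cells are mapped to their bottleneck codes.
#'
#' @param model a trained `mmd_autoencoder`.
#' @param x an `expression_batch` (genes must match training) or a cells x
#'   genes matrix.
#' @return cells x code_dim matrix.
#' @export
embed <- function(model, x) {
  stopifnot(inherits(model, "mmd_autoencoder"))
  if (inherits(x, "expression_batch")) {
    if (!identical(x$gene_ids, model$gene_ids))
      stop("gene list does not match the training data", call. = FALSE)
    x <- t(x$values)
  }
  x <- as.matrix(x)
  if (ncol(x) != model$params$sizes[1])
    stop("input dimension does not match the model", call. = FALSE)
  a <- x
  for (l in seq_len(model$code_layer)) {
    z <- sweep(a %*% model$params$w[[l]], 2, model$params$b[[l]], "+")
    a <- if (l == model$code_layer) z else relu(z)
  }
  a
}

#' Reconstruct expression profiles through the full autoencoder
#'
#' @param model a trained `mmd_autoencoder`.
#' @param x matrix (cells x genes) or `expression_batch`.
#' @return cells x genes matrix of reconstructions in [0, 1].
#' @export
reconstruct <- function(model, x) {
  stopifnot(inherits(model, "mmd_autoencoder"))
  if (inherits(x, "expression_batch")) x <- t(x$values)
  fwd <- ae_forward(model$params, as.matrix(x), model$code_layer)
  fwd$a[[length(fwd$a)]]
}

#' Per-epoch training history
#'
#' @param x a `mmd_autoencoder`.
#' @param ... unused.
#' @return tibble: epoch, recon, transfer, lambda, total.
#' @export
tidy.mmd_autoencoder <- function(x, ...) x$history

#' One-row model summary
#'
#' @param x a `mmd_autoencoder`.
#' @param ... unused.
#' @return one-row tibble: architecture, epochs, final losses.
#' @export
glance.mmd_autoencoder <- function(x, ...) {
  tibble::tibble(
    layers = paste(x$params$sizes, collapse = "-"),
    code_dim = x$params$sizes[x$code_layer + 1],
    epochs = x$config$epochs,
    final_recon = utils::tail(x$history$recon, 1),
    final_transfer = utils::tail(x$history$transfer, 1),
    final_total = utils::tail(x$history$total, 1))
}

#' Stack the per-batch codes with their labels
#'
#' @param model a trained `mmd_autoencoder` with codes.
#' @param batches the batches the model was trained on (for labels).
#' @return tibble: cell_id, batch, cell_type, z1..zd.
#' @export
code_table <- function(model, batches) {
  labs <- batch_labels(batches)
  z <- do.call(rbind, model$codes)
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  dplyr::bind_cols(labs, tibble::as_tibble(z))
}
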