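# squared Euclidean cross-distances between rows of a and b
sq_dists <- function(a, b) {
  d <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d[d < 0] <- 0
  d
}

#' Median-heuristic kernel bandwidths
#'
#' The base bandwidth is the median pairwise Euclidean distance between rows
#' of `z`; the returned list is `mults` times that value. Degenerate inputs
#' (all rows equal) fall back to bandwidth 1.
#'
#' @param z numeric matrix of samples (rows).
#' @param mults multipliers (default 1, 2, 4, 8, 16).
#' @return numeric vector of bandwidths.
#' @export
median_bandwidths <- function(z, mults = c(1, 2, 4, 8, 16)) {
  d <- sqrt(sq_dists(z, z))
  med <- stats::median(d[upper.tri(d)])
  if (!is.finite(med) || med <= 0) med <- 1
  mults * med
}

#' Biased squared maximum mean discrepancy
#'
#' V-statistic estimate of MMD^2 between two samples under a sum of Gaussian
#' RBF kernels k(x, y) = sum_s exp(-||x - y||^2 / (2 s^2)):
#' mean(K_AA) + mean(K_BB) - 2 mean(K_AB). The biased form is nonnegative and
#' is zero when the two row sets coincide.
#'
#' @param a,b numeric sample matrices (rows = observations), equal column
#'   counts.
#' @param bandwidths positive kernel bandwidths (the `s` above).
#' @return a nonnegative scalar.
#' @export
mmd2 <- function(a, b, bandwidths = c(1, 2, 4, 8, 16)) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("dimension mismatch", call. = FALSE)
  if (nrow(a) < 1 || nrow(b) < 1) stop("need at least one row each", call. = FALSE)
  ksum <- function(d2) {
    out <- 0
    for (s in bandwidths) out <- out + exp(-d2 / (2 * s^2))
    out
  }
  val <- mean(ksum(sq_dists(a, a))) + mean(ksum(sq_dists(b, b))) -
    2 * mean(ksum(sq_dists(a, b)))
  max(val, 0)
}

# analytic gradient of mmd2(a, b) w.r.t. the rows of a and of b
mmd2_grad <- function(a, b, bandwidths) {
  n <- nrow(a); m <- nrow(b)
  daa <- sq_dists(a, a); dbb <- sq_dists(b, b); dab <- sq_dists(a, b)
  ga <- matrix(0, n, ncol(a)); gb <- matrix(0, m, ncol(b))
  for (s in bandwidths) {
    kaa <- exp(-daa / (2 * s^2))
    kbb <- exp(-dbb / (2 * s^2))
    kab <- exp(-dab / (2 * s^2))
    ga <- ga - (2 / (n^2 * s^2)) * (rowSums(kaa) * a - kaa %*% a) +
      (2 / (n * m * s^2)) * (rowSums(kab) * a - kab %*% b)
    gb <- gb - (2 / (m^2 * s^2)) * (rowSums(kbb) * b - kbb %*% b) +
      (2 / (n * m * s^2)) * (colSums(kab) * b - crossprod(kab, a))
  }
  list(a = ga, b = gb)
}
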