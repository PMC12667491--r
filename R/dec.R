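# Deep embedded clustering head: trainable centroids, Student-t soft
# assignment, sharpened target distribution, and the KL refinement loss.

#' Initialize DEC centroids by k-means
#'
#' Runs k-means (k-means++-style via multiple restarts of `stats::kmeans`)
#' on the embedding and sets each centroid to the mean of its assigned
#' spots. An empty cluster triggers a re-run with a new sub-seed, up to 5
#' attempts.
#'
#' @param Z embedding matrix (n x d).
#' @param J number of centroids (default 20; deliberately decoupled from
#'   the final number of spatial domains).
#' @param seed integer seed.
#' @param restarts k-means restarts (default 20).
#' @return J x d centroid matrix.
#' @export
init_centroids <- function(Z, J = 20, seed = 1L, restarts = 20) {
  if (J > nrow(Z)) stop("J exceeds the number of spots", call. = FALSE)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  for (attempt in 1:5) {
    set.seed(derive_seed(seed, paste0("kmeans", attempt)))
    km <- tryCatch(
      stats::kmeans(Z, centers = J, nstart = restarts, iter.max = 100),
      error = function(e) NULL)
    if (!is.null(km) && all(km$size > 0)) {
      ctr <- km$centers
      dimnames(ctr) <- NULL
      return(ctr)
    }
  }
  stop("k-means produced an empty cluster in 5 attempts", call. = FALSE)
}

# squared Euclidean distances between rows of Z and rows of C
sqdist_to_centroids <- function(Z, C) {
  zn <- rowSums(Z * Z)
  cn <- rowSums(C * C)
  d2 <- outer(zn, cn, `+`) - 2 * tcrossprod(Z, C)
  pmax(d2, 0)
}

#' Student-t soft assignment
#'
#' `q_ij = (1 + ||z_i - phi_j||^2)^-1`, normalized per spot; each row of Q
#' sums to 1.
#'
#' @param Z embedding (n x d).
#' @param centroids J x d centroid matrix.
#' @return n x J row-stochastic matrix.
#' @export
soft_assign <- function(Z, centroids) {
  S <- 1 / (1 + sqdist_to_centroids(Z, centroids))
  S / rowSums(S)
}

#' Sharpened target distribution
#'
#' `p_ij = (q_ij^2 / f_j) / sum_j' (q_ij'^2 / f_j')` with cluster
#' frequencies `f_j = sum_i q_ij`: confident assignments are up-weighted
#' while large clusters are discounted.
#'
#' @param Q row-stochastic soft assignment.
#' @return n x J row-stochastic target.
#' @export
target_distribution <- function(Q) {
  f <- colSums(Q)
  W <- sweep(Q^2, 2L, f, `/`)
  W / rowSums(W)
}

#' DEC refinement loss
#'
#' `KL(P || Q) = sum_ij p_ij log(p_ij / q_ij)`, with `0 log 0 := 0`.
#' P is treated as a constant during optimization.
#'
#' @param P target distribution.
#' @param Q soft assignment.
#' @return non-negative scalar, 0 iff P = Q.
#' @export
loss_dec <- function(P, Q) {
  if (!all(dim(P) == dim(Q))) stop_dim("Q", dim(Q), dim(P))
  nz <- P > 0
  sum(P[nz] * log(P[nz] / Q[nz]))
}

# Gradients of loss_dec with respect to Z and the centroids, holding P
# fixed. With s_ij = (1 + d_ij^2)^-1 one gets
#   dL/dz_i  =  sum_j 2 s_ij (p_ij - q_ij) (z_i - phi_j)
#   dL/dphi_j = -sum_i 2 s_ij (p_ij - q_ij) (z_i - phi_j)
dec_gradients <- function(Z, centroids, P) {
  S <- 1 / (1 + sqdist_to_centroids(Z, centroids))
  Q <- S / rowSums(S)
  W <- 2 * S * (P - Q)                     # n x J coefficient matrix
  dZ <- Z * rowSums(W) - W %*% centroids
  dC <- -crossprod(W, Z) + centroids * colSums(W)
  list(dZ = dZ, dC = dC, Q = Q)
}
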