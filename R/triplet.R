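# Cross-slice mutual-nearest-neighbor anchoring, readout aggregation of
# positive/negative neighborhoods, and the margin triplet loss used for
# batch correction.

#' Find cross-slice mutual nearest neighbors
#'
#' For every unordered pair of slices, cosine-similarity nearest-neighbor
#' sets of size `nn_size` are computed in both directions; a spot pair
#' `(i, j)` is an anchor pair iff each lies in the other's set. Pairs are
#' returned in both orientations so every anchored spot can serve as an
#' anchor.
#'
#' @param Z embedding matrix (n x d).
#' @param slice_of integer slice index per spot.
#' @param nn_size neighborhood size for MNN detection (default 50).
#' @return data.frame with columns `i`, `j` (1-based global spot indices,
#'   `i` the anchor); zero rows (with a warning) when only one slice is
#'   present.
#' @export
find_mnn_anchors <- function(Z, slice_of, nn_size = 50) {
  us <- sort(unique(slice_of))
  if (length(us) < 2L) {
    warning("single slice: no cross-slice anchors, triplet loss skipped")
    return(data.frame(i = integer(0), j = integer(0)))
  }
  nrm <- row_norms(Z)
  nrm[nrm == 0] <- 1
  Zn <- Z / nrm
  out_i <- list(); out_j <- list(); idx <- 1L
  for (a in seq_along(us)) for (b in seq_along(us)) {
    if (a >= b) next
    ia <- which(slice_of == us[a]); ib <- which(slice_of == us[b])
    S <- tcrossprod(Zn[ia, , drop = FALSE], Zn[ib, , drop = FALSE])
    ka <- min(nn_size, length(ib)); kb <- min(nn_size, length(ia))
    # top-ka neighbors in b for each spot of a, and vice versa
    nn_ab <- apply(S, 1L, function(s) order(s, decreasing = TRUE)[seq_len(ka)])
    nn_ba <- apply(S, 2L, function(s) order(s, decreasing = TRUE)[seq_len(kb)])
    memb_ab <- matrix(FALSE, length(ia), length(ib))
    memb_ab[cbind(rep(seq_along(ia), each = ka), as.integer(nn_ab))] <- TRUE
    memb_ba <- matrix(FALSE, length(ib), length(ia))
    memb_ba[cbind(rep(seq_along(ib), each = kb), as.integer(nn_ba))] <- TRUE
    mutual <- which(memb_ab & t(memb_ba), arr.ind = TRUE)
    if (nrow(mutual) > 0) {
      gi <- ia[mutual[, 1]]; gj <- ib[mutual[, 2]]
      out_i[[idx]] <- c(gi, gj); out_j[[idx]] <- c(gj, gi)
      idx <- idx + 1L
    }
  }
  if (idx == 1L) return(data.frame(i = integer(0), j = integer(0)))
  df <- data.frame(i = unlist(out_i), j = unlist(out_j))
  df[order(df$i, df$j), , drop = FALSE]
}

#' Aggregate a positive readout representation
#'
#' Selects the `alpha` most cosine-similar cross-slice candidates of the
#' anchor and returns the mean of their embeddings. Fewer than `alpha`
#' candidates are clamped (all are used).
#'
#' @param Z embedding matrix.
#' @param anchor anchor spot index.
#' @param cross_candidates candidate spot indices on other slices
#'   (typically the anchor's MNN partners).
#' @param alpha aggregation size (default 2).
#' @return the aggregated positive vector `z_plus`.
#' @export
readout_positive <- function(Z, anchor, cross_candidates, alpha = 2) {
  if (length(cross_candidates) == 0L)
    stop("no cross-slice candidates for anchor", call. = FALSE)
  sel <- select_positive_set(Z, anchor, cross_candidates, alpha)
  colMeans(Z[sel, , drop = FALSE])
}

select_positive_set <- function(Z, anchor, cross_candidates, alpha) {
  a <- Z[anchor, ]
  na <- sqrt(sum(a * a)); if (na == 0) na <- 1
  C <- Z[cross_candidates, , drop = FALSE]
  nc <- row_norms(C); nc[nc == 0] <- 1
  sim <- as.numeric(C %*% a) / (nc * na)
  k <- min(alpha, length(cross_candidates))
  cross_candidates[order(sim, decreasing = TRUE)[seq_len(k)]]
}

#' Sample and aggregate a negative readout representation
#'
#' Draws `alpha` spots uniformly without replacement from all spots outside
#' the excluded set (anchor, its positive set, and typically its
#' intra-slice graph neighbors) and returns their mean embedding.
#'
#' @param Z embedding matrix.
#' @param anchor anchor spot index.
#' @param excluded indices excluded from the negative pool.
#' @param alpha aggregation size (default 2).
#' @param seed integer seed; draws are reproducible.
#' @return the aggregated negative vector `z_minus`.
#' @export
sample_negative_readout <- function(Z, anchor, excluded, alpha = 2,
                                    seed = 1L) {
  pool <- setdiff(seq_len(nrow(Z)), unique(c(anchor, excluded)))
  if (length(pool) == 0L) stop("empty negative pool", call. = FALSE)
  if (length(pool) < alpha) {
    warning("negative pool smaller than alpha; clamped")
    alpha <- length(pool)
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  sel <- if (length(pool) == alpha) pool else sample(pool, alpha)
  colMeans(Z[sel, , drop = FALSE])
}

#' Margin triplet loss
#'
#' `(1/N) sum_i max(||z_i - z_i^+||^2 - ||z_i - z_i^-||^2 + tau, 0)` over
#' anchors with aggregated positive and negative representations.
#'
#' @param Z embedding matrix.
#' @param anchors anchor spot indices (length N).
#' @param positives,negatives N x d matrices of aggregated readouts.
#' @param tau margin (default 1.0).
#' @return non-negative scalar; 0 with a warning when N = 0.
#' @export
loss_triplet <- function(Z, anchors, positives, negatives, tau = 1.0) {
  n <- length(anchors)
  if (n == 0L) {
    warning("no triplets: loss is 0")
    return(0)
  }
  Za <- Z[anchors, , drop = FALSE]
  dp <- rowSums((Za - positives)^2)
  dn <- rowSums((Za - negatives)^2)
  mean(pmax(dp - dn + tau, 0))
}

# Build the fixed triplet structure used between anchor refreshes: for
# each anchored spot, the positive index set (top-alpha MNN partners by
# cosine similarity) and a random negative set drawn outside the anchor's
# positives and intra-slice graph neighborhood. Aggregation matrices Mp
# and Mn (N x n, rows sum to 1) let the per-step loss and gradient be
# computed as sparse products against the current embedding.
build_triplet_structure <- function(Z, slice_of, A, nn_size = 50,
                                    alpha = 2, seed = 1L) {
  pairs <- find_mnn_anchors(Z, slice_of, nn_size = nn_size)
  if (nrow(pairs) == 0L) return(NULL)
  anchors <- unique(pairs$i)
  partner <- split(pairs$j, pairs$i)
  n <- nrow(Z)
  Asp <- methods::as(A, "CsparseMatrix")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  pos_i <- integer(0); pos_j <- integer(0); pos_x <- numeric(0)
  neg_i <- integer(0); neg_j <- integer(0); neg_x <- numeric(0)
  keep <- logical(length(anchors))
  for (t in seq_along(anchors)) {
    a <- anchors[t]
    cand <- partner[[as.character(a)]]
    sel <- select_positive_set(Z, a, cand, alpha)
    nbrs <- which(Asp[, a] != 0)
    pool <- setdiff(seq_len(n), c(a, sel, nbrs))
    if (length(pool) == 0L) next
    k <- min(alpha, length(pool))
    neg <- if (length(pool) == k) pool else sample(pool, k)
    keep[t] <- TRUE
    pos_i <- c(pos_i, rep(t, length(sel))); pos_j <- c(pos_j, sel)
    pos_x <- c(pos_x, rep(1 / length(sel), length(sel)))
    neg_i <- c(neg_i, rep(t, k)); neg_j <- c(neg_j, neg)
    neg_x <- c(neg_x, rep(1 / k, k))
  }
  anchors <- anchors[keep]
  rid <- cumsum(keep)                      # compact row ids after drops
  N <- length(anchors)
  if (N == 0L) return(NULL)
  Mp <- Matrix::sparseMatrix(i = rid[pos_i], j = pos_j, x = pos_x,
                             dims = c(N, n))
  Mn <- Matrix::sparseMatrix(i = rid[neg_i], j = neg_j, x = neg_x,
                             dims = c(N, n))
  list(anchors = anchors, Mp = Mp, Mn = Mn, N = N)
}

# Loss and gradient wrt Z for a fixed triplet structure.
triplet_loss_grad <- function(Z, ts, tau = 1.0) {
  Za <- Z[ts$anchors, , drop = FALSE]
  Zp <- as.matrix(ts$Mp %*% Z)
  Zn <- as.matrix(ts$Mn %*% Z)
  dp <- rowSums((Za - Zp)^2)
  dn <- rowSums((Za - Zn)^2)
  marg <- dp - dn + tau
  act <- marg > 0
  loss <- sum(pmax(marg, 0)) / ts$N
  dZ <- matrix(0, nrow(Z), ncol(Z))
  if (any(act)) {
    w <- as.numeric(act) / ts$N
    dA <- 2 * w * (Zn - Zp)                 # d/dZa (dp - dn)
    dP <- -2 * w * (Za - Zp)
    dN <- 2 * w * (Za - Zn)
    # scatter-add anchor gradients (anchors are unique by construction)
    dZ[ts$anchors, ] <- dZ[ts$anchors, ] + dA
    dZ <- dZ + as.matrix(Matrix::crossprod(ts$Mp, dP)) +
      as.matrix(Matrix::crossprod(ts$Mn, dN))
  }
  list(loss = loss, dZ = dZ)
}
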