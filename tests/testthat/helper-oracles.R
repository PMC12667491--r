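# Independent oracles used to check the package implementations. These are
# deliberately naive (pair enumeration, scalar loops, dhyper-based
# expectations) and share no code with the implementations they test.

# pair-enumeration ARI: classify every pair of observations, then apply the
# permutation-model expectation directly
oracle_ari <- function(a, b) {
  n <- length(a)
  ss <- 0; s_a <- 0; s_b <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ea <- a[i] == a[j]; eb <- b[i] == b[j]
    if (ea && eb) ss <- ss + 1
    if (ea) s_a <- s_a + 1
    if (eb) s_b <- s_b + 1
  }
  total <- n * (n - 1) / 2
  exp_ss <- s_a * s_b / total
  mx <- (s_a + s_b) / 2
  if (mx == exp_ss) return(1)
  (ss - exp_ss) / (mx - exp_ss)
}

oracle_entropy <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

oracle_mi <- function(a, b) {
  n <- length(a)
  mi <- 0
  for (u in unique(a)) for (v in unique(b)) {
    p_uv <- sum(a == u & b == v) / n
    if (p_uv > 0)
      mi <- mi + p_uv * log(p_uv / (sum(a == u) / n * sum(b == v) / n))
  }
  mi
}

oracle_nmi <- function(a, b) {
  ha <- oracle_entropy(a); hb <- oracle_entropy(b)
  if (ha == 0 && hb == 0) return(1)
  d <- (ha + hb) / 2
  if (d == 0) return(0)
  oracle_mi(a, b) / d
}

# exact EMI via dhyper (the implementation uses lchoose sums instead)
oracle_emi <- function(a, b) {
  n <- length(a)
  rs <- as.integer(table(a)); cs <- as.integer(table(b))
  emi <- 0
  for (ai in rs) for (bj in cs) {
    for (nij in max(1, ai + bj - n):min(ai, bj)) {
      pr <- stats::dhyper(nij, bj, n - bj, ai)
      if (pr > 0) emi <- emi + pr * nij / n * log(n * nij / (ai * bj))
    }
  }
  emi
}

oracle_ami <- function(a, b) {
  ha <- oracle_entropy(a); hb <- oracle_entropy(b)
  if (ha == 0 && hb == 0) return(1)
  mi <- oracle_mi(a, b)
  emi <- oracle_emi(a, b)
  den <- (ha + hb) / 2 - emi
  if (abs(den) < 1e-15) return(0)
  (mi - emi) / den
}

oracle_v_measure <- function(truth, pred) {
  ht <- oracle_entropy(truth); hp <- oracle_entropy(pred)
  mi <- oracle_mi(truth, pred)
  hom <- if (ht == 0) 1 else mi / ht
  com <- if (hp == 0) 1 else mi / hp
  v <- if (hom + com == 0) 0 else 2 * hom * com / (hom + com)
  c(hom = hom, com = com, v = v)
}

# power iteration for the dominant eigenvalue of a (symmetric) operator
oracle_top_eigenvalue <- function(M, iters = 500) {
  M <- as.matrix(M)
  v <- rep(1, nrow(M)) / sqrt(nrow(M))
  for (i in seq_len(iters)) {
    w <- M %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- as.numeric(w / nw)
  }
  as.numeric(t(v) %*% M %*% v)
}

# scalar-loop LISI: per-spot Gaussian weights calibrated by bisection to
# the target perplexity over the k nearest neighbors, then 1/sum p_c^2
oracle_lisi <- function(emb, cats, perplexity) {
  n <- nrow(emb)
  k <- min(n - 1, floor(3 * perplexity))
  cats <- as.integer(factor(cats))
  out <- numeric(n)
  for (i in 1:n) {
    d2 <- colSums((t(emb) - emb[i, ])^2)
    d2[i] <- Inf
    nb <- order(d2)[1:k]
    dd <- d2[nb] - min(d2[nb])
    lo <- 0; hi <- Inf; beta <- 1
    for (it in 1:100) {
      w <- exp(-beta * dd)
      h <- log(sum(w)) + beta * sum(dd * w) / sum(w)
      if (abs(h - log(perplexity)) < 1e-7) break
      if (h > log(perplexity)) { lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else 2 * beta
      } else { hi <- beta
        beta <- (beta + lo) / 2
      }
    }
    w <- exp(-beta * dd); w <- w / sum(w)
    p <- tapply(w, cats[nb], sum)
    out[i] <- 1 / sum(p^2)
  }
  out
}
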