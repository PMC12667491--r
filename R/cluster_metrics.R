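# Final model-based clustering of the latent embedding and the evaluation
# metrics: pair-counting and information-theoretic clustering agreement,
# and perplexity-calibrated local inverse Simpson's indices.

#' Model-based clustering of the embedding
#'
#' EM for a Gaussian mixture with a shared full covariance matrix across
#' components (mclust's EEE shape), initialized from k-means, with 10
#' restarts under a fixed seed; the restart with the highest
#' log-likelihood wins. Degenerate covariances are ridge-regularized and
#' retried with growing ridge before erroring.
#'
#' @param Z embedding matrix (n x d).
#' @param n_domains number of spatial domains (user-set per tissue; >= 2).
#' @param seed integer seed.
#' @param restarts number of EM restarts (default 10).
#' @param max_iter EM iterations per restart (default 200).
#' @return integer vector of hard labels in `0 .. n_domains-1`.
#' @export
cluster_embedding <- function(Z, n_domains, seed = 1L, restarts = 10,
                              max_iter = 200) {
  if (n_domains < 2) stop("n_domains must be >= 2", call. = FALSE)
  Z <- as.matrix(Z)
  best <- NULL
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, paste0("gmm", r)))
    fit <- tryCatch(gmm_em_once(Z, n_domains, max_iter),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best))
    stop("EM failed in all restarts (degenerate covariance)", call. = FALSE)
  best$labels
}

gmm_em_once <- function(Z, K, max_iter) {
  n <- nrow(Z); d <- ncol(Z)
  km <- stats::kmeans(Z, centers = K, nstart = 5, iter.max = 100)
  mu <- km$centers
  pi_k <- pmax(km$size, 1) / sum(pmax(km$size, 1))
  resp <- matrix(0, n, K); resp[cbind(seq_len(n), km$cluster)] <- 1
  Sigma <- pooled_cov(Z, resp, mu)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    ch <- chol_ridge(Sigma)
    logdens <- vapply(seq_len(K), function(k)
      dmvnorm_chol(Z, mu[k, ], ch), numeric(n))
    logp <- sweep(logdens, 2L, log(pi_k), `+`)
    lse <- logsumexp_rows(logp)
    ll <- sum(lse)
    resp <- exp(logp - lse)
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-10)
    pi_k <- nk / n
    mu <- sweep(crossprod(resp, Z), 1L, nk, `/`)
    Sigma <- pooled_cov(Z, resp, mu)
    if (is.finite(ll_old) && abs(ll - ll_old) < 1e-6 * abs(ll)) break
    ll_old <- ll
  }
  list(labels = max.col(resp) - 1L, loglik = ll, mu = mu, Sigma = Sigma,
       pi = pi_k)
}

pooled_cov <- function(Z, resp, mu) {
  n <- nrow(Z); d <- ncol(Z)
  S <- matrix(0, d, d)
  for (k in seq_len(ncol(resp))) {
    Zc <- sweep(Z, 2L, mu[k, ])
    S <- S + crossprod(Zc * resp[, k], Zc)
  }
  S / n
}

chol_ridge <- function(S) {
  ridge <- 1e-6 * mean(diag(S))
  if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-8
  for (i in 1:6) {
    ch <- tryCatch(chol(S + diag(ridge, nrow(S))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
    ridge <- ridge * 100
  }
  stop("covariance not positive definite after ridge retries", call. = FALSE)
}

dmvnorm_chol <- function(Z, mu, ch) {
  d <- ncol(Z)
  Zc <- sweep(Z, 2L, mu)
  Y <- backsolve(ch, t(Zc), transpose = TRUE)
  q <- colSums(Y * Y)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + q)
}

# ---------------------------------------------------------------------------
# pair-counting and information-theoretic metrics

contingency <- function(a, b) {
  if (length(a) != length(b))
    stop("label vectors differ in length", call. = FALSE)
  table(factor(a), factor(b))
}

comb2 <- function(x) x * (x - 1) / 2

#' Adjusted Rand index
#'
#' `form = "standard"` (default) is the Hubert-Arabie permutation-model
#' ARI. `form = "paper"` is the pair-count variant
#' `(TP + TN - E) / (TP + TN + FP + FN - E)` with
#' `E = ((TP+FP)(TP+FN) + (FN+TN)(FP+TN)) / (TP+TN+FP+FN)`, where TP/TN/
#' FP/FN count spot pairs co-clustered / separated in both labelings or in
#' only one. The two forms do not coincide in general; both are exposed.
#'
#' @param a,b label vectors of equal length >= 2.
#' @param form `"standard"` or `"paper"`.
#' @return a scalar in `[-1, 1]`.
#' @export
ari <- function(a, b, form = c("standard", "paper")) {
  form <- match.arg(form)
  ct <- contingency(a, b)
  n <- length(a)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  sum_ij <- sum(comb2(ct))
  sum_a <- sum(comb2(rowSums(ct)))
  sum_b <- sum(comb2(colSums(ct)))
  total <- comb2(n)
  if (form == "standard") {
    expected <- sum_a * sum_b / total
    mx <- (sum_a + sum_b) / 2
    if (mx == expected) return(1)          # both labelings trivial
    (sum_ij - expected) / (mx - expected)
  } else {
    TP <- sum_ij
    FP <- sum_a - sum_ij                   # same in a, split in b
    FN <- sum_b - sum_ij
    TN <- total - TP - FP - FN
    E <- ((TP + FP) * (TP + FN) + (FN + TN) * (FP + TN)) / total
    den <- total - E
    if (den == 0) return(1)
    (TP + TN - E) / den
  }
}

entropy_counts <- function(cnt) {
  n <- sum(cnt)
  p <- cnt[cnt > 0] / n
  -sum(p * log(p))
}

mutual_information <- function(ct) {
  n <- sum(ct)
  mi <- 0
  rs <- rowSums(ct); cs <- colSums(ct)
  for (i in seq_len(nrow(ct))) for (j in seq_len(ncol(ct))) {
    nij <- ct[i, j]
    if (nij > 0) mi <- mi + nij / n * log(nij * n / (rs[i] * cs[j]))
  }
  as.numeric(mi)
}

# Expected mutual information under the hypergeometric permutation model.
expected_mi <- function(rs, cs, n) {
  emi <- 0
  for (ai in rs) for (bj in cs) {
    lo <- max(1, ai + bj - n)
    hi <- min(ai, bj)
    if (hi < lo) next
    for (nij in lo:hi) {
      lp <- lchoose(bj, nij) + lchoose(n - bj, ai - nij) - lchoose(n, ai)
      emi <- emi + nij / n * log(n * nij / (ai * bj)) * exp(lp)
    }
  }
  as.numeric(emi)
}

#' Normalized mutual information (arithmetic normalization)
#' @param a,b label vectors.
#' @return scalar in `[0, 1]`; 1 for matching trivial labelings.
#' @export
nmi <- function(a, b) {
  ct <- contingency(a, b)
  ha <- entropy_counts(rowSums(ct)); hb <- entropy_counts(colSums(ct))
  if (ha == 0 && hb == 0) return(1)
  mi <- mutual_information(ct)
  den <- (ha + hb) / 2
  if (den == 0) return(0)
  mi / den
}

#' Adjusted mutual information (arithmetic normalization)
#' @param a,b label vectors.
#' @return scalar in `[-1, 1]`, ~0 for independent labelings.
#' @export
ami <- function(a, b) {
  ct <- contingency(a, b)
  n <- sum(ct)
  ha <- entropy_counts(rowSums(ct)); hb <- entropy_counts(colSums(ct))
  if (ha == 0 && hb == 0) return(1)
  mi <- mutual_information(ct)
  emi <- expected_mi(rowSums(ct), colSums(ct), n)
  den <- (ha + hb) / 2 - emi
  if (abs(den) < 1e-15) return(0)
  (mi - emi) / den
}

#' Average clustering consistency
#'
#' The arithmetic mean of NMI and AMI.
#'
#' @param a,b label vectors.
#' @return `(nmi(a,b) + ami(a,b)) / 2`.
#' @export
acc_score <- function(a, b) (nmi(a, b) + ami(a, b)) / 2

#' Homogeneity, completeness and V-measure
#'
#' Homogeneity is `1 - H(truth|pred)/H(truth)`, completeness
#' `1 - H(pred|truth)/H(pred)`, and the V-measure their harmonic mean,
#' with the `0/0 := 1` convention for degenerate single-class inputs.
#'
#' @param truth,pred label vectors (ground truth first).
#' @return named list with `hom`, `com`, `v`.
#' @export
v_measure <- function(truth, pred) {
  ct <- contingency(truth, pred)
  ht <- entropy_counts(rowSums(ct)); hp <- entropy_counts(colSums(ct))
  mi <- mutual_information(ct)
  hom <- if (ht == 0) 1 else mi / ht       # 1 - H(t|p)/H(t) = MI/H(t)
  com <- if (hp == 0) 1 else mi / hp
  v <- if (hom + com == 0) 0 else 2 * hom * com / (hom + com)
  list(hom = hom, com = com, v = v)
}

# ---------------------------------------------------------------------------
# local inverse Simpson's index

#' Local inverse Simpson's index
#'
#' For each spot, Gaussian-kernel weights over its `3*perplexity` nearest
#' neighbors are calibrated by binary search so the weight entropy equals
#' `log(perplexity)`; the score is the inverse Simpson's index
#' `1 / sum_c p_c^2` of the weighted category distribution. With slice
#' labels this is iLISI (higher = better batch mixing); with domain
#' labels cLISI (lower = purer neighborhoods).
#'
#' @param embedding numeric matrix (n x d).
#' @param categories per-spot category labels.
#' @param perplexity neighborhood scale (default 30); must satisfy
#'   `perplexity < n/3` (otherwise the neighborhood is reduced, with a
#'   warning).
#' @return numeric vector of per-spot scores in
#'   `[1, number of categories]`.
#' @export
lisi <- function(embedding, categories, perplexity = 30) {
  Z <- as.matrix(embedding)
  n <- nrow(Z)
  categories <- as.integer(factor(categories))
  ncat <- max(categories)
  k <- floor(3 * perplexity)
  if (k >= n) {
    warning("fewer spots than 3*perplexity; reducing neighborhood")
    k <- n - 1L
    perplexity <- min(perplexity, k / 3)
  }
  # brute-force kNN in chunks (desk scale; avoids an extra dependency)
  scores <- numeric(n)
  zn <- rowSums(Z * Z)
  chunk <- max(1L, floor(2e7 / n))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    D2 <- outer(zn[s:e], zn, `+`) - 2 * tcrossprod(Z[s:e, , drop = FALSE], Z)
    for (r in seq_len(e - s + 1L)) {
      i <- s + r - 1L
      d2 <- D2[r, ]; d2[i] <- Inf
      nb <- order(d2)[seq_len(k)]
      w <- calibrate_weights(pmax(d2[nb], 0), perplexity)
      p <- vapply(seq_len(ncat), function(c0)
        sum(w[categories[nb] == c0]), numeric(1))
      scores[i] <- 1 / sum(p * p)
    }
  }
  scores
}

# binary search for the Gaussian bandwidth reaching the target perplexity
calibrate_weights <- function(d2, perplexity, tol = 1e-5, iters = 64) {
  target <- log(perplexity)
  beta <- 1; lo <- -Inf; hi <- Inf
  d2 <- d2 - min(d2)
  for (it in seq_len(iters)) {
    w <- exp(-beta * d2)
    sw <- sum(w)
    if (sw == 0) { h <- 0 } else {
      h <- log(sw) + beta * sum(d2 * w) / sw
    }
    if (abs(h - target) < tol) break
    if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
    else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
  }
  w <- exp(-beta * d2)
  w / sum(w)
}

#' Evaluate an embedding and clustering
#'
#' Computes the full metrics report: agreement between predicted and true
#' domains (when truth is available) and iLISI/cLISI.
#'
#' @param Z embedding matrix.
#' @param pred predicted domain labels (optional).
#' @param truth true domain labels (optional).
#' @param batch slice/batch labels (optional).
#' @param perplexity LISI perplexity (default 30).
#' @return list of class `metrics_report`.
#' @export
evaluate_embedding <- function(Z, pred = NULL, truth = NULL, batch = NULL,
                               perplexity = 30) {
  out <- list()
  if (!is.null(pred) && !is.null(truth)) {
    vm <- v_measure(truth, pred)
    out$ari <- ari(truth, pred)
    out$ari_paper_form <- ari(truth, pred, form = "paper")
    out$nmi <- nmi(truth, pred)
    out$ami <- ami(truth, pred)
    out$acc <- acc_score(truth, pred)
    out$hom <- vm$hom; out$com <- vm$com; out$v_measure <- vm$v
  }
  if (!is.null(batch))
    out$ilisi_mean <- mean(lisi(Z, batch, perplexity))
  if (!is.null(truth))
    out$clisi_mean <- mean(lisi(Z, truth, perplexity))
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%-15s %.4f\n", nm, x[[nm]]))
  invisible(x)
}
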