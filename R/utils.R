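# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a root seed and a tag
#'
#' All stochastic stages (masking, reparameterization noise, k-means,
#' negative sampling, simulation) draw their own seed from one root seed so
#' that a single integer makes a whole run reproducible. The result is kept
#' below 2^31 - 1.
#'
#' @param root integer root seed.
#' @param tag character tag naming the consumer (e.g. "mask", "eps").
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(root, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(as.numeric(root)) %% 1e6 * 1009 + h * 31) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dim <- function(what, got, want) {
  stop(sprintf("%s: dimension mismatch (got %s, expected %s)", what,
               paste(got, collapse = "x"), paste(want, collapse = "x")),
       call. = FALSE)
}

# Row-wise L2 norms of a dense matrix.
row_norms <- function(M) sqrt(rowSums(M * M))

# Cosine similarity between corresponding rows of two matrices.
# Zero-norm rows get cosine 0 (maximum, direction-free penalty in the SCE
# loss; documented in the methods vignette).
row_cosine <- function(U, V) {
  nu <- row_norms(U); nv <- row_norms(V)
  s <- rowSums(U * V)
  out <- ifelse(nu > 0 & nv > 0, s / (nu * nv), 0)
  pmin(pmax(out, -1), 1)
}

# Stable log-sum-exp over matrix rows.
logsumexp_rows <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}
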