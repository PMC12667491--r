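# Spot masking: sample the masked vertex set V_m and substitute a single
# learnable vector for the masked rows of the reduced expression matrix.

#' Sample the masked spot set
#'
#' Draws `floor(rho * n)` spot indices uniformly without replacement.
#' A fixed-size draw (rather than per-spot Bernoulli) keeps the masked-set
#' size deterministic, which is also the denominator of the scaled cosine
#' reconstruction loss.
#'
#' @param n total number of spots.
#' @param rho mask rate in `[0, 1)`; default 0.2.
#' @param seed integer seed; the same `(n, rho, seed)` always yields the
#'   same set.
#' @return object of class `mask_spec` with fields `rho`, `V_m` (1-based
#'   indices), `seed`.
#' @export
sample_mask <- function(n, rho = 0.2, seed = 1L) {
  if (rho < 0 || rho >= 1)
    stop("rho must lie in [0, 1): at least one unmasked spot required",
         call. = FALSE)
  size <- floor(rho * n)
  V_m <- if (size > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
    sort(sample.int(n, size))
  } else integer(0)
  structure(list(rho = rho, V_m = V_m, seed = as.integer(seed)),
            class = "mask_spec")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' Replace masked rows by the learnable mask vector
#'
#' Rows listed in `spec$V_m` are replaced by `mask_vector`; all other rows
#' are returned unchanged. The input is never modified in place.
#'
#' @param X numeric matrix (spots x reduced dimension).
#' @param spec a `mask_spec` from [sample_mask()].
#' @param mask_vector numeric vector of length `ncol(X)`; during training
#'   this is a trainable model parameter.
#' @return the masked matrix.
#' @export
apply_mask <- function(X, spec, mask_vector) {
  if (length(spec$V_m) > 0 && max(spec$V_m) > nrow(X))
    stop("mask index out of range for X", call. = FALSE)
  if (length(mask_vector) != ncol(X))
    stop_dim("mask_vector", length(mask_vector), ncol(X))
  X_mask <- X
  if (length(spec$V_m) > 0)
    X_mask[spec$V_m, ] <- matrix(mask_vector, nrow = length(spec$V_m),
                                 ncol = ncol(X), byrow = TRUE)
  X_mask
}
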