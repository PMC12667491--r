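# Masked variational graph autoencoder.
#
# Encoder: two fully connected layers produce a per-spot representation
# Z_f; a first graph convolution ReLU(BN(A_hat Z_f W0)) yields a shared
# hidden state from which two further graph convolutions produce mu and
# log sigma^2; the reparameterization trick gives Z_g; the final embedding
# is Z = Z_f + Z_g. Decoders: inner-product sigmoid(Z Z^T) for the
# adjacency, a single linear graph convolution for the expression.
# Losses: mean squared adjacency reconstruction, analytic Gaussian KL to
# N(0, I), and a scaled cosine error on the masked spots only.

#' Initialize a VGAE model
#'
#' @param m input dimension (number of principal components).
#' @param fc_dims dimensions of the two fully connected layers
#'   (default `c(64, 16)`); the second is the latent dimension d_f.
#' @param gcn_hidden width of the first graph convolution (default 64).
#' @param seed seed for Glorot weight initialization.
#' @param relu_logvar apply ReLU to the log-variance head (the published
#'   form; forces sigma >= 1). Set FALSE for an unconstrained head.
#' @param reparam_mode `"standard"` for `mu + exp(0.5*logvar)*eps`
#'   (default) or `"literal"` for `mu + logvar*eps`.
#' @return an object of class `vgae_model` holding parameters, batch-norm
#'   state and architecture metadata.
#' @export
vgae_init <- function(m, fc_dims = c(64, 16), gcn_hidden = 64, seed = 1L,
                      relu_logvar = TRUE,
                      reparam_mode = c("standard", "literal")) {
  reparam_mode <- match.arg(reparam_mode)
  d <- fc_dims[2]
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  params <- list(
    # small random init: an all-zero mask token would sit in the dead
    # region of the first ReLU and never receive gradient
    mask_vec = stats::rnorm(m, sd = 0.1),
    W1 = glorot(m, fc_dims[1]), b1 = rep(0, fc_dims[1]),
    W2 = glorot(fc_dims[1], d), b2 = rep(0, d),
    W0 = glorot(d, gcn_hidden),
    g0 = rep(1, gcn_hidden), beta0 = rep(0, gcn_hidden),
    Wmu = glorot(gcn_hidden, d), gmu = rep(1, d), bmu = rep(0, d),
    Wsig = glorot(gcn_hidden, d), gsig = rep(1, d), bsig = rep(0, d),
    Wdec = glorot(d, m), bdec = rep(0, m))
  bn <- list(h0 = bn_new(gcn_hidden), mu = bn_new(d), sig = bn_new(d))
  structure(list(params = params, bn = bn, m = m, fc_dims = fc_dims,
                 gcn_hidden = gcn_hidden, d = d,
                 relu_logvar = relu_logvar, reparam_mode = reparam_mode),
            class = "vgae_model")
}

#' @export
print.vgae_model <- function(x, ...) {
  cat(sprintf("<vgae_model> input %d -> FC %d -> d_f %d; GCN hidden %d\n",
              x$m, x$fc_dims[1], x$d, x$gcn_hidden))
  invisible(x)
}

#' Reparameterization trick
#'
#' `"standard"` mode computes `mu + exp(0.5*logvar) * eps`; `"literal"`
#' mode the printed variant `mu + logvar * eps` (which collapses to `mu`
#' when `logvar = 0`).
#'
#' @param mu,logvar posterior parameters (n x d matrices).
#' @param eps Gaussian noise matrix of the same shape, or a single integer
#'   seed from which it is drawn, or 0 for the posterior mean.
#' @param mode `"standard"` (default) or `"literal"`.
#' @return the sampled latent `Z_g`.
#' @export
reparameterize <- function(mu, logvar, eps = 0,
                           mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  if (length(eps) == 1L) {
    if (eps == 0) {
      eps <- matrix(0, nrow(mu), ncol(mu))
    } else {
      old <- get_rng_state(); on.exit(restore_rng_state(old))
      set.seed(as.integer(eps))
      eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
    }
  }
  if (!all(dim(eps) == dim(mu))) stop_dim("eps", dim(eps), dim(mu))
  if (mode == "standard") mu + exp(0.5 * logvar) * eps else mu + logvar * eps
}

# Full forward pass with cached intermediates for backpropagation.
# eps: noise matrix, or 0 for the posterior mean.
vgae_forward <- function(model, X_mask, A_hat, training = FALSE, eps = 0) {
  p <- model$params
  if (ncol(X_mask) != model$m) stop_dim("X_mask", ncol(X_mask), model$m)
  pre1 <- sweep(X_mask %*% p$W1, 2L, p$b1, `+`)
  a1 <- pmax(pre1, 0)
  Zf <- sweep(a1 %*% p$W2, 2L, p$b2, `+`)

  m0 <- as.matrix(A_hat %*% (Zf %*% p$W0))
  bn0 <- bn_forward(m0, model$bn$h0, p$g0, p$beta0, training)
  model$bn$h0 <- bn0$bn
  h0 <- pmax(bn0$y, 0)

  mmu <- as.matrix(A_hat %*% (h0 %*% p$Wmu))
  bnm <- bn_forward(mmu, model$bn$mu, p$gmu, p$bmu, training)
  model$bn$mu <- bnm$bn
  mu <- pmax(bnm$y, 0)

  msig <- as.matrix(A_hat %*% (h0 %*% p$Wsig))
  bns <- bn_forward(msig, model$bn$sig, p$gsig, p$bsig, training)
  model$bn$sig <- bns$bn
  logvar <- if (model$relu_logvar) pmax(bns$y, 0) else bns$y

  if (length(eps) == 1L && eps == 0) eps <- matrix(0, nrow(mu), ncol(mu))
  Zg <- reparameterize(mu, logvar, eps, mode = model$reparam_mode)
  Z <- Zf + Zg
  Xt <- as.matrix(A_hat %*% (Z %*% p$Wdec))
  Xt <- sweep(Xt, 2L, p$bdec, `+`)

  list(model = model,
       cache = list(X_mask = X_mask, A_hat = A_hat, pre1 = pre1, a1 = a1,
                    Zf = Zf, m0 = m0, bn0 = bn0, h0 = h0,
                    bnm = bnm, mu = mu, bns = bns, logvar = logvar,
                    eps = eps, Zg = Zg, Z = Z, Xt = Xt,
                    training = training))
}

#' Encode spots into the latent embedding
#'
#' Runs the encoder on (optionally masked) reduced expression and the
#' normalized adjacency and returns all latent blocks.
#'
#' @param X_mask numeric matrix (n x m), typically the masked PCA matrix.
#' @param A_hat normalized sparse adjacency from [normalize_adjacency()].
#' @param model a `vgae_model`.
#' @param training use batch statistics in the normalization layers
#'   (TRUE during optimization) or running averages (FALSE, extraction).
#' @param eps noise matrix, integer seed, or 0 for the posterior mean.
#' @return list of class `latent_embedding`: `Z_f`, `mu`, `logvar`, `Z_g`,
#'   and `Z = Z_f + Z_g`.
#' @export
vgae_encode <- function(X_mask, A_hat, model, training = FALSE, eps = 0) {
  if (length(eps) == 1L && eps != 0) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(as.integer(eps))
    eps <- matrix(stats::rnorm(nrow(X_mask) * model$d), nrow(X_mask), model$d)
  }
  fw <- vgae_forward(model, X_mask, A_hat, training = training, eps = eps)
  c <- fw$cache
  structure(list(Z_f = c$Zf, mu = c$mu, logvar = c$logvar, Z_g = c$Zg,
                 Z = c$Z), class = "latent_embedding")
}

#' Inner-product adjacency decoder
#'
#' @param Z latent embedding (n x d).
#' @return dense symmetric matrix `sigmoid(Z Z^T)` with entries in (0, 1).
#' @export
decode_adjacency <- function(Z) {
  S <- tcrossprod(Z)
  1 / (1 + exp(-S))
}

#' Linear graph-convolution expression decoder
#'
#' @param Z latent embedding.
#' @param A_hat normalized adjacency.
#' @param model a `vgae_model` (uses its decoder weights).
#' @return reconstructed reduced expression `A_hat Z W_dec + b` (n x m).
#' @export
decode_expression <- function(Z, A_hat, model) {
  p <- model$params
  Xt <- as.matrix(A_hat %*% (Z %*% p$Wdec))
  sweep(Xt, 2L, p$bdec, `+`)
}

#' Adjacency reconstruction loss
#'
#' Mean squared difference between the observed binary adjacency and its
#' reconstruction, averaged over all n^2 entries so the magnitude does not
#' grow with the number of spots.
#'
#' @param A observed adjacency (dense or sparse).
#' @param A_tilde reconstruction from [decode_adjacency()].
#' @return non-negative scalar.
#' @export
loss_graph <- function(A, A_tilde) {
  A <- as.matrix(A)
  if (!all(dim(A) == dim(A_tilde))) stop_dim("A_tilde", dim(A_tilde), dim(A))
  mean((A - A_tilde)^2)
}

#' Gaussian KL divergence to the standard normal prior
#'
#' Analytic KL of `N(mu, diag(exp(logvar)))` from `N(0, I)`, summed over
#' latent dimensions and averaged over spots.
#'
#' @param mu,logvar posterior parameters.
#' @return non-negative scalar.
#' @export
loss_kl <- function(mu, logvar) {
  if (!all(dim(mu) == dim(logvar))) stop_dim("logvar", dim(logvar), dim(mu))
  -0.5 * sum(1 + logvar - mu^2 - exp(logvar)) / nrow(mu)
}

#' Scaled cosine error on masked spots
#'
#' `(1/|V_m|) * sum_{i in V_m} (1 - cos(x_i, x_hat_i))^gamma`: the
#' reconstruction of each masked spot is compared with its true (pre-mask)
#' feature vector by cosine similarity, and errors are sharpened by the
#' scaling factor `gamma >= 1`. Rows with zero norm contribute the maximal
#' direction-free term (cosine treated as 0).
#'
#' @param X true feature matrix (pre-mask).
#' @param X_tilde reconstruction.
#' @param V_m masked spot indices (1-based); must be nonempty.
#' @param gamma scaling factor, >= 1 (default 2).
#' @return scalar in `[0, 2^gamma]`.
#' @export
loss_sce <- function(X, X_tilde, V_m, gamma = 2) {
  if (length(V_m) == 0L) stop("V_m is empty: SCE loss undefined", call. = FALSE)
  if (gamma < 1) stop("gamma must be >= 1", call. = FALSE)
  cs <- row_cosine(X[V_m, , drop = FALSE], X_tilde[V_m, , drop = FALSE])
  mean((1 - cs)^gamma)
}

#' Total VGAE loss
#'
#' Unweighted sum of the adjacency, KL and masked-reconstruction terms;
#' the lambda weighting of the overall objective happens in the trainer.
#'
#' @param lg,lkl,lsce the three component losses.
#' @return their sum.
#' @export
loss_vgae <- function(lg, lkl, lsce) lg + lkl + lsce

# ---------------------------------------------------------------------------
# Backward pass. Returns gradients for every parameter. `A_dense` is the
# observed adjacency as a dense matrix; `dZ_extra` carries gradients from
# the DEC and triplet heads (already lambda-weighted); `lambda1` scales the
# VGAE loss. When V_m is empty the SCE term is skipped.
vgae_backward <- function(model, cache, A_dense, X_orig, V_m, gamma = 2,
                          lambda1 = 1, dZ_extra = NULL, kl_weight = 1,
                          use_graph = TRUE, use_kl = TRUE, use_sce = TRUE) {
  p <- model$params
  n <- nrow(cache$Z)
  Z <- cache$Z
  dZ <- if (is.null(dZ_extra)) matrix(0, n, ncol(Z)) else dZ_extra

  # graph loss: L = mean((A - sigmoid(ZZ^T))^2)
  if (use_graph && lambda1 != 0) {
    At <- decode_adjacency(Z)
    G <- (2 / n^2) * (At - A_dense) * At * (1 - At)   # symmetric
    dZ <- dZ + lambda1 * 2 * (G %*% Z)
  }

  # SCE loss through the expression decoder
  dXt <- NULL
  if (use_sce && lambda1 != 0 && length(V_m) > 0) {
    U <- X_orig[V_m, , drop = FALSE]
    V <- cache$Xt[V_m, , drop = FALSE]
    nu <- row_norms(U); nv <- row_norms(V)
    ok <- nu > 0 & nv > 0
    cs <- ifelse(ok, rowSums(U * V) / (nu * nv), 0)
    cs <- pmin(pmax(cs, -1), 1)
    coef <- -gamma * (1 - cs)^(gamma - 1) / length(V_m)   # d/dcos
    dV <- matrix(0, length(V_m), ncol(U))
    if (any(ok)) {
      dcos_dV <- U[ok, , drop = FALSE] / (nu[ok] * nv[ok]) -
        V[ok, , drop = FALSE] * (cs[ok] / nv[ok]^2)
      dV[ok, ] <- coef[ok] * dcos_dV
    }
    dXt <- matrix(0, n, ncol(cache$Xt))
    dXt[V_m, ] <- lambda1 * dV
  }

  grads <- list()
  if (!is.null(dXt)) {
    # Xt = A_hat Z Wdec + bdec
    AdXt <- as.matrix(cache$A_hat %*% dXt)      # A_hat symmetric
    grads$Wdec <- crossprod(Z, AdXt)
    grads$bdec <- colSums(dXt)
    dZ <- dZ + AdXt %*% t(p$Wdec)
  } else {
    grads$Wdec <- p$Wdec * 0
    grads$bdec <- p$bdec * 0
  }

  # split Z = Zf + Zg
  dZg <- dZ
  dZf <- dZ

  # KL contributions enter mu and logvar directly
  dmu <- dZg
  if (model$reparam_mode == "standard") {
    dlogvar <- dZg * cache$eps * 0.5 * exp(0.5 * cache$logvar)
  } else {
    dlogvar <- dZg * cache$eps
  }
  if (use_kl && lambda1 != 0 && kl_weight != 0) {
    w <- lambda1 * kl_weight
    dmu <- dmu + w * cache$mu / n
    dlogvar <- dlogvar + w * (-0.5) * (1 - exp(cache$logvar)) / n
  }

  # mu head: mu = ReLU(BN(A_hat h0 Wmu))
  dmu_pre <- dmu * (cache$bnm$y > 0)
  bb <- bn_backward(dmu_pre, p$gmu, cache$bnm$cache)
  grads$gmu <- bb$dgamma; grads$bmu <- bb$dbeta
  dMmu <- as.matrix(cache$A_hat %*% bb$dx)
  grads$Wmu <- crossprod(cache$h0, dMmu)
  dh0 <- dMmu %*% t(p$Wmu)

  # logvar head
  dsig_pre <- if (model$relu_logvar) dlogvar * (cache$bns$y > 0) else dlogvar
  bs <- bn_backward(dsig_pre, p$gsig, cache$bns$cache)
  grads$gsig <- bs$dgamma; grads$bsig <- bs$dbeta
  dMsig <- as.matrix(cache$A_hat %*% bs$dx)
  grads$Wsig <- crossprod(cache$h0, dMsig)
  dh0 <- dh0 + dMsig %*% t(p$Wsig)

  # first GCN: h0 = ReLU(BN(A_hat Zf W0))
  dh0_pre <- dh0 * (cache$bn0$y > 0)
  b0 <- bn_backward(dh0_pre, p$g0, cache$bn0$cache)
  grads$g0 <- b0$dgamma; grads$beta0 <- b0$dbeta
  dM0 <- as.matrix(cache$A_hat %*% b0$dx)
  grads$W0 <- crossprod(cache$Zf, dM0)
  dZf <- dZf + dM0 %*% t(p$W0)

  # FC stack: Zf = a1 W2 + b2, a1 = ReLU(X_mask W1 + b1)
  grads$W2 <- crossprod(cache$a1, dZf)
  grads$b2 <- colSums(dZf)
  da1 <- (dZf %*% t(p$W2)) * (cache$pre1 > 0)
  grads$W1 <- crossprod(cache$X_mask, da1)
  grads$b1 <- colSums(da1)
  dXmask <- da1 %*% t(p$W1)
  grads$mask_vec <- if (length(V_m) > 0)
    colSums(dXmask[V_m, , drop = FALSE]) else p$mask_vec * 0
  grads
}
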