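# Minimal neural-network plumbing: Glorot initialization, batch
# normalization with running statistics, and the Adam optimizer. All
# gradients in the package are hand-derived and checked against finite
# differences in the test suite.

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

bn_new <- function(d) {
  list(run_mean = rep(0, d), run_var = rep(1, d))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Forward pass; gamma/beta are trainable parameters owned by the model.
# In training mode batch statistics are used and the running averages
# updated; in inference mode the running averages are used so the
# extracted embedding does not depend on batch composition.
bn_forward <- function(x, bn, gamma, beta, training) {
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu)
    v <- colMeans(xc * xc)                 # biased variance, as in torch BN
    inv <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(xc, 2L, inv, `*`)
    bn$run_mean <- (1 - BN_MOMENTUM) * bn$run_mean + BN_MOMENTUM * mu
    n <- nrow(x)
    unb <- if (n > 1) v * n / (n - 1) else v
    bn$run_var <- (1 - BN_MOMENTUM) * bn$run_var + BN_MOMENTUM * unb
    cache <- list(xhat = xhat, inv = inv)
  } else {
    inv <- 1 / sqrt(bn$run_var + BN_EPS)
    xhat <- sweep(sweep(x, 2L, bn$run_mean), 2L, inv, `*`)
    cache <- list(xhat = xhat, inv = inv)
  }
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(y = y, bn = bn, cache = cache)
}

# Backward pass through training-mode batch normalization.
bn_backward <- function(dy, gamma, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, gamma, `*`)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- sweep(dxhat, 2L, m1) - sweep(xhat, 2L, m2, `*`)
  dx <- sweep(dx, 2L, cache$inv, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Adam with decoupled-from-nothing (classic L2) weight decay: the decay
# term wd * theta is added to the raw gradient before the moment updates,
# matching the framework default the model was tuned with.
adam_new <- function(params, lr = 5e-4, weight_decay = 1e-4,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, wd = weight_decay, b1 = beta1, b2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- g + opt$wd * params[[nm]]
    opt$m[[nm]] <- opt$b1 * opt$m[[nm]] + (1 - opt$b1) * g
    opt$v[[nm]] <- opt$b2 * opt$v[[nm]] + (1 - opt$b2) * g * g
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(opt = opt, params = params)
}
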