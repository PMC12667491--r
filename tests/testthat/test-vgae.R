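# vgae: encoder/decoders, losses, reparameterization, gradients.

make_toy <- function(n = 12, m = 7, d = 4, seed = 42) {
  set.seed(seed)
  co <- matrix(runif(n * 2), n, 2)
  g <- build_knn_graph(co, k = 3)
  list(X = matrix(rnorm(n * m), n, m),
       A = as.matrix(g$A),
       A_hat = normalize_adjacency(g$A),
       model = vgae_init(m, fc_dims = c(6, d), gcn_hidden = 5, seed = 3),
       n = n, m = m, d = d)
}

test_that("reparameterize closed forms and determinism", {
  mu <- matrix(1:6 / 2, 2, 3)
  lv <- matrix(0, 2, 3)
  e <- matrix(rnorm(6), 2, 3)
  expect_equal(reparameterize(mu, lv, 0), mu)                  # eps = 0
  expect_equal(reparameterize(mu, lv, 0, mode = "literal"), mu)
  # logvar = 0: standard adds eps, literal collapses to mu
  expect_equal(reparameterize(mu, lv, e), mu + e)
  expect_equal(reparameterize(mu, lv, e, mode = "literal"), mu)
  # general closed form
  lv2 <- matrix(log(4), 2, 3)
  expect_equal(reparameterize(mu, lv2, e), mu + 2 * e)
  expect_equal(reparameterize(mu, lv2, e, mode = "literal"),
               mu + log(4) * e)
  # seeded draws reproduce
  expect_equal(reparameterize(mu, lv2, 77L), reparameterize(mu, lv2, 77L))
})

test_that("decode_adjacency closed forms", {
  Z0 <- matrix(0, 3, 2)
  expect_equal(decode_adjacency(Z0), matrix(0.5, 3, 3))
  Zo <- rbind(c(1, 0), c(0, 1))
  At <- decode_adjacency(Zo)
  expect_equal(At[1, 2], 0.5)
  expect_equal(At[1, 1], 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(At, t(At))
  big <- decode_adjacency(100 * matrix(1, 2, 2))
  expect_true(all(big > 1 - 1e-10))
})

test_that("loss closed forms: graph, KL, SCE, total", {
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(loss_graph(A, A), 0)
  Atld <- A; Atld[1, 1] <- 0.5
  expect_equal(loss_graph(A, Atld), 0.0625)     # 0.5^2 / 4
  expect_gte(loss_graph(A, matrix(runif(4), 2, 2)), 0)

  expect_equal(loss_kl(matrix(0, 3, 2), matrix(0, 3, 2)), 0)
  expect_equal(loss_kl(matrix(1, 1, 1), matrix(0, 1, 1)), 0.5)
  set.seed(1)
  expect_gte(loss_kl(matrix(rnorm(10), 5, 2), matrix(rnorm(10), 5, 2)), 0)

  X <- rbind(c(1, 0), c(0, 2), c(1, 1))
  expect_equal(loss_sce(X, 3 * X, 1:3, gamma = 2), 0)   # proportional rows
  expect_equal(loss_sce(rbind(c(1, 0)), rbind(c(0, 1)), 1, gamma = 2), 1)
  expect_equal(loss_sce(rbind(c(1, 0)), rbind(c(-1, 0)), 1, gamma = 1), 2)
  expect_error(loss_sce(X, X, integer(0)), "empty")
  expect_error(loss_sce(X, X, 1:3, gamma = 0.5), "gamma")

  expect_equal(loss_vgae(0, 0, 0), 0)
  expect_equal(loss_vgae(1, 2, 3), 6)
})

test_that("SCE loss is bounded by [0, 2^gamma] and handles zero rows", {
  set.seed(2)
  for (gamma in c(1, 2, 3)) {
    X <- matrix(rnorm(60), 10, 6)
    Y <- matrix(rnorm(60), 10, 6)
    l <- loss_sce(X, Y, 1:10, gamma = gamma)
    expect_gte(l, 0); expect_lte(l, 2^gamma)
  }
  # zero-norm reconstruction row contributes the direction-free maximum 1
  expect_equal(loss_sce(rbind(c(1, 1)), rbind(c(0, 0)), 1, gamma = 2), 1)
})

test_that("encoder is permutation-equivariant and shape-checked", {
  ns <- asNamespace("spatchwork")
  toy <- make_toy()
  eps <- matrix(rnorm(toy$n * toy$d), toy$n, toy$d)
  emb <- vgae_encode(toy$X, toy$A_hat, toy$model, training = TRUE, eps = eps)
  expect_equal(emb$Z, emb$Z_f + emb$Z_g)
  expect_equal(dim(emb$mu), c(toy$n, toy$d))
  p <- sample(toy$n)
  embp <- vgae_encode(toy$X[p, ], toy$A_hat[p, p], toy$model,
                      training = TRUE, eps = eps[p, ])
  expect_equal(embp$Z, emb$Z[p, ], tolerance = 1e-10)
  xt <- decode_expression(emb$Z, toy$A_hat, toy$model)
  xtp <- decode_expression(emb$Z[p, ], toy$A_hat[p, p], toy$model)
  expect_equal(xtp, xt[p, ], tolerance = 1e-10)
  expect_error(vgae_encode(toy$X[, 1:3], toy$A_hat, toy$model), "mismatch")
})

test_that("edgeless graph with self-loops reduces GCN layers to dense layers", {
  ns <- asNamespace("spatchwork")
  n <- 6; m <- 5
  set.seed(4)
  X <- matrix(rnorm(n * m), n, m)
  A0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), dims = c(n, n))
  I_hat <- normalize_adjacency(A0)          # identity
  model <- vgae_init(m, fc_dims = c(4, 3), gcn_hidden = 4, seed = 5)
  fw <- ns$vgae_forward(model, X, I_hat, training = FALSE,
                        eps = matrix(0, n, 3))
  # manual per-spot dense computation using running stats (inference mode)
  Zf <- fw$cache$Zf
  manual <- pmax(sweep(Zf %*% model$params$W0, 2,
                       sqrt(1 + 1e-5), `/`), 0)   # BN with init stats
  expect_equal(fw$cache$h0, manual, tolerance = 1e-10)
})

test_that("full backward pass matches finite differences", {
  ns <- asNamespace("spatchwork")
  toy <- make_toy(n = 10, m = 5, d = 3)
  V_m <- c(2L, 7L)
  eps <- matrix(rnorm(toy$n * toy$d), toy$n, toy$d)
  lossfun <- function(model) {
    Xm <- apply_mask(toy$X, list(V_m = V_m), model$params$mask_vec)
    fw <- ns$vgae_forward(model, Xm, toy$A_hat, training = TRUE, eps = eps)
    loss_graph(toy$A, decode_adjacency(fw$cache$Z)) +
      0.3 * loss_kl(fw$cache$mu, fw$cache$logvar) +
      loss_sce(toy$X, fw$cache$Xt, V_m, gamma = 2)
  }
  Xm <- apply_mask(toy$X, list(V_m = V_m), toy$model$params$mask_vec)
  fw <- ns$vgae_forward(toy$model, Xm, toy$A_hat, training = TRUE, eps = eps)
  grads <- ns$vgae_backward(toy$model, fw$cache, toy$A, toy$X, V_m,
                            gamma = 2, kl_weight = 0.3)
  h <- 1e-6
  set.seed(99)
  for (nm in names(grads)) {
    p0 <- toy$model$params[[nm]]
    for (ii in sample(length(p0), min(3, length(p0)))) {
      mp <- toy$model; mp$params[[nm]][ii] <- p0[ii] + h
      mm <- toy$model; mm$params[[nm]][ii] <- p0[ii] - h
      gn <- (lossfun(mp) - lossfun(mm)) / (2 * h)
      expect_equal(grads[[nm]][ii], gn, tolerance = 1e-4,
                   label = sprintf("d%s[%d]", nm, ii))
    }
  }
})

test_that("training the graph loss alone decreases it monotonically", {
  ns <- asNamespace("spatchwork")
  set.seed(31)
  n <- 15; m <- 4
  X <- matrix(rnorm(n * m), n, m)
  co <- matrix(runif(n * 2), n, 2)
  g <- build_knn_graph(co, k = 2)
  A_hat <- normalize_adjacency(g$A)
  A <- as.matrix(g$A)
  model <- vgae_init(m, fc_dims = c(4, 3), gcn_hidden = 4, seed = 6)
  opt <- ns$adam_new(model$params, lr = 5e-3, weight_decay = 0)
  losses <- numeric(50)
  for (e in 1:50) {
    fw <- ns$vgae_forward(model, X, A_hat, training = TRUE,
                          eps = matrix(0, n, 3))
    model <- fw$model
    losses[e] <- loss_graph(A, decode_adjacency(fw$cache$Z))
    gr <- ns$vgae_backward(model, fw$cache, A, X, integer(0),
                           use_kl = FALSE, use_sce = FALSE)
    st <- ns$adam_step(opt, model$params, gr)
    opt <- st$opt; model$params <- st$params
  }
  # overall monotone decrease (allow tiny per-step wiggle from Adam)
  expect_lt(losses[50], losses[1])
  expect_true(all(diff(losses) < 1e-3))
})
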