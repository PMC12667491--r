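# triplet: MNN anchoring, readout aggregation, margin loss.

test_that("identical slices anchor every spot to its twin", {
  set.seed(61)
  Z1 <- matrix(rnorm(40), 10, 4)
  Z <- rbind(Z1, Z1)
  sl <- rep(1:2, each = 10)
  pairs <- find_mnn_anchors(Z, sl, nn_size = 1)
  twin <- pairs[pairs$i <= 10, ]
  expect_equal(nrow(twin), 10)
  expect_equal(twin$j, twin$i + 10)
})

test_that("single slice yields an empty anchor list with a warning", {
  Z <- matrix(rnorm(20), 5, 4)
  expect_warning(p <- find_mnn_anchors(Z, rep(1, 5)), "single slice")
  expect_equal(nrow(p), 0)
})

test_that("non-mutual top-1 pairs are excluded at nn_size = 1", {
  # slice A: a1, a2, a3; slice B: b1, b2, b3 with hand-set geometry:
  # a1's top-1 in B is b1, but b1's top-1 in A is a2 -> (a1, b1) excluded
  Za <- rbind(c(1, 0.00), c(1, 0.10), c(0, 1))
  Zb <- rbind(c(1, 0.09), c(0.9, 0.5), c(0, 1.2))
  Z <- rbind(Za, Zb)
  sl <- rep(1:2, each = 3)
  # verify premise with an exhaustive cosine table
  cs <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  simtab <- outer(1:3, 1:3, Vectorize(function(i, j) cs(Za[i, ], Zb[j, ])))
  expect_equal(which.max(simtab[1, ]), 1L)      # a1 -> b1
  expect_equal(which.max(simtab[, 1]), 2L)      # b1 -> a2
  pairs <- find_mnn_anchors(Z, sl, nn_size = 1)
  expect_false(any(pairs$i == 1 & pairs$j == 4))
  expect_true(any(pairs$i == 2 & pairs$j == 4)) # mutual pair kept
})

test_that("readout_positive averages the top-alpha candidates", {
  Z <- rbind(c(1, 0), c(0.9, 0.1), c(0.5, 0.5), c(-1, 0))
  # alpha = 1: single most similar candidate
  expect_equal(readout_positive(Z, 1, c(2, 3, 4), alpha = 1), Z[2, ])
  # alpha = 2: mean of the two most similar
  expect_equal(readout_positive(Z, 1, c(2, 3, 4), alpha = 2),
               colMeans(Z[c(2, 3), ]))
  # clamp when fewer candidates than alpha
  expect_equal(readout_positive(Z, 1, c(2), alpha = 5), Z[2, ])
  expect_error(readout_positive(Z, 1, integer(0)), "candidates")
})

test_that("sample_negative_readout is seeded and clamps", {
  set.seed(62)
  Z <- matrix(rnorm(40), 10, 4)
  z1 <- sample_negative_readout(Z, 1, excluded = 2:4, alpha = 3, seed = 5)
  z2 <- sample_negative_readout(Z, 1, excluded = 2:4, alpha = 3, seed = 5)
  expect_identical(z1, z2)
  # forced draw: pool has exactly alpha spots
  z3 <- sample_negative_readout(Z, 1, excluded = 2:8, alpha = 2, seed = 1)
  z4 <- sample_negative_readout(Z, 1, excluded = 2:8, alpha = 2, seed = 99)
  expect_equal(z3, colMeans(Z[9:10, ]))
  expect_identical(z3, z4)
  # pool smaller than alpha clamps with warning
  expect_warning(z5 <- sample_negative_readout(Z, 1, 2:9, alpha = 3, seed = 1),
                 "clamped")
  expect_equal(z5, Z[10, ])
})

test_that("loss_triplet closed forms and inactive margins", {
  Z <- rbind(c(0, 0), c(3, 4))
  # anchor equals positive, negative at squared distance 2, tau = 1
  expect_equal(loss_triplet(Z, 1, rbind(c(0, 0)), rbind(c(1, 1)), tau = 1), 0)
  # dp = 4, dn = 1, tau = 1 -> 4
  expect_equal(loss_triplet(Z, 1, rbind(c(2, 0)), rbind(c(0, 1)), tau = 1), 4)
  expect_warning(l0 <- loss_triplet(Z, integer(0),
                                    matrix(0, 0, 2), matrix(0, 0, 2)),
                 "no triplets")
  expect_equal(l0, 0)
  # zero whenever every anchor satisfies dn >= dp + tau
  set.seed(63)
  n <- 6
  Zr <- matrix(rnorm(n * 3), n, 3)
  pos <- Zr + matrix(rnorm(n * 3, sd = 0.01), n, 3)
  neg <- Zr + 100
  expect_equal(loss_triplet(Zr, 1:n, pos, neg, tau = 1), 0)
})

test_that("triplet structure gradient matches finite differences", {
  ns <- asNamespace("spatchwork")
  set.seed(64)
  n <- 16
  Z <- rbind(matrix(rnorm(24, 0), 8, 3), matrix(rnorm(24, 1), 8, 3))
  sl <- rep(1:2, each = 8)
  A <- build_knn_graph(matrix(runif(n * 2), n, 2), k = 2)$A
  ts <- ns$build_triplet_structure(Z, sl, Matrix::bdiag(A[1:8, 1:8],
                                                        A[9:16, 9:16]),
                                   nn_size = 4, alpha = 2, seed = 9)
  expect_false(is.null(ts))
  g <- ns$triplet_loss_grad(Z, ts, tau = 1)
  f <- function(Z) {
    Za <- Z[ts$anchors, , drop = FALSE]
    dp <- rowSums((Za - as.matrix(ts$Mp %*% Z))^2)
    dn <- rowSums((Za - as.matrix(ts$Mn %*% Z))^2)
    sum(pmax(dp - dn + 1, 0)) / ts$N
  }
  expect_equal(g$loss, f(Z), tolerance = 1e-12)
  h <- 1e-6
  for (ii in sample(length(Z), 6)) {
    Zp <- Z; Zp[ii] <- Zp[ii] + h
    Zm <- Z; Zm[ii] <- Zm[ii] - h
    expect_equal(g$dZ[ii], (f(Zp) - f(Zm)) / (2 * h), tolerance = 1e-4)
  }
})

test_that("triplet training pulls matched cross-slice domains together", {
  ns <- asNamespace("spatchwork")
  set.seed(65)
  # two slices, two directionally distinct domains, constant batch shift
  base <- rbind(cbind(rnorm(10, 5, 0.3), rnorm(10, 0, 0.3), rnorm(10, 0, 0.3)),
                cbind(rnorm(10, 0, 0.3), rnorm(10, 5, 0.3), rnorm(10, 0, 0.3)))
  Z <- rbind(base, base + 1)
  sl <- rep(1:2, each = 20)
  dom <- rep(rep(1:2, each = 10), 2)
  A <- Matrix::Diagonal(40) * 0
  centd <- function(Z) {
    m <- function(s, d) colMeans(Z[sl == s & dom == d, ])
    sqrt(sum((m(1, 1) - m(2, 1))^2)) + sqrt(sum((m(1, 2) - m(2, 2))^2))
  }
  d0 <- centd(Z)
  ts <- ns$build_triplet_structure(Z, sl, A, nn_size = 10, alpha = 2,
                                   seed = 1)
  for (i in 1:100) Z <- Z - 0.05 * ns$triplet_loss_grad(Z, ts, 1)$dZ
  expect_lt(centd(Z), d0)
})
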