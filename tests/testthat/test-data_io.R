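# data_io: loading, gene filtering, normalization/HVG, PCA.

test_that("load_slices parses CSV and MTX inputs and preserves spot order", {
  dir <- withr::local_tempdir()
  cnt <- matrix(c(1, 0, 2, 0, 3, 1), nrow = 3,
                dimnames = list(paste0("sp", 1:3), c("g1", "g2")))
  write.csv(cnt, file.path(dir, "counts.csv"))
  write.csv(data.frame(x = 1:3, y = c(0, 1, 0)),
            file.path(dir, "coords.csv"), row.names = FALSE)
  sl <- load_slices(list(list(counts = file.path(dir, "counts.csv"),
                              coords = file.path(dir, "coords.csv"))),
                    format = "csv")
  expect_length(sl, 1)
  expect_equal(nrow(sl[[1]]$counts), 3)
  expect_equal(sl[[1]]$spot_ids, paste0("sp", 1:3))
  expect_equal(as.matrix(sl[[1]]$counts), cnt, ignore_attr = TRUE)

  # MTX round trip through write_simulation
  sim <- simulate_slices(tiny_sim_spec())
  out <- withr::local_tempdir()
  write_simulation(sim, out)
  paths <- lapply(seq_along(sim$slices), function(s)
    list(counts = file.path(out, sprintf("slice%d", s), "matrix.mtx"),
         coords = file.path(out, sprintf("slice%d", s), "coords.csv"),
         id = sprintf("slice%d", s)))
  sl2 <- load_slices(paths, format = "mtx")
  expect_length(sl2, 2)
  expect_equal(vapply(sl2, `[[`, character(1), "slice_id"),
               c("slice1", "slice2"))
  expect_equal(as.matrix(sl2[[1]]$counts),
               as.matrix(sim$slices[[1]]$counts), ignore_attr = TRUE)
})

test_that("structural errors: coordinate mismatch and missing files", {
  dir <- withr::local_tempdir()
  cnt <- matrix(1:6, nrow = 3, dimnames = list(paste0("s", 1:3), c("a", "b")))
  write.csv(cnt, file.path(dir, "counts.csv"))
  write.csv(data.frame(x = 1:2, y = 1:2), file.path(dir, "coords.csv"),
            row.names = FALSE)
  expect_error(load_slices(list(list(counts = file.path(dir, "counts.csv"),
                                     coords = file.path(dir, "coords.csv"))),
                           format = "csv"), "coordinate rows")
  expect_error(load_slices(list(list(counts = file.path(dir, "counts.csv"),
                                     coords = file.path(dir, "nope.csv"))),
                           format = "csv"), "not found")
  expect_error(slice_data(matrix(-1, 1, 1), cbind(0, 0), "s"),
               "non-negative")
})

test_that("filter_genes applies both thresholds on concatenated data", {
  # 5-gene toy; brute-force the retained set from the stated rule
  set.seed(1)
  c1 <- matrix(0L, 40, 5); c2 <- matrix(0L, 40, 5)
  colnames(c1) <- colnames(c2) <- paste0("g", 1:5)
  c1[1:30, 1] <- 1L; c2[1:30, 1] <- 1L     # g1: 60 spots, total 60
  c1[1:25, 2] <- 20L; c2[1:24, 2] <- 20L   # g2: 49 spots, total 980
  c1[1:40, 3] <- 0L                        # g3: absent
  c1[1:5, 4] <- 1L; c2[1:4, 4] <- 1L       # g4: 9 spots, total 9
  c1[, 5] <- 2L; c2[, 5] <- 2L             # g5: 80 spots, total 160
  sl <- list(toy_slice(c1, "a"), toy_slice(c2, "b"))
  expressed <- colSums(rbind(c1, c2) > 0)
  totals <- colSums(rbind(c1, c2))
  expected <- paste0("g", which(expressed >= 50 & totals >= 10))
  out <- filter_genes(sl, min_spots = 50, min_total = 10)
  expect_equal(out[[1]]$gene_names, expected)
  expect_equal(out[[2]]$gene_names, expected)
  # the gene seen in 49 spots is removed despite a large total
  expect_false("g2" %in% out[[1]]$gene_names)
  # idempotence
  out2 <- filter_genes(out, min_spots = 50, min_total = 10)
  expect_identical(out2[[1]]$gene_names, out[[1]]$gene_names)
  # zero survivors is an explicit error naming both thresholds
  expect_error(filter_genes(sl, min_spots = 1000, min_total = 1),
               "min_spots=1000.*min_total=1")
})

test_that("normalize_log_hvg scales, transforms and ranks dispersions", {
  # identical library sizes: scaling is the identity
  cnt <- matrix(rpois(200, 5), 20, 10,
                dimnames = list(NULL, paste0("g", 1:10)))
  cnt <- cnt - (rowSums(cnt) - median(rowSums(cnt))) %o% c(1, rep(0, 9))
  cnt[cnt < 0] <- 0
  sl <- list(toy_slice(cnt))
  E <- normalize_log_hvg(sl, n_hvg = 10)
  lib <- rowSums(cnt)
  expect_equal(unname(as.matrix(E)),
               unname(log1p(cnt / lib * median(lib))), tolerance = 1e-12,
               ignore_attr = TRUE)

  # constant gene never selected; top-k matches direct dispersion ranking
  set.seed(5)
  cnt2 <- matrix(rnbinom(600, mu = 8, size = 2), 60, 10,
                 dimnames = list(NULL, paste0("g", 1:10)))
  cnt2[, 4] <- 5L                           # constant gene
  sl2 <- list(toy_slice(cnt2))
  E2 <- normalize_log_hvg(sl2, n_hvg = 3)
  expect_false("g4" %in% attr(E2, "hvg"))
  expect_equal(ncol(E2), 3)
  expect_warning(normalize_log_hvg(sl2, n_hvg = 50), "clamped")
})

test_that("reduce_pca matches eigendecomposition and is invertible", {
  set.seed(3)
  # rank-2 matrix reconstructs exactly with 2 components
  B <- matrix(rnorm(40), 20, 2) %*% matrix(rnorm(10), 2, 5)
  red <- reduce_pca(B, 2)
  back <- red$X %*% t(red$basis$rotation)
  back <- sweep(back, 2L, red$basis$center, `+`)
  expect_lt(max(abs(back - B)), 1e-8)

  # component variances equal covariance eigenvalues
  E <- matrix(rnorm(300), 50, 6)
  red2 <- reduce_pca(E, 4)
  ev <- eigen(stats::cov(E), symmetric = TRUE)$values[1:4]
  expect_equal(unname(apply(red2$X, 2, stats::var)), ev, tolerance = 1e-8)

  # determinism
  red3 <- reduce_pca(E, 4)
  expect_identical(red2$X, red3$X)
  expect_warning(reduce_pca(E, 6), "reduced")
})

test_that("preprocessing preserves spot count and slice order", {
  sim <- simulate_slices(tiny_sim_spec())
  ds <- small_dataset()$ds
  expect_equal(ds$n, sum(vapply(sim$slices, function(s) nrow(s$counts),
                                integer(1))))
  expect_equal(ds$slice_of, rep(1:2, each = 120))
  expect_true(all(is.finite(ds$X)))
})
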