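# Multi-slice simulator: shared spatial domains across slices,
# domain-specific expression programs, per-slice multiplicative batch
# effects, negative binomial counts and Bernoulli dropout. Everything is
# reproducible from one seed.

#' Simulation specification
#'
#' @param n_slices number of tissue sections (default 3).
#' @param spots_per_slice spots per section (default 600).
#' @param n_genes genes (default 300).
#' @param n_domains shared spatial domains (default 5).
#' @param domain_geometry `"bands"` (horizontal strata shared across
#'   slices) or `"voronoi"` (shared seed points, per-slice jitter).
#' @param de_strength log-fold scale of the domain expression programs
#'   (default 1.5: program genes are ~4.5-fold up in their domain).
#' @param batch_strength sdlog of the per-slice per-gene log-normal batch
#'   factors (default 0.5).
#' @param dropout extra Bernoulli zeroing probability in `[0, 1)`
#'   (default 0.2).
#' @param library_size_mean mean library size per spot (default 1500).
#' @param dispersion negative binomial dispersion (default 0.5, i.e.
#'   `size = 2`).
#' @param program_frac fraction of genes in each domain's program
#'   (default 0.2).
#' @param irregular place spots uniformly at random instead of on a
#'   jittered grid (imaging-platform-like layouts; default FALSE).
#' @param seed root seed (default 1).
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n_slices = 3, spots_per_slice = 600,
                            n_genes = 300, n_domains = 5,
                            domain_geometry = c("bands", "voronoi"),
                            de_strength = 1.5, batch_strength = 0.5,
                            dropout = 0.2, library_size_mean = 1500,
                            dispersion = 0.5, program_frac = 0.2,
                            irregular = FALSE, seed = 1L) {
  domain_geometry <- match.arg(domain_geometry)
  stopifnot(n_slices >= 1, spots_per_slice > 0, n_genes > 0,
            n_domains >= 1, dropout >= 0, dropout < 1,
            de_strength >= 0, batch_strength >= 0, dispersion > 0)
  if (n_domains > spots_per_slice)
    stop("n_domains exceeds spots per slice: degenerate geometry",
         call. = FALSE)
  structure(as.list(environment()), class = "simulation_spec")
}

# jittered grid covering the unit square, hex-like row offset
place_spots <- function(n, irregular) {
  if (irregular) return(cbind(x = stats::runif(n), y = stats::runif(n)))
  nc <- ceiling(sqrt(n)); nr <- ceiling(n / nc)
  g <- expand.grid(col = seq_len(nc), row = seq_len(nr))[seq_len(n), ]
  x <- (g$col - 0.5 + ifelse(g$row %% 2 == 0, 0.25, -0.25)) / nc
  y <- (g$row - 0.5) / nr
  jit <- 0.2 / nc
  cbind(x = x + stats::runif(n, -jit, jit),
        y = y + stats::runif(n, -jit, jit))
}

#' Simulate multi-slice spatial transcriptomics data
#'
#' Gene mean model: `mu_gd = base_g * exp(de_strength * program_gd)` with
#' sparse binary domain programs; slice `s` multiplies gene `g` by a
#' log-normal batch factor `b_gs ~ LogNormal(0, batch_strength)`; per-spot
#' expected counts are `libsize_i * p_g` (relative means renormalized per
#' spot) and realized as negative binomial with fixed dispersion, then
#' thinned by Bernoulli dropout.
#'
#' @param spec a [simulation_spec()].
#' @return list of class `simulation` with `slices` (list of
#'   [slice_data()], labels attached), `truth` (data.frame: spot, slice,
#'   domain), `programs` (gene x domain binary matrix), `spec`.
#' @export
simulate_slices <- function(spec) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(derive_seed(spec$seed, "sim"))
  G <- spec$n_genes; D <- spec$n_domains
  base_g <- exp(stats::rnorm(G, mean = 0, sd = 1))
  programs <- matrix(0L, G, D)
  n_prog <- max(1L, round(spec$program_frac * G))
  for (d in seq_len(D)) programs[sample.int(G, n_prog), d] <- 1L
  vor_seeds <- if (spec$domain_geometry == "voronoi")
    cbind(stats::runif(D), stats::runif(D))
  size <- 1 / spec$dispersion

  slices <- vector("list", spec$n_slices)
  truth <- vector("list", spec$n_slices)
  for (s in seq_len(spec$n_slices)) {
    set.seed(derive_seed(spec$seed, paste0("slice", s)))
    n <- spec$spots_per_slice
    coords <- place_spots(n, spec$irregular)
    dom <- switch(spec$domain_geometry,
      # equal-frequency horizontal strata: band index is the floor of the
      # rank-scaled y coordinate, so marginals match 1/D per band
      bands = ceiling(D * rank(coords[, "y"], ties.method = "first") / n),
      voronoi = {
        jit <- vor_seeds + matrix(stats::rnorm(2 * D, sd = 0.02), D, 2)
        d2 <- outer(rowSums(coords^2), rowSums(jit^2), `+`) -
          2 * coords %*% t(jit)
        max.col(-d2)
      })
    b_gs <- if (spec$batch_strength > 0)
      exp(stats::rnorm(G, 0, spec$batch_strength)) else rep(1, G)
    mu_gd <- base_g * exp(spec$de_strength * programs)   # G x D
    lib <- stats::rlnorm(n, log(spec$library_size_mean) - 0.3^2 / 2, 0.3)
    counts <- matrix(0L, n, G)
    for (d in seq_len(D)) {
      idx <- which(dom == d)
      if (length(idx) == 0L) next
      p_g <- mu_gd[, d] * b_gs
      p_g <- p_g / sum(p_g)
      mu_mat <- outer(lib[idx], p_g)
      counts[idx, ] <- stats::rnbinom(length(mu_mat), mu = mu_mat,
                                      size = size)
    }
    if (spec$dropout > 0) {
      keep <- stats::rbinom(length(counts), 1L, 1 - spec$dropout)
      counts <- counts * keep
    }
    dimnames(counts) <- list(sprintf("s%d_spot%d", s, seq_len(n)),
                             sprintf("gene%d", seq_len(G)))
    slices[[s]] <- slice_data(counts, coords, sprintf("slice%d", s),
                              labels = dom)
    truth[[s]] <- data.frame(spot = rownames(counts), slice = s,
                             domain = dom)
  }
  structure(list(slices = slices, truth = do.call(rbind, truth),
                 programs = programs, spec = spec), class = "simulation")
}

#' Extract ground-truth labels from a simulation
#'
#' @param sim a `simulation` from [simulate_slices()].
#' @return list with `domain` (generating domain label per spot, slices
#'   concatenated in order) and `batch` (slice index per spot).
#' @export
ground_truth <- function(sim) {
  list(domain = sim$truth$domain, batch = sim$truth$slice)
}

#' Write a simulation to disk (MTX + coords + truth per slice)
#'
#' @param sim a `simulation`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(sim$slices)) {
    sl <- sim$slices[[s]]
    sd <- file.path(dir, sl$slice_id)
    dir.create(sd, showWarnings = FALSE)
    Matrix::writeMM(Matrix::t(sl$counts), file.path(sd, "matrix.mtx"))
    writeLines(sl$gene_names, file.path(sd, "features.tsv"))
    writeLines(sl$spot_ids, file.path(sd, "barcodes.tsv"))
    utils::write.csv(data.frame(x = sl$coords[, 1], y = sl$coords[, 2]),
                     file.path(sd, "coords.csv"), row.names = FALSE)
    utils::write.csv(data.frame(domain = sl$labels),
                     file.path(sd, "truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}
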