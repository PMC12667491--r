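# Shared fixtures, all generated in code. The small joint dataset used by
# the training tests is memoized so several test files can reuse it.

.fixture_env <- new.env(parent = emptyenv())

tiny_sim_spec <- function(...) {
  simulation_spec(n_slices = 2, spots_per_slice = 120, n_genes = 80,
                  n_domains = 3, library_size_mean = 800, seed = 7L, ...)
}

# a small but learnable joint dataset (2 slices x 120 spots, 3 domains)
small_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    sim <- simulate_slices(tiny_sim_spec())
    ds <- suppressWarnings(build_joint_dataset(
      sim$slices, min_spots = 10, min_total = 10,
      n_hvg = 80, n_components = 30, k = 6))
    .fixture_env$ds <- ds
    .fixture_env$gt <- ground_truth(sim)
  }
  list(ds = .fixture_env$ds, gt = .fixture_env$gt)
}

# deterministic toy slice with hand-set counts
toy_slice <- function(counts, slice_id = "s1", coords = NULL) {
  n <- nrow(counts)
  if (is.null(coords)) coords <- cbind(seq_len(n), 0)
  slice_data(counts, coords, slice_id)
}

random_labels <- function(n, k, seed) {
  set.seed(seed)
  sample.int(k, n, replace = TRUE)
}
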