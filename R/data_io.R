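# Reading per-slice expression + coordinates and the preprocessing chain:
# gene filtering on the concatenated data, library-size normalization,
# log1p, highly-variable-gene selection, PCA reduction.

#' Construct a SliceData object
#'
#' A `SliceData` bundles one tissue section: a spots x genes count matrix,
#' 2D spot coordinates in platform units, a slice identifier, and optional
#' per-spot domain labels.
#'
#' @param counts non-negative numeric matrix or sparse Matrix, spots x genes.
#' @param coords numeric matrix/data.frame with one row per spot, 2 columns.
#' @param slice_id character scalar.
#' @param labels optional per-spot domain annotation (factor/character).
#' @param gene_names,spot_ids optional identifiers; default from dimnames.
#' @return an object of class `slice_data`.
#' @export
slice_data <- function(counts, coords, slice_id, labels = NULL,
                       gene_names = NULL, spot_ids = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative", call. = FALSE)
  coords <- as.matrix(coords)
  if (ncol(coords) < 2L) stop("coords must have 2 columns", call. = FALSE)
  coords <- coords[, 1:2, drop = FALSE]
  if (nrow(coords) != nrow(counts))
    stop(sprintf(
      "slice '%s': %d spots in counts but %d coordinate rows",
      slice_id, nrow(counts), nrow(coords)), call. = FALSE)
  gene_names <- gene_names %||% colnames(counts) %||%
    paste0("gene", seq_len(ncol(counts)))
  if (anyDuplicated(gene_names))
    stop("gene_names must be unique within a slice", call. = FALSE)
  spot_ids <- spot_ids %||% rownames(counts) %||%
    paste0(slice_id, "_spot", seq_len(nrow(counts)))
  if (!is.null(labels) && length(labels) != nrow(counts))
    stop("labels length must equal spot count", call. = FALSE)
  colnames(counts) <- gene_names
  rownames(counts) <- spot_ids
  structure(list(counts = counts, coords = coords,
                 slice_id = as.character(slice_id),
                 labels = labels, gene_names = gene_names,
                 spot_ids = spot_ids),
            class = "slice_data")
}

#' @export
print.slice_data <- function(x, ...) {
  cat(sprintf("<slice_data> '%s': %d spots x %d genes%s\n", x$slice_id,
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$labels)) "" else ", labelled"))
  invisible(x)
}

#' Load slices from disk
#'
#' Each element of `paths` describes one slice as a named list with entries
#' `counts` and `coords` (file paths) and optionally `labels` and `id`.
#' Formats:
#' \describe{
#'   \item{mtx}{`counts` is a Matrix Market file with genes as rows and
#'     spots as columns (CellRanger convention), accompanied by
#'     `features`/`barcodes` TSVs (defaulting to `features.tsv` /
#'     `barcodes.tsv` next to the matrix); `coords` is a CSV with columns
#'     x,y in barcode order.}
#'   \item{csv}{`counts` is a dense CSV, spots x genes, first column =
#'     spot id; `coords` a CSV with x,y columns.}
#'   \item{h5container}{an HDF5 single-cell container with datasets
#'     `X` (genes x spots, dense) or CSC groups, `var/_index`,
#'     `obs/_index`, and per-spot coordinate columns under `obs`
#'     (names via `coord_cols`). Requires the rhdf5 package.}
#' }
#'
#' @param paths list of per-slice path lists.
#' @param format one of "mtx", "csv", "h5container".
#' @param coord_cols names of the coordinate columns (h5container only).
#' @return list of [slice_data()] objects, input order preserved.
#' @export
load_slices <- function(paths, format = c("mtx", "csv", "h5container"),
                        coord_cols = c("x", "y")) {
  format <- match.arg(format)
  lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    id <- p$id %||% sprintf("slice%d", i)
    loader <- switch(format, mtx = load_slice_mtx, csv = load_slice_csv,
                     h5container = function(p, id)
                       load_slice_h5(p, id, coord_cols))
    loader(p, id)
  })
}

read_coords <- function(path, n_expected, slice_id) {
  if (!file.exists(path))
    stop(sprintf("slice '%s': coordinates file not found: %s",
                 slice_id, path), call. = FALSE)
  co <- utils::read.csv(path)
  num <- vapply(co, is.numeric, logical(1))
  xy <- if (all(c("x", "y") %in% names(co))) co[, c("x", "y")]
        else co[, which(num)[1:2]]
  if (nrow(xy) != n_expected)
    stop(sprintf("slice '%s': %d spots but %d coordinate rows",
                 slice_id, n_expected, nrow(xy)), call. = FALSE)
  as.matrix(xy)
}

load_slice_mtx <- function(p, id) {
  m <- Matrix::readMM(p$counts)           # genes x spots
  dir <- dirname(p$counts)
  feat <- p$features %||% file.path(dir, "features.tsv")
  barc <- p$barcodes %||% file.path(dir, "barcodes.tsv")
  gn <- if (file.exists(feat))
    utils::read.delim(feat, header = FALSE)[[1]] else NULL
  bc <- if (file.exists(barc))
    utils::read.delim(barc, header = FALSE)[[1]] else NULL
  counts <- Matrix::t(m)
  coords <- read_coords(p$coords, nrow(counts), id)
  labels <- if (!is.null(p$labels)) utils::read.csv(p$labels)[[1]]
  slice_data(counts, coords, id, labels = labels,
             gene_names = gn, spot_ids = bc)
}

load_slice_csv <- function(p, id) {
  df <- utils::read.csv(p$counts, row.names = 1, check.names = FALSE)
  counts <- as.matrix(df)
  coords <- read_coords(p$coords, nrow(counts), id)
  labels <- if (!is.null(p$labels)) utils::read.csv(p$labels)[[1]]
  slice_data(counts, coords, id, labels = labels)
}

load_slice_h5 <- function(p, id, coord_cols) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("h5container input requires the rhdf5 package", call. = FALSE)
  f <- p$counts
  X <- rhdf5::h5read(f, "X")                # genes x spots or CSC group
  if (is.list(X)) {
    shape <- attr(X, "shape") %||% rhdf5::h5readAttributes(f, "X")$shape
    X <- Matrix::sparseMatrix(i = as.integer(X$indices) + 1L,
                              p = as.integer(X$indptr),
                              x = as.numeric(X$data),
                              dims = rev(as.integer(shape)))
  }
  genes <- as.character(rhdf5::h5read(f, "var/_index"))
  spots <- as.character(rhdf5::h5read(f, "obs/_index"))
  counts <- if (nrow(X) == length(genes)) Matrix::t(X) else X
  obs <- rhdf5::h5ls(f)
  have <- obs$name[obs$group == "/obs"]
  if (!all(coord_cols %in% have))
    stop(sprintf("slice '%s': coordinate columns %s missing from obs",
                 id, paste(coord_cols, collapse = ",")), call. = FALSE)
  coords <- cbind(as.numeric(rhdf5::h5read(f, paste0("obs/", coord_cols[1]))),
                  as.numeric(rhdf5::h5read(f, paste0("obs/", coord_cols[2]))))
  slice_data(counts, coords, id, gene_names = genes, spot_ids = spots)
}

#' Filter genes on the concatenated multi-slice data
#'
#' Slices are first intersected to a common gene universe, then a gene is
#' retained iff it is expressed (count > 0) in at least `min_spots` spots
#' across all slices together and its total count is at least `min_total`.
#' The same retained set is applied to every slice.
#'
#' @param slices list of [slice_data()].
#' @param min_spots minimum number of expressing spots (default 50).
#' @param min_total minimum total count (default 10).
#' @return list of filtered `slice_data` objects.
#' @export
filter_genes <- function(slices, min_spots = 50, min_total = 10) {
  common <- Reduce(intersect, lapply(slices, `[[`, "gene_names"))
  if (length(common) == 0L) stop("slices share no genes", call. = FALSE)
  slices <- lapply(slices, function(s) {
    s$counts <- s$counts[, common, drop = FALSE]
    s$gene_names <- common
    s
  })
  expressed <- Reduce(`+`, lapply(slices, function(s)
    Matrix::colSums(s$counts > 0)))
  totals <- Reduce(`+`, lapply(slices, function(s)
    Matrix::colSums(s$counts)))
  keep <- expressed >= min_spots & totals >= min_total
  if (!any(keep))
    stop(sprintf(
      "no gene passes the filters (min_spots=%d expressing spots, min_total=%d total counts)",
      min_spots, min_total), call. = FALSE)
  lapply(slices, function(s) {
    s$counts <- s$counts[, keep, drop = FALSE]
    s$gene_names <- common[keep]
    s
  })
}

#' Normalize, log-transform and select highly variable genes
#'
#' Per-spot counts are scaled to the median library size of the
#' concatenated data, log(1+x)-transformed, and the `n_hvg` genes with the
#' highest normalized dispersion (dispersion = var/mean of the log data,
#' z-scored within 20 mean-expression bins) are kept. Rows are ordered
#' slice-by-slice in input order.
#'
#' @param slices list of filtered [slice_data()].
#' @param n_hvg number of highly variable genes to keep (default 2000).
#' @return dense numeric matrix (total spots x n_hvg) with attributes
#'   `hvg` (gene names) and `slice_of` (integer slice index per row).
#' @export
normalize_log_hvg <- function(slices, n_hvg = 2000) {
  counts <- do.call(rbind, lapply(slices, `[[`, "counts"))
  slice_of <- rep(seq_along(slices),
                  vapply(slices, function(s) nrow(s$counts), integer(1)))
  lib <- Matrix::rowSums(counts)
  lib[lib == 0] <- 1
  target <- stats::median(lib)
  E <- as.matrix(counts / lib * target)
  E <- log1p(E)
  mu <- colMeans(E)
  v <- apply(E, 2L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # Seurat-style normalized dispersion: z-score within mean bins so that
  # highly expressed genes do not dominate the ranking.
  bins <- cut(mu, breaks = unique(stats::quantile(mu, probs = seq(0, 1, length.out = 21))),
              include.lowest = TRUE)
  nd <- stats::ave(disp, bins, FUN = function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  nd[v == 0] <- -Inf                      # constant genes are never HVGs
  if (n_hvg > ncol(E)) {
    warning(sprintf("n_hvg=%d exceeds gene count %d; clamped", n_hvg, ncol(E)))
    n_hvg <- ncol(E)
  }
  keep <- order(nd, decreasing = TRUE)[seq_len(n_hvg)]
  keep <- sort(keep)
  out <- E[, keep, drop = FALSE]
  attr(out, "hvg") <- colnames(counts)[keep]
  attr(out, "slice_of") <- slice_of
  out
}

#' Reduce expression to principal components
#'
#' Centers the matrix and projects it onto the leading principal axes.
#' The basis (rotation, column means, gene names) is returned for the
#' inverse mapping used by [denoise_expression()].
#'
#' @param E numeric matrix (spots x genes), typically from
#'   [normalize_log_hvg()].
#' @param n_components target dimensionality (default 200).
#' @param seed kept for interface symmetry; the truncated SVD used here is
#'   deterministic.
#' @return list with `X` (spots x n_components) and `basis`
#'   (list: rotation, center, genes).
#' @export
reduce_pca <- function(E, n_components = 200, seed = 0L) {
  r <- min(nrow(E), ncol(E))
  if (n_components >= r) {
    warning(sprintf("n_components=%d >= min(dim)=%d; reduced to %d",
                    n_components, r, r - 1L))
    n_components <- r - 1L
  }
  ctr <- colMeans(E)
  Ec <- sweep(E, 2L, ctr)
  sv <- svd(Ec, nu = 0, nv = n_components)
  rot <- sv$v
  # deterministic sign convention: largest-|loading| entry positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  X <- Ec %*% rot
  dimnames(X) <- list(rownames(E), paste0("PC", seq_len(ncol(X))))
  list(X = X,
       basis = list(rotation = rot, center = ctr, genes = colnames(E),
                    sdev = sv$d[seq_len(n_components)] / sqrt(max(1, nrow(E) - 1))))
}

#' Build the joint dataset fed to the model
#'
#' Runs the preprocessing chain (gene filter, normalization, HVG, PCA) and
#' builds the block-diagonal normalized spatial graph.
#'
#' @param slices list of [slice_data()].
#' @param min_spots,min_total gene filter thresholds, see [filter_genes()].
#' @param n_hvg highly variable genes to retain.
#' @param n_components PCA dimensionality.
#' @param k spatial neighbors per spot.
#' @param metric distance metric for the spatial graph.
#' @param seed root seed (PCA is deterministic; kept for provenance).
#' @return object of class `joint_dataset` with fields `X`, `A` (binary
#'   block-diagonal adjacency), `A_hat` (symmetrically normalized with
#'   self-loops), `slice_of`, `gene_space`, `coords`, `labels`, `slice_ids`.
#' @export
build_joint_dataset <- function(slices, min_spots = 50, min_total = 10,
                                n_hvg = 2000, n_components = 200,
                                k = 8, metric = "euclidean", seed = 0L) {
  slices <- filter_genes(slices, min_spots = min_spots, min_total = min_total)
  E <- normalize_log_hvg(slices, n_hvg = n_hvg)
  red <- reduce_pca(E, n_components = n_components, seed = seed)
  graphs <- lapply(slices, function(s)
    build_knn_graph(s$coords, k = k, metric = metric))
  G <- block_diagonal_join(graphs)
  A_hat <- normalize_adjacency(G$A, add_self_loops = TRUE)
  labels <- if (all(!vapply(slices, function(s) is.null(s$labels), logical(1))))
    unlist(lapply(slices, `[[`, "labels"), use.names = FALSE) else NULL
  structure(list(
    X = red$X,
    A = G$A,
    A_hat = A_hat,
    slice_of = attr(E, "slice_of"),
    gene_space = red$basis,
    coords = do.call(rbind, lapply(slices, `[[`, "coords")),
    labels = labels,
    slice_ids = vapply(slices, `[[`, character(1), "slice_id"),
    n = nrow(red$X), m = ncol(red$X)), class = "joint_dataset")
}

#' @export
print.joint_dataset <- function(x, ...) {
  cat(sprintf("<joint_dataset> %d spots x %d PCs, %d slices, %d edges\n",
              x$n, x$m, length(x$slice_ids), Matrix::nnzero(x$A) / 2))
  invisible(x)
}
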