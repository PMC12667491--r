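# Downstream utilities: center-aligned 3D stacking of consecutive
# sections, inverse-PCA expression denoising, and per-domain marker
# ranking.

#' Stack slices in 3D by center alignment
#'
#' Each slice is translated so its 2D coordinate centroid sits at the
#' origin; consecutive slices are given z-coordinates
#' `slice_index * z_spacing`. No rotation or scaling is applied
#' (consecutive sections are assumed to share orientation).
#'
#' @param slices list of [slice_data()].
#' @param z_spacing distance between consecutive sections (default 1).
#' @return object of class `stack3d`: `coords3d` (n x 3), `z_spacing`,
#'   `slice_order`, `slice_of`.
#' @export
center_align_stack <- function(slices, z_spacing = 1) {
  if (length(slices) == 0L) stop("need at least one slice", call. = FALSE)
  parts <- lapply(seq_along(slices), function(s) {
    co <- slices[[s]]$coords
    ctr <- colMeans(co)
    cbind(x = co[, 1] - ctr[1], y = co[, 2] - ctr[2],
          z = (s - 1) * z_spacing)
  })
  structure(list(coords3d = do.call(rbind, parts), z_spacing = z_spacing,
                 slice_order = vapply(slices, `[[`, character(1), "slice_id"),
                 slice_of = rep(seq_along(slices),
                                vapply(parts, nrow, integer(1)))),
            class = "stack3d")
}

#' Denoise expression by inverse PCA of the decoder output
#'
#' Maps the decoder's reconstruction in PCA space back to the highly
#' variable gene space using the stored basis, and clips negative values
#' at zero (log-normalized expression is non-negative).
#'
#' @param X_tilde reconstructed reduced matrix (n x n_components), e.g.
#'   from [decode_expression()].
#' @param gene_space the `gene_space`/`basis` stored by
#'   [build_joint_dataset()] / [reduce_pca()].
#' @return denoised matrix (n x genes) with gene names.
#' @export
denoise_expression <- function(X_tilde, gene_space) {
  if (is.null(gene_space$rotation))
    stop("PCA basis missing: run reduce_pca/build_joint_dataset first",
         call. = FALSE)
  E <- X_tilde %*% t(gene_space$rotation)
  E <- sweep(E, 2L, gene_space$center, `+`)
  E[E < 0] <- 0
  colnames(E) <- gene_space$genes
  E
}

#' Rank marker genes per domain
#'
#' Wilcoxon rank-sum test of each gene in-domain versus all other spots,
#' with Benjamini-Hochberg adjusted p-values and log2 fold change of mean
#' expression (+1 pseudocount). Domains with fewer than 3 spots are
#' skipped with a warning.
#'
#' @param expression numeric matrix (spots x genes), e.g. denoised or
#'   log-normalized expression.
#' @param labels per-spot domain labels.
#' @param top_n markers reported per domain (default 10).
#' @return data.frame with columns `domain`, `gene`, `rank`, `statistic`,
#'   `log2fc`, `p_value`, `p_adj`.
#' @export
rank_markers <- function(expression, labels, top_n = 10) {
  labels <- as.character(labels)
  doms <- sort(unique(labels))
  out <- list()
  for (d in doms) {
    in_d <- labels == d
    if (sum(in_d) < 3) {
      warning(sprintf("domain '%s' has < 3 spots; skipped", d))
      next
    }
    nin <- sum(in_d); nout <- sum(!in_d)
    # rank-sum statistic per gene, z-scored (normal approximation with
    # tie correction is unnecessary for ranking; p-values via wilcox)
    stats_g <- apply(expression, 2L, function(g) {
      r <- rank(g)
      sum(r[in_d]) - nin * (nin + 1) / 2      # Mann-Whitney U
    })
    pv <- vapply(seq_len(ncol(expression)), function(j) {
      suppressWarnings(stats::wilcox.test(
        expression[in_d, j], expression[!in_d, j],
        alternative = "greater", exact = FALSE)$p.value)
    }, numeric(1))
    m_in <- colMeans(expression[in_d, , drop = FALSE])
    m_out <- colMeans(expression[!in_d, , drop = FALSE])
    lfc <- log2((m_in + 1) / (m_out + 1))
    padj <- stats::p.adjust(pv, method = "BH")
    ord <- order(stats_g, decreasing = TRUE)[seq_len(min(top_n,
                                                         ncol(expression)))]
    out[[d]] <- data.frame(
      domain = d,
      gene = colnames(expression)[ord] %||% as.character(ord),
      rank = seq_along(ord),
      statistic = stats_g[ord], log2fc = lfc[ord],
      p_value = pv[ord], p_adj = padj[ord], row.names = NULL)
  }
  do.call(rbind, out)
}
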