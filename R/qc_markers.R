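#' Filter low-quality nuclei
#'
#' Removes nuclei with fewer than `min_genes` detected genes, more than
#' `max_genes` detected genes, or a mitochondrial transcript fraction above
#' `max_mito` (removal bounds exclusive, exactly as published: remove <500,
#' remove >8000, remove >5%). Detected gene = count > 0. Mitochondrial genes
#' are identified by id prefix. Removed counts per criterion are logged.
#'
#' @param cm A `CountMatrix`.
#' @param min_genes,max_genes Detected-gene bounds (cells kept when
#'   `min_genes <= detected <= max_genes`).
#' @param max_mito Maximum mitochondrial fraction (kept when `<= max_mito`).
#' @param mito_prefix Gene-id prefix marking mitochondrial genes.
#' @return The filtered `CountMatrix`.
#' @export
filter_nuclei <- function(cm, min_genes = 500L, max_genes = 8000L,
                          max_mito = 0.05, mito_prefix = "MT-") {
  detected <- Matrix::colSums(cm$counts > 0)
  depth <- Matrix::colSums(cm$counts)
  mito_genes <- startsWith(cm$gene_ids, mito_prefix)
  mito_frac <- if (any(mito_genes))
    Matrix::colSums(cm$counts[mito_genes, , drop = FALSE]) / pmax(depth, 1)
  else rep(0, length(depth))
  low <- detected < min_genes
  high <- detected > max_genes
  mito <- mito_frac > max_mito
  keep <- !(low | high | mito)
  am_log(sprintf(
    "filter_nuclei: removed %d (<%d genes), %d (>%d genes), %d (mito >%g); kept %d/%d",
    sum(low), min_genes, sum(high), max_genes, sum(mito), max_mito,
    sum(keep), length(keep)))
  if (!any(keep)) stopf("filter_nuclei: all cells removed")
  subset_cells(cm, which(keep))
}

#' Depth-normalize and log-transform counts
#'
#' Size factor per cell = depth / median depth; values =
#' `log1p(counts / size_factor)`. A deterministic, variance-reasonable
#' log-scale stand-in for regression-based variance stabilization (see the
#' methods vignette). Raw counts travel with the object because marker
#' detection tests on raw counts.
#'
#' @param cm A `CountMatrix`.
#' @return An object of class `NormalizedMatrix` with fields `values`
#'   (genes x cells, sparse), `size_factors`, `counts` and the `CountMatrix`
#'   annotation fields.
#' @export
normalize_counts <- function(cm) {
  depth <- Matrix::colSums(cm$counts)
  if (any(depth == 0)) stopf("cells with zero total counts")
  sf <- depth / median(depth)
  scaled <- cm$counts %*% Matrix::Diagonal(x = 1 / sf)
  values <- scaled
  values@x <- log1p(values@x)
  dimnames(values) <- dimnames(cm$counts)
  structure(list(values = values, size_factors = setNames(sf, cm$barcodes),
                 log_base = "natural (log1p)", counts = cm$counts,
                 gene_ids = cm$gene_ids, barcodes = cm$barcodes,
                 sample_of = cm$sample_of, celltype_of = cm$celltype_of,
                 gene_pos = cm$gene_pos),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix: %d genes x %d cells (%s)\n",
              nrow(x$values), ncol(x$values), x$log_base))
  invisible(x)
}

#' Cluster marker detection (Wilcoxon, Bonferroni)
#'
#' One-vs-rest Wilcoxon rank-sum test per gene on raw counts, reporting
#' log2 fold-change (on depth-normalized means, pseudocount 1), expression
#' fractions in and out of the cluster, raw and Bonferroni-adjusted p.
#' Only genes with positive difference, `log2fc > min_log2fc` and expressed
#' in more than `min_frac` of cells in at least one of the two groups are
#' reported. Bonferroni is over all genes tested.
#'
#' @param nm A `NormalizedMatrix`.
#' @param labels Per-cell cluster labels (named by barcode or in cell order).
#' @param min_log2fc,min_frac,only_positive Reporting thresholds.
#' @return A `data.frame` (`MarkerTable`): `cluster`, `gene`, `log2fc`,
#'   `frac_in`, `frac_out`, `p`, `p_adj`, sorted by cluster then `p_adj`.
#' @export
detect_markers <- function(nm, labels, min_log2fc = 0.25, min_frac = 0.10,
                           only_positive = TRUE) {
  labels <- as.character(labels)
  if (length(labels) != length(nm$barcodes)) stopf("one label per cell required")
  tab <- table(labels)
  if (length(tab) < 2) stopf("need >= 2 labels")
  counts <- as.matrix(nm$counts)
  scaled <- expm1(as.matrix(nm$values))
  n_genes <- nrow(counts)
  out <- list()
  for (cl in names(tab)) {
    if (tab[[cl]] < 3) {
      warnf("detect_markers: label '%s' has <3 cells, skipped", cl)
      next
    }
    in_cl <- labels == cl
    m_in <- rowMeans(scaled[, in_cl, drop = FALSE])
    m_out <- rowMeans(scaled[, !in_cl, drop = FALSE])
    f_in <- rowMeans(counts[, in_cl, drop = FALSE] > 0)
    f_out <- rowMeans(counts[, !in_cl, drop = FALSE] > 0)
    log2fc <- log2(m_in + 1) - log2(m_out + 1)
    keep <- (f_in > min_frac | f_out > min_frac) & log2fc > min_log2fc
    if (only_positive) keep <- keep & (m_in > m_out)
    idx <- which(keep)
    if (!length(idx)) next
    p <- vapply(idx, function(g) {
      wilcox.test(counts[g, in_cl], counts[g, !in_cl], exact = FALSE)$p.value
    }, numeric(1))
    out[[cl]] <- data.frame(cluster = cl, gene = nm$gene_ids[idx],
                            log2fc = log2fc[idx], frac_in = f_in[idx],
                            frac_out = f_out[idx], p = p,
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(cluster = character(), gene = character(),
                      log2fc = numeric(), frac_in = numeric(),
                      frac_out = numeric(), p = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$p_adj <- pmin(res$p * n_genes, 1)
  res <- res[order(res$cluster, res$p_adj, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}
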