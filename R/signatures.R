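#' Single-sample gene-set enrichment (ssGSEA) score
#'
#' The rank-based running-sum statistic: genes are ranked by expression
#' (average ranks for ties, the highest-expressed gene carrying the largest
#' rank). Walking the genes from highest to lowest expression, the score is
#' the sum over positions of the difference between the weighted in-set
#' ECDF (weights `rank^alpha`, normalized over the set) and the unweighted
#' out-of-set ECDF. Deterministic; invariant to monotone rank-preserving
#' transformations of the expression values. The degenerate case where the
#' set covers every gene is defined as 0.
#'
#' @param expr Named numeric vector: one sample's expression over genes.
#' @param gene_set Character vector; must intersect `names(expr)`.
#' @param alpha Rank-weighting exponent (default 0.25).
#' @return A single number.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25) {
  if (is.null(names(expr))) stopf("expr must be named by gene")
  in_set <- names(expr) %in% unique(gene_set)
  if (!any(in_set)) stopf("ssgsea_score: empty intersection with gene set")
  n <- length(expr)
  m <- sum(in_set)
  if (m == n) return(0)
  r <- rank(expr, ties.method = "average")
  ord <- order(-expr, names(expr))      # descending, ties stable by gene id
  in_ord <- in_set[ord]
  w <- r[ord]^alpha
  w[!in_ord] <- 0
  cdf_in <- cumsum(w) / sum(w)
  cdf_out <- cumsum(!in_ord) / (n - m)
  sum(cdf_in - cdf_out)
}

#' ssGSEA scores for many samples and gene sets
#'
#' @param expr samples x genes matrix (e.g. `BulkCohort$expr`).
#' @param gene_sets Named list of character vectors.
#' @param alpha Rank exponent.
#' @param normalize If `TRUE`, divide all scores by the range of scores
#'   across the table (off by default).
#' @return samples x sets numeric matrix.
#' @export
ssgsea_matrix <- function(expr, gene_sets, alpha = 0.25, normalize = FALSE) {
  out <- vapply(gene_sets, function(gs)
    apply(expr, 1, function(v) ssgsea_score(v, gs, alpha)),
    numeric(nrow(expr)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(expr),
                                       dimnames = list(rownames(expr),
                                                       names(gene_sets)))
  if (normalize) {
    rng <- diff(range(out))
    if (rng > 0) out <- out / rng
  }
  out
}

#' Build a cell-population signature matrix
#'
#' Mean depth-normalized expression per population over the marker-gene
#' space (union of cluster markers). Populations with fewer than
#' `min_cells_signature` cells are excluded and logged. Near-collinear
#' columns trigger a condition-number warning.
#'
#' @param cm A `CountMatrix`.
#' @param labels Per-cell population labels.
#' @param marker_table A `MarkerTable` from [detect_markers()] supplying the
#'   gene space; `NULL` uses all genes.
#' @param min_cells_signature Published default 50.
#' @return A `SignatureMatrix`: genes x populations matrix with a
#'   `cell_counts` attribute.
#' @export
build_signature_matrix <- function(cm, labels, marker_table = NULL,
                                   min_cells_signature = 50L) {
  labels <- as.character(labels)
  if (length(labels) != length(cm$barcodes)) stopf("one label per cell")
  depth <- Matrix::colSums(cm$counts)
  scaled <- cm$counts %*% Matrix::Diagonal(x = median(depth) / depth)
  genes <- if (is.null(marker_table)) cm$gene_ids else
    intersect(unique(marker_table$gene), cm$gene_ids)
  if (!length(genes)) stopf("no marker genes present")
  gi <- match(genes, cm$gene_ids)
  tab <- table(labels)
  use <- names(tab)[tab >= min_cells_signature]
  dropped <- setdiff(names(tab), use)
  if (length(dropped))
    am_log(sprintf("build_signature_matrix: excluded %s (<%d cells)",
                   paste(dropped, collapse = ", "), min_cells_signature))
  if (length(use) < 1) stopf("no population reaches min_cells_signature")
  sig <- vapply(use, function(pp)
    Matrix::rowMeans(scaled[gi, labels == pp, drop = FALSE]),
    numeric(length(gi)))
  rownames(sig) <- genes
  if (ncol(sig) >= 2) {
    kp <- kappa(sig, exact = FALSE)
    if (!is.finite(kp) || kp > 1e8)
      warnf("build_signature_matrix: near-collinear columns (kappa = %.3g)",
            kp)
  }
  structure(sig, cell_counts = tab[use], class = c("SignatureMatrix",
                                                   class(sig)))
}

#' Cell-fraction deconvolution by non-negative least squares
#'
#' Per sample, the bulk vector over the shared gene space is regressed on
#' the signature columns under a non-negativity constraint
#' (`pracma::lsqnonneg`); coefficients are renormalized to sum to 1 so the
#' output lies in the simplex. The per-sample residual norm is reported.
#'
#' @param bulk A `BulkCohort` (or samples x genes matrix).
#' @param sig A `SignatureMatrix` with at least 2 populations.
#' @param min_gene_overlap Error floor on shared genes (default 50).
#' @return `list(fractions = samples x populations matrix, residuals =
#'   named numeric)`.
#' @export
deconvolve <- function(bulk, sig, min_gene_overlap = 50L) {
  expr <- if (inherits(bulk, "BulkCohort")) bulk$expr else as.matrix(bulk)
  if (ncol(sig) < 2) stopf("need >= 2 populations")
  shared <- intersect(colnames(expr), rownames(sig))
  if (length(shared) < min_gene_overlap)
    stopf("gene overlap %d below floor %d", length(shared), min_gene_overlap)
  S <- as.matrix(sig)[shared, , drop = FALSE]
  fr <- matrix(NA_real_, nrow(expr), ncol(S),
               dimnames = list(rownames(expr), colnames(S)))
  res <- setNames(numeric(nrow(expr)), rownames(expr))
  for (i in seq_len(nrow(expr))) {
    y <- as.numeric(expr[i, shared])
    fit <- pracma::lsqnonneg(S, y)
    x <- fit$x
    if (sum(x) == 0) {
      warnf("deconvolve: all-zero fit for %s, uniform fractions returned",
            rownames(expr)[i])
      x <- rep(1, length(x))
    }
    fr[i, ] <- x / sum(x)
    res[i] <- sqrt(sum((y - S %*% fit$x)^2))
  }
  list(fractions = fr, residuals = res)
}

#' Split validation of deconvolution on held-out pseudobulk
#'
#' Per population, draws a training set of exactly 1000 cells when the
#' population has more than `big_population` cells, otherwise 50% of its
#' cells; builds the signature matrix from the training cells; forms a
#' pseudobulk from the held-out cells (summed counts); deconvolves it and
#' reports the Pearson correlation between estimated fractions and the true
#' held-out proportions. Reproducible under `seed`.
#'
#' @param cm A `CountMatrix`.
#' @param labels Per-cell population labels.
#' @param sig_builder Function `(cm_train, labels_train) -> SignatureMatrix`;
#'   the default builds mean profiles over all genes with the configured
#'   cell floor.
#' @param seed RNG seed for the training draws.
#' @param n_train,big_population Published protocol: 1000 and 2000.
#' @param min_cells_signature Passed to the default builder.
#' @return `list(r, estimated, truth, n_train)`; `n_train` is the named
#'   per-population training-set size.
#' @export
split_validate <- function(cm, labels, sig_builder = NULL, seed = 1L,
                           n_train = 1000L, big_population = 2000L,
                           min_cells_signature = 50L) {
  labels <- as.character(labels)
  if (is.null(sig_builder))
    sig_builder <- function(cm_t, lab_t)
      build_signature_matrix(cm_t, lab_t,
                             min_cells_signature = min_cells_signature)
  pops <- sort(unique(labels))
  train_idx <- with_seed(seed, {
    unlist(lapply(pops, function(pp) {
      cells <- which(labels == pp)
      k <- if (length(cells) > big_population) n_train
           else floor(length(cells) / 2)
      sample(cells, k)
    }))
  })
  n_tr <- table(labels[train_idx])[pops]
  test_idx <- setdiff(seq_along(labels), train_idx)
  sig <- sig_builder(subset_cells(cm, train_idx), labels[train_idx])
  pseudo <- Matrix::rowSums(cm$counts[, test_idx, drop = FALSE])
  pb <- matrix(pseudo, 1, dimnames = list("pseudobulk", cm$gene_ids))
  est <- deconvolve(pb, sig, min_gene_overlap = min(50L, nrow(sig)))
  truth <- table(factor(labels[test_idx], levels = colnames(sig)))
  truth <- as.numeric(truth) / sum(truth)
  names(truth) <- colnames(sig)
  est_v <- est$fractions[1, names(truth)]
  r <- cor(est_v, truth)
  am_log(sprintf("split_validate: r = %.3f over %d populations", r,
                 length(truth)))
  list(r = r, estimated = est_v, truth = truth,
       n_train = setNames(as.integer(n_tr), pops))
}
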