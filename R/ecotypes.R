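#' Z-score signature columns within datasets and cap
#'
#' Per signature and per dataset, scores are standardized to mean 0, SD 1
#' (so the datasets can be merged), then clamped to `[-zcap, zcap]`.
#' Constant columns within a dataset become zeros with a warning; the
#' number of clamped values is logged and attached as an attribute.
#'
#' @param scores samples x signatures matrix.
#' @param dataset_of Dataset id per sample (named by sample or in row
#'   order); each dataset needs at least 3 samples.
#' @param zcap Published default 3.
#' @return Matrix of the same shape with attribute `n_clamped`.
#' @export
zscore_cap <- function(scores, dataset_of, zcap = 3) {
  scores <- as.matrix(scores)
  dataset_of <- as.character(dataset_of)
  if (length(dataset_of) != nrow(scores)) stopf("one dataset id per sample")
  if (any(table(dataset_of) < 3)) stopf("each dataset needs >= 3 samples")
  z <- scores
  for (d in unique(dataset_of)) {
    rows <- dataset_of == d
    block <- scores[rows, , drop = FALSE]
    mu <- colMeans(block)
    sg <- apply(block, 2, sd)
    if (any(sg == 0)) {
      warnf("zscore_cap: constant column(s) in dataset %s set to 0", d)
      sg[sg == 0] <- Inf
    }
    z[rows, ] <- sweep(sweep(block, 2, mu), 2, sg, `/`)
  }
  n_clamped <- sum(abs(z) > zcap)
  if (n_clamped) am_log(sprintf("zscore_cap: %d values clamped to +/-%g",
                                n_clamped, zcap))
  z <- pmin(pmax(z, -zcap), zcap)
  attr(z, "n_clamped") <- n_clamped
  z
}

#' Group signatures into ecotypes by consensus partition clustering
#'
#' Signatures are the objects, samples the features. For each k in
#' `2..max_k`, samples are subsampled `n_resamples` times at
#' `subsample_frac`; each subsample is clustered by average-linkage
#' hierarchical clustering with distance 1 - Pearson correlation, and
#' co-clustering of signature pairs is accumulated into a consensus matrix.
#' k is chosen to maximize mean within-cluster consensus minus mean
#' between-cluster consensus of the partition obtained by clustering the
#' consensus matrix at k; ties go to the smallest k. Deterministic under
#' `seed`.
#'
#' @param z samples x signatures matrix (capped Z-scores from
#'   [zscore_cap()]); needs >= 4 signatures and >= 20 samples.
#' @param max_k Published default 10; must be < number of signatures.
#' @param n_resamples,subsample_frac Consensus scheme parameters (100, 0.8).
#' @param seed RNG seed.
#' @return An `EcotypeModel`: `list(assignment = named integer, k,
#'   consensus = signatures x signatures matrix at the chosen k,
#'   k_scores)`.
#' @export
consensus_partition <- function(z, max_k = 10L, n_resamples = 100L,
                                subsample_frac = 0.8, seed = 1L) {
  z <- as.matrix(z)
  p <- ncol(z); n <- nrow(z)
  if (p < 4) stopf("need >= 4 signatures")
  if (n < 20) stopf("need >= 20 samples")
  if (max_k >= p) stopf("max_k (%d) must be below the number of signatures (%d)",
                        max_k, p)
  sigs <- colnames(z) %||% sprintf("Sig%02d", seq_len(p))
  colnames(z) <- sigs
  ks <- 2:max_k
  with_seed(seed, {
    consensus <- lapply(ks, function(k) matrix(0, p, p,
                                               dimnames = list(sigs, sigs)))
    names(consensus) <- ks
    m <- max(2L, floor(n * subsample_frac))
    for (b in seq_len(n_resamples)) {
      rows <- sample.int(n, m)
      d <- as.dist(1 - cor(z[rows, , drop = FALSE]))
      hc <- hclust(d, method = "average")
      for (j in seq_along(ks)) {
        cl <- cutree(hc, k = ks[j])
        same <- outer(cl, cl, `==`) * 1
        consensus[[j]] <- consensus[[j]] + same
      }
    }
    consensus <- lapply(consensus, function(C) C / n_resamples)
    k_scores <- setNames(numeric(length(ks)), ks)
    assignments <- list()
    for (j in seq_along(ks)) {
      C <- consensus[[j]]
      hc2 <- hclust(as.dist(1 - C), method = "average")
      cl <- cutree(hc2, k = ks[j])
      assignments[[j]] <- cl
      same <- outer(cl, cl, `==`)
      off <- upper.tri(C)
      within <- C[off & same]
      between <- C[off & !same]
      k_scores[j] <- (if (length(within)) mean(within) else 1) -
        (if (length(between)) mean(between) else 0)
    }
    best <- which.max(k_scores)   # ties: smallest k (first index)
    am_log(sprintf("consensus_partition: chose k = %d (score %.3f)",
                   ks[best], k_scores[best]))
    structure(list(assignment = assignments[[best]], k = ks[best],
                   consensus = consensus[[best]], k_scores = k_scores),
              class = "EcotypeModel")
  })
}

#' @export
print.EcotypeModel <- function(x, ...) {
  cat(sprintf("EcotypeModel: %d ecotypes over %d signatures\n", x$k,
              length(x$assignment)))
  invisible(x)
}

#' Per-sample ecotype scores
#'
#' The score of a sample for an ecotype is the sum of its capped Z-scores
#' over the ecotype's member signatures — exactly, so scores are linear in
#' the inputs and invariant to member order.
#'
#' @param z samples x signatures capped Z-score matrix.
#' @param model An `EcotypeModel` (or a named assignment vector).
#' @return samples x ecotypes matrix, columns `Eco1..Ecok`.
#' @export
ecotype_scores <- function(z, model) {
  assignment <- if (inherits(model, "EcotypeModel")) model$assignment
                else model
  z <- as.matrix(z)
  miss <- setdiff(names(assignment), colnames(z))
  if (length(miss)) stopf("signatures missing from z: %s",
                          paste(miss, collapse = ", "))
  eks <- sort(unique(assignment))
  out <- vapply(eks, function(e) {
    members <- names(assignment)[assignment == e]
    rowSums(z[, members, drop = FALSE])
  }, numeric(nrow(z)))
  colnames(out) <- sprintf("Eco%d", eks)
  rownames(out) <- rownames(z)
  out
}
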