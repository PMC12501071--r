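#' Sørensen index of two gene sets
#'
#' `2 |A ∩ B| / (|A| + |B|)`, in `[0, 1]`: 1 iff the sets are equal, 0 iff
#' disjoint. Inputs are treated as sets (duplicates removed).
#'
#' @param a,b Non-empty character vectors.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' sorensen_index(c("g1", "g2", "g3"), c("g2", "g3", "g4"))  # 2/3
sorensen_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) stopf("sorensen_index: empty set")
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Per-tumor candidate gene modules from PCA
#'
#' PCA on centered (not scaled) log-normalized expression of one tumor's
#' cells; zero-variance genes are excluded before the decomposition. Each of
#' the first `n_components` components yields two modules: the `top_k` genes
#' with the largest positive loadings and the `top_k` with the largest
#' negative loadings (ties broken by gene id). Tumors with fewer than
#' `min_cells` cells are skipped with a logged reason.
#'
#' @param nm A `NormalizedMatrix` restricted to one tumor's cells (or pass
#'   `tumor` to subset by `sample_of`).
#' @param tumor Optional sample id to subset on.
#' @param n_components,top_k,min_cells Parameters (published defaults 10,
#'   50, 250).
#' @return List of `GeneModule`s: `list(id, source_tumor, component, sign,
#'   genes)`. Empty list when the tumor is skipped.
#' @export
extract_candidate_modules <- function(nm, tumor = NULL, n_components = 10L,
                                      top_k = 50L, min_cells = 250L) {
  cells <- seq_along(nm$barcodes)
  if (!is.null(tumor)) cells <- which(nm$sample_of == tumor)
  src <- if (is.null(tumor)) unique(nm$sample_of)[1] else tumor
  if (length(cells) < min_cells) {
    am_log(sprintf(
      "extract_candidate_modules: %s skipped, limited number of steroid cells (<%d)",
      src, min_cells))
    return(list())
  }
  vals <- as.matrix(nm$values[, cells, drop = FALSE])
  v <- apply(vals, 1, var)
  vals <- vals[v > 0, , drop = FALSE]
  if (nrow(vals) < top_k) stopf("fewer than top_k variable genes")
  pc <- prcomp(t(vals), center = TRUE, scale. = FALSE,
               rank. = min(n_components, ncol(vals) - 1, nrow(vals)))
  load <- pc$rotation
  mods <- list()
  for (k in seq_len(min(n_components, ncol(load)))) {
    lk <- load[, k]
    ord_pos <- order(-lk, names(lk))
    ord_neg <- order(lk, names(lk))
    for (sgn in c("pos", "neg")) {
      genes <- names(lk)[if (sgn == "pos") ord_pos[seq_len(top_k)]
                         else ord_neg[seq_len(top_k)]]
      id <- sprintf("%s_PC%02d_%s", src, k, sgn)
      mods[[id]] <- list(id = id, source_tumor = src, component = k,
                         sign = sgn, genes = genes)
    }
  }
  mods
}

#' Pairwise Sørensen similarity of gene modules
#'
#' @param modules List of `GeneModule`s (from
#'   [extract_candidate_modules()]).
#' @return Symmetric matrix with unit diagonal, module ids on both axes.
#' @export
module_similarity <- function(modules) {
  n <- length(modules)
  ids <- vapply(modules, `[[`, character(1), "id")
  sim <- diag(1, n)
  dimnames(sim) <- list(ids, ids)
  if (n < 2) return(sim)
  sets <- lapply(modules, function(m) unique(m$genes))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- 2 * length(intersect(sets[[i]], sets[[j]])) /
      (length(sets[[i]]) + length(sets[[j]]))
    sim[i, j] <- sim[j, i] <- s
  }
  sim
}

#' Discard non-recurrent modules from a similarity matrix
#'
#' A module is kept iff it has at least `min_neighbors` other modules with
#' similarity at or above `sim_threshold` ("associated"); applied in a
#' single pass, not iterated.
#'
#' @param sim Square symmetric Sørensen matrix.
#' @param sim_threshold,min_neighbors Published defaults 0.4 and 2.
#' @return The submatrix of kept modules (possibly 0 x 0, with a logged
#'   note).
#' @export
filter_nonrecurrent <- function(sim, sim_threshold = 0.4, min_neighbors = 2L) {
  off <- sim; diag(off) <- NA
  n_assoc <- rowSums(off >= sim_threshold, na.rm = TRUE)
  keep <- n_assoc >= min_neighbors
  am_log(sprintf("filter_nonrecurrent: kept %d/%d modules", sum(keep),
                 length(keep)))
  if (!any(keep)) am_log("filter_nonrecurrent: empty result")
  sim[keep, keep, drop = FALSE]
}

#' Cluster recurrent modules across tumors
#'
#' Agglomerative clustering (average linkage) of modules with distance
#' `1 - Sørensen`. The dendrogram cut height is scanned from fine to coarse;
#' at each cut, qualifying clusters are those spanning at least `min_tumors`
#' distinct source tumors. The retained partition is the finest cut whose
#' number of qualifying clusters is maximal; non-qualifying clusters at that
#' cut are dropped, not merged further. Deterministic given input.
#'
#' @param sim_filtered Filtered similarity matrix
#'   (from [filter_nonrecurrent()]).
#' @param modules The full module list (source tumors looked up by id).
#' @param min_tumors Published default 3.
#' @return List of cluster skeletons `list(member_ids, tumors)`; empty list
#'   when no cut yields a qualifying cluster.
#' @export
cluster_modules <- function(sim_filtered, modules, min_tumors = 3L) {
  ids <- rownames(sim_filtered)
  if (length(ids) < 2) {
    am_log("cluster_modules: fewer than 2 modules, empty result")
    return(list())
  }
  tumor_of <- vapply(modules, `[[`, character(1), "source_tumor")
  names(tumor_of) <- vapply(modules, `[[`, character(1), "id")
  hc <- hclust(as.dist(1 - sim_filtered), method = "average")
  heights <- c(0, sort(unique(hc$height)) + 1e-9)
  best <- list(count = -1L, part = NULL)
  for (h in heights) {
    part <- cutree(hc, h = h)
    qual <- vapply(split(ids, part), function(mem)
      length(unique(tumor_of[mem])) >= min_tumors, logical(1))
    if (sum(qual) > best$count) best <- list(count = sum(qual), part = part)
  }
  if (best$count < 1) {
    am_log("cluster_modules: no cluster spans >= min_tumors tumors")
    return(list())
  }
  groups <- split(ids, best$part)
  groups <- Filter(function(mem) length(unique(tumor_of[mem])) >= min_tumors,
                   groups)
  out <- lapply(groups, function(mem)
    list(member_ids = unname(mem),
         tumors = sort(unique(unname(tumor_of[mem])))))
  names(out) <- NULL
  # deterministic order: by first member id
  out[order(vapply(out, function(cl) cl$member_ids[1], character(1)))]
}

#' Consensus genes of a module cluster
#'
#' For each gene, count the distinct tumors whose member modules contain it;
#' keep genes present in at least `recurrence_fraction` of the cluster's
#' tumors (inclusive boundary). A gene appearing in both signed modules of
#' one tumor counts once.
#'
#' @param cluster A skeleton from [cluster_modules()].
#' @param modules Full module list.
#' @param recurrence_fraction Published default 0.5.
#' @param id Consensus module id.
#' @return A `ConsensusModule`: `list(id, member_ids, tumors, genes)`, or
#'   `NULL` (with warning) if no gene reaches the threshold.
#' @export
derive_consensus_genes <- function(cluster, modules,
                                   recurrence_fraction = 0.5, id = "CM") {
  mods <- modules[cluster$member_ids]
  per_tumor <- lapply(split(mods, vapply(mods, `[[`, character(1),
                                         "source_tumor")),
                      function(ms) unique(unlist(lapply(ms, `[[`, "genes"))))
  n_tum <- length(per_tumor)
  gene_counts <- table(unlist(per_tumor))
  keep <- names(gene_counts)[gene_counts / n_tum >= recurrence_fraction]
  if (!length(keep)) {
    warnf("derive_consensus_genes: empty consensus for %s, cluster dropped", id)
    return(NULL)
  }
  list(id = id, member_ids = cluster$member_ids, tumors = cluster$tumors,
       genes = sort(keep))
}

#' Recurrent gene-module discovery across tumors
#'
#' The four-step procedure end-to-end: (i) per-tumor PCA candidate modules
#' (top `top_k` positive and negative loading genes of the first
#' `n_components` components, tumors under `min_cells` cells skipped);
#' (ii) Sørensen similarity with single-pass filtering of modules associated
#' (similarity >= `sim_threshold`) with fewer than `min_neighbors` others;
#' (iii) average-linkage clustering retaining clusters spanning at least
#' `min_tumors` tumors at the finest qualifying cut; (iv) consensus genes
#' present in at least `recurrence_fraction` of each cluster's tumors.
#'
#' @param nm A `NormalizedMatrix` with `sample_of` labels.
#' @param cfg An [default_config()] list (relevant fields: `n_components`,
#'   `top_k`, `min_cell_count`, `sim_threshold`, `min_neighbors`,
#'   `min_tumors`, `recurrence_fraction`).
#' @return `list(consensus, modules, similarity, similarity_filtered,
#'   clusters)`; `consensus` is a list of `ConsensusModule`s named
#'   `CM1, CM2, ...`.
#' @export
discover_modules <- function(nm, cfg = default_config()) {
  tumors <- unique(nm$sample_of)
  modules <- list()
  for (t in tumors)
    modules <- c(modules, extract_candidate_modules(
      nm, tumor = t, n_components = cfg$n_components, top_k = cfg$top_k,
      min_cells = cfg$min_cell_count))
  if (!length(modules)) return(list(consensus = list(), modules = list(),
                                    similarity = NULL,
                                    similarity_filtered = NULL,
                                    clusters = list()))
  sim <- module_similarity(modules)
  sim_f <- filter_nonrecurrent(sim, cfg$sim_threshold, cfg$min_neighbors)
  clusters <- cluster_modules(sim_f, modules, cfg$min_tumors)
  consensus <- list()
  for (i in seq_along(clusters)) {
    cm <- derive_consensus_genes(clusters[[i]], modules,
                                 cfg$recurrence_fraction,
                                 id = sprintf("CM%d", length(consensus) + 1))
    if (!is.null(cm)) consensus[[cm$id]] <- cm
  }
  am_log(sprintf("discover_modules: %d candidate -> %d recurrent -> %d consensus",
                 length(modules), nrow(sim_f), length(consensus)))
  list(consensus = consensus, modules = modules, similarity = sim,
       similarity_filtered = sim_f, clusters = clusters)
}

#' Score consensus modules per cell and label by maximal score
#'
#' Module score = mean log-normalized expression of the module genes minus
#' the mean of expression-bin-matched control genes: all genes are binned
#' into `n_bins` by average expression, and `n_ctrl` control genes are drawn
#' from the bin of each module gene under the given seed. Each cell is
#' labeled with the module of highest score; ties go to the lowest module id
#' and are counted in the log.
#'
#' @param nm A `NormalizedMatrix`.
#' @param consensus List of `ConsensusModule`s (or plain named list of gene
#'   vectors). Module genes absent from the matrix are dropped with a
#'   warning; a module with no genes present is an error.
#' @param n_bins,n_ctrl Control-matching parameters (defaults 25, 50).
#' @param seed RNG seed for the control draw.
#' @return `list(scores = cells x modules matrix, label = named character
#'   vector, controls = per-module integer vector of the sampled control
#'   gene rows)`.
#' @export
score_cells <- function(nm, consensus, n_bins = 25L, n_ctrl = 50L,
                        seed = 1L) {
  if (!length(consensus)) stopf("score_cells: no modules")
  gene_sets <- lapply(consensus, function(m)
    if (is.list(m)) m$genes else as.character(m))
  if (is.null(names(gene_sets)))
    names(gene_sets) <- sprintf("CM%d", seq_along(gene_sets))
  vals <- nm$values
  avg <- Matrix::rowMeans(vals)
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
             labels = FALSE)
  bin_members <- split(seq_along(avg), bin)
  controls <- list()
  scores <- with_seed(seed, {
    vapply(names(gene_sets), function(id) {
      genes <- gene_sets[[id]]
      present <- intersect(genes, nm$gene_ids)
      if (length(present) < length(genes))
        warnf("score_cells: %d/%d genes of %s absent, dropped",
              length(genes) - length(present), length(genes), id)
      if (!length(present)) stopf("score_cells: no genes of %s present", id)
      gi <- match(present, nm$gene_ids)
      ctrl <- unlist(lapply(gi, function(g) {
        pool <- bin_members[[as.character(bin[g])]]
        pool[sample.int(length(pool), min(n_ctrl, length(pool)))]
      }))
      controls[[id]] <<- ctrl
      as.numeric(Matrix::colMeans(vals[gi, , drop = FALSE]) -
                   Matrix::colMeans(vals[ctrl, , drop = FALSE]))
    }, numeric(ncol(vals)))
  })
  rownames(scores) <- nm$barcodes
  ord <- order(colnames(scores))
  scores_ord <- scores[, ord, drop = FALSE]
  lab_idx <- apply(scores_ord, 1, which_max_first)
  label <- setNames(colnames(scores_ord)[lab_idx], nm$barcodes)
  n_ties <- sum(apply(scores_ord, 1, function(s) sum(s == max(s)) > 1))
  if (n_ties) am_log(sprintf("score_cells: %d tied cells (lowest id wins)",
                             n_ties))
  list(scores = scores, label = label, controls = controls)
}

#' Gene-set Jaccard index
#'
#' @param a,b Character vectors (treated as sets).
#' @return `|A ∩ B| / |A ∪ B|`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  length(intersect(a, b)) / length(union(a, b))
}
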