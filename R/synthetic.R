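#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The generator emulates the
#' structure of a multi-tumor single-nucleus atlas: per-tumor count matrices
#' with planted shared and private expression programs, chromosomal
#' gains/losses against a normal reference population, microenvironment cell
#' types with distinct centroids, and bulk cohorts formed as mixtures of
#' cell-type signatures whose survival hazard depends on planted ecotype
#' scores.
#'
#' @param n_tumors Number of tumors.
#' @param cells_per_tumor Cells generated per tumor.
#' @param n_genes Genes in the panel.
#' @param planted_modules List of modules, each
#'   `list(size =, carriers =, effect =)`: gene-set size, integer ids of
#'   carrier tumors, log-scale activity effect when a cell is "on".
#' @param on_fraction Probability a cell of a carrier tumor is "on" for a
#'   module (two-component on/off activity).
#' @param n_celltypes Number of microenvironment cell types (distinct
#'   centroids) for deconvolution tests.
#' @param celltype_separation Log-scale SD of centroid offsets between cell
#'   types.
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param baseline_meanlog,baseline_sdlog Log-normal law of per-gene baseline
#'   means.
#' @param cnv_events List of events, each
#'   `list(span = number of genes, fold = fold-change, frac = carrier
#'   fraction of query cells)`.
#' @param n_chromosomes Chromosomes over which genes are laid out evenly.
#' @param n_reference_cells,n_query_cells Reference / query population sizes
#'   for the CNV generator.
#' @param cohort_n Bulk cohort size.
#' @param ecotype_blocks List of integer vectors: signature indices forming
#'   each planted ecotype block.
#' @param block_cor Within-block correlation of planted signature scores, in
#'   `[0, 1)`.
#' @param log_hazard Numeric vector, one log hazard ratio per ecotype block
#'   (per SD of ecotype score).
#' @param noise_sd SD of multiplicative log-normal noise on bulk mixtures.
#' @param base_rate Baseline event hazard (per day).
#' @param censor_rate Rate of the independent exponential censoring law;
#'   the default (2/3 of `base_rate`) yields roughly 40% censoring under a
#'   null hazard.
#' @param seed RNG seed.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(n_tumors = 6L, cells_per_tumor = 800L,
                       n_genes = 2000L, planted_modules = list(),
                       on_fraction = 0.45, n_celltypes = 5L,
                       celltype_separation = 1.2, nb_dispersion = 0.1,
                       baseline_meanlog = -1, baseline_sdlog = 0.7,
                       cnv_events = list(), n_chromosomes = 5L,
                       n_reference_cells = 300L, n_query_cells = 100L,
                       cohort_n = 200L, ecotype_blocks = list(),
                       block_cor = 0.8, log_hazard = numeric(),
                       noise_sd = 0.1, base_rate = 1 / 1000,
                       censor_rate = 2 / (3 * 1000), seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_tumors > 0, cells_per_tumor > 0, n_genes > 0,
            nb_dispersion > 0, block_cor >= 0, block_cor < 1)
  for (m in planted_modules) {
    stopifnot(m$size > 0, m$effect >= 0, length(m$carriers) >= 1)
    if (any(m$carriers < 1 | m$carriers > n_tumors))
      stopf("carrier tumors must be within 1..n_tumors")
  }
  for (ev in cnv_events)
    stopifnot(ev$span > 0, ev$fold > 0, ev$frac >= 0, ev$frac <= 1)
  structure(cfg, class = "sim_config")
}

# Disjoint gene blocks for planted modules, assigned from the front of the
# panel; errors if the panel is too small.
assign_module_genes <- function(cfg) {
  sizes <- vapply(cfg$planted_modules, `[[`, numeric(1), "size")
  if (sum(sizes) > cfg$n_genes)
    stopf("planted module genes (%d) exceed n_genes (%d)",
          sum(sizes), cfg$n_genes)
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  lapply(seq_along(sizes), function(i) seq(starts[i], ends[i]))
}

#' Generate a multi-tumor single-nucleus dataset with planted programs
#'
#' Counts are negative binomial around
#' `exp(baseline + sum(activity * effect))` where per-cell module activity is
#' a two-component on/off mixture, so per-tumor PCA can capture each planted
#' program. Same seed, same output.
#'
#' @param cfg A [sim_config()].
#' @return `list(cm = CountMatrix, truth = list(...))`. `truth` carries
#'   `activity` (cells x modules 0/1), `module_genes` (list of gene-id
#'   vectors), `carriers` (list of carrier tumor ids per module).
#' @export
generate_multi_tumor_dataset <- function(cfg) {
  with_seed(cfg$seed, {
    gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
    base <- rlnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
    gene_idx <- assign_module_genes(cfg)
    n_mod <- length(cfg$planted_modules)
    n_cells <- cfg$n_tumors * cfg$cells_per_tumor
    tumor_of <- rep(sprintf("T%02d", seq_len(cfg$n_tumors)),
                    each = cfg$cells_per_tumor)
    barcodes <- sprintf("%s_C%04d", tumor_of,
                        rep(seq_len(cfg$cells_per_tumor), cfg$n_tumors))
    activity <- matrix(0L, n_cells, max(n_mod, 1),
                       dimnames = list(barcodes, if (n_mod) sprintf("M%02d", seq_len(n_mod))))
    size <- 1 / cfg$nb_dispersion
    blocks <- vector("list", cfg$n_tumors)
    for (t in seq_len(cfg$n_tumors)) {
      cells_t <- which(tumor_of == sprintf("T%02d", t))
      logmu <- matrix(log(base), cfg$n_genes, length(cells_t))
      for (m in seq_len(n_mod)) {
        pm <- cfg$planted_modules[[m]]
        if (!(t %in% pm$carriers)) next
        on <- rbinom(length(cells_t), 1, cfg$on_fraction)
        activity[cells_t, m] <- on
        logmu[gene_idx[[m]], on == 1] <-
          logmu[gene_idx[[m]], on == 1, drop = FALSE] + pm$effect
      }
      counts_t <- matrix(rnbinom(length(logmu), mu = exp(logmu), size = size),
                         cfg$n_genes, length(cells_t))
      blocks[[t]] <- as(Matrix::Matrix(counts_t, sparse = TRUE), "CsparseMatrix")
    }
    counts <- do.call(cbind, blocks)
    cm <- count_matrix(counts, gene_ids, barcodes, tumor_of,
                       rep("steroid", n_cells))
    truth <- list(
      activity = if (n_mod) activity[, seq_len(n_mod), drop = FALSE] else NULL,
      module_genes = lapply(gene_idx, function(ix) gene_ids[ix]),
      carriers = lapply(cfg$planted_modules, `[[`, "carriers"))
    list(cm = cm, truth = truth)
  })
}

#' Generate reference and query cells with planted copy-number events
#'
#' Genes are laid out evenly over `n_chromosomes` with 1-based coordinates.
#' Carrier query cells have their expected counts scaled by the event
#' fold-change across the event's gene span before negative-binomial
#' sampling; the unaltered reference population is included and labeled
#' `"reference"` (`celltype_of`), queries `"query"`.
#'
#' @param cfg A [sim_config()] with `cnv_events`.
#' @return `list(cm = CountMatrix with gene_pos, truth = list(...))`;
#'   `truth$carrier` is a logical per query barcode (any event), and
#'   `truth$event_genes` lists the gene ids of each event span.
#' @export
generate_cnv_cells <- function(cfg) {
  with_seed(cfg$seed, {
    n_g <- cfg$n_genes
    gene_ids <- sprintf("G%04d", seq_len(n_g))
    per_chr <- ceiling(n_g / cfg$n_chromosomes)
    chrom <- sprintf("chr%d", rep(seq_len(cfg$n_chromosomes),
                                  each = per_chr)[seq_len(n_g)])
    pos_in_chr <- unlist(lapply(split(seq_len(n_g), chrom)[unique(chrom)],
                                seq_along), use.names = FALSE)
    gene_pos <- data.frame(gene_id = gene_ids, chrom = chrom,
                           start = (pos_in_chr - 1) * 10000 + 1,
                           end = pos_in_chr * 10000,
                           stringsAsFactors = FALSE)
    base <- rlnorm(n_g, cfg$baseline_meanlog, cfg$baseline_sdlog)
    size <- 1 / cfg$nb_dispersion
    n_ref <- cfg$n_reference_cells; n_qry <- cfg$n_query_cells
    barcodes <- c(sprintf("REF_%04d", seq_len(n_ref)),
                  sprintf("QRY_%04d", seq_len(n_qry)))
    # event spans: consecutive genes within one chromosome, spaced from the
    # start of successive chromosomes
    event_span <- list(); carrier <- matrix(FALSE, n_qry, length(cfg$cnv_events))
    for (e in seq_along(cfg$cnv_events)) {
      ev <- cfg$cnv_events[[e]]
      ch <- sprintf("chr%d", ((e - 1) %% cfg$n_chromosomes) + 1)
      in_ch <- which(chrom == ch)
      if (ev$span > length(in_ch))
        stopf("event span %d exceeds chromosome size %d", ev$span, length(in_ch))
      event_span[[e]] <- in_ch[seq_len(ev$span)]
      carrier[, e] <- runif(n_qry) < ev$frac
    }
    mu <- matrix(base, n_g, n_ref + n_qry)
    for (e in seq_along(cfg$cnv_events)) {
      idx <- n_ref + which(carrier[, e])
      if (length(idx))
        mu[event_span[[e]], idx] <- mu[event_span[[e]], idx, drop = FALSE] *
          cfg$cnv_events[[e]]$fold
    }
    counts <- matrix(rnbinom(length(mu), mu = mu, size = size), n_g)
    cm <- count_matrix(Matrix::Matrix(counts, sparse = TRUE), gene_ids,
                       barcodes, rep(c("REF", "QRY"), c(n_ref, n_qry)),
                       rep(c("reference", "query"), c(n_ref, n_qry)),
                       gene_pos)
    truth <- list(
      carrier = setNames(apply(carrier, 1, any), barcodes[-seq_len(n_ref)]),
      carrier_by_event = carrier,
      event_genes = lapply(event_span, function(ix) gene_ids[ix]))
    list(cm = cm, truth = truth)
  })
}

#' Generate microenvironment cells with distinct cell-type centroids
#'
#' Each cell type has a log-normal centroid offset on a random quarter of the
#' genes, giving well-separated mean profiles for signature-matrix and
#' deconvolution tests.
#'
#' @param cfg A [sim_config()].
#' @param cells_per_type Cells per cell type (scalar or vector recycled to
#'   `n_celltypes`).
#' @return `list(cm = CountMatrix, centroids = genes x types matrix of true
#'   mean counts)`.
#' @export
generate_celltype_dataset <- function(cfg, cells_per_type = 400L) {
  with_seed(cfg$seed + 1L, {
    n_g <- cfg$n_genes
    gene_ids <- sprintf("G%04d", seq_len(n_g))
    base <- rlnorm(n_g, cfg$baseline_meanlog, cfg$baseline_sdlog)
    k <- cfg$n_celltypes
    n_per <- rep_len(as.integer(cells_per_type), k)
    offs <- matrix(0, n_g, k)
    for (j in seq_len(k)) {
      marked <- sample.int(n_g, max(1L, round(n_g / 4)))
      offs[marked, j] <- rnorm(length(marked), 0, cfg$celltype_separation)
    }
    centroids <- base * exp(offs)
    size <- 1 / cfg$nb_dispersion
    type_of <- rep(sprintf("CT%d", seq_len(k)), n_per)
    mu <- centroids[, rep(seq_len(k), n_per), drop = FALSE]
    counts <- matrix(rnbinom(length(mu), mu = mu, size = size), n_g)
    barcodes <- sprintf("%s_%04d", type_of,
                        unlist(lapply(n_per, seq_len), use.names = FALSE))
    cm <- count_matrix(Matrix::Matrix(counts, sparse = TRUE), gene_ids,
                       barcodes, rep("ME", sum(n_per)), type_of)
    colnames(centroids) <- sprintf("CT%d", seq_len(k))
    rownames(centroids) <- gene_ids
    list(cm = cm, centroids = centroids)
  })
}

#' Generate a bulk cohort as mixtures of signatures with planted survival
#'
#' Expression is `proportions %*% t(signatures)` under multiplicative
#' log-normal noise; per-sample proportions are Dirichlet(1) and sum to 1.
#' Planted ecotype scores are sums of standardized proportions over each
#' block of `cfg$ecotype_blocks` (indices into signature columns); survival
#' times are exponential with log-hazard
#' `sum(log_hazard[b] * z(ecotype score b))`, censored by an independent
#' exponential clock; three `dataset_id` strata are assigned round-robin.
#'
#' @param cfg A [sim_config()].
#' @param signature_matrix genes x populations matrix of non-negative mean
#'   expression (e.g. from [generate_celltype_dataset()] centroids or
#'   [build_signature_matrix()]).
#' @return `list(cohort = BulkCohort, truth = list(proportions,
#'   ecotype_scores, log_hazard))`.
#' @export
generate_bulk_cohort <- function(cfg, signature_matrix) {
  with_seed(cfg$seed + 2L, {
    S <- as.matrix(signature_matrix)
    k <- ncol(S); n <- cfg$cohort_n
    g <- rgamma(n * k, shape = 1)
    P <- matrix(g, n, k)
    P <- P / rowSums(P)
    colnames(P) <- colnames(S)
    expr <- P %*% t(S)
    if (cfg$noise_sd > 0)
      expr <- expr * matrix(rlnorm(length(expr), 0, cfg$noise_sd), n)
    sample_ids <- sprintf("S%03d", seq_len(n))
    rownames(expr) <- sample_ids
    # planted ecotype scores: z-scored block sums of true proportions
    blocks <- cfg$ecotype_blocks
    eco <- NULL; eta <- rep(0, n)
    if (length(blocks)) {
      eco <- vapply(blocks, function(ix) {
        s <- rowSums(P[, ix, drop = FALSE])
        as.numeric(scale(s))
      }, numeric(n))
      colnames(eco) <- sprintf("Eco%d", seq_along(blocks))
      lh <- rep_len(cfg$log_hazard, length(blocks))
      eta <- as.numeric(eco %*% lh)
    }
    t_dfs <- rexp(n, rate = cfg$base_rate * 1.5 * exp(eta))
    t_os <- t_dfs + rexp(n, rate = cfg$base_rate * exp(eta))
    c_dfs <- rexp(n, rate = cfg$censor_rate)
    c_os <- c_dfs + rexp(n, rate = cfg$censor_rate)
    clinical <- data.frame(
      sample_id = sample_ids,
      time_dfs = pmin(t_dfs, c_dfs), event_dfs = as.integer(t_dfs <= c_dfs),
      time_os = pmin(t_os, c_os), event_os = as.integer(t_os <= c_os),
      stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                     prob = c(0.2, 0.35, 0.3, 0.15)),
      dataset_id = rep(c("D1", "D2", "D3"), length.out = n),
      stringsAsFactors = FALSE)
    truth <- list(proportions = P, ecotype_scores = eco,
                  log_hazard = if (length(blocks))
                    rep_len(cfg$log_hazard, length(blocks)) else numeric())
    list(cohort = bulk_cohort(expr, clinical), truth = truth)
  })
}

#' Simulate correlated signature-score columns in planted blocks
#'
#' Each block shares a latent factor: scores are
#' `sqrt(r) * factor + sqrt(1 - r) * noise`, giving pairwise within-block
#' correlation `r` and zero between blocks. Used by the ecotype recovery
#' tests.
#'
#' @param n_samples Rows.
#' @param blocks List of integer vectors partitioning `1..n_signatures`.
#' @param r Within-block correlation in `[0, 1)`.
#' @param seed RNG seed.
#' @param dataset_of Optional dataset ids (default one dataset).
#' @return `list(scores = samples x signatures matrix, membership = integer
#'   block id per signature)`.
#' @export
simulate_signature_scores <- function(n_samples, blocks, r = 0.8, seed = 1L,
                                      dataset_of = NULL) {
  with_seed(seed, {
    p <- max(unlist(blocks))
    scores <- matrix(rnorm(n_samples * p) * sqrt(1 - r), n_samples, p)
    membership <- integer(p)
    for (b in seq_along(blocks)) {
      f <- rnorm(n_samples)
      for (j in blocks[[b]]) {
        scores[, j] <- scores[, j] + sqrt(r) * f
        membership[j] <- b
      }
    }
    colnames(scores) <- sprintf("Sig%02d", seq_len(p))
    rownames(scores) <- sprintf("S%03d", seq_len(n_samples))
    list(scores = scores, membership = membership)
  })
}

#' Simulate a survival dataset with planted per-SD log hazard ratios
#'
#' Covariates are iid standard normal; event times exponential with
#' log-hazard `x %*% beta`; censoring independent exponential. A small
#' driver for Cox calibration and power tests.
#'
#' @param n Samples.
#' @param beta Named numeric vector of log hazard ratios per SD.
#' @param base_rate,censor_rate Baseline hazards of event / censoring clocks.
#' @param seed RNG seed.
#' @return `list(cohort = BulkCohort (expression is a placeholder),
#'   covariates = data.frame)`.
#' @export
simulate_survival_data <- function(n, beta, base_rate = 1 / 1000,
                                   censor_rate = 2 / 3000, seed = 1L) {
  with_seed(seed, {
    p <- length(beta)
    x <- matrix(rnorm(n * p), n, p)
    colnames(x) <- names(beta) %||% sprintf("X%d", seq_len(p))
    eta <- as.numeric(x %*% beta)
    tt <- rexp(n, rate = base_rate * exp(eta))
    cc <- rexp(n, rate = censor_rate)
    sample_ids <- sprintf("S%03d", seq_len(n))
    clinical <- data.frame(
      sample_id = sample_ids,
      time_dfs = pmin(tt, cc), event_dfs = as.integer(tt <= cc),
      time_os = pmin(tt, cc), event_os = as.integer(tt <= cc),
      stage = sample(c("I", "II", "III"), n, replace = TRUE),
      dataset_id = "SIM", stringsAsFactors = FALSE)
    expr <- matrix(1, n, 2, dimnames = list(sample_ids, c("g1", "g2")))
    cov_df <- as.data.frame(x)
    rownames(cov_df) <- sample_ids
    list(cohort = bulk_cohort(expr, clinical), covariates = cov_df)
  })
}

#' Study conditions for the CNV caller simulations
#'
#' A [sim_config()] preset emulating the input of the windowed CNV caller at
#' the scale of a real single-nucleus experiment: 8,000 genes passing the
#' mean-count floor, laid out over 22 chromosomes, with a reference pool of
#' 800 normal cells (large enough that the 0.5% empirical tail of each
#' window's reference distribution rests on several observations) and 40
#' query cells.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
cnv_sim_config <- function(...) {
  args <- list(n_genes = 8000L, n_chromosomes = 22L,
               n_reference_cells = 800L, n_query_cells = 40L)
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
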