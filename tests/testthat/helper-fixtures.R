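# In-code fixture builders shared across test files.

make_cm <- function(mat, samples = NULL, celltypes = NULL, gene_ids = NULL,
                    barcodes = NULL, gene_pos = NULL) {
  mat <- as.matrix(mat)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%03d", seq_len(nrow(mat)))
  if (is.null(barcodes)) barcodes <- sprintf("C%03d", seq_len(ncol(mat)))
  if (is.null(samples)) samples <- rep("S1", ncol(mat))
  count_matrix(Matrix::Matrix(mat, sparse = TRUE), gene_ids, barcodes,
               samples, celltypes, gene_pos)
}

# A NormalizedMatrix built directly from a values matrix, for deterministic
# arithmetic checks that bypass depth normalization.
make_nm <- function(values, counts = NULL, samples = NULL, gene_pos = NULL,
                    celltypes = NULL) {
  values <- as.matrix(values)
  gene_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%03d", seq_len(nrow(values)))
  barcodes <- colnames(values)
  if (is.null(barcodes)) barcodes <- sprintf("C%03d", seq_len(ncol(values)))
  dimnames(values) <- list(gene_ids, barcodes)
  if (is.null(counts)) counts <- matrix(1, nrow(values), ncol(values),
                                        dimnames = dimnames(values))
  if (is.null(samples)) samples <- rep("S1", ncol(values))
  if (is.null(celltypes)) celltypes <- rep("unknown", ncol(values))
  structure(list(values = Matrix::Matrix(values, sparse = TRUE),
                 size_factors = setNames(rep(1, ncol(values)), barcodes),
                 log_base = "natural (log1p)",
                 counts = Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                 gene_ids = gene_ids, barcodes = barcodes,
                 sample_of = setNames(as.character(samples), barcodes),
                 celltype_of = setNames(as.character(celltypes), barcodes),
                 gene_pos = gene_pos),
            class = "NormalizedMatrix")
}

# The acceptance-scale multi-tumor design: 3 programs shared by >= 4 of 6
# tumors plus one private program per tumor, 50 genes each.
shared_private_config <- function(seed = 11L, effect = 1.5,
                                  n_tumors = 6L, cells_per_tumor = 800L,
                                  n_genes = 2000L) {
  mods <- list(
    list(size = 50, carriers = c(1, 2, 3, 4), effect = effect),
    list(size = 50, carriers = c(2, 3, 4, 5), effect = effect),
    list(size = 50, carriers = c(1, 3, 5, 6), effect = effect))
  for (t in seq_len(n_tumors))
    mods <- c(mods, list(list(size = 50, carriers = t, effect = effect)))
  sim_config(n_tumors = n_tumors, cells_per_tumor = cells_per_tumor,
             n_genes = n_genes, planted_modules = mods, seed = seed)
}

# Matrix whose cells have prescribed detected-gene counts and exact
# mitochondrial count totals (one MT gene holds all mito counts).
qc_fixture <- function() {
  n_genes <- 9000
  ids <- c(sprintf("MT-%d", 1:10), sprintf("G%04d", 1:(n_genes - 10)))
  nonmito <- c(400, 500, 600, 8000, 8500, 600, 570)
  mito_counts <- c(0, 0, 6, 0, 0, 40, 30) # 40/640 = 6.25%; 30/600 = 5% exactly
  cols <- lapply(seq_along(nonmito), function(i) {
    v <- numeric(n_genes)
    v[10 + seq_len(nonmito[i])] <- 1
    v[1] <- mito_counts[i]
    v
  })
  m <- do.call(cbind, cols)
  make_cm(m, gene_ids = ids,
          barcodes = sprintf("cell_%d", seq_along(nonmito)))
}

run_null_cnv <- function(seed) {
  cfg <- cnv_sim_config(cnv_events = list(), seed = seed)
  sim <- generate_cnv_cells(cfg)
  nm <- suppressMessages(normalize_counts(sim$cm))
  ref <- sim$cm$barcodes[sim$cm$celltype_of == "reference"]
  prof <- suppressWarnings(suppressMessages(run_cnv(nm, ref)))
  qry <- !(rownames(prof$signal) %in% ref)
  list(call_rate = mean(prof$calls[qry, ] != "neutral"),
       malignant_rate = mean(prof$malignant[qry]))
}
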