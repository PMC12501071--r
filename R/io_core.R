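#' Construct a CountMatrix
#'
#' The container for single-nucleus data: a genes x cells matrix of
#' non-negative integer counts plus per-cell sample and cell-type labels and,
#' optionally, gene genomic positions (1-based inclusive bp) used by the CNV
#' caller.
#'
#' @param counts genes x cells matrix (dense or `Matrix` sparse) of
#'   non-negative integers.
#' @param gene_ids,barcodes Unique ordered identifiers for rows / columns.
#' @param sample_of Character vector, one sample id per barcode.
#' @param celltype_of Character vector, one label per barcode; defaults to
#'   `"unknown"`.
#' @param gene_pos Optional `data.frame` with columns `gene_id`, `chrom`,
#'   `start`, `end` for (a subset of) the genes.
#' @param metadata Optional `data.frame` of extra per-cell columns, carried
#'   through untouched.
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, gene_ids, barcodes, sample_of,
                         celltype_of = NULL, gene_pos = NULL,
                         metadata = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != length(gene_ids))
    stopf("dimension mismatch: %d matrix rows vs %d gene ids",
          nrow(counts), length(gene_ids))
  if (ncol(counts) != length(barcodes))
    stopf("dimension mismatch: %d matrix columns vs %d barcodes",
          ncol(counts), length(barcodes))
  if (anyDuplicated(gene_ids)) stopf("duplicate ids in gene_ids")
  if (anyDuplicated(barcodes)) stopf("duplicate ids in barcodes")
  x <- counts@x
  if (any(x < 0)) stopf("counts must be >= 0")
  if (any(x != round(x))) stopf("counts must be integers")
  if (is.null(celltype_of)) celltype_of <- rep("unknown", length(barcodes))
  if (length(sample_of) != length(barcodes) || anyNA(sample_of))
    stopf("every barcode needs a sample id")
  if (length(celltype_of) != length(barcodes))
    stopf("celltype_of length mismatch")
  if (!is.null(gene_pos)) {
    need <- c("gene_id", "chrom", "start", "end")
    if (!all(need %in% names(gene_pos)))
      stopf("gene_pos needs columns %s", paste(need, collapse = ", "))
    if (any(gene_pos$start > gene_pos$end)) stopf("gene_pos: start > end")
    if (any(!nzchar(gene_pos$chrom))) stopf("gene_pos: empty chromosome")
  }
  dimnames(counts) <- list(gene_ids, barcodes)
  structure(list(counts = counts, gene_ids = gene_ids, barcodes = barcodes,
                 sample_of = setNames(as.character(sample_of), barcodes),
                 celltype_of = setNames(as.character(celltype_of), barcodes),
                 gene_pos = gene_pos, metadata = metadata),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells, %d samples%s\n",
              length(x$gene_ids), length(x$barcodes),
              length(unique(x$sample_of)),
              if (is.null(x$gene_pos)) "" else ", with gene positions"))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Subset a CountMatrix by cells (and optionally genes)
#'
#' @param cm A `CountMatrix`.
#' @param cells Barcodes or logical/integer index over cells.
#' @param genes Gene ids or index over genes (default all).
#' @return A `CountMatrix`.
#' @export
subset_cells <- function(cm, cells, genes = NULL) {
  if (is.character(cells)) cells <- match(cells, cm$barcodes)
  if (is.null(genes)) genes <- seq_along(cm$gene_ids)
  if (is.character(genes)) genes <- match(genes, cm$gene_ids)
  md <- if (is.null(cm$metadata)) NULL else cm$metadata[cells, , drop = FALSE]
  gp <- if (is.null(cm$gene_pos)) NULL else
    cm$gene_pos[cm$gene_pos$gene_id %in% cm$gene_ids[genes], , drop = FALSE]
  count_matrix(cm$counts[genes, cells, drop = FALSE],
               cm$gene_ids[genes], cm$barcodes[cells],
               cm$sample_of[cells], cm$celltype_of[cells], gp, md)
}

#' Read 10x-style triplet counts
#'
#' Reads a Matrix Market coordinate file plus one-id-per-line gene and barcode
#' TSVs (first column used) and a per-barcode metadata TSV with at least
#' columns `barcode` and `sample`; a `celltype` column is optional. Any
#' further metadata columns are carried through untouched. An optional
#' BED-like gene-position TSV (`gene_id`, `chrom`, `start`, `end`) supplies
#' genomic coordinates for the CNV caller.
#'
#' @param matrix_path,genes_path,barcodes_path,metadata_path File paths.
#' @param gene_pos_path Optional gene position TSV.
#' @return A `CountMatrix`.
#' @export
read_counts <- function(matrix_path, genes_path, barcodes_path, metadata_path,
                        gene_pos_path = NULL) {
  for (p in c(matrix_path, genes_path, barcodes_path, metadata_path))
    if (!file.exists(p)) stopf("missing file: %s", p)
  m <- Matrix::readMM(matrix_path)
  first_col <- function(p) {
    x <- read.delim(p, header = FALSE, stringsAsFactors = FALSE)[[1]]
    as.character(x)
  }
  gene_ids <- first_col(genes_path)
  barcodes <- first_col(barcodes_path)
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!all(c("barcode", "sample") %in% names(meta)))
    stopf("metadata needs 'barcode' and 'sample' columns")
  idx <- match(barcodes, meta$barcode)
  if (anyNA(idx)) stopf("metadata missing %d barcodes", sum(is.na(idx)))
  meta <- meta[idx, , drop = FALSE]
  ct <- if ("celltype" %in% names(meta)) meta$celltype else NULL
  gp <- NULL
  if (!is.null(gene_pos_path)) {
    gp <- read.delim(gene_pos_path, stringsAsFactors = FALSE)
  }
  cm <- count_matrix(m, gene_ids, barcodes, meta$sample, ct, gp, meta)
  am_log(sprintf("read_counts: %d genes x %d cells from %s",
                 nrow(cm$counts), ncol(cm$counts), matrix_path))
  cm
}

#' Write a CountMatrix as 10x-style triplet files
#'
#' @param cm A `CountMatrix`.
#' @param dir Output directory (created if absent). Writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`, `metadata.tsv` and, when positions are
#'   present, `gene_pos.tsv`.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cm$counts, file.path(dir, "matrix.mtx"))
  writeLines(cm$gene_ids, file.path(dir, "features.tsv"))
  writeLines(cm$barcodes, file.path(dir, "barcodes.tsv"))
  meta <- data.frame(barcode = cm$barcodes, sample = unname(cm$sample_of),
                     celltype = unname(cm$celltype_of),
                     stringsAsFactors = FALSE)
  if (!is.null(cm$metadata)) {
    extra <- cm$metadata[, setdiff(names(cm$metadata), names(meta)),
                         drop = FALSE]
    if (ncol(extra)) meta <- cbind(meta, extra)
  }
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(cm$gene_pos))
    write.table(cm$gene_pos, file.path(dir, "gene_pos.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read / write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' genes. Order-preserving; duplicate genes within a set are removed with a
#' logged warning.
#'
#' @param path File path.
#' @return `read_gmt`: a named list of character vectors with a
#'   `description` attribute per set.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("missing file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("GMT line with <3 fields: %s", substr(ln, 1, 40))
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      am_log(sprintf("read_gmt: %d duplicate genes removed in set %s",
                     sum(duplicated(genes)), f[1]))
      genes <- genes[!duplicated(genes)]
    }
    sets[[f[1]]] <- structure(genes, description = f[2])
  }
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a BulkCohort
#'
#' @param expr samples x genes matrix of non-negative reals, rownames =
#'   sample ids.
#' @param clinical `data.frame` with `sample_id`, survival columns
#'   (`time_dfs`, `event_dfs`, `time_os`, `event_os`), `stage`
#'   (`"I"`..`"IV"`) and `dataset_id`; extra covariates carried through.
#' @return Object of class `BulkCohort`.
#' @export
bulk_cohort <- function(expr, clinical) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stopf("expr needs sample-id rownames")
  if (anyDuplicated(rownames(expr))) stopf("duplicate sample ids")
  if (!"sample_id" %in% names(clinical)) stopf("clinical needs 'sample_id'")
  if (!"dataset_id" %in% names(clinical))
    stopf("clinical needs 'dataset_id' (required for per-dataset Z-scoring)")
  clinical <- clinical[match(rownames(expr), clinical$sample_id), ,
                       drop = FALSE]
  if (anyNA(clinical$sample_id)) stopf("clinical missing samples")
  for (ev in intersect(c("event_dfs", "event_os"), names(clinical))) {
    v <- clinical[[ev]]
    if (!all(v %in% c(0, 1, NA))) stopf("malformed event flag in %s", ev)
  }
  for (tm in intersect(c("time_dfs", "time_os"), names(clinical))) {
    v <- clinical[[tm]]
    if (any(v < 0, na.rm = TRUE)) stopf("negative time in %s", tm)
  }
  if (any(expr < 0)) stopf("expr must be non-negative")
  structure(list(expr = expr, clinical = clinical), class = "BulkCohort")
}

#' @export
print.BulkCohort <- function(x, ...) {
  cat(sprintf("BulkCohort: %d samples x %d genes, datasets: %s\n",
              nrow(x$expr), ncol(x$expr),
              paste(unique(x$clinical$dataset_id), collapse = ", ")))
  invisible(x)
}

#' Read a bulk cohort from expression + clinical TSVs
#'
#' Expression: samples x genes with a `sample_id` first column. Clinical: one
#' row per sample. The two tables are inner-joined on sample id; the joined
#' count is logged. Missing survival fields stay missing.
#'
#' @param expr_path,clinical_path File paths.
#' @return A `BulkCohort`.
#' @export
read_cohort <- function(expr_path, clinical_path) {
  ex <- read.delim(expr_path, stringsAsFactors = FALSE, check.names = FALSE)
  cl <- read.delim(clinical_path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(ex)) stopf("expression needs 'sample_id' column")
  shared <- intersect(ex$sample_id, cl$sample_id)
  if (!length(shared)) stopf("empty sample intersection")
  am_log(sprintf("read_cohort: %d shared samples (%d expr, %d clinical)",
                 length(shared), nrow(ex), nrow(cl)))
  ex <- ex[match(shared, ex$sample_id), , drop = FALSE]
  m <- as.matrix(ex[, setdiff(names(ex), "sample_id"), drop = FALSE])
  rownames(m) <- shared
  bulk_cohort(m, cl[match(shared, cl$sample_id), , drop = FALSE])
}

#' Write a bulk cohort as TSVs
#'
#' @param cohort A `BulkCohort`.
#' @param expr_path,clinical_path Output paths.
#' @export
write_cohort <- function(cohort, expr_path, clinical_path) {
  ex <- data.frame(sample_id = rownames(cohort$expr), cohort$expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(ex, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$clinical, clinical_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(expr_path)
}
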