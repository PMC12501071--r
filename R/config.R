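#' Default run configuration
#'
#' All tunable parameters of the pipeline in one place, with defaults equal to
#' the published values of the study the pipeline re-implements: QC thresholds
#' (min 500 / max 8000 detected genes, 5% mitochondrial fraction), module
#' discovery (10 PCA components, top 50 genes per signed component, Sorensen
#' association threshold 0.4 with at least 2 neighbors, clusters spanning at
#' least 3 tumors, consensus genes in at least 50% of tumors, 250-cell
#' minimum per tumor), the CNV caller (100-gene window, 0.1 mean-count gene
#' floor, 1.5-SD denoising, 99% reference interval, 3% altered-genome rule),
#' signatures (50-cell minimum per population), ecotypes (Z-cap 3, max_k 10)
#' and survival (alpha 0.05).
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `am_config`.
#' @export
#' @examples
#' cfg <- default_config(window = 50)
#' cfg$window
default_config <- function(...) {
  cfg <- list(
    # QC
    min_genes = 500L, max_genes = 8000L, max_mito = 0.05, mito_prefix = "MT-",
    # markers
    min_log2fc = 0.25, min_frac = 0.10, only_positive = TRUE,
    # gene modules
    n_components = 10L, top_k = 50L, sim_threshold = 0.4, min_neighbors = 2L,
    min_tumors = 3L, min_cell_count = 250L, recurrence_fraction = 0.5,
    n_bins = 25L, n_ctrl = 50L,
    # CNV
    window = 100L, min_mean_count = 0.1, denoise_sd = 1.5, ci_level = 0.99,
    genome_fraction = 0.03,
    # signatures
    min_cells_signature = 50L, ssgsea_alpha = 0.25, min_gene_overlap = 50L,
    # ecotypes
    zcap = 3, max_k = 10L, n_resamples = 100L, subsample_frac = 0.8,
    # survival
    alpha = 0.05,
    # plumbing
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stopf("unknown config fields: %s", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "am_config")
}

#' Write / read a run configuration
#'
#' Round-trips losslessly through YAML so a run can be reproduced from its
#' config file alone. On read, the resolved configuration is echoed to the log.
#'
#' @param cfg An `am_config` list.
#' @param path File path.
#' @return `read_config` returns the `am_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(default_config, raw)
  am_log("config: ", paste(names(cfg), unlist(lapply(cfg, format)),
                           sep = "=", collapse = " "))
  cfg
}
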