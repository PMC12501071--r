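#' Sliding-window CNV signal against a reference population
#'
#' Genes with mean raw count below `min_mean_count` across all cells are
#' removed; remaining genes are ordered by genomic position. Per cell, the
#' window signal is the mean over the window's genes of (log-normalized
#' expression minus the reference-cell mean of that gene). Windows slide by
#' one gene and never span a chromosome boundary; chromosomes with fewer
#' genes than the window are skipped with a warning.
#'
#' @param nm A `NormalizedMatrix` whose `gene_pos` covers its genes.
#' @param reference_cells Barcodes of the unaltered reference population.
#' @param window Genes per window (published default 100).
#' @param min_mean_count Mean raw-count floor (published default 0.1).
#' @return A `CnvProfile`: `list(windows, signal, reference_cells, calls,
#'   altered_fraction, malignant)`, with `signal` cells x windows and
#'   `calls` and the per-cell fields `NULL` until [call_windows()] /
#'   [call_malignant()].
#' @export
window_smooth <- function(nm, reference_cells, window = 100L,
                          min_mean_count = 0.1) {
  if (is.null(nm$gene_pos)) stopf("gene positions required")
  if (!length(reference_cells)) stopf("empty reference set")
  if (!all(reference_cells %in% nm$barcodes))
    stopf("unknown reference barcodes")
  mean_count <- Matrix::rowMeans(nm$counts)
  keep <- mean_count >= min_mean_count
  am_log(sprintf("window_smooth: %d/%d genes pass mean count >= %g",
                 sum(keep), length(keep), min_mean_count))
  gp <- nm$gene_pos[match(nm$gene_ids[keep], nm$gene_pos$gene_id), ]
  if (anyNA(gp$gene_id)) stopf("genes missing from gene_pos")
  ord <- order(gp$chrom, gp$start)
  gp <- gp[ord, ]
  vals <- as.matrix(nm$values[match(gp$gene_id, nm$gene_ids), , drop = FALSE])
  ref_idx <- match(reference_cells, nm$barcodes)
  centered <- vals - rowMeans(vals[, ref_idx, drop = FALSE])
  win_list <- list(); sig_list <- list()
  for (ch in unique(gp$chrom)) {
    rows <- which(gp$chrom == ch)
    if (length(rows) < window) {
      warnf("window_smooth: chromosome %s has <%d genes, skipped", ch, window)
      next
    }
    cs <- apply(centered[rows, , drop = FALSE], 2, cumsum)
    cs <- rbind(0, cs)
    n_w <- length(rows) - window + 1
    sw <- (cs[(window + 1):(window + n_w), , drop = FALSE] -
             cs[1:n_w, , drop = FALSE]) / window
    sig_list[[ch]] <- sw
    win_list[[ch]] <- data.frame(
      chrom = ch, first_gene = gp$gene_id[rows[seq_len(n_w)]],
      last_gene = gp$gene_id[rows[seq_len(n_w) + window - 1]],
      stringsAsFactors = FALSE)
  }
  if (!length(sig_list)) stopf("no chromosome has enough genes for a window")
  signal <- t(do.call(rbind, sig_list))   # cells x windows
  windows <- do.call(rbind, win_list)
  rownames(windows) <- NULL
  colnames(signal) <- sprintf("%s_w%04d", windows$chrom,
                              unlist(lapply(sig_list, function(s)
                                seq_len(nrow(s))), use.names = FALSE))
  rownames(signal) <- nm$barcodes
  structure(list(windows = windows, signal = signal,
                 reference_cells = reference_cells, calls = NULL,
                 altered_fraction = NULL, malignant = NULL),
            class = "CnvProfile")
}

#' @export
print.CnvProfile <- function(x, ...) {
  cat(sprintf("CnvProfile: %d cells x %d windows (%d reference cells)%s\n",
              nrow(x$signal), ncol(x$signal), length(x$reference_cells),
              if (is.null(x$calls)) "" else ", called"))
  invisible(x)
}

#' Denoise a CNV profile around the reference mean
#'
#' Let mu and sigma be the mean and SD of the reference cells' signals
#' pooled over all windows; query signals within `mu +/- k_sd * sigma` are
#' flattened to mu, values outside are unchanged. Reference rows are left
#' untouched so the calling interval stays empirical. Idempotent.
#'
#' @param profile A `CnvProfile`.
#' @param k_sd Published default 1.5.
#' @return The denoised `CnvProfile`.
#' @export
denoise_cnv <- function(profile, k_sd = 1.5) {
  ref <- rownames(profile$signal) %in% profile$reference_cells
  pooled <- profile$signal[ref, , drop = FALSE]
  mu <- mean(pooled); sigma <- sd(as.numeric(pooled))
  q <- profile$signal[!ref, , drop = FALSE]
  inside <- abs(q - mu) <= k_sd * sigma
  q[inside] <- mu
  profile$signal[!ref, ] <- q
  profile$denoise <- list(mu = mu, sigma = sigma, k_sd = k_sd)
  profile
}

#' Call per-window gains and losses by reference interval
#'
#' Per window, the empirical `(1-ci_level)/2` and `1-(1-ci_level)/2`
#' quantiles of the reference cells' signal define the neutral interval;
#' signal below is called `loss`, above `gain`, inside `neutral`.
#' `altered_fraction` per cell = non-neutral windows / windows.
#'
#' @param profile A `CnvProfile` (typically after [denoise_cnv()]).
#' @param ci_level Published default 0.99.
#' @return The `CnvProfile` with `calls` and `altered_fraction` filled.
#' @export
call_windows <- function(profile, ci_level = 0.99) {
  ref <- rownames(profile$signal) %in% profile$reference_cells
  if (sum(ref) < 50)
    warnf("call_windows: only %d reference cells, quantiles unstable",
          sum(ref))
  a <- (1 - ci_level) / 2
  lo <- apply(profile$signal[ref, , drop = FALSE], 2, quantile, probs = a)
  hi <- apply(profile$signal[ref, , drop = FALSE], 2, quantile,
              probs = 1 - a)
  calls <- matrix("neutral", nrow(profile$signal), ncol(profile$signal),
                  dimnames = dimnames(profile$signal))
  calls[sweep(profile$signal, 2, lo, `<`)] <- "loss"
  calls[sweep(profile$signal, 2, hi, `>`)] <- "gain"
  profile$calls <- calls
  profile$altered_fraction <- rowMeans(calls != "neutral")
  profile
}

#' Per-cell malignancy verdict from altered genome fraction
#'
#' A cell is malignant iff its altered fraction (non-neutral windows over
#' all windows, the window-space proxy for genome span) strictly exceeds
#' `genome_fraction`.
#'
#' @param profile A called `CnvProfile`.
#' @param genome_fraction Published default 0.03 (">3% of the genome").
#' @return The `CnvProfile` with the logical `malignant` field filled.
#' @export
call_malignant <- function(profile, genome_fraction = 0.03) {
  if (is.null(profile$altered_fraction)) stopf("call_windows first")
  profile$malignant <- profile$altered_fraction > genome_fraction
  profile
}

#' Run the CNV caller end-to-end
#'
#' [window_smooth()] then [denoise_cnv()], [call_windows()] and
#' [call_malignant()] with the configured parameters.
#'
#' @param nm A `NormalizedMatrix` with gene positions.
#' @param reference_cells Reference barcodes.
#' @param cfg A [default_config()] (fields `window`, `min_mean_count`,
#'   `denoise_sd`, `ci_level`, `genome_fraction`).
#' @return A fully-called `CnvProfile`.
#' @export
run_cnv <- function(nm, reference_cells, cfg = default_config()) {
  profile <- window_smooth(nm, reference_cells, cfg$window,
                           cfg$min_mean_count)
  profile <- denoise_cnv(profile, cfg$denoise_sd)
  profile <- call_windows(profile, cfg$ci_level)
  call_malignant(profile, cfg$genome_fraction)
}
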