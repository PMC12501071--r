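# A deterministic profile for rule checks, bypassing smoothing.
mk_profile <- function(signal, ref_cells) {
  structure(list(windows = data.frame(chrom = "chr1",
                                      first_gene = colnames(signal),
                                      last_gene = colnames(signal)),
                 signal = signal, reference_cells = ref_cells,
                 calls = NULL, altered_fraction = NULL, malignant = NULL),
            class = "CnvProfile")
}

test_that("window smoothing is the windowed mean of reference-centered expression", {
  n_g <- 400; n_ref <- 20
  gp <- data.frame(gene_id = sprintf("G%03d", 1:n_g), chrom = "chr1",
                   start = seq_len(n_g) * 100, end = seq_len(n_g) * 100 + 50)
  base <- matrix(rep(seq(0.5, 1.5, length.out = n_g), n_ref + 1), n_g)
  # query cell: +log(2) on genes 50..249 (a 200-gene span)
  base[50:249, n_ref + 1] <- base[50:249, n_ref + 1] + log(2)
  colnames(base) <- c(sprintf("R%02d", 1:n_ref), "Q1")
  nm <- make_nm(base, gene_pos = gp)
  prof <- suppressMessages(window_smooth(nm, sprintf("R%02d", 1:n_ref)))
  expect_equal(ncol(prof$signal), n_g - 100 + 1)
  # reference cells are exactly centered
  expect_true(all(abs(prof$signal[1:n_ref, ]) < 1e-12))
  # windows fully inside the span read exactly log(2)
  inside <- 50:(249 - 99)
  expect_true(all(abs(prof$signal["Q1", inside] - log(2)) < 1e-12))
  # windows fully past the span read 0
  outside <- 250:(n_g - 99)
  expect_true(all(abs(prof$signal["Q1", outside]) < 1e-12))
})

test_that("low-count genes are excluded and short chromosomes skipped", {
  n_g <- 250
  gp <- data.frame(gene_id = sprintf("G%03d", 1:n_g),
                   chrom = rep(c("chr1", "chr2"), c(220, 30)),
                   start = seq_len(n_g), end = seq_len(n_g) + 1)
  vals <- matrix(1, n_g, 30)
  counts <- matrix(1, n_g, 30)
  counts[5, ] <- c(1, rep(0, 29))  # mean 1/30 < 0.1 -> dropped
  nm <- make_nm(vals, counts = counts, gene_pos = gp)
  expect_warning(
    prof <- suppressMessages(window_smooth(nm, nm$barcodes[1:20])),
    "chr2")
  # chr1 keeps 219 of 220 genes -> 120 windows; chr2 skipped
  expect_equal(ncol(prof$signal), 219 - 100 + 1)
  expect_false("G005" %in% prof$windows$first_gene)
})

test_that("denoising flattens within-band signal to the reference mean and is idempotent", {
  set.seed(6)
  sig <- matrix(rnorm(30 * 50), 30, 50,
                dimnames = list(c(sprintf("R%02d", 1:20), sprintf("Q%02d", 1:10)),
                                sprintf("w%02d", 1:50)))
  ref <- sprintf("R%02d", 1:20)
  prof <- mk_profile(sig, ref)
  mu <- mean(sig[ref, ]); sigma <- sd(as.numeric(sig[ref, ]))
  d1 <- denoise_cnv(prof, 1.5)
  q <- d1$signal[sprintf("Q%02d", 1:10), ]
  flat <- abs(sig[sprintf("Q%02d", 1:10), ] - mu) <= 1.5 * sigma
  expect_true(all(q[flat] == mu))
  expect_true(all(q[!flat] == sig[sprintf("Q%02d", 1:10), ][!flat]))
  # fully in-band signal flattens entirely
  prof2 <- mk_profile(rbind(sig[ref, ],
                            Q1 = rep(mu + 0.5 * sigma, 50)), ref)
  expect_true(all(denoise_cnv(prof2, 1.5)$signal["Q1", ] == mu))
  # idempotence
  d2 <- denoise_cnv(d1, 1.5)
  expect_identical(d2$signal, d1$signal)
})

test_that("window calls use the reference interval and the malignancy rule is strict at 3%", {
  set.seed(9)
  ref_names <- sprintf("R%03d", 1:200)
  sig <- matrix(rnorm(200 * 100), 200, 100,
                dimnames = list(ref_names, sprintf("w%03d", 1:100)))
  med <- apply(sig, 2, median)
  qsig <- rbind(sig, Qmed = med)
  prof <- suppressWarnings(call_windows(mk_profile(qsig, ref_names)))
  expect_true(all(prof$calls["Qmed", ] == "neutral"))
  # forced calls: push k windows far outside the interval
  mk_q <- function(k) {
    v <- med; if (k > 0) v[seq_len(k)] <- 10
    v
  }
  qs <- rbind(sig, Q2 = mk_q(2), Q3 = mk_q(3), Q5 = mk_q(5))
  prof2 <- call_malignant(suppressWarnings(call_windows(mk_profile(qs, ref_names))))
  expect_equal(unname(prof2$altered_fraction[c("Q2", "Q3", "Q5")]),
               c(0.02, 0.03, 0.05))
  expect_identical(unname(prof2$malignant[c("Q2", "Q3", "Q5")]),
                   c(FALSE, FALSE, TRUE))  # 3% boundary: strict >
  # small reference pools warn
  expect_warning(call_windows(mk_profile(qsig[c(1:30, 201), ], ref_names[1:30])),
                 "quantiles unstable")
})

test_that("planted gains are called in carriers with high window sensitivity", {
  cfg <- cnv_sim_config(n_genes = 2000, n_chromosomes = 4,
                        n_reference_cells = 300, n_query_cells = 40,
                        cnv_events = list(list(span = 300, fold = 2, frac = 1)),
                        seed = 3)
  sim <- generate_cnv_cells(cfg)
  nm <- suppressMessages(normalize_counts(sim$cm))
  ref <- sim$cm$barcodes[sim$cm$celltype_of == "reference"]
  prof <- suppressMessages(run_cnv(nm, ref))
  ev <- sim$truth$event_genes[[1]]
  inside <- prof$windows$first_gene %in% ev & prof$windows$last_gene %in% ev
  qry <- setdiff(rownames(prof$signal), ref)
  expect_gte(mean(prof$calls[qry, inside] == "gain"), 0.9)
  expect_true(all(prof$malignant[qry]))
})

test_that("calls are invariant to query order and common depth scaling", {
  cfg <- cnv_sim_config(n_genes = 1200, n_chromosomes = 3,
                        n_reference_cells = 150, n_query_cells = 20,
                        cnv_events = list(list(span = 200, fold = 1.8, frac = 0.5)),
                        seed = 12)
  sim <- generate_cnv_cells(cfg)
  # pre-apply the mean-count floor so depth scaling cannot change the gene
  # panel (the floor is defined on raw counts)
  pass <- Matrix::rowMeans(sim$cm$counts) >= 0.1
  sim$cm <- subset_cells(sim$cm, seq_along(sim$cm$barcodes), which(pass))
  ref <- sim$cm$barcodes[sim$cm$celltype_of == "reference"]
  run_calls <- function(cm) {
    prof <- suppressMessages(suppressWarnings(
      run_cnv(normalize_counts(cm), ref)))
    prof$calls[order(rownames(prof$calls)), ]
  }
  c1 <- run_calls(sim$cm)
  set.seed(2)
  perm <- sample(ncol(sim$cm$counts))
  cm_p <- count_matrix(sim$cm$counts[, perm], sim$cm$gene_ids,
                       sim$cm$barcodes[perm], sim$cm$sample_of[perm],
                       sim$cm$celltype_of[perm], sim$cm$gene_pos)
  expect_identical(run_calls(cm_p), c1)
  # common depth scaling: median-target normalization absorbs the factor up
  # to the log1p pseudocount, so calls agree except at interval boundaries
  cm_s <- count_matrix(sim$cm$counts * 3, sim$cm$gene_ids, sim$cm$barcodes,
                       sim$cm$sample_of, sim$cm$celltype_of, sim$cm$gene_pos)
  c_s <- run_calls(cm_s)
  expect_gte(mean(c_s == c1), 0.99)
})
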