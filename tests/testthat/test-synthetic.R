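test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_tumors = 2, cells_per_tumor = 50, n_genes = 100,
                    planted_modules = list(list(size = 20, carriers = 1:2,
                                                effect = 1.5)),
                    seed = 7)
  a <- generate_multi_tumor_dataset(cfg)
  b <- generate_multi_tumor_dataset(cfg)
  expect_identical(as.matrix(a$cm$counts), as.matrix(b$cm$counts))
  expect_identical(a$truth$activity, b$truth$activity)
  cfg2 <- cfg; cfg2$seed <- 8
  expect_false(identical(as.matrix(a$cm$counts),
                         as.matrix(generate_multi_tumor_dataset(cfg2)$cm$counts)))

  ccfg <- sim_config(n_genes = 400, n_chromosomes = 2,
                     n_reference_cells = 30, n_query_cells = 10,
                     cnv_events = list(list(span = 100, fold = 2, frac = 0.5)),
                     seed = 3)
  expect_identical(as.matrix(generate_cnv_cells(ccfg)$cm$counts),
                   as.matrix(generate_cnv_cells(ccfg)$cm$counts))
})

test_that("generated counts are non-negative integers and times positive", {
  cfg <- sim_config(n_tumors = 2, cells_per_tumor = 40, n_genes = 80,
                    seed = 5)
  sim <- generate_multi_tumor_dataset(cfg)
  x <- sim$cm$counts@x
  expect_true(all(x >= 0) && all(x == round(x)))
  ct <- generate_celltype_dataset(sim_config(n_genes = 80, n_celltypes = 3,
                                             seed = 5), 30)
  bk <- generate_bulk_cohort(sim_config(n_genes = 80, cohort_n = 50,
                                        seed = 5), ct$centroids)
  expect_true(all(bk$cohort$clinical$time_dfs > 0))
  expect_true(all(bk$cohort$clinical$time_os > 0))
  expect_true(all(bk$cohort$clinical$event_os %in% 0:1))
})

test_that("null construction has pure negative-binomial variance and no leading structure", {
  cfg <- sim_config(n_tumors = 1, cells_per_tumor = 500, n_genes = 300,
                    planted_modules = list(list(size = 50, carriers = 1,
                                                effect = 0)),
                    nb_dispersion = 0.1, seed = 21)
  sim <- generate_multi_tumor_dataset(cfg)
  m <- as.matrix(sim$cm$counts)
  mu <- rowMeans(m)
  v_obs <- apply(m, 1, var)
  v_th <- mu + 0.1 * mu^2
  ratio <- v_obs[mu > 0.2] / v_th[mu > 0.2]
  expect_gt(median(ratio), 0.8)
  expect_lt(median(ratio), 1.25)
  # leading PC explains no more variance than in a gene-wise permuted
  # (structure-free) version of the same matrix
  nm <- suppressMessages(normalize_counts(sim$cm))
  vals <- as.matrix(nm$values)
  pc <- prcomp(t(vals), center = TRUE)
  share <- pc$sdev[1]^2 / sum(pc$sdev^2)
  set.seed(1)
  vperm <- t(apply(vals, 1, sample))
  pc0 <- prcomp(t(vperm), center = TRUE)
  share0 <- pc0$sdev[1]^2 / sum(pc0$sdev^2)
  expect_lt(share, 1.5 * share0)
})

test_that("planted module activity raises module-gene expression in on-cells of carrier tumors", {
  cfg <- sim_config(n_tumors = 6, cells_per_tumor = 100, n_genes = 300,
                    planted_modules = list(list(size = 50, carriers = 1:4,
                                                effect = 2)),
                    seed = 13)
  sim <- generate_multi_tumor_dataset(cfg)
  m <- as.matrix(sim$cm$counts)
  genes <- match(sim$truth$module_genes[[1]], sim$cm$gene_ids)
  for (t in sprintf("T%02d", 1:4)) {
    cells <- sim$cm$sample_of == t
    on <- sim$truth$activity[cells, 1] == 1
    mod_mean <- colMeans(m[genes, cells, drop = FALSE])
    expect_gt(mean(mod_mean[on]), mean(mod_mean[!on]))
  }
})

test_that("CNV generator scales carrier counts by the event fold-change", {
  cfg <- sim_config(n_genes = 1000, n_chromosomes = 2,
                    n_reference_cells = 200, n_query_cells = 100,
                    cnv_events = list(list(span = 300, fold = 2, frac = 1)),
                    seed = 17)
  sim <- generate_cnv_cells(cfg)
  genes <- match(sim$truth$event_genes[[1]], sim$cm$gene_ids)
  ref <- sim$cm$celltype_of == "reference"
  qry <- sim$cm$celltype_of == "query"
  m_ref <- mean(as.matrix(sim$cm$counts[genes, ref]))
  m_car <- mean(as.matrix(sim$cm$counts[genes, qry]))
  expect_gt(m_car / m_ref, 1.8)  # ~2x within 10%
  expect_lt(m_car / m_ref, 2.2)

  cfg0 <- cfg; cfg0$cnv_events <- list(list(span = 300, fold = 2, frac = 0))
  expect_false(any(generate_cnv_cells(cfg0)$truth$carrier))
})

test_that("noiseless bulk mixtures are exact and proportions lie on the simplex", {
  sig <- cbind(a = c(1, 2, 3, 4, 0), b = c(4, 0, 1, 2, 5))
  rownames(sig) <- sprintf("G%03d", 1:5)
  cfg <- sim_config(n_genes = 5, cohort_n = 30, noise_sd = 0, seed = 9)
  bk <- generate_bulk_cohort(cfg, sig)
  P <- bk$truth$proportions
  expect_equal(unname(rowSums(P)), rep(1, 30))
  expect_equal(unname(bk$cohort$expr), unname(P %*% t(sig)))
  # noisy case still sums to 1
  bk2 <- generate_bulk_cohort(sim_config(n_genes = 5, cohort_n = 25,
                                         noise_sd = 0.3, seed = 10), sig)
  expect_equal(unname(rowSums(bk2$truth$proportions)), rep(1, 25))
})

test_that("null planted hazard gives calibrated Cox confidence intervals on true scores", {
  set.seed(42)
  sig <- matrix(rlnorm(60 * 5), 60, 5,
                dimnames = list(sprintf("G%03d", 1:60), sprintf("P%d", 1:5)))
  covered <- logical(100)
  for (i in 1:100) {
    cfg <- sim_config(n_genes = 60, cohort_n = 120, noise_sd = 0.1,
                      ecotype_blocks = list(1:2, 3:5), log_hazard = c(0, 0),
                      seed = 1000 + i)
    bk <- generate_bulk_cohort(cfg, sig)
    df <- data.frame(time = bk$cohort$clinical$time_os,
                     event = bk$cohort$clinical$event_os,
                     s = bk$truth$ecotype_scores[, 1])
    ci <- summary(survival::coxph(survival::Surv(time, event) ~ s,
                                  data = df))$conf.int
    covered[i] <- ci[1, "lower .95"] <= 1 && ci[1, "upper .95"] >= 1
  }
  expect_gte(mean(covered), 0.9)
})
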