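test_that("Sørensen index matches hand examples and the brute-force oracle", {
  expect_equal(sorensen_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(sorensen_index(c("a", "b"), c("c", "d")), 0)
  expect_equal(sorensen_index(c("g1", "g2", "g3"), c("g2", "g3", "g4")),
               2 * 2 / (3 + 3))
  expect_error(sorensen_index(character(), "a"), "empty set")
  set.seed(5)
  universe <- sprintf("g%03d", 1:60)
  for (i in 1:200) {
    a <- sample(universe, sample(1:30, 1))
    b <- sample(universe, sample(1:30, 1))
    expect_identical(sorensen_index(a, b), brute_sorensen(a, b))
  }
})

test_that("per-tumor PCA emits exactly 2 x n_components modules of top_k genes", {
  cfg <- sim_config(n_tumors = 1, cells_per_tumor = 300, n_genes = 400,
                    planted_modules = list(list(size = 50, carriers = 1,
                                                effect = 2)),
                    seed = 19)
  sim <- generate_multi_tumor_dataset(cfg)
  nm <- normalize_counts(sim$cm)
  mods <- suppressMessages(extract_candidate_modules(nm, tumor = "T01"))
  expect_length(mods, 20)
  expect_true(all(vapply(mods, function(m) length(m$genes), integer(1)) == 50))
  expect_true(all(vapply(mods, function(m) m$component, integer(1)) %in% 1:10))
  # the planted program is captured by PC1's signed modules
  pc1 <- unique(unlist(lapply(mods[1:2], `[[`, "genes")))
  overlap <- length(intersect(pc1, sim$truth$module_genes[[1]]))
  expect_gte(overlap, 45)
  # under-sized tumors are skipped
  small <- subset_cells(sim$cm, 1:200)
  expect_length(suppressMessages(
    extract_candidate_modules(normalize_counts(small), tumor = "T01")), 0)
})

test_that("non-recurrent module filtering applies the neighbor rule exactly", {
  mk <- function(vals) {
    n <- nrow(vals)
    dimnames(vals) <- list(sprintf("m%d", 1:n), sprintf("m%d", 1:n))
    vals
  }
  # m1 neighbors: 0.5, 0.45, 0.1 -> kept; m4 best 0.5 second 0.1 -> discarded
  s <- mk(rbind(c(1, 0.5, 0.45, 0.1), c(0.5, 1, 0.45, 0.1),
                c(0.45, 0.45, 1, 0.1), c(0.1, 0.1, 0.1, 1)))
  kept <- suppressMessages(filter_nonrecurrent(s))
  expect_identical(rownames(kept), c("m1", "m2", "m3"))
  # one strong neighbor is not enough
  s2 <- mk(rbind(c(1, 0.9, 0.39), c(0.9, 1, 0.39), c(0.39, 0.39, 1)))
  expect_identical(nrow(suppressMessages(filter_nonrecurrent(s2))), 0L)
  # boundary: all off-diagonals below 0.4
  s3 <- mk(matrix(0.39, 3, 3) + diag(0.61, 3))
  expect_identical(nrow(suppressMessages(filter_nonrecurrent(s3))), 0L)
  # monotonicity: lowering the threshold never decreases survivors
  set.seed(8)
  for (i in 1:20) {
    r <- matrix(runif(64), 8); r <- (r + t(r)) / 2; diag(r) <- 1
    dimnames(r) <- list(sprintf("m%d", 1:8), sprintf("m%d", 1:8))
    n_hi <- nrow(suppressMessages(filter_nonrecurrent(r, 0.6)))
    n_lo <- nrow(suppressMessages(filter_nonrecurrent(r, 0.3)))
    expect_gte(n_lo, n_hi)
  }
})

test_that("module clustering keeps blocks spanning >= 3 tumors at the finest cut", {
  # two planted blocks from 4 tumors each, one 2-tumor block, one singleton
  mk_mod <- function(id, tumor) list(id = id, source_tumor = tumor,
                                     component = 1, sign = "pos",
                                     genes = character())
  ids <- c(sprintf("a%d", 1:4), sprintf("b%d", 1:4), sprintf("c%d", 1:2), "solo")
  tumors <- c(sprintf("T%d", 1:4), sprintf("T%d", 1:4), c("T1", "T2"), "T9")
  modules <- setNames(Map(mk_mod, ids, tumors), ids)
  n <- length(ids)
  s <- matrix(0.05, n, n, dimnames = list(ids, ids))
  s[1:4, 1:4] <- 0.8; s[5:8, 5:8] <- 0.8; s[9:10, 9:10] <- 0.8
  diag(s) <- 1
  cl <- suppressMessages(cluster_modules(s, modules))
  expect_length(cl, 2)
  got <- lapply(cl, function(x) sort(x$member_ids))
  expect_true(list(sort(ids[1:4])) %in% got || identical(got[[1]], sort(ids[1:4])))
  expect_setequal(unlist(got), ids[1:8])  # 2-tumor block and singleton dropped
})

test_that("consensus genes follow tumor-level counting at the 50% boundary", {
  mk_mod <- function(id, tumor, genes) list(id = id, source_tumor = tumor,
                                            component = 1, sign = "pos",
                                            genes = genes)
  modules <- list(
    m1 = mk_mod("m1", "T1", c("gA", "gB", "gD")),
    m2 = mk_mod("m2", "T1", c("gD")),            # gD twice in T1: counts once
    m3 = mk_mod("m3", "T2", c("gA", "gB")),
    m4 = mk_mod("m4", "T3", c("gB")),
    m5 = mk_mod("m5", "T4", c("gB", "gC")))
  cluster <- list(member_ids = names(modules), tumors = sprintf("T%d", 1:4))
  cm <- derive_consensus_genes(cluster, modules, 0.5, id = "CM1")
  # gA in 2/4 tumors = 50% inclusive -> kept; gC, gD in 1/4 -> excluded
  expect_setequal(cm$genes, c("gA", "gB"))
  expect_identical(cm$genes, brute_consensus(modules))
  # empty consensus drops the cluster with a warning
  solo <- list(
    x1 = mk_mod("x1", "T1", "g1"), x2 = mk_mod("x2", "T2", "g2"),
    x3 = mk_mod("x3", "T3", "g3"), x4 = mk_mod("x4", "T4", "g4"))
  expect_warning(
    out <- derive_consensus_genes(list(member_ids = names(solo),
                                       tumors = sprintf("T%d", 1:4)),
                                  solo, 0.5, id = "CMx"),
    "empty consensus")
  expect_null(out)
})

test_that("cell scoring is linear, argmax-labeled and recovers planted activity", {
  # deterministic values: gene baselines well separated so the expression
  # bins are unchanged by a single-cell shift
  vals <- matrix(rep(seq(1, 20, length.out = 200), 60), 200, 60)
  nm <- make_nm(vals)
  mod_rows <- seq(5, 200, by = 10)
  modA <- nm$gene_ids[mod_rows]; modB <- nm$gene_ids[mod_rows + 2]
  # shift module A genes by +1 in cell 1
  vals2 <- vals; vals2[mod_rows, 1] <- vals2[mod_rows, 1] + 1
  nm2 <- make_nm(vals2)
  sc1 <- suppressMessages(score_cells(nm, list(A = modA, B = modB), seed = 4))
  sc2 <- suppressMessages(score_cells(nm2, list(A = modA, B = modB), seed = 4))
  expect_identical(sc1$controls, sc2$controls)  # bins undisturbed
  # score shift = +1 minus the mean shift of the sampled control genes
  ctrl_shift <- mean(sc2$controls$A %in% mod_rows)
  expect_equal(sc2$scores[1, "A"] - sc1$scores[1, "A"], 1 - ctrl_shift,
               tolerance = 1e-12)
  # module B's own genes unshifted: its score moves only via shared controls
  ctrl_shift_b <- mean(sc2$controls$B %in% mod_rows)
  expect_equal(sc2$scores[1, "B"] - sc1$scores[1, "B"], -ctrl_shift_b,
               tolerance = 1e-12)
  expect_equal(unname(sc2$label[1]), "A")
  # all other cells untouched
  expect_equal(sc2$scores[-1, ], sc1$scores[-1, ])
  # argmax labeling with deterministic tie-break to the lowest module id
  nm3 <- make_nm(matrix(1, 50, 4))
  sc3 <- suppressMessages(score_cells(nm3, list(M2 = nm3$gene_ids[1:10],
                                                M1 = nm3$gene_ids[1:10]),
                                      seed = 1))
  expect_true(all(sc3$label == "M1"))
  # missing genes dropped with warning; fully absent module errors
  expect_warning(suppressMessages(
    score_cells(nm, list(A = c(modA, "NOPE")), seed = 1)), "absent")
  expect_error(suppressMessages(
    score_cells(nm, list(A = c("NO1", "NO2")), seed = 1)), "no genes")
})

test_that("planted-program cells are labeled with their program's module", {
  cfg <- sim_config(n_tumors = 2, cells_per_tumor = 300, n_genes = 500,
                    planted_modules = list(
                      list(size = 40, carriers = 1:2, effect = 2),
                      list(size = 40, carriers = 1:2, effect = 2)),
                    seed = 23)
  sim <- generate_multi_tumor_dataset(cfg)
  nm <- normalize_counts(sim$cm)
  sets <- list(P1 = sim$truth$module_genes[[1]], P2 = sim$truth$module_genes[[2]])
  sc <- suppressMessages(score_cells(nm, sets, seed = 2))
  act <- sim$truth$activity
  pure1 <- act[, 1] == 1 & act[, 2] == 0
  pure2 <- act[, 2] == 1 & act[, 1] == 0
  expect_gte(mean(sc$label[pure1] == "P1"), 0.9)
  expect_gte(mean(sc$label[pure2] == "P2"), 0.9)
})

test_that("module discovery is invariant to cell and gene permutations", {
  cfg <- shared_private_config(seed = 31, cells_per_tumor = 300,
                               n_genes = 600)
  cfg$planted_modules <- cfg$planted_modules[1:3]  # shared programs only
  sim <- generate_multi_tumor_dataset(cfg)
  cfg_small <- default_config(min_cell_count = 250L)
  nm <- normalize_counts(sim$cm)
  res <- suppressMessages(discover_modules(nm, cfg_small))
  set.seed(3)
  gperm <- sample(nrow(sim$cm$counts)); cperm <- sample(ncol(sim$cm$counts))
  cm_p <- count_matrix(sim$cm$counts[gperm, cperm],
                       sim$cm$gene_ids[gperm], sim$cm$barcodes[cperm],
                       sim$cm$sample_of[cperm], sim$cm$celltype_of[cperm])
  res_p <- suppressMessages(discover_modules(normalize_counts(cm_p), cfg_small))
  sets <- lapply(res$consensus, function(x) sort(x$genes))
  sets_p <- lapply(res_p$consensus, function(x) sort(x$genes))
  expect_equal(length(sets), length(sets_p))
  # same gene sets up to module id renaming
  match_j <- vapply(sets, function(s)
    max(vapply(sets_p, function(q) jaccard_index(s, q), numeric(1))),
    numeric(1))
  expect_true(all(match_j == 1))
})
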