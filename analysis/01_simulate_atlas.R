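#!/usr/bin/env Rscript
# Simulate the synthetic multi-tumor atlas used throughout the analysis:
# 6 tumors x 800 steroid cells x 2,000 genes, with 3 expression programs
# shared by >= 4 tumors and one private program per tumor. Writes a small
# 10x-style excerpt plus the ground-truth program gene lists under results/,
# and the full dataset under scratch/ for inspection.

library(atlasmods)

dir.create("results/atlas", showWarnings = FALSE, recursive = TRUE)
dir.create("scratch/atlas", showWarnings = FALSE, recursive = TRUE)

mods <- list(
  list(size = 50, carriers = c(1, 2, 3, 4), effect = 1.5),
  list(size = 50, carriers = c(2, 3, 4, 5), effect = 1.5),
  list(size = 50, carriers = c(1, 3, 5, 6), effect = 1.5))
for (t in 1:6) mods <- c(mods, list(list(size = 50, carriers = t, effect = 1.5)))

cfg <- sim_config(n_tumors = 6, cells_per_tumor = 800, n_genes = 2000,
                  planted_modules = mods, seed = 11)
sim <- generate_multi_tumor_dataset(cfg)

cat(sprintf("simulated %d genes x %d cells over %d tumors\n",
            nrow(sim$cm$counts), ncol(sim$cm$counts),
            length(unique(sim$cm$sample_of))))

# full dataset to scratch (bulky), a small excerpt to results as a
# round-trip demonstration of the triplet format
write_counts(sim$cm, "scratch/atlas/full")
excerpt <- subset_cells(sim$cm, seq(1, ncol(sim$cm$counts), by = 200),
                        genes = 1:300)
write_counts(excerpt, "results/atlas/excerpt")
back <- read_counts("results/atlas/excerpt/matrix.mtx",
                    "results/atlas/excerpt/features.tsv",
                    "results/atlas/excerpt/barcodes.tsv",
                    "results/atlas/excerpt/metadata.tsv")
stopifnot(identical(as.matrix(back$counts), as.matrix(excerpt$counts)))
cat("triplet round-trip on the excerpt: identical\n")

# ground truth as GMT: the planted program gene lists
truth_sets <- sim$truth$module_genes
names(truth_sets) <- c(sprintf("shared_%d", 1:3), sprintf("private_T%02d", 1:6))
write_gmt(truth_sets, "results/atlas/planted_programs.gmt")

carriers <- data.frame(
  program = names(truth_sets),
  carrier_tumors = vapply(sim$truth$carriers, function(x)
    paste(sprintf("T%02d", x), collapse = ","), character(1)))
write.table(carriers, "results/atlas/planted_carriers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote planted program gene lists and carrier table under results/atlas/\n")
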