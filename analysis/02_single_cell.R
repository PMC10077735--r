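#!/usr/bin/env Rscript

# Single-cell arm: QC, normalization, silhouette-optimized clustering,
# metacell pooling, regulon inference, metaVIPER activity, activity-space
# re-clustering and master-regulator ranking. Reads the data written by
# 01_simulate.R and leaves every artifact (with a manifest) under
# results/pipeline/.

suppressMessages(library(scactivity))

dat <- "results/data"
counts <- read_counts(file.path(dat, "sc.mtx"),
                      file.path(dat, "sc_genes.tsv"),
                      file.path(dat, "sc_barcodes.tsv"))
cell_meta <- read.delim(file.path(dat, "cell_meta.tsv"))
regulators <- readLines(file.path(dat, "regulators.txt"))
bulk_counts <- as.matrix(read.delim(file.path(dat, "bulk_counts.tsv"),
                                    row.names = 1, check.names = FALSE))
bulk_groups <- readLines(file.path(dat, "bulk_groups.tsv"))

cfg <- default_config(
  seed = 20260927L, out_dir = "results/pipeline",
  resolution_grid = seq(0.01, 1, length.out = 10),
  silhouette_repeats = 30, n_boot = 30, n_meta = 150,
  regulon_min_targets = 10, network_per_cluster = FALSE)

res <- suppressWarnings(run_pipeline(
  counts, regulators, cfg,
  bulk = list(counts = bulk_counts, groups = bulk_groups),
  pathway_sets = list(homeostatic_program = jsonlite::read_json(
    file.path(dat, "truth.json"),
    simplifyVector = TRUE)$homeostatic_program),
  cell_meta = cell_meta))

message("retained cells: ", ncol(res$filtered))
message("expression clusters: ", length(unique(res$clusters$labels)),
        " at resolution ", res$clusters$resolution)
message("activity clusters: ",
        length(unique(res$activity_clusters$labels)))
message("inferred regulons: ",
        sum(vapply(res$regulon_sets, length, integer(1))))
for (k in names(res$gsea))
  message(sprintf("activity cluster %s: GSEA NES %.2f, p %.4f", k,
                  res$gsea[[k]]$NES, res$gsea[[k]]$p_perm))
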