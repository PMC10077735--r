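#!/usr/bin/env Rscript

# Builds the study's synthetic datasets: a 5-cluster single-cell cohort
# whose clusters are driven by planted regulator programs, and a two-group
# bulk cohort in which the cluster-1 ("homeostatic") program is suppressed
# in the disease group. Writes 10x-style MTX + TSV and bulk TSV under
# results/data/ together with the ground truth as JSON.

suppressMessages(library(scactivity))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
master <- 20260927L

net <- generate_truth_network(1000, 30, 35, pos_fraction = 0.7,
                              seed = master)
act <- make_cluster_activities(net, 5, level = 2)
sim <- simulate_sc_counts(net, act, cells_per_cluster = 200,
                          seed = master + 1L)
homeo <- net$regulators[which(act[, 1] > 0)]
bulk <- simulate_bulk_counts(net, n_group1 = 18, n_group2 = 20,
                             bulk_effects = setNames(rep(-2, length(homeo)),
                                                     homeo),
                             seed = master + 2L)

write_counts(sim$counts, out, "sc")
write.table(sim$cell_meta, file.path(out, "cell_meta.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(gene = rownames(bulk$counts), bulk$counts,
                       check.names = FALSE),
            file.path(out, "bulk_counts.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(as.character(bulk$groups), file.path(out, "bulk_groups.tsv"))
writeLines(net$regulators, file.path(out, "regulators.txt"))

jsonlite::write_json(list(
  seed = master,
  edges = sim$truth$network$edges,
  cluster_activities = as.data.frame(sim$truth$cluster_activities),
  homeostatic_program = homeo,
  bulk_truth_log2fc = as.list(bulk$truth_de[abs(bulk$truth_de) > 0])),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

message("cells: ", ncol(sim$counts), "; genes: ", nrow(sim$counts),
        "; bulk samples: ", ncol(bulk$counts))
message("homeostatic program: ", paste(homeo, collapse = ", "))
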