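#' Default pipeline configuration
#'
#' All stage parameters of the end-to-end analysis with their defaults.
#' Values supplied in `...` (or read from a YAML file via
#' [read_pipeline_config()]) override defaults; the master seed
#' deterministically derives every stage seed.
#'
#' @param ... overrides of any default.
#' @return named list of class `pipeline_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = "results/pipeline",
    # QC
    min_umi = 1000, gene_range = c(300, 8000), max_mito = 5,
    min_complexity = 0.8,
    # normalization / HVG / PCA
    n_hvg = 3000, n_pcs = 30,
    # clustering
    k_neighbors = 20, resolution_grid = seq(0.01, 1.0, length.out = 25),
    silhouette_repeats = 100, silhouette_subsample = 500,
    # metacells / network
    n_meta = 250, meta_k = 10, n_boot = 100, mi_p_threshold = 1e-8,
    dpi_tolerance = 0, n_null_pairs = 500,
    regulon_max_targets = 50, regulon_min_targets = 25,
    # activity / MRs
    signature_method = "zscore", mr_n_boot = 100, top_mr = 100,
    # bulk / GSEA / GSVA
    gsea_weight = 1, gsea_n_perm = 1000, gsva_mode = "max_diff",
    gsva_input = "activity",
    per_sample_standardize = FALSE,
    network_per_cluster = TRUE)
  utils::modifyList(cfg, list(...))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of overrides.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

stage_file <- function(out_dir, name) file.path(out_dir, name)

#' Run the end-to-end protein-activity pipeline
#'
#' Executes: QC -> normalization/HVG -> PCA -> silhouette-optimized Louvain
#' clustering -> metacell pooling -> per-cluster bootstrap-consensus
#' networks -> signatures -> metaVIPER -> activity-space re-clustering ->
#' master regulators -> (optionally) bulk differential expression -> GSEA
#' of each activity cluster's top master regulators with leading edges ->
#' (optionally) per-cell GSVA. Every tabular artifact is written under
#' `config$out_dir` with a JSON manifest of parameters, seeds and content
#' hashes. Omitting `bulk` skips the DEG/GSEA stages; omitting
#' `pathway_sets` skips GSVA (both noted in the manifest).
#'
#' @param counts genes x cells UMI counts.
#' @param regulators regulator id vector (or named list of classes).
#' @param config a `pipeline_config` (see [default_config()]).
#' @param bulk optional list(counts, groups) for the bulk arm.
#' @param pathway_sets optional named gene-set list for GSVA.
#' @param cell_meta optional per-cell metadata written alongside labels.
#' @return invisible list with all in-memory stage results plus `manifest`.
#' @export
run_pipeline <- function(counts, regulators, config = default_config(),
                         bulk = NULL, pathway_sets = NULL,
                         cell_meta = NULL) {
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  res <- list()
  skipped <- character(0)

  metrics <- compute_qc_metrics(counts)
  filtered <- filter_cells(counts, metrics,
                           list(min_umi = config$min_umi,
                                gene_range = config$gene_range,
                                max_mito = config$max_mito,
                                min_complexity = config$min_complexity))
  write_tsv(attr(filtered, "qc_report"), stage_file(out_dir, "qc_report.tsv"))
  writeLines(colnames(filtered), stage_file(out_dir, "retained_barcodes.tsv"))

  norm <- normalize_pearson_residuals(filtered)
  norm <- select_hvg(norm, n = min(config$n_hvg, nrow(filtered)))
  if (isTRUE(config$per_sample_standardize) && !is.null(cell_meta)) {
    sm <- cell_meta$sample[match(colnames(filtered), cell_meta$barcode)]
    norm <- standardize_per_sample(norm, sm)
  }
  emb <- run_pca(norm, n_pcs = config$n_pcs)

  clust <- optimize_resolution(emb, grid = config$resolution_grid,
                               n_repeats = config$silhouette_repeats,
                               subsample = min(config$silhouette_subsample,
                                               ncol(filtered)),
                               k_neighbors = config$k_neighbors,
                               seed = derive_seed(seed, 2L))
  write_tsv(data.frame(barcode = names(clust$labels),
                       cluster = clust$labels),
            stage_file(out_dir, "expression_clusters.tsv"))
  write_tsv(clust$silhouette_trace,
            stage_file(out_dir, "silhouette_trace_expression.tsv"))

  meta <- pool_metacells(filtered, clust$labels, emb,
                         n_meta = config$n_meta, k = config$meta_k,
                         seed = derive_seed(seed, 3L))

  contexts <- if (isTRUE(config$network_per_cluster))
    sort(unique(meta$origin_cluster)) else "all"
  networks <- list(); regulon_sets <- list()
  for (cx in contexts) {
    vals <- if (identical(cx, "all")) meta$values
            else meta$values[, meta$origin_cluster == cx, drop = FALSE]
    if (ncol(vals) < 10) {
      skipped <- c(skipped, paste0("network_context_", cx))
      next
    }
    nw <- bootstrap_consensus_network(
      vals, regulators, n_boot = config$n_boot,
      p_threshold = config$mi_p_threshold,
      dpi_tolerance = config$dpi_tolerance,
      n_null_pairs = config$n_null_pairs,
      context_id = as.character(cx),
      seed = derive_seed(seed, 10L + as.integer(factor(cx))[1]))
    if (nrow(nw$edges) == 0) {
      skipped <- c(skipped, paste0("network_context_", cx))
      next
    }
    regs <- build_regulons(nw, vals,
                           max_targets = config$regulon_max_targets,
                           min_targets = config$regulon_min_targets)
    if (length(regs) == 0) {
      skipped <- c(skipped, paste0("regulons_context_", cx))
      next
    }
    networks[[paste0("context_", cx)]] <- nw
    regulon_sets[[paste0("context_", cx)]] <- regs
    write_tsv(nw$edges,
              stage_file(out_dir, paste0("network_context_", cx, ".tsv")))
  }
  assert_that(length(regulon_sets) > 0, "no context yielded regulons")

  cpm <- t(t(as.matrix(filtered)) / pmax(colSums(as.matrix(filtered)), 1)) * 1e6
  sig <- compute_signatures(log2(cpm + 1), method = config$signature_method)
  act <- metaviper_activity(sig, regulon_sets)
  write_matrix_tsv(act$values, stage_file(out_dir, "activity_matrix.tsv"))

  act_emb <- run_pca(compute_signatures(act$values),
                     n_pcs = min(config$n_pcs, nrow(act$values) - 1L))
  act_clust <- optimize_resolution(
    act_emb, grid = config$resolution_grid,
    n_repeats = config$silhouette_repeats,
    subsample = min(config$silhouette_subsample, ncol(act$values)),
    k_neighbors = config$k_neighbors, seed = derive_seed(seed, 4L))
  write_tsv(data.frame(barcode = names(act_clust$labels),
                       cluster = act_clust$labels),
            stage_file(out_dir, "activity_clusters.tsv"))

  mr <- master_regulators(act, act_clust$labels, n_boot = config$mr_n_boot,
                          seed = derive_seed(seed, 5L))
  write_tsv(mr, stage_file(out_dir, "master_regulators.tsv"))
  top_mrs <- top_master_regulators(mr, n = config$top_mr)

  gsea_results <- NULL
  if (!is.null(bulk)) {
    deg <- differential_expression(bulk$counts, bulk$groups)
    write_tsv(deg, stage_file(out_dir, "bulk_deg.tsv"))
    ranked <- rank_genes(deg)
    gsea_results <- list()
    for (k in names(top_mrs)) {
      gs <- intersect(top_mrs[[k]], ranked$gene)
      if (length(gs) < 5) {
        skipped <- c(skipped, paste0("gsea_cluster_", k))
        next
      }
      gsea_results[[k]] <- gsea(ranked, gs, weight_p = config$gsea_weight,
                                n_perm = config$gsea_n_perm,
                                seed = derive_seed(seed, 6L))
    }
    if (length(gsea_results)) {
      summ <- do.call(rbind, lapply(names(gsea_results), function(k) {
        g <- gsea_results[[k]]
        data.frame(cluster = k, set_size = g$set_size, ES = g$ES,
                   NES = g$NES, p = g$p_perm,
                   significant = abs(g$NES) > 1 & g$p_perm < 0.05,
                   leading_edge = paste(g$leading_edge, collapse = ","))
      }))
      write_tsv(summ, stage_file(out_dir, "gsea_results.tsv"))
    }
  } else skipped <- c(skipped, "bulk_deg", "gsea")

  gsva <- NULL
  if (!is.null(pathway_sets)) {
    gsva_in <- if (identical(config$gsva_input, "expression"))
      log2(cpm + 1) else act$values
    gsva <- gsva_scores(gsva_in, pathway_sets, mode = config$gsva_mode)
    write_matrix_tsv(gsva, stage_file(out_dir, "gsva_scores.tsv"))
  } else skipped <- c(skipped, "gsva")

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest[.]json$", files)]
  manifest <- list(
    parameters = config[order(names(config))],
    master_seed = seed,
    skipped_stages = as.list(skipped),
    outputs = lapply(setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, stage_file(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(qc_metrics = metrics, filtered = filtered, norm = norm,
                 embedding = emb, clusters = clust, metacells = meta,
                 networks = networks, regulon_sets = regulon_sets,
                 activity = act, activity_clusters = act_clust,
                 mr_table = mr, top_mrs = top_mrs,
                 gsea = gsea_results, gsva = gsva, manifest = manifest))
}
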