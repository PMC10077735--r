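# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Standard desk-scale planted dataset: 1000 genes, 25 regulators x 40
# targets, 5 one-hot clusters, 200 cells each.
fx_sc <- function() fixture("sc", function() {
  net <- generate_truth_network(1000, 25, 40, pos_fraction = 0.7, seed = 11)
  act <- make_cluster_activities(net, 5, level = 2)
  sim <- simulate_sc_counts(net, act, cells_per_cluster = 200, seed = 42)
  qc <- compute_qc_metrics(sim$counts)
  filtered <- filter_cells(sim$counts, qc)
  norm <- select_hvg(normalize_pearson_residuals(filtered),
                     n = nrow(filtered))
  emb <- run_pca(norm, n_pcs = 30)
  list(net = net, act = act, sim = sim, qc = qc, filtered = filtered,
       norm = norm, emb = emb,
       truth_lab = sim$truth$cell_labels[colnames(filtered)])
})

# Two well-separated Gaussian blobs in 5 dimensions.
fx_blobs <- function(n_per = 100, d = 5, sep = 8, seed = 3) {
  with_seed <- scactivity:::with_seed
  with_seed(seed, {
    # cluster means sit on different coordinate axes so the clusters are
    # separated in profile shape (visible to correlation distance), not
    # just by a uniform offset
    m1 <- c(sep, rep(0, d - 1))
    m2 <- c(0, sep, rep(0, d - 2))
    x <- rbind(sweep(matrix(rnorm(n_per * d), n_per), 2, m1, "+"),
               sweep(matrix(rnorm(n_per * d), n_per), 2, m2, "+"))
    rownames(x) <- paste0("c", seq_len(2 * n_per))
    list(coords = x, labels = rep(1:2, each = n_per))
  })
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

edge_f1 <- function(pred, truth_edges) {
  tk <- paste(truth_edges$regulator, truth_edges$target)
  pk <- paste(pred$regulator, pred$target)
  tp <- sum(pk %in% tk)
  prec <- tp / max(length(pk), 1)
  rec <- tp / length(tk)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}
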