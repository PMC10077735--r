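#' Principal component analysis of normalized expression
#'
#' Runs PCA on the highly-variable-gene residuals (genes centered). Column
#' signs are fixed by making the largest-magnitude gene loading of each
#' component positive, so results are fully deterministic.
#'
#' @param norm a `normalized_matrix` with `hvg_flags` set (or any genes x
#'   cells numeric matrix, in which case all rows are used).
#' @param n_pcs number of components to keep.
#' @return list of class `embedding`: `coords` (cells x n_pcs),
#'   `explained_variance`, `n_pcs`, `loadings`.
#' @export
run_pca <- function(norm, n_pcs = 30) {
  assert_that(n_pcs > 0, "n_pcs must be positive")
  x <- if (inherits(norm, "normalized_matrix")) {
    assert_that(!is.null(norm$hvg_flags), "select_hvg() must be run first")
    norm$values[norm$hvg_flags, , drop = FALSE]
  } else as.matrix(norm)
  n_pcs <- min(n_pcs, ncol(x) - 1L, nrow(x))
  xc <- x - rowMeans(x)            # center each gene
  sv <- svd(t(xc), nu = n_pcs, nv = n_pcs)
  coords <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  loadings <- sv$v
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      coords[, j] <- -coords[, j]
    }
  }
  rownames(coords) <- colnames(x)
  rownames(loadings) <- rownames(x)
  ev <- sv$d[seq_len(n_pcs)]^2 / sum(sv$d^2)
  structure(list(coords = coords, explained_variance = ev,
                 n_pcs = n_pcs, loadings = loadings), class = "embedding")
}

#' Elbow-based advisory choice of component count
#'
#' Max-distance-to-chord detector on the explained-variance curve.
#'
#' @param embedding an `embedding`.
#' @return integer suggested number of components.
#' @export
elbow_n_pcs <- function(embedding) {
  ev <- embedding$explained_variance
  n <- length(ev)
  if (n < 3) return(n)
  x <- seq_len(n)
  chord <- ev[1] + (ev[n] - ev[1]) * (x - 1) / (n - 1)
  which.max(chord - ev + (ev - chord) * 0)  # distance below the chord
}

snn_graph <- function(coords, k_neighbors, prune = 1 / 15) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  knn <- t(apply(d, 1L, function(r) order(r)[seq_len(k_neighbors + 1L)]))
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k_neighbors + 1L),
                              j = as.vector(t(knn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  jac <- shared / (2 * (k_neighbors + 1L) - shared)
  jac[jac < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE)
}

#' Louvain clustering on a shared-nearest-neighbor graph
#'
#' Builds a Euclidean KNN graph in PC space, weights edges by Jaccard
#' overlap of neighbor lists, and optimizes modularity with the Louvain
#' algorithm at the given resolution. Labels are relabeled contiguously by
#' decreasing cluster size.
#'
#' @param embedding an `embedding` (or a cells x dims matrix).
#' @param k_neighbors neighbors for the KNN graph.
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed (Louvain visits vertices in random order).
#' @return list of class `cluster_assignment`: `labels` (named integer),
#'   `resolution`, `mean_silhouette` (NA until scored), `silhouette_trace`.
#' @export
louvain_cluster <- function(embedding, k_neighbors = 20, resolution = 0.8,
                            seed = 1L) {
  coords <- if (inherits(embedding, "embedding")) embedding$coords
            else as.matrix(embedding)
  assert_that(k_neighbors < nrow(coords),
              "need more cells than k_neighbors")
  g <- snn_graph(coords, k_neighbors)
  cl <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  labels <- igraph::membership(cl)
  sizes <- sort(table(labels), decreasing = TRUE)
  relab <- setNames(seq_along(sizes), names(sizes))
  labels <- as.integer(relab[as.character(labels)])
  names(labels) <- rownames(coords)
  structure(list(labels = labels, resolution = resolution,
                 mean_silhouette = NA_real_, silhouette_trace = NULL),
            class = "cluster_assignment")
}

#' Mean silhouette with correlation distance
#'
#' Silhouette width with dissimilarity `1 - Pearson r` between cells' PC
#' coordinate vectors. Singleton clusters score 0 (the standard convention).
#'
#' @param embedding an `embedding` or cells x dims matrix.
#' @param labels integer cluster labels (>= 2 distinct values).
#' @return mean silhouette width (scalar).
#' @export
silhouette_correlation <- function(embedding, labels) {
  coords <- if (inherits(embedding, "embedding")) embedding$coords
            else as.matrix(embedding)
  labels <- as.integer(labels)
  assert_that(length(unique(labels)) >= 2,
              "silhouette undefined for a single cluster")
  d <- stats::as.dist(1 - cor(t(coords)))
  sil <- cluster::silhouette(labels, d)
  mean(sil[, "sil_width"])
}

#' Silhouette-optimized Louvain resolution selection
#'
#' For each resolution in `grid`, clusters all cells, then scores the
#' induced partition by the mean correlation-distance silhouette over
#' `n_repeats` random cell subsamples. The resolution maximizing the mean
#' silhouette is selected (ties go to the smaller resolution) and its
#' full-data clustering is returned with the complete trace.
#'
#' @param embedding an `embedding`.
#' @param grid resolutions to scan, within [0.01, 1.0].
#' @param n_repeats random subsamples per resolution (default 100).
#' @param subsample cells per subsample (default min(500, n_cells)).
#' @param k_neighbors KNN parameter passed to [louvain_cluster()].
#' @param seed integer seed.
#' @return a `cluster_assignment` with `silhouette_trace` (data.frame:
#'   resolution, n_clusters, mean_sil, sd_sil) and `mean_silhouette` set.
#' @export
optimize_resolution <- function(embedding,
                                grid = seq(0.01, 1.0, length.out = 25),
                                n_repeats = 100, subsample = NULL,
                                k_neighbors = 20, seed = 1L) {
  assert_that(all(grid >= 0.01 - 1e-12 & grid <= 1.0 + 1e-12),
              "grid must lie within [0.01, 1.0]")
  coords <- embedding$coords
  n <- nrow(coords)
  subsample <- subsample %||% min(500L, n)
  if (subsample < 50) warning("subsample < 50: silhouette will be unstable")
  subsample <- min(subsample, n)
  sub_idx <- with_seed(derive_seed(seed, 1L), replicate(
    n_repeats, sample.int(n, subsample), simplify = FALSE))
  fits <- lapply(seq_along(grid), function(i)
    louvain_cluster(embedding, k_neighbors, grid[i],
                    seed = derive_seed(seed, 100L + i)))
  trace <- do.call(rbind, lapply(seq_along(grid), function(i) {
    lab <- fits[[i]]$labels
    if (length(unique(lab)) < 2)
      return(data.frame(resolution = grid[i], n_clusters = 1L,
                        mean_sil = NA_real_, sd_sil = NA_real_))
    sils <- vapply(sub_idx, function(ix) {
      l <- lab[ix]
      if (length(unique(l)) < 2) return(NA_real_)
      silhouette_correlation(coords[ix, , drop = FALSE], l)
    }, numeric(1))
    data.frame(resolution = grid[i], n_clusters = length(unique(lab)),
               mean_sil = mean(sils, na.rm = TRUE),
               sd_sil = sd(sils, na.rm = TRUE))
  }))
  score <- ifelse(is.na(trace$mean_sil), -Inf, trace$mean_sil)
  best <- which(score == max(score))[1L]  # ties -> smaller resolution
  out <- fits[[best]]
  out$mean_silhouette <- trace$mean_sil[best]
  out$silhouette_trace <- trace
  out
}

# Vectorized one-vs-rest Wilcoxon rank-sum with normal approximation and
# tie correction, computed from per-gene ranks over all cells.
rank_sum_test <- function(values, in_group) {
  n <- ncol(values)
  n1 <- sum(in_group); n2 <- n - n1
  rk <- t(apply(values, 1L, rank))
  r1 <- rowSums(rk[, in_group, drop = FALSE])
  u <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tie_term <- apply(values, 1L, function(x) {
    tt <- table(x); sum(tt^3 - tt)
  })
  sig2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  sig2[sig2 <= 0] <- NA
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
  p <- 2 * pnorm(-abs(z))
  p[is.na(p)] <- 1
  list(p = p, z = z)
}

#' Cluster marker genes by one-vs-rest rank-sum test
#'
#' For each cluster and gene, a two-sided Wilcoxon rank-sum test of the
#' cluster's cells against all others on the normalized values, with
#' Bonferroni correction over genes x clusters. Log fold changes are
#' computed on depth-normalized counts: `log2(mean_in + eps) -
#' log2(mean_out + eps)`, eps = 1e-9.
#'
#' @param norm a `normalized_matrix` (its `values` feed the test) or a
#'   genes x cells matrix.
#' @param labels per-cell integer cluster labels (or `cluster_assignment`).
#' @param counts optional raw counts for the fold-change column; when
#'   omitted the normalized values are used.
#' @return data.frame: cluster, gene, logFC, p, p_adj_bonferroni, pct_in,
#'   pct_out.
#' @export
find_markers <- function(norm, labels, counts = NULL) {
  values <- if (inherits(norm, "normalized_matrix")) norm$values
            else as.matrix(norm)
  if (inherits(labels, "cluster_assignment")) labels <- labels$labels
  labels <- as.integer(labels)
  cl <- sort(unique(labels))
  assert_that(length(cl) >= 2, "need at least 2 clusters")
  expr <- if (!is.null(counts)) {
    cm <- as.matrix(counts)
    t(t(cm) / pmax(colSums(cm), 1)) * 1e6
  } else values
  eps <- 1e-9
  out <- list()
  for (k in cl) {
    ing <- labels == k
    if (sum(ing) < 2) {
      warning("cluster ", k, " has fewer than 2 cells; skipped")
      next
    }
    ts <- rank_sum_test(values, ing)
    m_in <- rowMeans(expr[, ing, drop = FALSE])
    m_out <- rowMeans(expr[, !ing, drop = FALSE])
    # ratio of depth-normalized means; on already-log-scale input (which
    # can be negative) fall back to the difference of means
    lfc <- if (min(expr) < 0) m_in - m_out
           else log2(m_in + eps) - log2(m_out + eps)
    out[[length(out) + 1L]] <- data.frame(
      cluster = k, gene = rownames(values),
      logFC = lfc,
      p = ts$p,
      pct_in = rowMeans(expr[, ing, drop = FALSE] > 0),
      pct_out = rowMeans(expr[, !ing, drop = FALSE] > 0),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$p_adj_bonferroni <- pmin(1, res$p * nrow(res))
  res[order(res$cluster, res$p, -res$logFC),
      c("cluster", "gene", "logFC", "p", "p_adj_bonferroni",
        "pct_in", "pct_out")]
}

#' Top markers per cluster
#'
#' @param markers output of [find_markers()].
#' @param n markers per cluster (default 50, ranked by p then logFC).
#' @param positive_only keep only positive-logFC markers.
#' @return named list of gene vectors, one per cluster.
#' @export
top_markers <- function(markers, n = 50, positive_only = TRUE) {
  if (positive_only) markers <- markers[markers$logFC > 0, , drop = FALSE]
  split(markers$gene, markers$cluster) |>
    lapply(function(g) head(g, n))
}

#' Over-representation analysis against gene-set collections
#'
#' Hypergeometric upper-tail test of a gene list against each set, with
#' Bonferroni correction across sets.
#'
#' @param gene_list character vector (must be a subset of `universe`).
#' @param gene_sets named list of gene vectors (e.g. from [read_gmt()]).
#' @param universe background gene identifiers.
#' @return data.frame: set, overlap, set_size, p_hypergeometric,
#'   p_adj_bonferroni.
#' @export
ora_enrichment <- function(gene_list, gene_sets, universe) {
  universe <- unique(universe)
  assert_that(length(universe) > 0, "empty universe")
  assert_that(all(gene_list %in% universe),
              "gene_list must be a subset of the universe")
  gene_list <- unique(gene_list)
  n_u <- length(universe)
  n_l <- length(gene_list)
  rows <- lapply(names(gene_sets), function(s) {
    set <- intersect(unique(gene_sets[[s]]), universe)
    k <- length(intersect(gene_list, set))
    p <- phyper(k - 1, length(set), n_u - length(set), n_l,
                lower.tail = FALSE)
    data.frame(set = s, overlap = k, set_size = length(set),
               p_hypergeometric = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj_bonferroni <- pmin(1, res$p_hypergeometric * nrow(res))
  res[order(res$p_hypergeometric), ]
}
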