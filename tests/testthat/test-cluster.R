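test_that("PCA is deterministic and reports rank through explained variance", {
  with_seed <- scactivity:::with_seed
  # rank-2 data: components beyond 2 explain (numerically) nothing
  g <- with_seed(5, {
    scores <- matrix(rnorm(60), 30, 2)
    load <- matrix(rnorm(16), 2, 8)
    m <- t(scores %*% load) + 0  # 8 genes x 30 cells
    dimnames(m) <- list(paste0("G", 1:8), paste0("c", 1:30))
    m
  })
  emb <- run_pca(g, n_pcs = 5)
  expect_lt(sum(emb$explained_variance[3:5]), 1e-10)
  emb2 <- run_pca(g, n_pcs = 5)
  expect_identical(emb$coords, emb2$coords)
  expect_error(run_pca(g, n_pcs = 0), "n_pcs")
})

test_that("PCA separates planted clusters", {
  fx <- fx_sc()
  coords <- fx$emb$coords[, 1:4]
  lab <- fx$truth_lab
  cents <- do.call(rbind, lapply(1:5, function(k)
    colMeans(coords[lab == k, , drop = FALSE])))
  within_sd <- mean(vapply(1:5, function(k)
    mean(apply(coords[lab == k, , drop = FALSE], 2, sd)), numeric(1)))
  dmin <- min(dist(cents))
  expect_gt(dmin, within_sd)
})

test_that("Louvain recovers well-separated blobs regardless of seed", {
  b <- fx_blobs()
  cl <- louvain_cluster(b$coords, k_neighbors = 15, resolution = 0.1,
                        seed = 1)
  expect_equal(length(unique(cl$labels)), 2)
  expect_equal(ari(cl$labels, b$labels), 1)

  cl2 <- louvain_cluster(b$coords, k_neighbors = 15, resolution = 0.1,
                         seed = 99)
  expect_equal(ari(cl$labels, cl2$labels), 1)

  # cluster count does not decrease when resolution grows on this fixture
  cl_hi <- louvain_cluster(b$coords, k_neighbors = 15, resolution = 1.0,
                           seed = 1)
  expect_gte(length(unique(cl_hi$labels)), length(unique(cl$labels)))

  expect_error(louvain_cluster(b$coords[1:5, ], k_neighbors = 15, 0.1),
               "k_neighbors")
})

test_that("correlation-distance silhouette behaves across label quality", {
  b <- fx_blobs(n_per = 250)
  s_true <- silhouette_correlation(b$coords, b$labels)
  expect_gt(s_true, 0.9)

  rnd <- scactivity:::with_seed(8, sample(b$labels))
  expect_lt(abs(silhouette_correlation(b$coords, rnd)), 0.1)

  # cross-assigning half of each blob puts every cell marginally closer to
  # the opposite cluster than to its own
  lab_swap <- b$labels
  lab_swap[c(1:125, 251:375)] <- 3 - lab_swap[c(1:125, 251:375)]
  expect_lt(silhouette_correlation(b$coords, lab_swap), 0)

  expect_error(silhouette_correlation(b$coords, rep(1, 500)), "single")

  # correlation distance ignores positive affine rescaling of each cell
  scale_f <- scactivity:::with_seed(12, runif(500, 0.5, 3))
  shift <- scactivity:::with_seed(13, rnorm(500))
  rescaled <- b$coords * scale_f + shift
  expect_equal(silhouette_correlation(rescaled, b$labels), s_true,
               tolerance = 1e-10)
})

test_that("resolution optimization is reproducible and recovers blobs", {
  b <- fx_blobs()
  emb <- structure(list(coords = b$coords), class = "embedding")
  # default grid and repeat count follow the stated protocol
  expect_equal(range(eval(formals(optimize_resolution)$grid)), c(0.01, 1.0))
  expect_equal(eval(formals(optimize_resolution)$n_repeats), 100)

  grid <- seq(0.01, 1, length.out = 5)
  o1 <- suppressWarnings(optimize_resolution(emb, grid, n_repeats = 10,
                                             subsample = 100,
                                             k_neighbors = 15, seed = 4))
  o2 <- suppressWarnings(optimize_resolution(emb, grid, n_repeats = 10,
                                             subsample = 100,
                                             k_neighbors = 15, seed = 4))
  expect_identical(o1$labels, o2$labels)
  expect_identical(o1$resolution, o2$resolution)
  expect_equal(ari(o1$labels, b$labels), 1)
  expect_equal(nrow(o1$silhouette_trace), 5)
})

test_that("marker detection finds an exclusive gene and controls the null", {
  with_seed <- scactivity:::with_seed
  vals <- with_seed(10, {
    m <- matrix(rnorm(1001 * 120), 1001, 120)
    m[1001, 61:120] <- m[1001, 61:120] + 4  # exclusive to cluster 2
    dimnames(m) <- list(c(sprintf("N%04d", 1:1000), "MARKER"),
                        sprintf("c%03d", 1:120))
    m
  })
  labels <- rep(1:2, each = 60)
  mk <- find_markers(vals, labels)
  top2 <- mk[mk$cluster == 2, ][1, ]
  expect_equal(top2$gene, "MARKER")
  expect_lt(top2$p_adj_bonferroni, 0.05)
  expect_gt(top2$logFC, 0)

  # Bonferroni is exactly min(1, p * n_tests)
  expect_equal(mk$p_adj_bonferroni, pmin(1, mk$p * nrow(mk)))

  # null genes: FPR at alpha = 0.05 and KS uniformity
  null_p <- mk$p[mk$cluster == 1 & mk$gene != "MARKER"]
  expect_lte(mean(null_p < 0.05), 0.07)
  expect_gt(suppressWarnings(ks.test(null_p, "punif"))$p.value, 0.01)
})

test_that("single-member clusters are skipped with a warning", {
  vals <- matrix(rnorm(50 * 21), 50, 21,
                 dimnames = list(paste0("G", 1:50), paste0("c", 1:21)))
  labels <- c(rep(1, 10), rep(2, 10), 3)
  expect_warning(mk <- find_markers(vals, labels), "skipped")
  expect_false(3 %in% mk$cluster)
})

test_that("over-representation matches the closed-form hypergeometric", {
  universe <- paste0("G", 1:100)
  set <- paste0("G", 1:8)
  res <- ora_enrichment(set, list(exact = set), universe)
  expect_equal(res$p_hypergeometric, 1 / choose(100, 8))

  disj <- ora_enrichment(paste0("G", 1:5), list(other = paste0("G", 90:95)),
                         universe)
  expect_gte(disj$p_hypergeometric, 0.5)

  expect_error(ora_enrichment("NOT_THERE", list(s = set), universe),
               "subset")
  # marker lists default to the top 50 per cluster
  expect_equal(eval(formals(top_markers)$n), 50)
})
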