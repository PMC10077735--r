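with_seed <- scactivity:::with_seed

# Brute-force DPI oracle: enumerate all triangles explicitly.
dpi_oracle <- function(edges, tolerance = 0) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  mi <- setNames(edges$mi, key(edges$a, edges$b))
  nodes <- unique(c(edges$a, edges$b))
  drop <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    a <- edges$a[e]; c_ <- edges$b[e]
    for (b in nodes) {
      if (b == a || b == c_) next
      m1 <- mi[key(a, b)]; m2 <- mi[key(b, c_)]
      if (is.na(m1) || is.na(m2)) next
      if (edges$mi[e] < min(m1, m2) * (1 - tolerance)) drop[e] <- TRUE
    }
  }
  edges[!drop, , drop = FALSE]
}

random_graph <- function(n_nodes = 20, p_edge = 0.25, seed = 1) {
  with_seed(seed, {
    pairs <- t(combn(n_nodes, 2))
    sel <- runif(nrow(pairs)) < p_edge
    data.frame(a = paste0("n", pairs[sel, 1]),
               b = paste0("n", pairs[sel, 2]),
               mi = runif(sum(sel), 0.1, 2))
  })
}

test_that("metacell pooling conserves counts and respects the min rule", {
  fx <- fx_sc()
  sub <- fx$filtered[, 1:60]
  emb_sub <- structure(list(coords = fx$emb$coords[1:60, ]),
                       class = "embedding")
  labels <- fx$truth_lab[1:60]
  meta <- pool_metacells(sub, labels, emb_sub, n_meta = 20, k = 5, seed = 2)
  # exact conservation: pooled raw vector = sum of member columns
  for (i in seq_len(ncol(meta$raw))) {
    expect_equal(unname(meta$raw[, i]),
                 unname(rowSums(as.matrix(sub[, meta$members[[i]],
                                              drop = FALSE]))))
    expect_true(all(labels[meta$members[[i]]] == meta$origin_cluster[i]))
  }
  # log2 CPM renormalization
  expect_equal(unname(colSums(2^meta$values - 1)),
               rep(1e6, ncol(meta$values)), tolerance = 1e-6)

  # min(n_meta, cluster size): a 5-cell cluster yields 5 metacells
  tiny_lab <- c(rep(1, 5), rep(2, 55))
  meta2 <- pool_metacells(sub, tiny_lab, emb_sub, n_meta = 250, k = 3,
                          seed = 2)
  expect_equal(sum(meta2$origin_cluster == 1), 5)
  expect_equal(eval(formals(pool_metacells)$n_meta), 250)

  # k = 1 pools the seed cell alone
  meta3 <- pool_metacells(sub, labels, emb_sub, n_meta = 10, k = 1, seed = 4)
  for (i in seq_len(ncol(meta3$raw)))
    expect_equal(unname(meta3$raw[, i]),
                 unname(as.matrix(sub)[, meta3$members[[i]]]))
})

test_that("mutual information estimator separates dependence from noise", {
  x <- with_seed(31, rnorm(500))
  y_ind <- with_seed(32, rnorm(500))
  mi_ind <- estimate_mi(x, y_ind)
  null_dist <- vapply(1:200, function(i)
    estimate_mi(x, with_seed(100 + i, sample(y_ind)), seed = i), numeric(1))
  expect_lt(mi_ind, quantile(null_dist, 0.95) + 0.02)

  # perfect dependence: adaptive estimate within 10% of the binned oracle
  # (bins sized to ~5 points per marginal bin, the adaptive leaf scale)
  mi_dep <- estimate_mi(x, x)
  mi_oracle <- estimate_mi(x, x, method = "equal_freq_bins", n_bins = 100)
  expect_lt(abs(mi_dep - mi_oracle) / mi_oracle, 0.10)

  # rank symmetry: y = -x carries the same MI as y = x
  expect_equal(estimate_mi(x, -x), mi_dep, tolerance = 1e-6)

  # invariance under strictly monotone transforms (rank-based estimator)
  xp <- abs(x) + 1
  expect_equal(estimate_mi(log(xp), x), estimate_mi(xp, x),
               tolerance = 1e-6)
  expect_equal(estimate_mi(exp(x), x), estimate_mi(x, x), tolerance = 1e-6)

  expect_warning(mi0 <- estimate_mi(rep(1, length(x)), x), "constant")
  expect_equal(mi0, 0)

  # non-negativity over random pairs
  for (i in 1:10) {
    a <- with_seed(200 + i, rnorm(64))
    b <- with_seed(300 + i, rnorm(64))
    expect_gte(estimate_mi(a, b, seed = i), 0)
  }
})

test_that("MI null threshold is calibrated and monotone", {
  vals <- with_seed(41, matrix(rnorm(200 * 300), 200, 300,
                               dimnames = list(sprintf("G%03d", 1:200),
                                               NULL)))
  thr_med <- mi_null_threshold(vals, n_null_pairs = 600, p_threshold = 0.5,
                               seed = 3)
  null_mi <- attr(thr_med, "null_mi")
  med <- median(null_mi)
  expect_lte(abs(as.numeric(thr_med) - med), max(0.1 * med, 0.005))

  thrs <- vapply(c(1e-2, 1e-4, 1e-8), function(p)
    as.numeric(mi_null_threshold(vals, n_null_pairs = 600, p_threshold = p,
                                 seed = 3)), numeric(1))
  expect_true(all(diff(thrs) > 0))  # smaller p -> larger threshold

  # calibration: on independent data the edge count at p = 1e-3 stays in
  # the Poisson band of n_pairs * p
  thr <- as.numeric(mi_null_threshold(vals, n_null_pairs = 1000,
                                      p_threshold = 1e-3, seed = 5))
  n_pairs <- 4000
  hits <- with_seed(6, sum(vapply(seq_len(n_pairs), function(i) {
    a <- rnorm(300); b <- rnorm(300)
    scactivity:::.ap_mi_pair(rank(a, ties.method = "first"),
                             rank(b, ties.method = "first")) >= thr
  }, logical(1))))
  lam <- n_pairs * 1e-3
  expect_gte(hits, qpois(0.025, lam))
  expect_lte(hits, qpois(0.975, lam))
})

test_that("DPI matches exhaustive triangle enumeration", {
  tri <- data.frame(a = c("x", "y", "x"), b = c("y", "z", "z"),
                    mi = c(3, 2, 1))
  pruned <- apply_dpi(tri)
  expect_equal(nrow(pruned), 2)
  expect_false(any(pruned$mi == 1))

  chain <- data.frame(a = c("x", "y"), b = c("y", "z"), mi = c(2, 1))
  expect_equal(apply_dpi(chain), chain)

  for (s in 1:10) {
    g <- random_graph(seed = s)
    got <- apply_dpi(g)
    want <- dpi_oracle(g)
    expect_equal(got, want, info = paste("graph seed", s))
    # subset + idempotence properties
    expect_true(all(rownames(got) %in% rownames(g)))
    expect_equal(apply_dpi(got), got)
  }
})

test_that("bootstrap consensus holds its contracts on small planted data", {
  expect_equal(eval(formals(bootstrap_consensus_network)$n_boot), 100)
  # direct latent-activity data: 8 regulators driving 12 targets each
  net <- generate_truth_network(150, 8, 12, pos_fraction = 0.8, seed = 21)
  act <- matrix(0, 8, 1, dimnames = list(net$regulators, "c1"))
  sim <- simulate_sc_counts(net, act, 500, activity_noise_sd = 1.2,
                            seed = 22)
  cpm <- t(t(as.matrix(sim$counts)) /
             Matrix::colSums(sim$counts)) * 1e6
  vals <- log2(cpm + 1)
  nw <- bootstrap_consensus_network(vals, net$regulators, n_boot = 30,
                                    seed = 23)
  f1 <- edge_f1(nw$edges, net$edges)
  expect_gt(f1, 0.6)

  # fewer than 10 metacells is refused
  expect_error(bootstrap_consensus_network(vals[, 1:5], net$regulators),
               "fewer than 10")

  regs <- build_regulons(nw, vals, max_targets = 12, min_targets = 5)
  expect_gt(length(regs), 4)
  for (r in regs) {
    expect_equal(max(r$likelihood), 1)
    expect_false(r$regulator %in% r$targets)
    expect_false(any(duplicated(r$targets)))
    expect_lte(length(r$targets), 12)
  }
  # tfmode sign recovery on recovered true edges
  ok <- 0; tot <- 0
  for (r in names(regs)) {
    e <- net$edges[net$edges$regulator == r, ]
    m <- match(regs[[r]]$targets, e$target)
    sel <- !is.na(m)
    ok <- ok + sum(sign(regs[[r]]$tfmode[sel]) == e$sign[m[sel]])
    tot <- tot + sum(sel)
  }
  expect_gt(ok / tot, 0.9)
  expect_equal(eval(formals(build_regulons)$min_targets), 25)
})

test_that("consensus edge set shrinks as the MI p-threshold tightens", {
  net <- generate_truth_network(100, 5, 10, seed = 31)
  act <- matrix(0, 5, 1, dimnames = list(net$regulators, "c1"))
  sim <- simulate_sc_counts(net, act, 150, activity_noise_sd = 1, seed = 32)
  vals <- log2(t(t(as.matrix(sim$counts)) /
                   Matrix::colSums(sim$counts)) * 1e6 + 1)
  n_loose <- nrow(bootstrap_consensus_network(
    vals, net$regulators, n_boot = 10, p_threshold = 1e-3, seed = 5)$edges)
  n_tight <- nrow(bootstrap_consensus_network(
    vals, net$regulators, n_boot = 10, p_threshold = 1e-10, seed = 5)$edges)
  expect_lte(n_tight, n_loose)
})
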