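with_seed <- scactivity:::with_seed

random_signature <- function(n_genes = 2000, n_cells = 1, seed = 1) {
  with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_cells), n_genes, n_cells,
                dimnames = list(sprintf("g%05d", seq_len(n_genes)),
                                sprintf("c%03d", seq_len(n_cells))))
    m
  })
}

random_regulon <- function(genes, n, seed, uniform = TRUE) {
  with_seed(seed, list(
    regulator = "R", targets = sample(genes, n),
    tfmode = sample(c(-1, 1), n, replace = TRUE),
    likelihood = if (uniform) rep(1, n) else runif(n, 0.2, 1)))
}

test_that("signatures are internally referenced z-scores", {
  x <- rbind(g1 = c(1, 1), g2 = c(2, 5), g3 = c(2, 3))
  colnames(x) <- c("a", "b")
  s <- compute_signatures(x)
  expect_equal(unname(s["g1", ]), c(0, 0))  # constant gene
  expect_true(all(abs(rowMeans(s)) < 1e-6))

  same <- matrix(rep(1:5, 2), 5, 2,
                 dimnames = list(paste0("g", 1:5), c("a", "b")))
  expect_true(all(compute_signatures(same) == 0))

  expect_error(compute_signatures(matrix(1:3, 3, 1)), "2 cells")

  # planted targets of an active regulator carry positive signatures
  fx <- fx_sc()
  cpm <- t(t(as.matrix(fx$filtered)) / colSums(as.matrix(fx$filtered))) * 1e6
  sig <- compute_signatures(log2(cpm + 1))
  r1 <- fx$net$regulators[1]  # active in cluster 1
  e <- fx$net$edges[fx$net$edges$regulator == r1 & fx$net$edges$sign == 1, ]
  in1 <- fx$truth_lab == 1
  expect_gt(mean(sig[e$target, in1]), 0)
})

test_that("aREA NES matches its permutation null z-score", {
  sig <- random_signature(2000, seed = 5)
  q <- scactivity:::area_quantiles(sig)
  dmax <- 0
  for (i in 1:5) {
    n <- 25 + 5 * i
    reg <- random_regulon(rownames(sig), n, seed = 10 + i)
    nes <- area_nes(sig[, 1], reg, min_targets = 10)
    idx0 <- match(reg$targets, rownames(sig))
    w <- rep(1 / n, n)
    es_of <- function(idx) sum(w * reg$tfmode * q$q1[idx, 1] +
                                 w * (1 - abs(reg$tfmode)) * q$q2[idx, 1])
    es0 <- es_of(idx0)
    null_es <- with_seed(50 + i,
                         replicate(5000, es_of(sample(nrow(sig), n))))
    z_perm <- (es0 - mean(null_es)) / sd(null_es)
    dmax <- max(dmax, abs(z_perm - nes))
  }
  expect_lte(dmax, 0.15)
})

test_that("aREA null NES is standard normal and sign-antisymmetric", {
  sig <- random_signature(2000, seed = 6)
  nes_null <- vapply(1:1000, function(i)
    area_nes(sig[, 1], random_regulon(rownames(sig), 30, seed = 1000 + i),
             min_targets = 10), numeric(1))
  expect_lt(abs(mean(nes_null)), 0.1)
  expect_lt(abs(sd(nes_null) - 1), 0.1)

  reg <- random_regulon(rownames(sig), 40, seed = 3)
  reg_pos <- reg; reg_pos$tfmode <- rep(1, 40)
  reg_neg <- reg; reg_neg$tfmode <- rep(-1, 40)
  n1 <- area_nes(sig[, 1], reg_pos, min_targets = 10)
  n2 <- area_nes(sig[, 1], reg_neg, min_targets = 10)
  expect_equal(n2, -n1)

  # negating the whole signature negates the NES exactly
  expect_equal(area_nes(-sig[, 1], reg, min_targets = 10),
               -area_nes(sig[, 1], reg, min_targets = 10))

  # a regulon whose +1 targets own the top ranks scores far in the right tail
  ord <- order(-sig[, 1])
  top <- rownames(sig)[ord[1:30]]
  reg_top <- list(regulator = "R", targets = top, tfmode = rep(1, 30),
                  likelihood = rep(1, 30))
  expect_gt(area_nes(sig[, 1], reg_top, min_targets = 10), 3)
})

test_that("metaVIPER integration obeys its closed forms", {
  sig <- random_signature(1500, 4, seed = 8)
  regs <- setNames(lapply(1:6, function(i)
    random_regulon(rownames(sig), 30, seed = 20 + i)), paste0("P", 1:6))
  single <- viper_activity(sig, regs, min_targets = 10)
  mv1 <- metaviper_activity(sig, list(net1 = regs), min_targets = 10)
  expect_equal(mv1$values, single)

  # two networks with identical regulons: integrated NES = x * sqrt(2)
  mv2 <- metaviper_activity(sig, list(net1 = regs, net2 = regs),
                            min_targets = 10)
  expect_equal(mv2$values, single * sqrt(2))

  # order invariance
  mv2r <- metaviper_activity(sig, list(net2 = regs, net1 = regs),
                             min_targets = 10)
  expect_equal(mv2$values, mv2r$values)

  # a protein carried by no network is absent
  expect_false("NOT_A_PROTEIN" %in% rownames(mv2$values))
})

test_that("bootstrapped-t master regulators are calibrated and rank truth", {
  expect_equal(eval(formals(master_regulators)$n_boot), 100)
  # null: activity independent of labels -> FPR within [0.02, 0.08]
  act <- with_seed(30, matrix(rnorm(500 * 100), 500, 100,
                              dimnames = list(sprintf("P%03d", 1:500),
                                              sprintf("c%03d", 1:100))))
  labels <- rep(1:2, each = 50)
  mr <- master_regulators(act, labels, n_boot = 100, seed = 4)
  fpr <- mean(mr$p[mr$cluster == 1] < 0.05)
  expect_gte(fpr, 0.02)
  expect_lte(fpr, 0.08)

  # within-cluster ranks are a permutation ordered by decreasing stouffer_z
  sub <- mr[mr$cluster == 1, ]
  expect_equal(sort(sub$rank), seq_len(nrow(sub)))
  expect_true(all(diff(sub$stouffer_z[order(sub$rank)]) <= 1e-12))

  # planted signal: a protein elevated in one cluster tops its MR list
  act2 <- act[1:50, ]
  act2["P001", labels == 2] <- act2["P001", labels == 2] + 2
  mr2 <- master_regulators(act2, labels, n_boot = 100, seed = 5)
  r <- mr2$rank[mr2$cluster == 2 & mr2$protein == "P001"]
  expect_lte(r, 10)

  expect_warning(master_regulators(act[, 1:53], c(rep(1, 50), rep(2, 3), 2)[1:53],
                                   n_boot = 10, seed = 1),
                 regexp = NA)  # 3-cell cluster is still allowed
  expect_warning(
    master_regulators(act[, 1:52], c(rep(1, 50), 2, 2), n_boot = 10,
                      seed = 1), "skipped")
})

test_that("activity-space clustering separates planted programs", {
  fx <- fx_sc()
  cpm <- t(t(as.matrix(fx$filtered)) / colSums(as.matrix(fx$filtered))) * 1e6
  sig <- compute_signatures(log2(cpm + 1))
  act <- metaviper_activity(sig, list(truth = truth_regulons(fx$net)))
  emb <- run_pca(compute_signatures(act$values),
                 n_pcs = min(20, nrow(act$values) - 1))
  cl <- louvain_cluster(emb, k_neighbors = 20, resolution = 0.3, seed = 2)
  expect_gte(ari(cl$labels, fx$truth_lab), 0.8)
})
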