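#' Generate a planted regulatory network
#'
#' Builds a ground-truth regulatory network over a synthetic gene universe.
#' The first 20 gene identifiers are reserved as a mitochondrial block
#' (`MT-1` ... `MT-20`, following 10x naming conventions) so that per-cell
#' mitochondrial fractions are computable by name downstream. Regulators are
#' drawn from the non-mitochondrial genes; each receives `regulon_size`
#' distinct targets drawn from the remaining non-regulator genes, a
#' regulation sign (+1 with probability `pos_fraction`), and a coupling
#' strength.
#'
#' @param n_genes total number of genes in the universe.
#' @param n_regulators number of regulator genes.
#' @param regulon_size targets per regulator.
#' @param pos_fraction expected fraction of positive-sign edges, in [0, 1].
#' @param seed integer seed; the network is deterministic given the seed.
#' @param strength_range range of uniform coupling strengths per edge.
#' @return An object of class `truth_network`: list with `genes`,
#'   `regulators`, `edges` (data.frame regulator/target/sign/strength),
#'   `regulon_size`, `n_genes`.
#' @export
generate_truth_network <- function(n_genes, n_regulators, regulon_size,
                                   pos_fraction = 0.7, seed = 1L,
                                   strength_range = c(0.8, 1.2)) {
  assert_that(n_regulators <= n_genes,
              "n_regulators must not exceed n_genes")
  assert_that(pos_fraction >= 0 && pos_fraction <= 1,
              "pos_fraction must lie in [0, 1]")
  n_mito <- if (n_genes > 40) 20L else 0L
  genes <- c(if (n_mito > 0) paste0("MT-", seq_len(n_mito)),
             sprintf("G%05d", seq_len(n_genes - n_mito)))
  pool <- genes[(n_mito + 1L):n_genes]
  assert_that(n_regulators <= length(pool),
              "too many regulators for the non-mitochondrial gene pool")
  with_seed(seed, {
    regulators <- sort(sample(pool, n_regulators))
    target_pool <- setdiff(pool, regulators)
    assert_that(regulon_size <= length(target_pool),
                "regulon_size exceeds the available target pool")
    edges <- do.call(rbind, lapply(regulators, function(r) {
      tg <- sample(target_pool, regulon_size)
      data.frame(regulator = r, target = tg,
                 sign = ifelse(rbinom(regulon_size, 1L, pos_fraction) == 1L,
                               1, -1),
                 strength = runif(regulon_size, strength_range[1],
                                  strength_range[2]),
                 stringsAsFactors = FALSE)
    }))
    structure(list(genes = genes, regulators = regulators, edges = edges,
                   regulon_size = regulon_size, n_genes = n_genes),
              class = "truth_network")
  })
}

#' Default planted cluster-activity design
#'
#' Assigns each regulator one "on" cluster (activity `level`, in log2 units
#' of target fold change per unit strength) cycling through clusters;
#' activity is 0 elsewhere. This gives every cluster a distinctive active
#' regulator program.
#'
#' @param network a `truth_network`.
#' @param n_clusters number of planted clusters.
#' @param level activity of a regulator in its "on" cluster (log2 units);
#'   for the gaussian design, the SD of the activity draw.
#' @param design `"one_hot"` (each regulator on in exactly one cluster;
#'   interpretable master-regulator structure) or `"gaussian"` (iid
#'   `N(0, level^2)` profiles; regulators mutually distinguishable, the
#'   preferred design for network-recovery studies).
#' @param seed seed for the gaussian design.
#' @return regulators x clusters numeric matrix of latent activities.
#' @export
make_cluster_activities <- function(network, n_clusters, level = 2,
                                    design = c("one_hot", "gaussian"),
                                    seed = 1L) {
  design <- match.arg(design)
  nr <- length(network$regulators)
  dn <- list(network$regulators, paste0("cluster", seq_len(n_clusters)))
  if (design == "gaussian")
    return(with_seed(seed, matrix(rnorm(nr * n_clusters, 0, level),
                                  nr, n_clusters, dimnames = dn)))
  a <- matrix(0, nr, n_clusters, dimnames = dn)
  for (p in seq_len(nr)) a[p, ((p - 1L) %% n_clusters) + 1L] <- level
  a
}

qc_violator_rules <- c("low_umi", "high_mito", "few_genes", "low_complexity")

#' Simulate single-cell UMI counts with planted regulatory structure
#'
#' Draws a per-cluster negative-binomial expression template in which each
#' target gene's log2 mean is `baseline + sum(sign * strength * activity)`
#' over its incoming edges and each regulator gene's log2 mean tracks its
#' own latent activity, then multinomially thins every cell's template to a
#' log-normal library size (so column sums equal the drawn library sizes
#' exactly). A designated mitochondrial gene block receives the requested
#' per-cell UMI fraction in expectation. Cells listed in `qc_violators` are
#' forced to violate the named quality-control rule.
#'
#' @param truth a `truth_network`.
#' @param activities regulators x clusters latent activity matrix.
#' @param cells_per_cluster integer vector (recycled) of cells per cluster.
#' @param lib_size_lognormal c(meanlog, sdlog) of the library-size law.
#' @param nb_dispersion negative-binomial dispersion of the template
#'   (variance = mu + dispersion * mu^2).
#' @param mito_fraction expected mitochondrial UMI fraction, scalar or
#'   per-cell.
#' @param qc_violators named list of cell indices per rule; rules are
#'   `low_umi`, `high_mito`, `few_genes`, `low_complexity`.
#' @param activity_noise_sd SD of per-cell latent activity jitter around
#'   the cluster activity (within-cluster regulator variation; makes
#'   regulators identifiable to network inference).
#' @param n_samples number of synthetic donors cells are assigned to.
#' @param baseline_log2 c(mean, sd) of per-gene baseline log2 expression.
#' @param seed integer seed.
#' @return list with `counts` (sparse genes x cells dgCMatrix),
#'   `cell_meta` (barcode, sample, group, true_cluster) and `truth`
#'   (a `truth_bundle`: network, cluster_activities, cell_labels, seed).
#' @export
simulate_sc_counts <- function(truth, activities, cells_per_cluster,
                               lib_size_lognormal = c(meanlog = log(2500),
                                                      sdlog = 0.12),
                               nb_dispersion = 0.1,
                               mito_fraction = 0.03,
                               qc_violators = NULL,
                               activity_noise_sd = 0.5,
                               n_samples = 3L,
                               baseline_log2 = c(mean = 3, sd = 0.6),
                               seed = 1L) {
  assert_that(inherits(truth, "truth_network"), "truth must be a truth_network")
  assert_that(nrow(activities) == length(truth$regulators),
              "activities rows must match regulators")
  n_clusters <- ncol(activities)
  cells_per_cluster <- rep_len(cells_per_cluster, n_clusters)
  assert_that(all(cells_per_cluster >= 1), "cells_per_cluster must be >= 1")
  if (!is.null(qc_violators)) {
    bad <- setdiff(names(qc_violators), qc_violator_rules)
    if (length(bad))
      stop("unknown QC violator rule(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  genes <- truth$genes
  ng <- length(genes)
  mito <- grepl("^MT-", genes)
  n_cells <- sum(cells_per_cluster)
  cluster_of <- rep(seq_len(n_clusters), cells_per_cluster)

  with_seed(seed, {
    base <- rnorm(ng, baseline_log2[1], baseline_log2[2])
    names(base) <- genes
    # gene x regulator coupling matrix: sign*strength for edges, identity
    # for each regulator's own transcript
    e <- truth$edges
    nr <- length(truth$regulators)
    coupling <- Matrix::sparseMatrix(
      i = c(match(e$target, genes), match(truth$regulators, genes)),
      j = c(match(e$regulator, truth$regulators), seq_len(nr)),
      x = c(e$sign * e$strength, rep(1, nr)), dims = c(ng, nr))
    size <- 1 / nb_dispersion

    lib <- pmax(1L, round(rlnorm(n_cells, lib_size_lognormal[1],
                                 lib_size_lognormal[2])))
    m_frac <- rep_len(mito_fraction, n_cells)
    support <- vector("list", n_cells)  # optional gene-support restriction

    vio <- function(rule) as.integer(qc_violators[[rule]] %||% integer(0))
    for (i in vio("low_umi")) lib[i] <- sample(200:999, 1L)
    for (i in vio("high_mito")) m_frac[i] <- runif(1, 0.08, 0.20)
    nonmito_genes <- which(!mito)
    for (i in vio("few_genes"))
      support[[i]] <- sample(nonmito_genes, 200L)
    for (i in vio("low_complexity"))
      support[[i]] <- sample(nonmito_genes, 420L)

    counts <- matrix(0L, ng, n_cells)
    for (c_i in seq_len(n_cells)) {
      k <- cluster_of[c_i]
      a_c <- activities[, k] + rnorm(nr, 0, activity_noise_sd)
      mu <- 2^(base + as.vector(coupling %*% a_c))
      x <- rnbinom(ng, mu = mu, size = size)
      if (!is.null(support[[c_i]]))
        x[setdiff(nonmito_genes, support[[c_i]])] <- 0L
      p <- numeric(ng)
      s_n <- sum(x[!mito]); s_m <- sum(x[mito])
      if (s_n == 0) x[!mito][1L] <- s_n <- 1L
      if (s_m == 0) x[mito][1L] <- s_m <- 1L
      p[!mito] <- (1 - m_frac[c_i]) * x[!mito] / s_n
      p[mito] <- m_frac[c_i] * x[mito] / s_m
      counts[, c_i] <- rmultinom(1L, lib[c_i], p)[, 1L]
    }
    barcodes <- sprintf("cell_%05d", seq_len(n_cells))
    dimnames(counts) <- list(genes, barcodes)
    sample_id <- paste0("S", sample.int(n_samples, n_cells, replace = TRUE))
    group <- ifelse(as.integer(sub("^S", "", sample_id)) <=
                      ceiling(n_samples / 2), "healthy", "disease")
    meta <- data.frame(barcode = barcodes, sample = sample_id, group = group,
                       true_cluster = cluster_of, stringsAsFactors = FALSE)
    bundle <- structure(list(network = truth,
                             cluster_activities = activities,
                             cell_labels = setNames(cluster_of, barcodes),
                             bulk_effects = NULL, seed = as.integer(seed)),
                        class = "truth_bundle")
    list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "CsparseMatrix"),
         cell_meta = meta, truth = bundle)
  })
}

#' Simulate a two-group bulk RNA-seq cohort with planted effects
#'
#' The disease group's per-gene log2 means are shifted by the planted
#' network response to the supplied regulator activity changes:
#' `sum(sign * strength * delta_a)` over incoming edges for targets, and
#' `delta_a` for the regulator gene itself. Counts are negative binomial
#' with per-sample library factors.
#'
#' @param truth a `truth_network`.
#' @param n_group1,n_group2 sample sizes of the control and disease groups.
#' @param bulk_effects named numeric vector: regulator -> activity change
#'   (log2 units) in the disease group.
#' @param dispersion NB dispersion.
#' @param baseline_log2 c(mean, sd) of per-gene baseline log2 means.
#' @param seed integer seed.
#' @return list with `counts` (genes x samples integer matrix), `groups`
#'   (factor, levels control/disease) and `truth_de` (named planted log2FC
#'   per gene).
#' @export
simulate_bulk_counts <- function(truth, n_group1 = 18L, n_group2 = 20L,
                                 bulk_effects = NULL, dispersion = 0.1,
                                 baseline_log2 = c(mean = 5, sd = 1.5),
                                 seed = 1L) {
  assert_that(n_group1 >= 2 && n_group2 >= 2, "group sizes must be >= 2")
  if (is.null(bulk_effects) || length(bulk_effects) == 0) {
    warning("empty bulk_effects: returning a null-signal cohort")
    bulk_effects <- numeric(0)
  }
  unknown <- setdiff(names(bulk_effects), truth$regulators)
  assert_that(length(unknown) == 0,
              "bulk_effects names must be planted regulators")
  genes <- truth$genes
  ng <- length(genes)
  with_seed(seed, {
    base <- rnorm(ng, baseline_log2[1], baseline_log2[2])
    names(base) <- genes
    truth_de <- setNames(numeric(ng), genes)
    if (length(bulk_effects)) {
      e <- truth$edges[truth$edges$regulator %in% names(bulk_effects), ,
                       drop = FALSE]
      if (nrow(e)) {
        d <- e$sign * e$strength * bulk_effects[e$regulator]
        sh <- tapply(d, e$target, sum)
        truth_de[names(sh)] <- sh
      }
      truth_de[names(bulk_effects)] <-
        truth_de[names(bulk_effects)] + bulk_effects
    }
    n <- n_group1 + n_group2
    groups <- factor(rep(c("control", "disease"), c(n_group1, n_group2)),
                     levels = c("control", "disease"))
    libf <- rlnorm(n, 0, 0.1)
    counts <- matrix(0L, ng, n,
                     dimnames = list(genes, sprintf("B%02d", seq_len(n))))
    for (j in seq_len(n)) {
      mu <- 2^(base + if (groups[j] == "disease") truth_de else 0) * libf[j]
      counts[, j] <- rnbinom(ng, mu = mu, size = 1 / dispersion)
    }
    list(counts = counts, groups = groups, truth_de = truth_de)
  })
}
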