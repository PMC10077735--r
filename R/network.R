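#' Pool cells into metacells by K nearest neighbors
#'
#' Per cluster, samples up to `n_meta` seed cells without replacement; each
#' metacell sums the raw counts of the seed's `k` nearest same-cluster
#' neighbors in PC space (seed included), mitigating dropout before network
#' inference. Pooled counts are re-normalized to log2(CPM + 1).
#'
#' @param counts raw genes x cells counts.
#' @param labels per-cell cluster labels (or `cluster_assignment`).
#' @param embedding an `embedding` on the same cells.
#' @param n_meta maximum metacells per cluster (default 250).
#' @param k cells pooled per metacell (default 10).
#' @param seed integer seed for seed-cell sampling.
#' @return list of class `metacell_matrix`: `values` (genes x metacells
#'   log2 CPM), `raw` (pooled counts), `origin_cluster`, `members`, `k`.
#' @export
pool_metacells <- function(counts, labels, embedding, n_meta = 250, k = 10,
                           seed = 1L) {
  if (inherits(labels, "cluster_assignment")) labels <- labels$labels
  coords <- if (inherits(embedding, "embedding")) embedding$coords
            else as.matrix(embedding)
  m <- as.matrix(counts)
  assert_that(ncol(m) == nrow(coords) && ncol(m) == length(labels),
              "counts, embedding and labels must cover the same cells")
  cl <- sort(unique(labels))
  pooled <- list(); origin <- integer(0); members <- list()
  with_seed(seed, {
    for (g in cl) {
      ix <- which(labels == g)
      if (length(ix) < 2) {
        warning("cluster ", g, " has < 2 cells; passing through as singleton")
        for (i in ix) {
          pooled[[length(pooled) + 1L]] <- m[, i]
          origin <- c(origin, g)
          members[[length(members) + 1L]] <- colnames(m)[i]
        }
        next
      }
      seeds <- sample(ix, min(n_meta, length(ix)))
      kk <- min(k, length(ix))
      d <- as.matrix(dist(coords[ix, , drop = FALSE]))
      for (s in seeds) {
        pos <- match(s, ix)
        nb <- ix[order(d[pos, ])[seq_len(kk)]]  # seed itself is distance 0
        pooled[[length(pooled) + 1L]] <-
          rowSums(m[, nb, drop = FALSE])
        origin <- c(origin, g)
        members[[length(members) + 1L]] <- colnames(m)[nb]
      }
    }
  })
  raw <- do.call(cbind, pooled)
  colnames(raw) <- sprintf("meta_%04d", seq_len(ncol(raw)))
  rownames(raw) <- rownames(m)
  cpm <- t(t(raw) / pmax(colSums(raw), 1)) * 1e6
  structure(list(values = log2(cpm + 1), raw = raw,
                 origin_cluster = origin, members = members, k = k),
            class = "metacell_matrix")
}

#' Mutual information between two vectors
#'
#' Rank-based adaptive-partitioning estimator (recursive quadrant splitting
#' accepted by a chi-square test at the 5% critical value on 1 df, since
#' the rank margins pin the quadrant table's row and column sums), in nats.
#' An equal-frequency binned plug-in estimator is provided as an
#' independent oracle variant. Ties are broken by deterministic seeded
#' jitter of magnitude 1e-9 times the vector's SD.
#'
#' @param x,y numeric vectors of equal length >= 8.
#' @param method `"adaptive_partition"` (default) or `"equal_freq_bins"`.
#' @param n_bins bins per axis for the binned variant (default
#'   `floor(sqrt(n/5))`, at least 2).
#' @param seed seed for tie-breaking jitter.
#' @return MI estimate in nats (>= 0).
#' @export
estimate_mi <- function(x, y, method = c("adaptive_partition",
                                         "equal_freq_bins"),
                        n_bins = NULL, seed = 1L) {
  method <- match.arg(method)
  n <- length(x)
  assert_that(length(y) == n && n >= 8, "need equal-length vectors, n >= 8")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: MI = 0")
    return(0)
  }
  xr <- jittered_ranks(x, seed)
  yr <- jittered_ranks(y, seed + 1L)
  if (method == "adaptive_partition")
    return(.ap_mi_pair(as.integer(xr), as.integer(yr)))
  b <- n_bins %||% max(2L, floor(sqrt(n / 5)))
  bx <- ceiling(xr / (n / b)); by <- ceiling(yr / (n / b))
  tab <- table(factor(bx, levels = 1:b), factor(by, levels = 1:b)) / n
  px <- rowSums(tab); py <- colSums(tab)
  mi <- 0
  for (i in 1:b) for (j in 1:b)
    if (tab[i, j] > 0) mi <- mi + tab[i, j] * log(tab[i, j] / (px[i] * py[j]))
  max(0, as.numeric(mi))
}

#' Null-calibrated mutual-information threshold
#'
#' Estimates the MI null distribution from permutation-decoupled expression
#' pairs, fits the right tail by exponential regression of -log(empirical
#' p) on MI, and returns the MI value at the requested p-value.
#'
#' @param metacells a `metacell_matrix` (or genes x samples matrix).
#' @param regulators regulator gene ids (null pairs pair regulators with
#'   random genes; falls back to random-random pairs).
#' @param n_null_pairs number of null pairs (>= 100).
#' @param p_threshold target tail probability (default 1e-8).
#' @param seed integer seed.
#' @return MI threshold in nats, with attribute `null_mi`.
#' @export
mi_null_threshold <- function(metacells, regulators = NULL,
                              n_null_pairs = 3000, p_threshold = 1e-8,
                              seed = 1L) {
  values <- if (inherits(metacells, "metacell_matrix")) metacells$values
            else as.matrix(metacells)
  assert_that(n_null_pairs >= 100, "need >= 100 null pairs for the tail fit")
  ng <- nrow(values); n <- ncol(values)
  ridx <- if (!is.null(regulators))
    match(intersect(regulators, rownames(values)), rownames(values))
  else seq_len(ng)
  null_mi <- with_seed(seed, {
    vapply(seq_len(n_null_pairs), function(i) {
      a <- values[sample(ridx, 1L), ]
      b <- values[sample.int(ng, 1L), sample.int(n)]
      if (sd(a) == 0 || sd(b) == 0) return(0)
      .ap_mi_pair(as.integer(jittered_ranks(a, seed + 2L * i)),
                  as.integer(jittered_ranks(b, seed + 2L * i + 1L)))
    }, numeric(1))
  })
  # moderate tail probabilities come straight from the empirical null;
  # extreme ones extrapolate the exponential right tail (the null has a
  # point mass at 0 where no partition split is accepted, so the fit uses
  # only the strictly positive tail)
  if (p_threshold >= 20 / length(null_mi)) {
    thr <- as.numeric(quantile(null_mi, 1 - p_threshold))
    return(structure(thr, null_mi = null_mi))
  }
  srt <- sort(null_mi, decreasing = TRUE)
  p_emp <- seq_along(srt) / (length(srt) + 1)
  tail_sel <- p_emp <= 0.2 & srt > 0
  if (sum(tail_sel) < 10)
    stop("too few null pairs in the tail for the fit", call. = FALSE)
  fit <- stats::lm(nlp ~ mi, data = data.frame(nlp = -log(p_emp[tail_sel]),
                                               mi = srt[tail_sel]))
  slope <- stats::coef(fit)[["mi"]]
  assert_that(is.finite(slope) && slope > 0, "degenerate null tail fit")
  thr <- (-log(p_threshold) - stats::coef(fit)[["(Intercept)"]]) / slope
  structure(as.numeric(thr), null_mi = null_mi)
}

#' Data-processing-inequality pruning
#'
#' For every triangle of edges (a,b), (b,c), (a,c), removes (a,c) when
#' `MI(a,c) < min(MI(a,b), MI(b,c)) * (1 - tolerance)`. All removals are
#' decided against the original edge set (simultaneous, not sequential),
#' so the result is order-independent and idempotent.
#'
#' @param edges data.frame with columns a, b, mi (unique unordered pairs).
#' @param tolerance relative tolerance; 0 is the strict rule.
#' @return the pruned edges data.frame (a subset of the input rows).
#' @export
apply_dpi <- function(edges, tolerance = 0) {
  if (nrow(edges) == 0) return(edges)
  nodes <- unique(c(edges$a, edges$b))
  ai <- match(edges$a, nodes); bi <- match(edges$b, nodes)
  nn <- length(nodes)
  key <- function(i, j) pmin(i, j) * (nn + 1) + pmax(i, j)
  mi_map <- setNames(edges$mi, key(ai, bi))
  nbrs <- vector("list", nn)
  for (e in seq_len(nrow(edges))) {
    nbrs[[ai[e]]] <- c(nbrs[[ai[e]]], bi[e])
    nbrs[[bi[e]]] <- c(nbrs[[bi[e]]], ai[e])
  }
  drop <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    i <- ai[e]; j <- bi[e]
    common <- intersect(nbrs[[i]], nbrs[[j]])
    if (!length(common)) next
    m_ik <- mi_map[as.character(key(i, common))]
    m_jk <- mi_map[as.character(key(j, common))]
    if (any(edges$mi[e] < pmin(m_ik, m_jk) * (1 - tolerance)))
      drop[e] <- TRUE
  }
  edges[!drop, , drop = FALSE]
}

# MI edges (regulator vs all genes) above a threshold for one sample set.
mi_edges_once <- function(values, reg_idx, threshold, seed) {
  rk <- jittered_rank_matrix(values, seed)
  mim <- .ap_mi_matrix(rk, as.integer(reg_idx))
  genes <- rownames(values)
  regs <- genes[reg_idx]
  hits <- which(mim >= threshold, arr.ind = TRUE)
  if (nrow(hits) == 0)
    return(data.frame(a = character(0), b = character(0), mi = numeric(0)))
  e <- data.frame(a = regs[hits[, 1]], b = genes[hits[, 2]],
                  mi = mim[hits], stringsAsFactors = FALSE)
  # dedupe unordered pairs (regulator-regulator edges appear twice)
  k <- paste(pmin(e$a, e$b), pmax(e$a, e$b))
  e <- e[!duplicated(k), , drop = FALSE]
  e[e$a != e$b, , drop = FALSE]
}

#' Bootstrap-consensus mutual-information network
#'
#' ARACNe-style regulon inference: per bootstrap (metacells resampled with
#' replacement), MI is estimated between every regulator and every gene by
#' adaptive partitioning, edges below the null-calibrated MI threshold are
#' dropped and the data-processing inequality is applied; the consensus
#' keeps edges whose occurrence count across bootstraps exceeds the
#' Bonferroni-corrected Poisson upper tail of the mean per-edge count.
#' When several regulator classes are supplied each is run separately and
#' the resulting networks are combined by union.
#'
#' @param metacells a `metacell_matrix` or genes x samples matrix.
#' @param regulators character vector of regulator ids, or a named list of
#'   regulator classes.
#' @param n_boot bootstrap iterations (default 100).
#' @param p_threshold MI null tail probability (default 1e-8).
#' @param dpi_tolerance DPI tolerance (default 0, the strict rule).
#' @param mi_threshold optional pre-computed MI threshold (nats); computed
#'   by [mi_null_threshold()] when NULL.
#' @param n_null_pairs null pairs for threshold calibration.
#' @param consensus_alpha Bonferroni family-wise level of the Poisson
#'   consensus test.
#' @param context_id label stored on the returned network.
#' @param seed integer seed.
#' @return list of class `interaction_network`: `context_id`, `edges`
#'   (regulator, target, mi = mean MI over supporting bootstraps, count),
#'   `mi_threshold`, `n_bootstraps`, `regulators`.
#' @export
bootstrap_consensus_network <- function(metacells, regulators, n_boot = 100,
                                        p_threshold = 1e-8,
                                        dpi_tolerance = 0,
                                        mi_threshold = NULL,
                                        n_null_pairs = 3000,
                                        consensus_alpha = 0.05,
                                        context_id = "all", seed = 1L) {
  values <- if (inherits(metacells, "metacell_matrix")) metacells$values
            else as.matrix(metacells)
  assert_that(ncol(values) >= 10, "fewer than 10 metacells: network unstable")
  classes <- if (is.list(regulators)) regulators else list(all = regulators)
  all_edges <- list()
  thr_used <- numeric(0)
  for (ci in seq_along(classes)) {
    regs <- intersect(classes[[ci]], rownames(values))
    assert_that(length(regs) > 0,
                "no regulators of this class present in the gene universe")
    reg_idx <- match(regs, rownames(values))
    thr <- mi_threshold %||% mi_null_threshold(
      values, regs, n_null_pairs = n_null_pairs,
      p_threshold = p_threshold, seed = derive_seed(seed, 9000L + ci))
    thr_used <- c(thr_used, thr)
    counts_env <- new.env(parent = emptyenv())
    mi_sum <- new.env(parent = emptyenv())
    for (b in seq_len(n_boot)) {
      bseed <- derive_seed(seed, 1000L * ci + b)
      # bootstrap resample with duplicate collapse: repeated columns would
      # form rank-space clumps that bias MI upward for every gene pair
      cols <- with_seed(bseed,
                        unique(sample.int(ncol(values), replace = TRUE)))
      e <- mi_edges_once(values[, cols, drop = FALSE], reg_idx, thr,
                         seed = bseed + 1L)
      e <- apply_dpi(e, dpi_tolerance)
      if (nrow(e) == 0) next
      keys <- paste(e$a, e$b, sep = "\r")
      for (i in seq_len(nrow(e))) {
        k <- keys[i]
        counts_env[[k]] <- (counts_env[[k]] %||% 0L) + 1L
        mi_sum[[k]] <- (mi_sum[[k]] %||% 0) + e$mi[i]
      }
    }
    keys <- ls(counts_env)
    if (length(keys) == 0) next
    cnt <- vapply(keys, function(k) counts_env[[k]], integer(1))
    msum <- vapply(keys, function(k) mi_sum[[k]], numeric(1))
    # chance-level recurrence rate: occurrences spread over every possible
    # regulator-target pair; an edge must recur more often than the
    # Bonferroni-corrected Poisson upper tail of that rate
    n_possible <- length(regs) * (nrow(values) - 1)
    # chance recurrence rate estimated from the low-count mass only:
    # grow the null set upward from sporadic edges until the Poisson cut
    # stabilizes (smallest fixed point), so recurrent signal edges never
    # contaminate the rate
    cut <- 1L
    for (it in 1:25) {
      mu <- sum(cnt[cnt <= cut]) / n_possible
      cut_new <- max(1L, qpois(1 - consensus_alpha / n_possible, mu))
      if (cut_new <= cut) break
      cut <- cut_new
    }
    # cap so that unanimously recurring edges always qualify
    cut <- min(cut, n_boot - 1L)
    keep <- cnt > cut
    if (!any(keep)) next
    parts <- do.call(rbind, strsplit(keys[keep], "\r", fixed = TRUE))
    all_edges[[length(all_edges) + 1L]] <- data.frame(
      regulator = parts[, 1], target = parts[, 2],
      mi = msum[keep] / cnt[keep], count = cnt[keep],
      stringsAsFactors = FALSE)
  }
  edges <- if (length(all_edges)) {
    e <- do.call(rbind, all_edges)
    e[!duplicated(paste(e$regulator, e$target, sep = "\r")), , drop = FALSE]
  } else data.frame(regulator = character(0), target = character(0),
                    mi = numeric(0), count = integer(0))
  rownames(edges) <- NULL
  structure(list(context_id = context_id, edges = edges,
                 mi_threshold = thr_used, n_bootstraps = n_boot,
                 regulators = unname(unlist(classes))),
            class = "interaction_network")
}

#' Assemble regulons from a consensus network
#'
#' For each regulator: targets come from its consensus edges; the mode of
#' regulation (`tfmode`) is the Spearman correlation between regulator and
#' target across metacells; the `likelihood` is the edge MI scaled by the
#' regulon's maximum MI. Regulons are truncated to `max_targets` by
#' likelihood and dropped below `min_targets`.
#'
#' @param network an `interaction_network`.
#' @param metacells the `metacell_matrix` the network was inferred on.
#' @param max_targets cap on targets per regulon (default 50).
#' @param min_targets minimum regulon size to keep (default 25).
#' @return named list of regulons: each a list(regulator, targets, tfmode,
#'   likelihood).
#' @export
build_regulons <- function(network, metacells, max_targets = 50,
                           min_targets = 25) {
  values <- if (inherits(metacells, "metacell_matrix")) metacells$values
            else as.matrix(metacells)
  edges <- network$edges
  assert_that(nrow(edges) > 0, "network has no edges")
  out <- list()
  for (r in unique(edges$regulator)) {
    if (!r %in% rownames(values)) {
      warning("regulator ", r, " absent from expression matrix; dropped")
      next
    }
    e <- edges[edges$regulator == r & edges$target != r, , drop = FALSE]
    e <- e[e$target %in% rownames(values), , drop = FALSE]
    e <- e[!duplicated(e$target), , drop = FALSE]
    if (nrow(e) < min_targets) next
    e <- e[order(-e$mi), , drop = FALSE][seq_len(min(max_targets, nrow(e))), ]
    tf <- suppressWarnings(
      cor(values[r, ], t(values[e$target, , drop = FALSE]),
          method = "spearman"))[1, ]
    tf[is.na(tf)] <- 0
    lik <- e$mi / max(e$mi)
    out[[r]] <- list(regulator = r, targets = e$target,
                     tfmode = pmin(1, pmax(-1, unname(tf))),
                     likelihood = unname(lik))
  }
  out
}

#' Regulons from a planted truth network
#'
#' Converts a [generate_truth_network()] object into regulons usable by the
#' activity engine (tfmode = planted sign, likelihood proportional to
#' strength). Intended for oracle construction in tests.
#'
#' @param truth a `truth_network`.
#' @return named list of regulons.
#' @export
truth_regulons <- function(truth) {
  out <- list()
  for (r in truth$regulators) {
    e <- truth$edges[truth$edges$regulator == r, , drop = FALSE]
    out[[r]] <- list(regulator = r, targets = e$target,
                     tfmode = as.numeric(e$sign),
                     likelihood = e$strength / max(e$strength))
  }
  out
}
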