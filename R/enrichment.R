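#' Gene-set enrichment analysis on a ranked list
#'
#' Weighted Kolmogorov-Smirnov running sum: hits increment in proportion to
#' `|metric|^weight_p` (normalized over the set), misses decrement by
#' `1/(N - n)`. The enrichment score is the extremum of the walk. The null
#' distribution comes from `n_perm` random size-matched gene sets;
#' `NES = ES / mean(|null ES| of the matching sign)` and
#' `p = (1 + #{same-sign nulls with |ES_null| >= |ES|}) / (n_perm + 1)`.
#' The leading edge collects set members at or before the maximum (ES > 0)
#' or at or after the minimum (ES < 0).
#'
#' @param ranked a `ranked_list` (data.frame gene/metric in rank order).
#' @param gene_set character vector of members.
#' @param weight_p metric exponent (1 = weighted, 0 = classic KS).
#' @param n_perm random sets for the null (default 1000).
#' @param seed integer seed.
#' @return list of class `gsea_result`: set_size, ES, NES, p_perm,
#'   leading_edge, running_sum.
#' @export
gsea <- function(ranked, gene_set, weight_p = 1, n_perm = 1000, seed = 1L) {
  genes <- ranked$gene
  metric <- ranked$metric
  N <- length(genes)
  hit <- genes %in% gene_set
  n <- sum(hit)
  assert_that(n >= 5, "fewer than 5 set members in the ranked universe")
  assert_that(n < N, "gene set covers the entire universe")
  es_walk <- function(hit_idx) {
    h <- logical(N); h[hit_idx] <- TRUE
    wts <- abs(metric)^weight_p
    wh <- wts[h]
    if (sum(wh) == 0) wh <- rep(1, length(wh))
    inc <- numeric(N)
    inc[h] <- wh / sum(wh)
    inc[!h] <- -1 / (N - length(hit_idx))
    cumsum(inc)
  }
  rs <- es_walk(which(hit))
  i_max <- which.max(rs); i_min <- which.min(rs)
  es <- if (rs[i_max] >= -rs[i_min]) rs[i_max] else rs[i_min]
  null_es <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    w <- es_walk(sample.int(N, n))
    j_max <- which.max(w); j_min <- which.min(w)
    if (w[j_max] >= -w[j_min]) w[j_max] else w[j_min]
  }, numeric(1)))
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(es))) / (length(same) + 1)
  le <- if (es >= 0) genes[seq_len(i_max)][hit[seq_len(i_max)]]
        else genes[i_min:N][hit[i_min:N]]
  structure(list(set_size = n, ES = es, NES = nes, p_perm = p,
                 leading_edge = le, running_sum = rs),
            class = "gsea_result")
}

#' Intersect leading edges across analyses
#'
#' Exact intersection of named gene sets, with the overlap fraction
#' reported against each input set and against the union (both, since
#' either denominator is a defensible convention).
#'
#' @param le_sets named list of >= 2 gene sets.
#' @return list: shared, per_set_counts, frac_vs_each, frac_vs_union.
#' @export
intersect_leading_edges <- function(le_sets) {
  assert_that(length(le_sets) >= 2, "need at least two sets")
  le_sets <- lapply(le_sets, unique)
  shared <- Reduce(intersect, le_sets)
  un <- unique(unlist(le_sets))
  list(shared = shared,
       per_set_counts = vapply(le_sets, length, integer(1)),
       frac_vs_each = vapply(le_sets, function(s)
         length(shared) / length(s), numeric(1)),
       frac_vs_union = length(shared) / length(un))
}

#' Per-cell gene-set variation scores
#'
#' For each gene, a Gaussian-kernel cumulative density across cells
#' (bandwidth SD/4) gives a relative expression statistic; per cell, genes
#' are ranked by that statistic (descending) and scored by a KS-like
#' random walk with centered-rank weights (tau = 1). The score is the
#' maximum positive deviation plus the minimum negative deviation
#' (`max_diff`) or the largest absolute deviation (`classic`).
#'
#' @param matrix_vals genes-or-proteins x cells numeric matrix.
#' @param gene_sets named list of gene sets (>= 3 members in the universe).
#' @param mode `"max_diff"` (default) or `"classic"`.
#' @return pathways x cells score matrix of class `gsva_scores`.
#' @export
gsva_scores <- function(matrix_vals, gene_sets,
                        mode = c("max_diff", "classic")) {
  mode <- match.arg(mode)
  x <- as.matrix(matrix_vals)
  assert_that(ncol(x) >= 2, "need >= 2 cells")
  const <- apply(x, 1L, sd) == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) excluded")
    x <- x[!const, , drop = FALSE]
  }
  ng <- nrow(x); nc <- ncol(x)
  # kernel CDF per gene across cells
  z <- t(vapply(seq_len(ng), function(g) {
    v <- x[g, ]
    h <- sd(v) / 4
    vapply(v, function(xi) mean(pnorm((xi - v) / h)), numeric(1))
  }, numeric(nc)))
  dimnames(z) <- dimnames(x)
  genes <- rownames(x)
  scores <- matrix(NA_real_, length(gene_sets), nc,
                   dimnames = list(names(gene_sets), colnames(x)))
  for (si in seq_along(gene_sets)) {
    members <- intersect(unique(gene_sets[[si]]), genes)
    if (length(members) < 3) {
      warning("set ", names(gene_sets)[si], " overlaps universe by < 3; NA")
      next
    }
    hit0 <- genes %in% members
    n <- sum(hit0)
    for (j in seq_len(nc)) {
      ord <- order(-z[, j])
      hit <- hit0[ord]
      w <- abs(seq_len(ng) - (ng + 1) / 2)  # centered rank weight, tau = 1
      inc <- numeric(ng)
      inc[hit] <- w[hit] / sum(w[hit])
      inc[!hit] <- -1 / (ng - n)
      walk <- cumsum(inc)
      scores[si, j] <- if (mode == "max_diff")
        max(c(0, walk)) + min(c(0, walk))
      else walk[which.max(abs(walk))]
    }
  }
  class(scores) <- c("gsva_scores", class(scores))
  scores
}

#' Two-group comparison with test-choice guidance
#'
#' Student's t (Welch) or Mann-Whitney U, two-sided. A Shapiro normality
#' pre-check on each group is advisory: `recommended` names the branch it
#' supports. Degenerate variance under the t-test falls back to
#' Mann-Whitney with a warning.
#'
#' @param values numeric vector.
#' @param labels two-level grouping of the same length.
#' @param test `"student_t"` or `"mann_whitney"`.
#' @return list: statistic, p, test, recommended.
#' @export
compare_groups <- function(values, labels,
                           test = c("student_t", "mann_whitney")) {
  test <- match.arg(test)
  labels <- as.factor(labels)
  assert_that(nlevels(labels) == 2, "labels must have two levels")
  a <- values[labels == levels(labels)[1]]
  b <- values[labels == levels(labels)[2]]
  assert_that(length(a) >= 2 && length(b) >= 2, "need >= 2 per group")
  normal_ok <- function(v) {
    if (length(v) < 3 || length(unique(v)) < 3) return(FALSE)
    tryCatch(shapiro.test(v)$p.value > 0.05, error = function(e) FALSE)
  }
  recommended <- if (normal_ok(a) && normal_ok(b)) "student_t"
                 else "mann_whitney"
  if (test == "student_t" && (sd(a) == 0 && sd(b) == 0)) {
    warning("degenerate variance: falling back to Mann-Whitney")
    test <- "mann_whitney"
  }
  res <- if (test == "student_t") {
    h <- t.test(a, b)
    list(statistic = unname(h$statistic), p = h$p.value)
  } else {
    h <- suppressWarnings(wilcox.test(a, b, exact = length(values) < 50))
    list(statistic = unname(h$statistic), p = h$p.value)
  }
  c(res, list(test = test, recommended = recommended))
}
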