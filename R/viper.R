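#' Per-cell gene-expression signatures
#'
#' Transforms normalized expression into per-gene z-scores against the
#' all-cell internal reference (mean and SD across cells). Constant genes
#' receive signature 0. A rank-normal variant maps each gene's across-cell
#' ranks through the standard normal quantile function.
#'
#' @param norm_expression genes x cells numeric matrix (log2 CPM or
#'   residuals), or a `normalized_matrix`.
#' @param method `"zscore"` (default) or `"rank_normal"`.
#' @return genes x cells signature matrix of class `signature_matrix`.
#' @export
compute_signatures <- function(norm_expression,
                               method = c("zscore", "rank_normal")) {
  method <- match.arg(method)
  x <- if (inherits(norm_expression, "normalized_matrix"))
    norm_expression$values else as.matrix(norm_expression)
  assert_that(ncol(x) >= 2, "need >= 2 cells for an internal reference")
  if (method == "zscore") {
    mu <- rowMeans(x)
    sdv <- apply(x, 1L, sd)
    out <- (x - mu) / ifelse(sdv > 0, sdv, 1)
    out[sdv == 0, ] <- 0
  } else {
    out <- t(apply(x, 1L, function(r) {
      if (sd(r) == 0) return(rep(0, length(r)))
      qnorm(rank(r, ties.method = "average") / (length(r) + 1))
    }))
    dimnames(out) <- dimnames(x)
  }
  class(out) <- c("signature_matrix", class(out))
  out
}

# Rank-derived quantile matrices shared by all regulons for one signature
# matrix: q1 is the directional quantile, q2 the magnitude quantile.
area_quantiles <- function(signatures) {
  n <- nrow(signatures)
  r <- apply(signatures, 2L, function(col)
    rank(col, ties.method = "average") / (n + 1))
  list(q1 = qnorm(r), q2 = qnorm(0.5 + abs(r - 0.5)))
}

#' Analytic rank-based enrichment (aREA) score of one regulon
#'
#' Genes are rank-transformed to r in (0,1); the directional quantile is
#' `q1 = qnorm(r)` and the magnitude quantile `q2 = qnorm(0.5 + |r-0.5|)`.
#' Each target contributes `s = tfmode * q1 + (1 - |tfmode|) * q2`; the
#' enrichment score is the likelihood-weighted mean of the contributions
#' and the NES divides by `sqrt(sum(w^2))` of the normalized weights, so
#' the null is approximately standard normal.
#'
#' @param signature numeric gene vector (one cell) with names, or a
#'   genes x cells matrix.
#' @param regulon list(regulator, targets, tfmode, likelihood).
#' @param min_targets minimum usable targets (default 25, lowered to 10
#'   automatically when the gene universe has < 2000 genes).
#' @return NES scalar (single cell) or vector over cells; NA when the
#'   regulon has too few usable targets.
#' @export
area_nes <- function(signature, regulon, min_targets = NULL) {
  sig <- if (is.null(dim(signature))) cbind(signature) else signature
  min_targets <- min_targets %||% default_min_targets(nrow(sig))
  q <- area_quantiles(sig)
  res <- area_nes_from_quantiles(q, rownames(sig), regulon, min_targets)
  if (is.null(dim(signature))) res[1] else res
}

default_min_targets <- function(n_genes) if (n_genes < 2000) 10L else 25L

area_nes_from_quantiles <- function(q, genes, regulon, min_targets) {
  idx <- match(regulon$targets, genes)
  ok <- !is.na(idx)
  if (sum(ok) < min_targets) return(rep(NA_real_, ncol(q$q1)))
  idx <- idx[ok]
  m <- regulon$tfmode[ok]
  lik <- regulon$likelihood[ok]
  w <- lik / sum(lik)
  es <- as.vector(crossprod(w * m, q$q1[idx, , drop = FALSE]) +
                    crossprod(w * (1 - abs(m)), q$q2[idx, , drop = FALSE]))
  es / sqrt(sum(w^2))
}

#' Protein activity for one network
#'
#' aREA NES for every regulon of one network over all cells.
#'
#' @param signatures a `signature_matrix` (genes x cells).
#' @param regulons named regulon list (e.g. [build_regulons()]).
#' @param min_targets see [area_nes()].
#' @return proteins x cells NES matrix.
#' @export
viper_activity <- function(signatures, regulons, min_targets = NULL) {
  min_targets <- min_targets %||% default_min_targets(nrow(signatures))
  q <- area_quantiles(signatures)
  genes <- rownames(signatures)
  rows <- lapply(regulons, function(reg)
    area_nes_from_quantiles(q, genes, reg, min_targets))
  keep <- !vapply(rows, function(r) all(is.na(r)), logical(1))
  assert_that(any(keep), "no regulon met the minimum target requirement")
  out <- do.call(rbind, rows[keep])
  rownames(out) <- names(regulons)[keep]
  colnames(out) <- colnames(signatures)
  out
}

#' metaVIPER: integrate protein activity across networks
#'
#' Computes aREA NES against every network carrying a protein's regulon
#' and integrates per protein and cell with confidence weights
#' `w_n = NES_n^2`: `integrated = sum(w * NES) / sqrt(sum(w^2))`. A protein
#' present in exactly one network passes through unchanged; the result is
#' invariant to network ordering.
#'
#' @param signatures a `signature_matrix`.
#' @param networks list of regulon lists, or `interaction_network` objects
#'   paired with `metacells` to build regulons from.
#' @param min_targets see [area_nes()].
#' @return list of class `activity_matrix`: `values` (proteins x cells
#'   NES), `provenance` (per protein, the contributing network ids).
#' @export
metaviper_activity <- function(signatures, networks, min_targets = NULL) {
  assert_that(length(networks) >= 1, "need at least one network")
  if (is.null(names(networks)))
    names(networks) <- paste0("net", seq_along(networks))
  mats <- lapply(networks, function(nw) {
    regs <- if (inherits(nw, "interaction_network"))
      stop("pass regulon lists; build_regulons() converts networks")
    else nw
    viper_activity(signatures, regs, min_targets)
  })
  proteins <- sort(unique(unlist(lapply(mats, rownames))))
  nc <- ncol(signatures)
  num <- matrix(0, length(proteins), nc,
                dimnames = list(proteins, colnames(signatures)))
  den <- matrix(0, length(proteins), nc)
  prov <- setNames(vector("list", length(proteins)), proteins)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    i <- match(rownames(m), proteins)
    w <- m^2
    num[i, ] <- num[i, ] + w * m
    den[i, ] <- den[i, ] + w^2
    for (p in rownames(m)) prov[[p]] <- c(prov[[p]], nm)
  }
  vals <- num / sqrt(den)
  vals[!is.finite(vals)] <- 0
  structure(list(values = vals, provenance = prov),
            class = "activity_matrix")
}

#' Master regulators per cluster by bootstrapped t-test
#'
#' For each cluster and protein, the cluster's cells and the remaining
#' cells are resampled with replacement `n_boot` times and a Welch t
#' statistic is computed per resample. The table reports the bootstrap
#' mean t (`mean_boot_t`, whose normal tail gives the p-value), the
#' Stouffer-style ranking statistic `stouffer_z =
#' mean(t) * sqrt(n_boot) / sd(t)`, and the within-cluster rank by
#' decreasing `stouffer_z`.
#'
#' @param activity an `activity_matrix` (or proteins x cells matrix).
#' @param labels per-cell cluster labels (or `cluster_assignment`).
#' @param n_boot bootstrap resamples (default 100).
#' @param seed integer seed.
#' @return data.frame: cluster, protein, mean_boot_t, stouffer_z, p, rank.
#' @export
master_regulators <- function(activity, labels, n_boot = 100, seed = 1L) {
  vals <- if (inherits(activity, "activity_matrix")) activity$values
          else as.matrix(activity)
  if (inherits(labels, "cluster_assignment")) labels <- labels$labels
  labels <- as.integer(labels)
  cl <- sort(unique(labels))
  assert_that(length(cl) >= 2, "need >= 2 clusters")
  welch_t <- function(a, b) {
    m1 <- rowMeans(a); m2 <- rowMeans(b)
    v1 <- rowSums((a - m1)^2) / (ncol(a) - 1)
    v2 <- rowSums((b - m2)^2) / (ncol(b) - 1)
    (m1 - m2) / sqrt(pmax(v1 / ncol(a) + v2 / ncol(b), 1e-12))
  }
  out <- list()
  for (k in cl) {
    ing <- which(labels == k); outg <- which(labels != k)
    if (length(ing) < 3) {
      warning("cluster ", k, " has < 3 cells; skipped")
      next
    }
    tmat <- with_seed(derive_seed(seed, k), {
      vapply(seq_len(n_boot), function(b) {
        i <- sample(ing, replace = TRUE)
        o <- sample(outg, replace = TRUE)
        welch_t(vals[, i, drop = FALSE], vals[, o, drop = FALSE])
      }, numeric(nrow(vals)))
    })
    mt <- rowMeans(tmat)
    sdt <- apply(tmat, 1L, sd)
    sz <- mt * sqrt(n_boot) / pmax(sdt, 1e-8)
    p <- 2 * pnorm(-abs(mt))
    df <- data.frame(cluster = k, protein = rownames(vals),
                     mean_boot_t = mt, stouffer_z = sz, p = p,
                     stringsAsFactors = FALSE)
    df <- df[order(-df$stouffer_z), ]
    df$rank <- seq_len(nrow(df))
    out[[length(out) + 1L]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Top master regulators per cluster
#'
#' @param mr_table output of [master_regulators()].
#' @param n proteins per cluster (default 100, the GSEA input size).
#' @param positive_only keep only proteins whose activity is elevated in
#'   the cluster (stouffer_z > 0); a protein with depressed activity is
#'   not a master regulator of that cluster.
#' @return named list of protein vectors per cluster, ordered by rank.
#' @export
top_master_regulators <- function(mr_table, n = 100, positive_only = TRUE) {
  if (positive_only)
    mr_table <- mr_table[mr_table$stouffer_z > 0, , drop = FALSE]
  lapply(split(mr_table, mr_table$cluster), function(d)
    d$protein[order(d$rank)][seq_len(min(n, nrow(d)))])
}
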