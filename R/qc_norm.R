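#' Per-cell quality-control metrics
#'
#' Computes, for every cell: total UMIs, number of detected genes,
#' percentage of UMIs from the mitochondrial (`MT-` prefixed) gene block,
#' and the library complexity `log10(n_gene) / log10(n_umi)`.
#'
#' @param counts genes x cells count matrix (sparse or dense), rownames =
#'   gene symbols, colnames = barcodes.
#' @return data.frame with one row per cell: barcode, n_umi, n_gene,
#'   pct_mito, complexity, degenerate (TRUE when n_umi = 0; complexity is
#'   NA for n_umi < 2).
#' @export
compute_qc_metrics <- function(counts) {
  assert_that(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "counts must carry gene and barcode dimnames")
  m <- Matrix::Matrix(counts, sparse = TRUE)
  assert_that(min(m) >= 0, "counts must be non-negative")
  mito <- grepl("^MT-", rownames(m))
  n_umi <- Matrix::colSums(m)
  n_gene <- Matrix::colSums(m > 0)
  if (!any(mito)) {
    warning("no 'MT-' genes present; pct_mito set to 0")
    pct_mito <- rep(0, ncol(m))
  } else {
    pct_mito <- ifelse(n_umi > 0,
                       100 * Matrix::colSums(m[mito, , drop = FALSE]) / n_umi,
                       0)
  }
  complexity <- ifelse(n_umi >= 2, log10(pmax(n_gene, 1)) / log10(n_umi), NA)
  data.frame(barcode = colnames(m), n_umi = as.numeric(n_umi),
             n_gene = as.numeric(n_gene), pct_mito = as.numeric(pct_mito),
             complexity = as.numeric(complexity),
             degenerate = n_umi == 0, stringsAsFactors = FALSE)
}

#' Filter cells on quality-control thresholds
#'
#' A cell is retained iff `n_umi >= min_umi`, `gene_range[1] <= n_gene <=
#' gene_range[2]`, `pct_mito <= max_mito` and `complexity >=
#' min_complexity` (all boundaries inclusive on the keep side).
#'
#' @param counts genes x cells count matrix.
#' @param metrics output of [compute_qc_metrics()] on the same cells.
#' @param thresholds list with `min_umi`, `gene_range`, `max_mito`,
#'   `min_complexity`.
#' @return the retained genes x cells matrix, with attribute `qc_report`
#'   (data.frame: rule, removed) recording removals per rule.
#' @export
filter_cells <- function(counts, metrics,
                         thresholds = list(min_umi = 1000,
                                           gene_range = c(300, 8000),
                                           max_mito = 5,
                                           min_complexity = 0.8)) {
  assert_that(identical(metrics$barcode, colnames(counts)),
              "metrics were not computed on these cells")
  th <- utils::modifyList(list(min_umi = 1000, gene_range = c(300, 8000),
                               max_mito = 5, min_complexity = 0.8),
                          thresholds)
  pass_umi <- metrics$n_umi >= th$min_umi
  pass_gene <- metrics$n_gene >= th$gene_range[1] &
    metrics$n_gene <= th$gene_range[2]
  pass_mito <- metrics$pct_mito <= th$max_mito
  cx <- ifelse(is.na(metrics$complexity), -Inf, metrics$complexity)
  pass_cx <- cx >= th$min_complexity
  keep <- pass_umi & pass_gene & pass_mito & pass_cx
  report <- data.frame(
    rule = c("min_umi", "gene_range", "max_mito", "min_complexity"),
    removed = c(sum(!pass_umi), sum(!pass_gene), sum(!pass_mito),
                sum(!pass_cx)))
  if (!any(keep)) stop("no cells pass quality control", call. = FALSE)
  out <- counts[, keep, drop = FALSE]
  attr(out, "qc_report") <- report
  out
}

# Per-gene NB dispersion by maximum likelihood against fixed means,
# with a method-of-moments fallback.
estimate_theta <- function(y, mu) {
  mom <- function() {
    v <- var(y); m <- mean(mu)
    if (!is.finite(v) || v <= m) return(1e6)
    m^2 / (v - m)
  }
  th <- tryCatch(suppressWarnings(MASS::theta.ml(y, mu, limit = 25)),
                 error = function(e) mom())
  as.numeric(max(min(th, 1e6), 1e-4))
}

#' Regularized negative-binomial Pearson-residual normalization
#'
#' Per gene, fits an intercept-only NB model with log total-UMI offset
#' (`mu_gc = exp(beta0_g) * n_umi_c`), estimates a per-gene dispersion and
#' regularizes it by Gaussian-kernel smoothing of log10(theta) against
#' log10(gene mean), then returns Pearson residuals
#' `(x - mu) / sqrt(mu + mu^2/theta)` clipped to `+/- sqrt(n_cells)`.
#'
#' @param counts filtered genes x cells count matrix (>= 2 cells).
#' @param bandwidth kernel bandwidth on the log10 gene-mean axis.
#' @return list of class `normalized_matrix`: `values` (dense genes x cells
#'   residuals), `hvg_flags` (filled by [select_hvg()]), `model_params`
#'   (per-gene data.frame: gene, beta0, theta_raw, theta).
#' @export
normalize_pearson_residuals <- function(counts, bandwidth = 0.3) {
  m <- as.matrix(counts)
  nc <- ncol(m)
  assert_that(nc >= 2, "need at least 2 cells")
  depth <- colSums(m)
  assert_that(all(depth > 0), "cells with zero counts must be filtered first")
  tot <- rowSums(m)
  expressed <- tot > 0
  beta0 <- ifelse(expressed, log(tot / sum(depth)), -Inf)
  mu <- exp(beta0) %o% depth  # genes x cells fitted means
  theta_raw <- rep(NA_real_, nrow(m))
  idx <- which(expressed)
  theta_raw[idx] <- vapply(idx, function(g) estimate_theta(m[g, ], mu[g, ]),
                           numeric(1))
  gmean <- log10(tot / nc + 1e-9)
  theta <- theta_raw
  if (length(idx) >= 10) {
    ks <- ksmooth(gmean[idx], log10(theta_raw[idx]), kernel = "normal",
                  bandwidth = bandwidth, x.points = gmean[idx])
    sm <- 10^ks$y[match(gmean[idx], ks$x)]
    theta[idx] <- ifelse(is.finite(sm), sm, theta_raw[idx])
  }
  res <- matrix(0, nrow(m), nc, dimnames = dimnames(m))
  if (length(idx)) {
    v <- mu[idx, , drop = FALSE] +
      mu[idx, , drop = FALSE]^2 / theta[idx]
    res[idx, ] <- (m[idx, , drop = FALSE] - mu[idx, , drop = FALSE]) / sqrt(v)
  }
  clip <- sqrt(nc)
  res[res > clip] <- clip
  res[res < -clip] <- -clip
  structure(list(values = res, hvg_flags = NULL,
                 model_params = data.frame(gene = rownames(m), beta0 = beta0,
                                           theta_raw = theta_raw,
                                           theta = theta,
                                           expressed = expressed,
                                           stringsAsFactors = FALSE)),
            class = "normalized_matrix")
}

#' Select highly variable genes by residual variance
#'
#' Flags the top `n` genes by Pearson-residual variance; ties are broken by
#' lexicographic gene id. Genes with zero total count are excluded from the
#' ranking.
#'
#' @param norm a `normalized_matrix`.
#' @param n number of genes to flag (default 3000).
#' @return the `normalized_matrix` with `hvg_flags` (named logical) filled.
#' @export
select_hvg <- function(norm, n = 3000) {
  v <- apply(norm$values, 1L, var)
  eligible <- norm$model_params$expressed
  ng <- length(v)
  if (n > ng) {
    warning("n exceeds the number of genes; flagging all")
    n <- ng
  }
  ord <- order(-v, !eligible, rownames(norm$values))
  flags <- setNames(rep(FALSE, ng), rownames(norm$values))
  flags[ord[seq_len(min(n, sum(eligible)))]] <- TRUE
  norm$hvg_flags <- flags
  norm
}

#' Optional per-sample gene standardization
#'
#' Centers and scales each gene within each sample to remove additive
#' per-sample location/scale differences. Off by default in the pipeline.
#'
#' @param norm a `normalized_matrix`.
#' @param sample_id per-cell sample labels.
#' @return the `normalized_matrix` with standardized `values`.
#' @export
standardize_per_sample <- function(norm, sample_id) {
  assert_that(length(sample_id) == ncol(norm$values),
              "sample_id length must match cells")
  for (s in unique(sample_id)) {
    j <- sample_id == s
    x <- norm$values[, j, drop = FALSE]
    mu <- rowMeans(x)
    sdv <- apply(x, 1L, sd)
    sdv[sdv == 0] <- 1
    norm$values[, j] <- (x - mu) / sdv
  }
  norm
}
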