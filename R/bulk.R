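#' TMM normalization factors and log2 CPM
#'
#' Trimmed-mean-of-M-values factors (30% M-trim, 5% A-trim, reference =
#' sample whose upper quartile is closest to the mean upper quartile, the
#' standard TMM recipe as implemented in edgeR), then
#' `log2(CPM + 0.5)` with effective library sizes `lib * factor`.
#'
#' @param counts genes x samples non-negative integer matrix.
#' @return list: `norm_factors` (geometric mean 1), `log2cpm`
#'   (genes x samples), `lib_size`.
#' @export
tmm_log2cpm <- function(counts) {
  m <- as.matrix(counts)
  assert_that(ncol(m) >= 2, "need >= 2 samples")
  assert_that(all(m >= 0), "counts must be non-negative")
  lib <- colSums(m)
  if (any(lib == 0)) stop("zero-library sample", call. = FALSE)
  nf <- edgeR::calcNormFactors(m, method = "TMM",
                               logratioTrim = 0.3, sumTrim = 0.05)
  cpm <- t(t(m) / (lib * nf)) * 1e6
  list(norm_factors = nf, log2cpm = log2(cpm + 0.5), lib_size = lib)
}

#' Collapse duplicate feature identifiers
#'
#' Utility mirroring microarray probe handling: rows mapping to the same
#' gene are averaged; rows whose identifier names several genes
#' (separator `sep`) are dropped.
#'
#' @param mat features x samples matrix with feature rownames.
#' @param ids feature -> gene mapping (defaults to rownames).
#' @param sep separator marking multi-gene identifiers.
#' @return gene x samples matrix.
#' @export
collapse_ids <- function(mat, ids = rownames(mat), sep = "///") {
  keep <- !grepl(sep, ids, fixed = TRUE) & !is.na(ids) & ids != ""
  m <- mat[keep, , drop = FALSE]
  ids <- ids[keep]
  out <- rowsum(m, group = ids) / as.vector(table(ids)[sort(unique(ids))])
  out
}

# Inverse of trigamma by Newton iteration (for moment-matched prior df).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Two-group differential expression with a moderated weighted fit
#'
#' TMM-normalized log2 CPM values are fit per gene by weighted least
#' squares on the two-group contrast, with precision weights from a lowess
#' fit of the square-root residual SD against mean log2 count (the
#' mean-variance trend). Gene-wise variances are moderated toward the
#' trend-free pooled prior by empirical Bayes with a moment-matched prior
#' df, and p-values are Benjamini-Hochberg adjusted. The `passes` flag
#' applies `|log2FC| > 1` and adjusted p < 0.05.
#'
#' @param counts genes x samples counts.
#' @param groups two-level factor/character of length ncol(counts).
#' @param lfc_cutoff,alpha thresholds for the `passes` flag.
#' @return data.frame: gene, log2FC, t_moderated, p, p_adj_BH, passes.
#' @export
differential_expression <- function(counts, groups, lfc_cutoff = 1,
                                    alpha = 0.05) {
  groups <- as.factor(groups)
  assert_that(nlevels(groups) == 2, "groups must have exactly two levels")
  assert_that(all(table(groups) >= 2), "each group needs >= 2 samples")
  m <- as.matrix(counts)
  norm <- tmm_log2cpm(m)
  y <- norm$log2cpm
  n <- ncol(y)
  g2 <- groups == levels(groups)[2]
  n1 <- sum(!g2); n2 <- sum(g2)
  # first pass: unweighted group means and residual sd
  mu1 <- rowMeans(y[, !g2, drop = FALSE])
  mu2 <- rowMeans(y[, g2, drop = FALSE])
  fit0 <- cbind(mu1)[, rep(1, n)]; fit0[, g2] <- mu2
  resid0 <- y - fit0
  s0 <- sqrt(rowSums(resid0^2) / (n - 2))
  abar <- rowMeans(y) + mean(log2(norm$lib_size * norm$norm_factors)) - log2(1e6)
  lw <- lowess(abar, sqrt(s0), f = 0.5)
  trend <- stats::approxfun(lw$x, pmax(lw$y, 1e-3), rule = 2)
  # observation weights from predicted log2 abundance of the fitted value
  pred_a <- fit0 + mean(log2(norm$lib_size * norm$norm_factors)) - log2(1e6)
  w <- 1 / trend(pred_a)^4
  dim(w) <- dim(y)
  # weighted two-group fit per gene
  sw1 <- rowSums(w[, !g2, drop = FALSE]); sw2 <- rowSums(w[, g2, drop = FALSE])
  m1 <- rowSums((w * y)[, !g2, drop = FALSE]) / sw1
  m2 <- rowSums((w * y)[, g2, drop = FALSE]) / sw2
  beta <- m2 - m1
  fitw <- cbind(m1)[, rep(1, n)]; fitw[, g2] <- m2
  rss <- rowSums(w * (y - fitw)^2)
  df_res <- n - 2
  s2 <- rss / df_res
  se_unscaled <- sqrt(1 / sw1 + 1 / sw2)
  # empirical Bayes moderation, moment-matched on log s^2
  ok <- s2 > 0
  e <- log(s2[ok]) - digamma(df_res / 2) + log(df_res / 2)
  ev <- mean(e); vv <- var(e) - trigamma(df_res / 2)
  if (is.finite(vv) && vv > 0) {
    d0 <- 2 * trigamma_inverse(vv)
    s02 <- exp(ev + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(ev)
  }
  s2_post <- if (is.finite(d0)) (d0 * s02 + df_res * s2) / (d0 + df_res)
             else rep(s02, length(s2))
  df_total <- df_res + if (is.finite(d0)) d0 else 0
  tmod <- beta / (sqrt(s2_post) * se_unscaled)
  p <- 2 * pt(-abs(tmod), df = df_total)
  p_adj <- p.adjust(p, method = "BH")
  data.frame(gene = rownames(m), log2FC = beta, t_moderated = tmod,
             p = p, p_adj_BH = p_adj,
             passes = abs(beta) > lfc_cutoff & p_adj < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank genes by fold change for enrichment analysis
#'
#' Full descending log2FC ordering (ties broken by |t| then gene id), over
#' all genes by default or only the DEG-passing genes.
#'
#' @param deg output of [differential_expression()].
#' @param deg_only rank only genes with `passes = TRUE`.
#' @return data.frame of class `ranked_list`: gene, metric (log2FC), in
#'   rank order.
#' @export
rank_genes <- function(deg, deg_only = FALSE) {
  d <- if (deg_only) deg[deg$passes, , drop = FALSE] else deg
  ord <- order(-d$log2FC, -abs(d$t_moderated), d$gene)
  out <- data.frame(gene = d$gene[ord], metric = d$log2FC[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", class(out))
  out
}

#' Relative quantification by the 2^-ddCt method
#'
#' Technical replicates (rows sharing a sample) are averaged before
#' `dCt = target - reference`; `ddCt` subtracts the mean dCt of the
#' control condition; fold change is `2^-ddCt`.
#'
#' @param ct data.frame with columns sample, condition, target_ct,
#'   reference_ct.
#' @param control_condition the baseline condition label.
#' @return data.frame: sample, condition, d_ct, dd_ct, fold.
#' @export
delta_delta_ct <- function(ct, control_condition) {
  req <- c("sample", "condition", "target_ct", "reference_ct")
  assert_that(all(req %in% names(ct)), "ct table is missing columns")
  miss <- is.na(ct$reference_ct) | is.na(ct$target_ct)
  if (any(miss)) {
    warning(sum(miss), " row(s) with missing Ct dropped")
    ct <- ct[!miss, , drop = FALSE]
  }
  agg <- stats::aggregate(cbind(target_ct, reference_ct) ~ sample + condition,
                          data = ct, FUN = mean)
  assert_that(control_condition %in% agg$condition,
              "control condition absent from the table")
  agg$d_ct <- agg$target_ct - agg$reference_ct
  base <- mean(agg$d_ct[agg$condition == control_condition])
  agg$dd_ct <- agg$d_ct - base
  agg$fold <- 2^(-agg$dd_ct)
  agg[, c("sample", "condition", "d_ct", "dd_ct", "fold")]
}
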