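#' @useDynLib scactivity, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor dist kruskal.test ksmooth lowess mad median
#'   p.adjust phyper pnorm pt qnorm qpois quantile rbinom rlnorm rmultinom
#'   rnbinom rnorm runif sd setNames t.test var wilcox.test uniroot
#'   complete.cases shapiro.test
#' @importFrom utils head read.delim write.table
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All stochastic operations in the package
# route through this so that a stage seed fully determines its output.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage child seed from a master seed; kept below 2^31.
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 48271 + stage * 7919) %% 2147483647)
}

# Ranks with deterministic seeded jitter (magnitude 1e-9 * sd) to break
# ties before rank-based MI estimation.
jittered_ranks <- function(x, seed = 1L) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  j <- with_seed(seed, runif(length(x), -1, 1)) * 1e-9 * s
  rank(x + j, ties.method = "first")
}

# Row-wise jittered ranks for a genes x samples matrix.
jittered_rank_matrix <- function(m, seed = 1L) {
  jit <- with_seed(seed, matrix(runif(length(m), -1, 1), nrow(m), ncol(m)))
  s <- apply(m, 1L, sd)
  s[!is.finite(s) | s == 0] <- 1
  mj <- m + jit * (1e-9 * s)
  out <- t(apply(mj, 1L, rank, ties.method = "first"))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(m)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
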