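# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the given seed and restores the caller's random-number
#' state afterwards, so seeded package functions never perturb user
#' simulations. A `NULL` seed evaluates `expr` under the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_if_not <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

# xlog2x with the 0*log(0) = 0 convention used by all entropy-type features
xlog2 <- function(p) {
  out <- numeric(length(p))
  ok <- p > 0
  out[ok] <- p[ok] * log2(p[ok])
  out
}

# Population central moment of order k
central_moment <- function(x, k) mean((x - mean(x))^k)

# Mean of the upper triangle of a correlation matrix; 1 for a single column
# (a singleton set of variables is perfectly self-coherent by convention).
mean_pairwise_spearman <- function(mat, method = "spearman") {
  if (ncol(mat) < 2) return(1)
  cm <- stats::cor(mat, method = method)
  mean(cm[upper.tri(cm)])
}

# Deterministic hash of a configuration object (used for provenance fields)
config_hash <- function(x) rlang::hash(x)
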