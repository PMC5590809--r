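# Gene ranking against a radiomic feature.

#' Rank genes by weighted correlation with a radiomic feature
#'
#' For every gene, the Spearman rank correlation `rho` with the feature
#' across patients and its two-sided p-value; the ranking score is
#' `rho * (-log10 p)`, so genes are ordered by both strength and
#' reliability of the monotone association. The p-value uses the
#' t-distribution approximation (exact enumeration for n <= 9 without
#' ties) and is floored at 1e-300 so scores stay finite. Ties in the
#' final ordering are broken by gene id, making the ranking deterministic.
#'
#' @param expr Numeric genes x patients matrix.
#' @param f Named numeric vector of feature values (names = patient ids),
#'   or unnamed in the column order of `expr`.
#' @return A data.frame of class `ranked_gene_list` with columns `gene`,
#'   `rho`, `p`, `score`, sorted by decreasing score.
#' @export
gene_feature_rank <- function(expr, f) {
  if (!is.null(names(f))) {
    stop_if_not(all(colnames(expr) %in% names(f)),
                "feature vector missing some patients")
    f <- f[colnames(expr)]
  }
  n <- ncol(expr)
  stop_if_not(n >= 3, "need at least 3 aligned patients")
  stop_if_not(length(f) == n, "feature length must match patient count")
  if (stats::sd(f) == 0) {
    stop("zero-variance feature: rank correlation undefined", call. = FALSE)
  }
  rf <- rank(f)
  rg <- t(apply(expr, 1, rank))
  rfc <- rf - mean(rf)
  rgc <- rg - rowMeans(rg)
  denom <- sqrt(rowSums(rgc^2) * sum(rfc^2))
  rho <- as.numeric(rgc %*% rfc) / denom
  rho[denom == 0] <- 0          # constant gene: no association
  rho <- pmin(pmax(rho, -1), 1)
  if (n <= 9 && !anyDuplicated(rf)) {
    p <- vapply(seq_len(nrow(expr)), function(i) {
      if (anyDuplicated(rg[i, ])) {
        spearman_p_t(rho[i], n)
      } else {
        suppressWarnings(stats::cor.test(expr[i, ], f, method = "spearman",
                                         exact = TRUE)$p.value)
      }
    }, numeric(1))
  } else {
    p <- spearman_p_t(rho, n)
  }
  p <- pmax(pmin(p, 1), 1e-300)
  score <- rho * (-log10(p))
  genes <- rownames(expr) %||% paste0("g", seq_len(nrow(expr)))
  ord <- order(-score, genes)
  structure(data.frame(gene = genes[ord], rho = rho[ord], p = p[ord],
                       score = score[ord], stringsAsFactors = FALSE),
            class = c("ranked_gene_list", "data.frame"))
}

# Two-sided p for Spearman rho via the t approximation
spearman_p_t <- function(rho, n) {
  p <- numeric(length(rho))
  lim <- abs(rho) >= 1
  p[lim] <- 1e-300
  r <- rho[!lim]
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p[!lim] <- 2 * stats::pt(-abs(tt), df = n - 2)
  p
}

#' Filter a gene-set collection against an expression universe
#'
#' Intersects every set's membership with the measured gene universe, then
#' keeps sets whose in-universe size is within `[min_size, max_size]`
#' (inclusive; defaults 15 and 500, the conventional preranked-enrichment
#' filter).
#'
#' @param collection Named list of gene id vectors.
#' @param universe Character vector of measured gene ids.
#' @param min_size,max_size Inclusive size bounds after intersection.
#' @return Named list of filtered gene sets (members restricted to the
#'   universe).
#' @export
filter_gene_sets <- function(collection, universe, min_size = 15,
                             max_size = 500) {
  stop_if_not(length(universe) > 0, "empty gene universe")
  out <- lapply(collection, function(g) intersect(unique(g), universe))
  keep <- vapply(out, length, integer(1))
  out <- out[keep >= min_size & keep <= max_size]
  if (length(out) == 0) {
    warning("no gene sets left after size filtering", call. = FALSE)
  }
  out
}
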