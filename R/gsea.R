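# Preranked gene-set enrichment and the feature x pathway NES matrix.

# Weighted Kolmogorov-Smirnov running-sum statistic computed from the hit
# positions only. `w` are |score|^weight at the hit positions (ranking
# order); extremes of the running sum occur immediately before and after
# each hit, so scanning those points is exact.
es_from_positions <- function(pos, w, N) {
  nh <- length(pos)
  stop_if_not(nh >= 1, "empty gene set")
  stop_if_not(nh < N, "gene set equal to the whole universe")
  o <- order(pos)
  pos <- pos[o]
  w <- w[o]
  tot <- sum(w)
  if (tot == 0) w[] <- 1 / nh else w <- w / tot
  miss <- 1 / (N - nh)
  cum_hit <- cumsum(w)
  after <- cum_hit - (pos - seq_len(nh)) * miss
  before <- c(0, cum_hit[-nh]) - (pos - 1 - (seq_len(nh) - 1)) * miss
  # interleave in ranking-walk order so ties in |deviation| (up to
  # summation round-off) resolve to the earliest extreme, matching a
  # sequential scan of the running sum
  cand <- as.vector(rbind(before, after))
  aa <- abs(cand)
  cand[which(aa >= max(aa) - 1e-12)[1]]
}

#' Enrichment score of a gene set in a ranked list
#'
#' The weighted running-sum statistic of preranked gene-set enrichment:
#' walking down the ranking, hits increment the sum by
#' `|score|^weight_exp` (normalized over the set) and misses decrement it
#' by `1/(N - N_hit)`; the enrichment score is the signed maximum
#' deviation. `weight_exp = 0` recovers the classic unweighted
#' Kolmogorov-Smirnov statistic.
#'
#' @param ranking A [gene_feature_rank()] result, or a data.frame with
#'   columns `gene` and `score` sorted by decreasing score.
#' @param set Character vector of gene ids (a proper nonempty subset of
#'   the ranked universe).
#' @param weight_exp Weighting exponent on |score| (default 1).
#' @return Enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(ranking, set, weight_exp = 1) {
  pos <- which(ranking$gene %in% set)
  stop_if_not(length(pos) >= 1, "gene set has no genes in the ranking")
  es_from_positions(pos, abs(ranking$score[pos])^weight_exp,
                    nrow(ranking))
}

#' Preranked gene-set enrichment with permutation null
#'
#' Computes the enrichment score of every set, builds the gene-label
#' permutation null (random sets of identical size drawn from the ranked
#' universe, the only permutation scheme available to preranked input),
#' and reports the normalized enrichment score (ES divided by the mean
#' |null ES| of the matching sign), the matching-sign permutation p-value
#' with the plus-one convention, and Benjamini-Hochberg q-values over the
#' collection. Null draws are shared across sets of equal size.
#'
#' @param ranking A [gene_feature_rank()] result.
#' @param collection Named list of gene sets (already size-filtered).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation draws.
#' @param weight_exp Weighting exponent, as in [enrichment_score()].
#' @return data.frame with columns `set_id`, `size`, `ES`, `NES`,
#'   `p_value`, `q_value`.
#' @export
preranked_gsea <- function(ranking, collection, n_perm = 1000, seed = NULL,
                           weight_exp = 1) {
  stop_if_not(n_perm >= 100, "n_perm must be at least 100")
  stop_if_not(length(collection) >= 1, "empty collection")
  N <- nrow(ranking)
  if (all(ranking$score == 0)) {
    stop("degenerate ranking: all scores are zero", call. = FALSE)
  }
  w_all <- abs(ranking$score)^weight_exp
  idx_of <- function(set) which(ranking$gene %in% set)
  sizes <- vapply(collection, function(s) length(idx_of(s)), integer(1))
  stop_if_not(all(sizes >= 1), "a set has no genes in the ranking")
  stop_if_not(all(sizes < N), "a set equals the whole universe")
  es <- vapply(names(collection), function(nm) {
    pos <- idx_of(collection[[nm]])
    es_from_positions(pos, w_all[pos], N)
  }, numeric(1))
  null_by_size <- with_seed(seed, {
    out <- list()
    for (k in sort(unique(sizes))) {
      out[[as.character(k)]] <- vapply(seq_len(n_perm), function(i) {
        pos <- sample.int(N, k)
        es_from_positions(pos, w_all[pos], N)
      }, numeric(1))
    }
    out
  })
  res <- lapply(seq_along(es), function(i) {
    null <- null_by_size[[as.character(sizes[i])]]
    same <- null[sign(null) == sign(es[i])]
    if (length(same) == 0) same <- null   # no matching-sign draws: fall back
    c(nes = unname(es[i]) / mean(abs(same)),
      p = (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same)))
  })
  nes <- vapply(res, `[[`, numeric(1), "nes")
  p <- vapply(res, `[[`, numeric(1), "p")
  data.frame(set_id = names(collection), size = sizes, ES = es, NES = nes,
             p_value = p, q_value = stats::p.adjust(p, "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Feature x pathway association matrix of normalized enrichment scores
#'
#' For every radiomic feature: rank all genes by weighted correlation with
#' the feature, run preranked enrichment against the collection, and store
#' the normalized enrichment score. Rows are features, columns pathways;
#' the matrix is complete by construction.
#'
#' @param features Patients x features matrix (rownames = patient ids).
#' @param expr Genes x patients matrix, same patients.
#' @param collection Named list of gene sets (pre-filtered against the
#'   expression universe).
#' @param n_perm Permutations per feature.
#' @param seed Integer seed.
#' @param weight_exp Ranking weight exponent.
#' @return Object of class `association_matrix`: a list with numeric
#'   matrices `nes`, `p`, `q` (features x pathways).
#' @export
build_association_matrix <- function(features, expr, collection,
                                     n_perm = 1000, seed = NULL,
                                     weight_exp = 1) {
  features <- as.matrix(features)
  stop_if_not(identical(sort(rownames(features)), sort(colnames(expr))),
              "features and expression cover different patients")
  expr <- expr[, rownames(features), drop = FALSE]
  nm_f <- colnames(features)
  nm_s <- names(collection)
  nes <- p <- q <- matrix(NA_real_, length(nm_f), length(nm_s),
                          dimnames = list(nm_f, nm_s))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2,
                                      length(nm_f)))
  for (i in seq_along(nm_f)) {
    rk <- gene_feature_rank(expr, features[, i])
    gs <- preranked_gsea(rk, collection, n_perm = n_perm, seed = seeds[i],
                         weight_exp = weight_exp)
    nes[i, gs$set_id] <- gs$NES
    p[i, gs$set_id] <- gs$p_value
    q[i, gs$set_id] <- gs$q_value
  }
  structure(list(nes = nes, p = p, q = q), class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("<association_matrix> %d features x %d pathways (NES)\n",
              nrow(x$nes), ncol(x$nes)))
  invisible(x)
}

#' Per-patient pathway enrichment scores
#'
#' Single-sample rank-based enrichment: for each patient, genes are ranked
#' by that patient's expression profile and the unweighted running-sum
#' enrichment score of the set in that ranking is returned. The score is a
#' signed statistic whose sign is read downstream as pathway activation;
#' being rank-based, it is invariant under any monotone transform of a
#' patient's profile. This is a deliberately parameter-free variant of
#' single-sample enrichment scoring (the kernel-density variant adds free
#' parameters but the downstream analysis only consumes the sign and
#' ordering).
#'
#' @param expr Genes x patients matrix.
#' @param set Character vector of gene ids.
#' @return Named numeric vector of per-patient scores.
#' @export
per_patient_enrichment <- function(expr, set) {
  set <- intersect(set, rownames(expr))
  stop_if_not(length(set) >= 1, "empty gene set after universe intersection")
  stop_if_not(length(set) < nrow(expr), "set equals the whole universe")
  hit <- rownames(expr) %in% set
  N <- nrow(expr)
  out <- vapply(seq_len(ncol(expr)), function(j) {
    ord <- order(-expr[, j], rownames(expr))
    pos <- which(hit[ord])
    es_from_positions(pos, rep(1, length(pos)), N)
  }, numeric(1))
  names(out) <- colnames(expr)
  out
}

#' Per-patient enrichment matrix for many sets
#'
#' Convenience wrapper over [per_patient_enrichment()] returning a
#' patients x sets matrix, the pathway-score block used by module
#' coherence and validation.
#'
#' @param expr Genes x patients matrix.
#' @param collection Named list of gene sets.
#' @return Numeric patients x sets matrix.
#' @export
pathway_score_matrix <- function(expr, collection) {
  N <- nrow(expr)
  genes <- rownames(expr)
  # rank position of every gene in every patient's profile, computed once
  inv <- apply(expr, 2, function(x) order(order(-x, genes)))
  out <- matrix(NA_real_, ncol(expr), length(collection),
                dimnames = list(colnames(expr), names(collection)))
  for (k in seq_along(collection)) {
    rows <- which(genes %in% collection[[k]])
    stop_if_not(length(rows) >= 1 && length(rows) < N,
                "set empty or equal to the universe")
    w <- rep(1, length(rows))
    for (j in seq_len(ncol(expr))) {
      out[j, k] <- es_from_positions(inv[rows, j], w, N)
    }
  }
  out
}
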