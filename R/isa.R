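# Iterative Signature Algorithm biclustering of the NES matrix.

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' ISA biclustering of an association matrix
#'
#' Standard Iterative Signature Algorithm: the matrix is z-score
#' normalized by rows (`Er`) and by columns (`Ec`); from each random
#' sparse row seed, column scores `t(Er) %*% r` are z-scored and
#' thresholded, row scores `Ec %*% c` are z-scored and thresholded, and
#' the alternation is iterated to a fixed point. Every pair of thresholds
#' from `row_thresholds x col_thresholds` is run from `n_seeds` seeds (the
#' liberal 1.5 to 2.5 by 0.5 grid keeps weak signals); converged nonempty
#' biclusters are collected, exact duplicates collapsed. Seeds that do not
#' converge within `max_iter` iterations are discarded.
#'
#' @param m Numeric matrix (features x pathways), or an
#'   `association_matrix` whose `nes` slot is used.
#' @param row_thresholds,col_thresholds Positive z-score thresholds.
#' @param n_seeds Random seeds per threshold pair.
#' @param seed Integer RNG seed; fixed seed gives an identical candidate
#'   list.
#' @param max_iter Iteration cap per seed.
#' @return List of candidate modules, each
#'   `list(rows, cols, row_score, col_score, thr_row, thr_col)` with
#'   integer index vectors `rows`/`cols`.
#' @export
isa_bicluster <- function(m, row_thresholds = c(1.5, 2, 2.5),
                          col_thresholds = c(1.5, 2, 2.5), n_seeds = 100,
                          seed = NULL, max_iter = 100) {
  if (inherits(m, "association_matrix")) m <- m$nes
  stop_if_not(is.matrix(m) && !anyNA(m), "m must be a complete matrix")
  stop_if_not(all(row_thresholds > 0) && all(col_thresholds > 0),
              "thresholds must be positive")
  if (all(m == 0)) return(list())
  Er <- t(apply(m, 1, zscore))
  Ec <- apply(m, 2, zscore)
  nr <- nrow(m)
  nc <- ncol(m)
  thresh <- function(z, thr) ifelse(abs(z) > thr, z, 0)
  cands <- list()
  keys <- character(0)
  with_seed(seed, {
    for (tr in row_thresholds) {
      for (tc in col_thresholds) {
        for (s in seq_len(n_seeds)) {
          r <- numeric(nr)
          r[sample.int(nr, min(5L, nr))] <- 1
          seen <- character(0)
          converged <- FALSE
          for (it in seq_len(max_iter)) {
            cs <- as.numeric(crossprod(Er, r))
            cz <- thresh(zscore(cs), tc)
            if (all(cz == 0)) break
            rs <- as.numeric(Ec %*% cz)
            rz <- thresh(zscore(rs), tr)
            if (all(rz == 0)) break
            key <- paste(which(rz != 0), collapse = ",")
            key <- paste(key, paste(which(cz != 0), collapse = ","),
                         sep = "|")
            # a revisited membership state is a fixed point or limit
            # cycle: both count as converged
            if (key %in% seen) {
              converged <- TRUE
              break
            }
            seen <- c(seen, key)
            r <- rz / sqrt(sum(rz^2))
          }
          if (!converged) next
          rows <- which(rz != 0)
          cols <- which(cz != 0)
          # a 1 x 1 bicluster carries no coherence information (both
          # singleton sides are perfectly self-coherent by convention)
          if (length(rows) == 1 && length(cols) == 1) next
          kk <- paste(paste(rows, collapse = ","),
                      paste(cols, collapse = ","), sep = "|")
          if (kk %in% keys) next
          keys <- c(keys, kk)
          rn <- rz / sqrt(sum(rz^2))
          cn <- cz / sqrt(sum(cz^2))
          cands[[length(cands) + 1]] <- list(
            rows = rows, cols = cols, row_score = rz, col_score = cz,
            robustness = abs(as.numeric(t(rn) %*% Ec %*% cn)),
            thr_row = tr, thr_col = tc)
        }
      }
    }
  })
  cands
}

#' Robustness-filter ISA candidates against a permuted matrix
#'
#' The standard ISA noise filter: the input matrix is entry-permuted
#' (destroying all row/column structure while keeping the value
#' distribution), ISA is re-run with identical parameters, and real
#' candidates are kept only when their robustness score (the normalized
#' bilinear form of the module's row and column signatures through the
#' matrix) exceeds the best robustness any candidate achieves on the
#' permuted matrix. This removes fixed points that plain noise can
#' produce, which otherwise crowd the downstream FDR family.
#'
#' @param m The matrix given to [isa_bicluster()].
#' @param candidates Its candidate list.
#' @param row_thresholds,col_thresholds,n_seeds Parameters matching the
#'   original run.
#' @param n_permutations Number of permuted matrices; the cutoff is the
#'   maximum robustness over all of them, so more permutations give a
#'   stricter noise floor.
#' @param seed Integer seed for the permutations and the re-runs.
#' @return The retained sublist of `candidates`.
#' @export
isa_robustness_filter <- function(m, candidates,
                                  row_thresholds = c(1.5, 2, 2.5),
                                  col_thresholds = c(1.5, 2, 2.5),
                                  n_seeds = 100, n_permutations = 3,
                                  seed = NULL) {
  if (length(candidates) == 0) return(candidates)
  if (inherits(m, "association_matrix")) m <- m$nes
  seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2,
                                      n_permutations))
  cutoff <- 0
  for (s in seeds) {
    perm <- with_seed(s, matrix(sample(as.vector(m)), nrow(m), ncol(m)))
    null_cands <- isa_bicluster(perm, row_thresholds, col_thresholds,
                                n_seeds = n_seeds, seed = s)
    if (length(null_cands)) {
      cutoff <- max(cutoff, vapply(null_cands, `[[`, numeric(1),
                                   "robustness"))
    }
  }
  keep <- vapply(candidates, `[[`, numeric(1), "robustness") > cutoff
  candidates[keep]
}

#' Prune redundant bicluster candidates
#'
#' Greedy retention in decreasing robustness order: a candidate is dropped
#' when the Pearson correlation of its binary membership vector (rows and
#' columns concatenated) with any retained module exceeds `max_corr`
#' (default 0.3). The operation is idempotent.
#'
#' @param candidates List of candidates from [isa_bicluster()].
#' @param max_corr Maximum allowed membership correlation, in `(0, 1]`.
#' @param robustness Numeric vector ordering the candidates (larger =
#'   retained first); defaults to equal, i.e. input order.
#' @return The retained sublist of `candidates`.
#' @export
deduplicate_modules <- function(candidates, max_corr = 0.3,
                                robustness = NULL) {
  stop_if_not(max_corr > 0 && max_corr <= 1, "max_corr must be in (0, 1]")
  if (length(candidates) <= 1) return(candidates)
  robustness <- robustness %||% rep(0, length(candidates))
  nr <- max(vapply(candidates, function(x) max(x$rows), numeric(1)))
  nc <- max(vapply(candidates, function(x) max(x$cols), numeric(1)))
  nr <- max(nr, vapply(candidates, function(x) length(x$row_score),
                       numeric(1)))
  nc <- max(nc, vapply(candidates, function(x) length(x$col_score),
                       numeric(1)))
  memb <- vapply(candidates, function(x) {
    v <- numeric(nr + nc)
    v[x$rows] <- 1
    v[nr + x$cols] <- 1
    v
  }, numeric(nr + nc))
  ord <- order(-robustness)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0 ||
        all(stats::cor(memb[, i], memb[, kept, drop = FALSE]) <=
              max_corr)) {
      kept <- c(kept, i)
    }
  }
  candidates[sort(kept)]
}
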