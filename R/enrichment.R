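.collection_sets <- function(collection) {
  if (inherits(collection, "ontology")) collection$genes else collection
}

#' Over-representation analysis (hypergeometric test)
#'
#' Upper-tail hypergeometric test of a query gene set against each term of a
#' collection, with Benjamini-Hochberg control across tested terms. Term
#' gene sets are intersected with the universe before testing.
#'
#' @param query_genes character vector of query genes (subset of universe).
#' @param universe character vector, the gene universe.
#' @param collection named list of gene sets, or an `ontology`.
#' @param alpha adjusted-p significance threshold.
#' @return data frame of class `enrichment_result`: `term_id`, `size`,
#'   `overlap`, `p`, `adj_p`, `significant`, plus an `overlap_genes` list
#'   column.
#' @export
ora_enrich <- function(query_genes, universe, collection, alpha = 0.05) {
  sets <- .collection_sets(collection)
  query_genes <- unique(query_genes)
  universe <- unique(universe)
  if (!length(query_genes) || !length(universe))
    .stopf("query and universe must be non-empty")
  if (!all(query_genes %in% universe))
    .stopf("query genes must be contained in the universe")
  N <- length(universe); n <- length(query_genes)
  rows <- lapply(names(sets), function(id) {
    term <- intersect(sets[[id]], universe)
    if (!length(term)) return(NULL)
    ov <- intersect(term, query_genes)
    K <- length(term); k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) .stopf("no term overlaps the universe")
  out$adj_p <- bh_adjust(out$p)
  out$significant <- out$adj_p < alpha
  out$overlap_genes <- lapply(out$term_id, function(id)
    intersect(intersect(sets[[id]], universe), query_genes))
  class(out) <- c("enrichment_result", "data.frame")
  out
}

# Weighted running-sum enrichment score for hit positions `pos` (sorted) in
# a ranked list of length N with hit weights `w` (already |score|^exponent).
# Returns ES, the peak position, and which extreme achieved it.
.es_at_hits <- function(pos, w, N) {
  nh <- length(pos)
  wsum <- sum(w)
  if (wsum == 0) w <- rep(1 / nh, nh) else w <- w / wsum
  miss <- 1 / (N - nh)
  cw <- cumsum(w)
  after <- cw - (pos - seq_len(nh)) * miss          # just after each hit
  before <- c(0, cw[-nh]) - (pos - seq_len(nh)) * miss  # just before each hit
  hi <- max(after); lo <- min(before)
  if (hi >= -lo) list(es = hi, peak = pos[which.max(after)])
  else list(es = lo, peak = pos[which.min(before)])
}

#' Ranked gene-set enrichment (running-sum statistic)
#'
#' Classical weighted Kolmogorov-Smirnov-like running-sum enrichment over a
#' real-valued ranking (e.g. principal-component loadings). Hits increment
#' the running sum proportionally to `|score|^weight_exp` (normalized over
#' the set), misses decrement by `1/(N - n)`; the enrichment score ES is the
#' maximum deviation from zero. The null is a gene-label permutation
#' (uniformly resampled hit positions); `NES = ES / mean(|ES_perm|)` over
#' same-sign permutations, the p-value is the same-sign empirical tail, and
#' p-values are BH-adjusted across terms. Core (leading-edge) genes are the
#' ranked hits before the peak for positive ES, after it for negative ES.
#' Ties in the ranking are broken by stable input order.
#'
#' @param scores named numeric vector (gene scores; ranked internally,
#'   descending).
#' @param collection named list of gene sets, or an `ontology`.
#' @param n_perm number of permutations.
#' @param weight_exp weighting exponent (0 recovers the unweighted KS form).
#' @param seed integer seed.
#' @param min_size,max_size set-size bounds after intersection with the
#'   ranking.
#' @param alpha,nes_thresh significance thresholds (adjusted p and |NES|).
#' @return data frame of class `enrichment_result`: `term_id`, `size`,
#'   `es`, `nes`, `p`, `adj_p`, `significant`, plus a `core_genes` list
#'   column.
#' @export
gsea_rank <- function(scores, collection, n_perm = 1000, weight_exp = 1,
                      seed = 1L, min_size = 5L, max_size = 500L,
                      alpha = 0.05, nes_thresh = 1) {
  sets <- .collection_sets(collection)
  if (is.null(names(scores))) .stopf("'scores' must be named by gene")
  if (n_perm < 100) .warnf("n_perm < 100 gives a very coarse permutation p-value")
  o <- order(scores, decreasing = TRUE)   # ties: stable input order
  ranked <- names(scores)[o]
  rs <- abs(scores[o])^weight_exp
  N <- length(ranked)

  .with_seed(seed, {
    rows <- lapply(names(sets), function(id) {
      pos <- sort(match(intersect(sets[[id]], ranked), ranked))
      nh <- length(pos)
      if (nh == 0L) {
        message(sprintf("term %s skipped: no overlap with the ranked list", id))
        return(NULL)
      }
      if (nh < min_size || nh > max_size || nh >= N) return(NULL)
      obs <- .es_at_hits(pos, rs[pos], N)
      perm_es <- vapply(seq_len(n_perm), function(b) {
        pb <- sort(sample.int(N, nh))
        .es_at_hits(pb, rs[pb], N)$es
      }, 0)
      same <- perm_es[sign(perm_es) == sign(obs$es)]
      denom <- if (length(same)) mean(abs(same)) else mean(abs(perm_es))
      nes <- if (denom > 0) obs$es / denom else 0
      p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
      core <- if (obs$es >= 0) ranked[pos[pos <= obs$peak]]
              else ranked[pos[pos >= obs$peak]]
      out <- data.frame(term_id = id, size = nh, es = obs$es, nes = nes,
                        p = p, stringsAsFactors = FALSE)
      out$core_genes <- list(core)
      out
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) .stopf("no term passed the size bounds")
    out$adj_p <- bh_adjust(out$p)
    out$significant <- out$adj_p < alpha & abs(out$nes) >= nes_thresh
    out <- out[c("term_id", "size", "es", "nes", "p", "adj_p",
                 "significant", "core_genes")]
    class(out) <- c("enrichment_result", "data.frame")
    out
  })
}

#' Greedy Jaccard-based redundancy reduction of enriched terms
#'
#' Walks the results in order of ascending adjusted p (ties by raw p, then
#' term id) and drops any term whose gene-set Jaccard similarity to an
#' already retained term reaches `similarity_thresh`. The best term is
#' always retained and the output is a subset of the input.
#'
#' @param results an `enrichment_result` (needs `term_id` and `adj_p`).
#' @param collection named list of gene sets, or an `ontology`.
#' @param similarity_thresh Jaccard threshold at or above which a term is
#'   considered redundant.
#' @return the retained subset of `results`, in the greedy order.
#' @export
reduce_redundancy <- function(results, collection, similarity_thresh = 0.7) {
  if (!nrow(results)) return(results)
  sets <- .collection_sets(collection)
  ord <- order(results$adj_p, results$p, results$term_id)
  res <- results[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(res))) {
    gi <- sets[[res$term_id[i]]]
    redundant <- any(vapply(kept, function(j)
      .jaccard(gi, sets[[res$term_id[j]]]) >= similarity_thresh, TRUE))
    if (!redundant) kept <- c(kept, i)
  }
  out <- res[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}
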