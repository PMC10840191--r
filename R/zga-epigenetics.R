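#' Fuzzy c-means clustering
#'
#' Minimizes `sum_ij u_ij^m ||x_i - v_j||^2` by alternating membership and
#' centroid updates from a random initial membership matrix. Iteration stops
#' when the largest membership change falls below `tol`; non-convergence at
#' `max_iter` raises a warning and returns the best iterate. The objective
#' trace is returned and is non-increasing.
#'
#' @param x numeric matrix (rows = observations).
#' @param c number of clusters (`c < nrow(x)`).
#' @param m fuzzifier exponent (> 1).
#' @param seed integer seed.
#' @param tol convergence tolerance on memberships.
#' @param max_iter iteration cap.
#' @return list with `membership` (rows sum to 1), `centers`, `objective`
#'   (per-iteration trace), `iterations`, `converged`.
#' @export
fuzzy_cmeans <- function(x, c, m = 2, seed = 1L, tol = 1e-6, max_iter = 500L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (c >= n) .stopf("'c' must be smaller than the number of rows")
  if (m <= 1) .stopf("fuzzifier 'm' must exceed 1")
  .with_seed(seed, {
    u <- matrix(stats::runif(n * c), n, c)
    u <- u / rowSums(u)
    obj <- numeric(0)
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      um <- u^m
      centers <- t(um) %*% x / colSums(um)
      d2 <- outer(rowSums(x^2), rep(1, c)) - 2 * x %*% t(centers) +
        outer(rep(1, n), rowSums(centers^2))
      d2 <- pmax(d2, 0)
      obj <- c(obj, sum(um * d2))
      zero <- d2 < .Machine$double.eps
      u_new <- 1 / (d2^(1 / (m - 1)) * rowSums((1 / d2)^(1 / (m - 1))))
      if (any(zero)) {
        for (i in which(rowSums(zero) > 0L)) {
          u_new[i, ] <- 0
          u_new[i, zero[i, ]] <- 1 / sum(zero[i, ])
        }
      }
      delta <- max(abs(u_new - u))
      u <- u_new
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
      .warnf("fuzzy c-means did not converge in %d iterations (delta > %g)",
             max_iter, tol)
    dimnames(u) <- list(rownames(x), paste0("c", seq_len(c)))
    rownames(centers) <- colnames(u)
    list(membership = u, centers = centers, objective = obj,
         iterations = it, converged = converged)
  })
}

#' Classify genes into programmed expression waves
#'
#' Soft-clusters per-gene stage profiles (standardized across stages) with
#' fuzzy c-means and maps clusters to the programmed waves of
#' pre-implantation development: `maternal` (decaying from the oocyte),
#' `minor_zga` (1-cell peak), `major_zga` (2-cell peak), `mga` (rising
#' after the 2-cell stage) or `other`. A manual `cluster_wave_map` (named
#' character vector, `"c3" = "maternal"` etc.) is the primary interface;
#' without one, clusters are auto-mapped to the wave whose stage-profile
#' template ([wave_templates()]) correlates best with the cluster centroid,
#' falling back to `other` below `min_cor`.
#'
#' @param stage_means numeric matrix: genes x ordered stages (e.g. control
#'   condition means for MII, 1-cell, 2-cell, 4-cell).
#' @param c number of fuzzy clusters.
#' @param m fuzzifier.
#' @param cluster_wave_map optional named vector mapping cluster ids to
#'   waves.
#' @param seed,tol,max_iter passed to [fuzzy_cmeans()].
#' @param min_cor minimum template correlation for auto-mapping.
#' @return object of class `wave_classification`: data frame `gene`,
#'   `cluster`, `max_membership`, `wave`; the membership matrix, centers
#'   and cluster->wave map are attached as attributes.
#' @export
classify_waves <- function(stage_means, c = 25L, m = 2, cluster_wave_map = NULL,
                           seed = 1L, tol = 1e-6, max_iter = 500L,
                           min_cor = 0.8) {
  x <- as.matrix(stage_means)
  if (c >= nrow(x)) .stopf("'c' must be smaller than the number of genes")
  z <- .zscore_rows(x)
  fit <- fuzzy_cmeans(z, c = c, m = m, seed = seed, tol = tol,
                      max_iter = max_iter)
  hard <- max.col(fit$membership, ties.method = "first")
  maxu <- fit$membership[cbind(seq_len(nrow(z)), hard)]
  cl_ids <- colnames(fit$membership)

  if (is.null(cluster_wave_map)) {
    tmpl <- wave_templates(colnames(x) %||% as.character(seq_len(ncol(x))))
    tmpl <- tmpl[rownames(tmpl) != "other", , drop = FALSE]
    cluster_wave_map <- vapply(seq_len(c), function(j) {
      ctr <- fit$centers[j, ]
      if (stats::sd(ctr) == 0) return("other")
      cors <- apply(tmpl, 1L, function(t) stats::cor(ctr, t))
      if (max(cors) < min_cor) "other" else rownames(tmpl)[which.max(cors)]
    }, "")
    names(cluster_wave_map) <- cl_ids
  } else {
    if (!all(names(cluster_wave_map) %in% cl_ids))
      .stopf("cluster_wave_map names must be cluster ids (%s...)", cl_ids[1L])
    full <- stats::setNames(rep("other", c), cl_ids)
    full[names(cluster_wave_map)] <- cluster_wave_map
    cluster_wave_map <- full
  }

  out <- data.frame(gene = rownames(x), cluster = cl_ids[hard],
                    max_membership = maxu,
                    wave = unname(cluster_wave_map[cl_ids[hard]]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "membership") <- fit$membership
  attr(out, "centers") <- fit$centers
  attr(out, "cluster_wave_map") <- cluster_wave_map
  attr(out, "objective") <- fit$objective
  class(out) <- c("wave_classification", "data.frame")
  out
}

#' Fisher contingency test of DEG direction against a wave class
#'
#' Crosses the up- and downregulated DEG sets with membership in one
#' expression-wave class and applies the two-sided Fisher exact test (the
#' two-sided p sums hypergeometric probabilities of tables no more probable
#' than the observed one). With `table_style = "disjoint"` (the default)
#' the columns are in-wave / not-in-wave counts. `table_style =
#' "group_total"` instead places the whole DEG-set size in the second
#' column ("k out of n" pairs as a 2x2 table); it is provided because
#' published analyses sometimes tabulate the test that way.
#'
#' @param deg_sets named list with elements `up` and `down` (disjoint gene
#'   sets).
#' @param wave_genes genes belonging to the wave class.
#' @param table_style table construction, see above.
#' @return data frame `a`, `b`, `c`, `d`, `odds_ratio`, `p_value` (row
#'   name encodes the style); `a`/`c` are the in-wave counts of the up and
#'   down set.
#' @export
zga_contingency_test <- function(deg_sets, wave_genes,
                                 table_style = c("disjoint", "group_total")) {
  table_style <- match.arg(table_style)
  for (nm in c("up", "down")) {
    if (!length(deg_sets[[nm]])) .stopf("DEG set '%s' is empty", nm)
  }
  if (length(intersect(deg_sets$up, deg_sets$down)))
    .stopf("'up' and 'down' DEG sets must be disjoint")
  a <- length(intersect(deg_sets$up, wave_genes))
  c_ <- length(intersect(deg_sets$down, wave_genes))
  n1 <- length(unique(deg_sets$up)); n2 <- length(unique(deg_sets$down))
  b <- if (table_style == "disjoint") n1 - a else n1
  d <- if (table_style == "disjoint") n2 - c_ else n2
  tab <- matrix(c(a, b, c_, d), nrow = 2L, byrow = TRUE,
                dimnames = list(c("up", "down"), c("in_wave", "rest")))
  p <- stats::fisher.test(tab)$p.value
  or <- (a * d) / ifelse(b * c_ > 0, b * c_, NA_real_)
  data.frame(a = a, b = b, c = c_, d = d, odds_ratio = or, p_value = p,
             table_style = table_style, stringsAsFactors = FALSE)
}

#' Sum scored intervals over strand-aware promoter windows
#'
#' The promoter of a gene is the window `(window[1], window[2])` around its
#' TSS in transcript orientation: for a plus-strand gene the genomic window
#' is `[tss + window[1], tss + window[2])`, for a minus-strand gene
#' `[tss - window[2], tss - window[1])` (0-based, half-open, like the BED
#' input). Each interval contributes its score times the fraction of the
#' interval overlapping the promoter (`mode = "fraction"`), or its full
#' score on any overlap (`mode = "full"`). Genes without overlap score 0.
#'
#' @param track data frame with `chrom`, `start`, `end`, `name`, `score`
#'   (BED semantics) as from [read_bed()].
#' @param gene_model data frame with `gene`, `chrom`, `strand`, `tss`.
#' @param window numeric pair of offsets relative to the TSS, in
#'   transcript orientation (default TSS +/- 1 kb; use `c(-200, 100)` for
#'   accessibility-style windows).
#' @param mode overlap weighting, see above.
#' @return named numeric vector of promoter scores, one per model gene.
#' @export
promoter_feature_scores <- function(track, gene_model,
                                    window = c(-1000, 1000),
                                    mode = c("fraction", "full")) {
  mode <- match.arg(mode)
  if (window[2] <= window[1]) .stopf("'window' must be an increasing pair")
  plus <- gene_model$strand == "+"
  p_start <- ifelse(plus, gene_model$tss + window[1], gene_model$tss - window[2])
  p_end <- ifelse(plus, gene_model$tss + window[2], gene_model$tss - window[1])
  prom <- GenomicRanges::GRanges(
    gene_model$chrom,
    IRanges::IRanges(start = p_start + 1L, end = p_end)  # 0-based -> 1-based
  )
  iv <- GenomicRanges::GRanges(
    track$chrom, IRanges::IRanges(start = track$start + 1L, end = track$end))
  hits <- GenomicRanges::findOverlaps(iv, prom)
  scores <- stats::setNames(rep(0, nrow(gene_model)), gene_model$gene)
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(iv)[qi], IRanges::ranges(prom)[si]))
    contrib <- if (mode == "fraction") {
      track$score[qi] * ov / IRanges::width(IRanges::ranges(iv))[qi]
    } else track$score[qi]
    agg <- rowsum(contrib, group = si)
    scores[as.integer(rownames(agg))] <- agg[, 1L]
  }
  scores
}

#' Enrichment of DEG sets in top-scoring epigenetic-mark gene sets
#'
#' For every mark, the `top_n` genes by promoter score (ties at the
#' boundary broken by gene id) form the strongly associated gene set; each
#' (DEG set, mark) pair is tested by the upper-tail hypergeometric test
#' against the universe, with Benjamini-Hochberg adjustment over all tested
#' pairs and a significance flag at `adj_p < alpha`.
#'
#' @param deg_sets named list of DEG gene sets.
#' @param feature_scores named list (per mark) of named score vectors, as
#'   from [promoter_feature_scores()].
#' @param universe gene universe.
#' @param top_n size of the strongly associated set (must not exceed the
#'   universe).
#' @param alpha adjusted-p threshold.
#' @return data frame `deg_set`, `mark`, `overlap`, `p`, `adj_p`,
#'   `significant`.
#' @export
feature_enrichment <- function(deg_sets, feature_scores, universe,
                               top_n = 1000L, alpha = 0.01) {
  universe <- unique(universe)
  N <- length(universe)
  if (top_n > N) .stopf("'top_n' cannot exceed the universe size (%d)", N)
  top_sets <- lapply(feature_scores, function(s) {
    s <- s[names(s) %in% universe]
    miss <- setdiff(universe, names(s))
    s <- c(s, stats::setNames(rep(0, length(miss)), miss))
    names(s)[order(-s, names(s))][seq_len(top_n)]
  })
  rows <- do.call(rbind, lapply(names(deg_sets), function(ds) {
    q <- intersect(unique(deg_sets[[ds]]), universe)
    do.call(rbind, lapply(names(top_sets), function(mk) {
      k <- length(intersect(q, top_sets[[mk]]))
      p <- stats::phyper(k - 1, top_n, N - top_n, length(q), lower.tail = FALSE)
      data.frame(deg_set = ds, mark = mk, overlap = k, p = p,
                 stringsAsFactors = FALSE)
    }))
  }))
  rows$adj_p <- bh_adjust(rows$p)
  rows$significant <- rows$adj_p < alpha
  rows
}
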