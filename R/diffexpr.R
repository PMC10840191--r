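#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values (monotone in `p`, clipped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-gene linear-model differential expression
#'
#' Fits an ordinary least-squares one-way model per gene over the condition
#' groups and tests one contrast (treated minus reference) with a two-sided
#' t-test using the pooled residual variance (no empirical-Bayes
#' moderation). P-values are Benjamini-Hochberg adjusted over all tested
#' genes, and each gene is called `up` when `LFC >= lfc_thresh` with
#' `adj_p < alpha`, `down` for the mirrored rule, else `none`.
#'
#' @param es an `expr_set` or numeric matrix (log2, no missing values).
#' @param groups condition label per sample.
#' @param contrast character vector `c(treated, reference)`; both must be
#'   levels of `groups`.
#' @param lfc_thresh absolute log2-fold-change threshold.
#' @param alpha adjusted-p threshold.
#' @return data frame of class `deg_table`: `gene`, `lfc`, `p`, `adj_p`,
#'   `direction`, with the contrast stored as an attribute.
#' @export
fit_degs <- function(es, groups, contrast, lfc_thresh = 1, alpha = 0.05) {
  x <- if (inherits(es, "expr_set")) es$exprs else es
  if (anyNA(x)) .stopf("impute missing values first")
  groups <- factor(groups)
  if (length(contrast) != 2L || !all(contrast %in% levels(groups)))
    .stopf("'contrast' must name two levels of 'groups'")
  if (any(table(groups)[contrast] < 2L))
    .stopf("each contrasted condition needs at least 2 replicates")
  n <- ncol(x); k <- nlevels(groups)
  df <- n - k
  if (df <= 0L) .stopf("zero residual degrees of freedom (n = %d, groups = %d)", n, k)

  means <- vapply(levels(groups), function(lev)
    rowMeans(x[, groups == lev, drop = FALSE]), numeric(nrow(x)))
  rss <- rowSums((x - means[, as.character(groups)])^2)
  s2 <- rss / df
  n1 <- sum(groups == contrast[1L]); n2 <- sum(groups == contrast[2L])
  lfc <- means[, contrast[1L]] - means[, contrast[2L]]
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, Inf * sign(lfc)))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  adj_p <- bh_adjust(p)
  direction <- ifelse(lfc >= lfc_thresh & adj_p < alpha, "up",
                      ifelse(lfc <= -lfc_thresh & adj_p < alpha, "down", "none"))
  out <- data.frame(gene = rownames(x), lfc = lfc, p = p, adj_p = adj_p,
                    direction = direction, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "contrast") <- contrast
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Hopkins statistic of clustering tendency
#'
#' `H = sum(u) / (sum(u) + sum(w))` where `u` are nearest-neighbour
#' distances from uniform pseudo-points in the bounding box of the data to
#' the data, and `w` are nearest-neighbour distances from sampled data
#' points to the remaining data. `H` is about 0.5 for uniform data and
#' approaches 1 for strongly clustered data; values below 0.75 are treated
#' by the pipeline as lacking cluster structure.
#'
#' @param x numeric matrix (rows = observations).
#' @param n_probes number of probe points (default: 10% of rows, >= 5).
#' @param seed integer seed.
#' @return the statistic (scalar in (0, 1)).
#' @export
hopkins_statistic <- function(x, n_probes = NULL, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  n_probes <- n_probes %||% max(5L, floor(0.1 * n))
  if (n < 2L * n_probes) .stopf("need at least 2 * n_probes rows")
  lo <- apply(x, 2L, min); hi <- apply(x, 2L, max)
  if (all(hi - lo == 0)) .stopf("constant data: bounding box has zero volume")
  .with_seed(seed, {
    idx <- sample.int(n, n_probes)
    u_pts <- vapply(seq_along(lo), function(j)
      stats::runif(n_probes, lo[j], hi[j]), numeric(n_probes))
    u_pts <- matrix(u_pts, nrow = n_probes)
    nn <- function(p, ref) {
      d2 <- colSums((t(ref) - p)^2)
      sqrt(min(d2))
    }
    u <- vapply(seq_len(n_probes), function(i) nn(u_pts[i, ], x), 0)
    w <- vapply(seq_len(n_probes), function(i)
      nn(x[idx[i], ], x[-idx[i], , drop = FALSE]), 0)
    sum(u) / (sum(u) + sum(w))
  })
}

.wss_curve <- function(x, k_max, nstart, iter_max = 50L) {
  vapply(seq_len(k_max), function(k) {
    if (k == 1L) sum(scale(x, scale = FALSE)^2)
    else sum(stats::kmeans(x, centers = k, nstart = nstart,
                           iter.max = iter_max)$withinss)
  }, 0)
}

#' Choose the number of clusters by the elbow or gap statistic
#'
#' `elbow` picks the k maximizing the second difference of the total
#' within-cluster sum of squares over `k = 1..k_max` (the sharpest bend).
#' `gap` compares `log(W_k)` with its expectation under uniform reference
#' data drawn in the per-column ranges, and returns the smallest k with
#' `Gap(k) >= Gap(k+1) - s_{k+1}` (the one-standard-error rule).
#'
#' @param x numeric matrix (rows = observations).
#' @param k_max largest k considered (>= 2, and >= 3 for the elbow).
#' @param method `"elbow"` or `"gap"`.
#' @param seed integer seed.
#' @param B number of uniform reference data sets for the gap statistic.
#' @param nstart k-means restarts.
#' @return the chosen k.
#' @export
choose_cluster_number <- function(x, k_max, method = c("elbow", "gap"),
                                  seed = 1L, B = 50L, nstart = 10L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (k_max < 2L) .stopf("'k_max' must be at least 2")
  if (k_max >= nrow(x)) .stopf("'k_max' must be smaller than the number of rows")
  .with_seed(seed, {
    if (method == "elbow") {
      if (k_max < 3L) .stopf("the elbow method needs k_max >= 3")
      wss <- .wss_curve(x, k_max, nstart)
      d2 <- wss[seq_len(k_max - 2L)] - 2 * wss[seq(2L, k_max - 1L)] +
        wss[seq(3L, k_max)]
      which.max(d2) + 1L
    } else {
      lo <- apply(x, 2L, min); hi <- apply(x, 2L, max)
      logw <- log(.wss_curve(x, k_max, nstart))
      logw_ref <- vapply(seq_len(B), function(b) {
        ref <- vapply(seq_along(lo), function(j)
          stats::runif(nrow(x), lo[j], hi[j]), numeric(nrow(x)))
        log(.wss_curve(matrix(ref, nrow = nrow(x)), k_max, nstart = 2L))
      }, numeric(k_max))
      gap <- rowMeans(logw_ref) - logw
      s <- apply(logw_ref, 1L, stats::sd) * sqrt(1 + 1 / B)
      for (k in seq_len(k_max - 1L)) {
        if (gap[k] >= gap[k + 1L] - s[k + 1L]) return(k)
      }
      k_max
    }
  })
}

#' Partition differentially expressed genes into treatment-pattern groups
#'
#' Validates clustering tendency (Hopkins statistic must reach
#' `hopkins_thresh`, otherwise the data are treated as unclustered and the
#' function refuses with a diagnostic), performs Ward minimum-variance
#' (`ward.D2`) hierarchical clustering on Euclidean distances of per-gene
#' standardized expression, cuts the tree at `k`, and labels each cluster by
#' the sign pattern of its mean log2 fold changes: differential in both
#' treatments versus control -> `common`; differential in exactly one ->
#' that treatment's group; otherwise `unassigned`.
#'
#' @param expr numeric matrix (DEGs x samples, log2).
#' @param lfc_mat numeric matrix (DEGs x treatments) of log2 fold changes
#'   versus control.
#' @param k number of clusters.
#' @param group_lfc_thresh cluster-mean |LFC| needed to call a treatment
#'   differential.
#' @param hopkins_thresh clustering-tendency gate.
#' @param seed integer seed (Hopkins probe sampling).
#' @return data frame of class `deg_groups`: `gene`, `cluster`, `group`,
#'   with `k` and the Hopkins statistic as attributes.
#' @export
partition_deg_groups <- function(expr, lfc_mat, k, group_lfc_thresh = 1,
                                 hopkins_thresh = 0.75, seed = 1L) {
  expr <- as.matrix(expr)
  if (k > nrow(expr)) .stopf("'k' cannot exceed the number of DEGs")
  if (!identical(rownames(expr), rownames(lfc_mat)))
    .stopf("'expr' and 'lfc_mat' must have identical rownames")
  z <- .zscore_rows(expr)
  h <- hopkins_statistic(z, seed = seed)
  if (h < hopkins_thresh)
    .stopf(paste0("Hopkins statistic %.3f < %.2f: the DEG profiles look ",
                  "uniform; refusing to cluster"), h, hopkins_thresh)
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)

  trts <- colnames(lfc_mat)
  group <- vapply(seq_len(k), function(ci) {
    m <- colMeans(lfc_mat[cl == ci, , drop = FALSE])
    act <- abs(m) >= group_lfc_thresh
    if (all(act)) "common"
    else if (sum(act) == 1L) trts[act]
    else "unassigned"
  }, "")
  out <- data.frame(gene = rownames(expr), cluster = unname(cl),
                    group = group[cl], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "k") <- k
  attr(out, "hopkins") <- h
  class(out) <- c("deg_groups", "data.frame")
  out
}
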