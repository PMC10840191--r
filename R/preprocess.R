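#' Build a gene-by-sample expression matrix from probe tables
#'
#' Applies the probe-level detection rules of the microarray workflow: only
#' spots flagged `"positive and significant"` are treated as observed, the
#' rest become missing values. A probe is a valid detection in a condition
#' (stage x treatment) when at least one replicate of that condition is
#' observed; only probes that are valid detections in every condition are
#' retained. For genes measured by several probes, the probe with the
#' highest mean log2 signal across retained samples becomes the gene's
#' representative. Signals are log2-transformed.
#'
#' @param tables named list of probe tables (columns `probe_id`,
#'   `gene_symbol`, `signal`, `flag`), one per sample.
#' @param samples sample metadata data frame with columns `sample`, `stage`,
#'   `treatment`, `replicate`; `names(tables)` must match `samples$sample`.
#' @param valid_flag flag string marking an observed spot.
#' @return an object of class `expr_set`: list with `exprs` (genes x samples
#'   log2 matrix, `NA` where missing), `samples`, and `probes` (gene ->
#'   representative probe map).
#' @export
filter_and_collapse <- function(tables, samples,
                                valid_flag = "positive and significant") {
  if (!setequal(names(tables), samples$sample))
    .stopf("names(tables) must match samples$sample")
  tables <- tables[samples$sample]
  ref <- tables[[1L]]
  if (anyDuplicated(ref$probe_id))
    .stopf("duplicate probe_id within a sample")
  for (t in tables) {
    if (anyDuplicated(t$probe_id)) .stopf("duplicate probe_id within a sample")
    if (!identical(sort(t$probe_id), sort(ref$probe_id)))
      .stopf("all samples must share the same probe universe")
  }
  probe_ids <- ref$probe_id
  gene <- stats::setNames(ref$gene_symbol, ref$probe_id)

  sig <- vapply(tables, function(t) t$signal[match(probe_ids, t$probe_id)],
                numeric(length(probe_ids)))
  valid <- vapply(tables, function(t) t$flag[match(probe_ids, t$probe_id)] == valid_flag,
                  logical(length(probe_ids)))
  dimnames(sig) <- dimnames(valid) <- list(probe_ids, samples$sample)

  condition <- interaction(samples$stage, samples$treatment, drop = TRUE)
  ok_per_cond <- vapply(levels(condition), function(cc) {
    cols <- which(condition == cc)
    rowSums(valid[, cols, drop = FALSE]) >= 1L
  }, logical(length(probe_ids)))
  keep <- rowSums(ok_per_cond) == nlevels(condition)
  if (!any(keep)) .stopf("no probe survives flag filtering")

  sig <- sig[keep, , drop = FALSE]
  valid <- valid[keep, , drop = FALSE]
  lg <- log2(sig)
  lg[!valid] <- NA_real_

  probe_mean <- rowMeans(lg, na.rm = TRUE)
  gk <- gene[rownames(lg)]
  ord <- order(gk, -probe_mean, rownames(lg))
  rep_probe <- rownames(lg)[ord][!duplicated(gk[ord])]
  genes <- gk[rep_probe]

  exprs <- lg[rep_probe, , drop = FALSE]
  rownames(exprs) <- genes
  structure(list(
    exprs = exprs,
    samples = samples,
    probes = data.frame(gene = unname(genes), probe_id = rep_probe,
                        stringsAsFactors = FALSE)
  ), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples (%d missing values)\n",
              nrow(x$exprs), ncol(x$exprs), sum(is.na(x$exprs))))
  invisible(x)
}

.condition_of <- function(samples) {
  interaction(samples$stage, samples$treatment, drop = TRUE)
}

#' Impute missing expression values within condition groups
#'
#' Replaces each missing entry by the median of the observed replicates of
#' the same condition (stage x treatment); when a condition has no observed
#' replicate for a gene, the gene's row median is used. Observed entries are
#' never altered. This is a robust, outlier-insensitive imputer; it is the
#' package default and can be swapped for any function with the same
#' signature.
#'
#' @param es an `expr_set` (or a plain matrix plus `samples`).
#' @param samples sample metadata when `es` is a matrix.
#' @return the input with all missing values filled in.
#' @export
impute_missing <- function(es, samples = NULL) {
  x <- if (inherits(es, "expr_set")) es$exprs else es
  samples <- if (inherits(es, "expr_set")) es$samples else samples
  if (!anyNA(x)) return(es)
  bad <- rowSums(!is.na(x)) == 0L
  if (any(bad))
    .stopf("%d gene(s) have no observed value; filter them upstream (e.g. %s)",
           sum(bad), rownames(x)[which(bad)[1L]])
  condition <- .condition_of(samples)
  for (cc in levels(condition)) {
    cols <- which(condition == cc)
    sub <- x[, cols, drop = FALSE]
    miss <- which(is.na(sub), arr.ind = TRUE)
    if (!nrow(miss)) next
    med <- apply(sub, 1L, stats::median, na.rm = TRUE)
    rowmed <- apply(x, 1L, stats::median, na.rm = TRUE)
    fill <- ifelse(is.nan(med) | is.na(med), rowmed, med)
    sub[miss] <- fill[miss[, 1L]]
    x[, cols] <- sub
  }
  if (inherits(es, "expr_set")) { es$exprs <- x; es } else x
}

#' Permutation test for global distribution differences across groups
#'
#' Tests whether the sample-level signal distributions differ between
#' condition groups, deciding between global (full quantile) and group-aware
#' normalization. The statistic is a quantile ANOVA F-ratio: each sample is
#' reduced to its sorted value vector, and between-group variability of
#' these quantile vectors is compared with within-group variability. The
#' p-value comes from permuting group labels.
#'
#' @param es an `expr_set` or numeric matrix (no missing values).
#' @param groups group label per sample (defaults to stage x treatment).
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return list with `statistic`, `p.value`, `n_perm`.
#' @export
group_distribution_test <- function(es, groups = NULL, n_perm = 1000, seed = 1L) {
  x <- if (inherits(es, "expr_set")) es$exprs else es
  groups <- groups %||% (if (inherits(es, "expr_set")) .condition_of(es$samples) else NULL)
  if (is.null(groups)) .stopf("'groups' is required for a plain matrix")
  groups <- factor(groups)
  if (nlevels(groups) < 2L) .stopf("need at least 2 groups")
  if (any(table(groups) < 2L)) .stopf("every group needs at least 2 samples")
  if (n_perm < 100) .warnf("n_perm < 100 gives a very coarse permutation p-value")
  if (anyNA(x)) .stopf("impute missing values first")

  q <- apply(x, 2L, sort)             # quantile vector per sample
  n <- ncol(q); k <- nlevels(groups)
  fstat <- function(g) {
    gm <- rowMeans(q)
    ssb <- 0; ssw <- 0
    for (lev in levels(g)) {
      cols <- which(g == lev)
      cm <- rowMeans(q[, cols, drop = FALSE])
      ssb <- ssb + length(cols) * sum((cm - gm)^2)
      ssw <- ssw + sum((q[, cols, drop = FALSE] - cm)^2)
    }
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  obs <- fstat(groups)
  perm <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(b) fstat(sample(groups)), 0)
  })
  list(statistic = obs,
       p.value = (1 + sum(perm >= obs)) / (n_perm + 1),
       n_perm = n_perm)
}

#' Smooth (group-aware) quantile normalization
#'
#' Normalizes each sample toward a convex combination of the overall
#' reference quantiles and its group's reference quantiles. For quantile
#' `k`, the weight on the overall reference is `w_k = 1 - SSB_k / SST_k`
#' (between-group over total variability of the k-th quantile across
#' samples), median-smoothed along k and clipped to `[0, 1]`. When groups
#' are draws from one distribution, `w -> 1` and the result approaches full
#' quantile normalization; genuine group-level distributional differences
#' keep weight on the group reference and are preserved. Within-sample rank
#' order is preserved exactly. A group holding a single sample has group
#' quantiles equal to that sample itself.
#'
#' @param es an `expr_set` or numeric matrix without missing values.
#' @param groups group label per sample (defaults to stage x treatment).
#' @param window fraction of the quantile index used as the running-median
#'   smoothing window.
#' @return the input with normalized values.
#' @export
qsmooth_normalize <- function(es, groups = NULL, window = 0.05) {
  x <- if (inherits(es, "expr_set")) es$exprs else es
  groups <- groups %||% (if (inherits(es, "expr_set")) .condition_of(es$samples) else NULL)
  if (is.null(groups)) .stopf("'groups' is required for a plain matrix")
  groups <- factor(groups)
  if (anyNA(x)) .stopf("impute missing values first")

  n <- ncol(x); m <- nrow(x)
  q <- apply(x, 2L, sort)
  qbar <- rowMeans(q)
  qgrp <- vapply(levels(groups), function(lev)
    rowMeans(q[, groups == lev, drop = FALSE]), numeric(m))

  sst <- rowSums((q - qbar)^2)
  ssb <- rowSums(vapply(levels(groups), function(lev)
    sum(groups == lev) * (qgrp[, lev] - qbar)^2, numeric(m)))
  w <- ifelse(sst > 0, 1 - ssb / sst, 1)
  w <- pmin(pmax(w, 0), 1)
  if (m >= 3L) {
    k <- max(3L, floor(window * m))
    if (k %% 2L == 0L) k <- k + 1L
    if (k <= m) w <- stats::runmed(w, k, endrule = "median")
    w <- pmin(pmax(w, 0), 1)
  }

  out <- x
  for (j in seq_len(n)) {
    target <- w * qbar + (1 - w) * qgrp[, as.character(groups[j])]
    o <- order(x[, j])
    out[o, j] <- target
  }
  if (inherits(es, "expr_set")) { es$exprs <- out; es } else out
}

#' Principal component analysis of the expression matrix
#'
#' Gene-centered SVD-based PCA of the samples. Loadings are the orthonormal
#' gene-space directions; scores are the sample coordinates; the explained
#' variance fractions are computed from the singular values. Component signs
#' are fixed so each loading's largest-magnitude entry is positive.
#'
#' @param es an `expr_set` or numeric matrix (genes x samples).
#' @param n_components number of components to keep (default: all).
#' @return an object of class `pca_result`: list with `scores` (samples x
#'   components), `loadings` (genes x components), `variance_explained`.
#' @export
run_pca <- function(es, n_components = NULL) {
  x <- if (inherits(es, "expr_set")) es$exprs else es
  if (anyNA(x)) .stopf("impute missing values first")
  max_k <- min(dim(x))
  n_components <- n_components %||% max_k
  if (n_components <= 0) .stopf("'n_components' must be positive")
  if (n_components > max_k)
    .stopf("'n_components' cannot exceed min(genes, samples) = %d", max_k)
  p <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  k <- seq_len(n_components)
  flip <- vapply(k, function(j) {
    v <- p$rotation[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, 0)
  structure(list(
    scores = sweep(p$x[, k, drop = FALSE], 2L, flip, `*`),
    loadings = sweep(p$rotation[, k, drop = FALSE], 2L, flip, `*`),
    variance_explained = ve[k]
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d components; variance explained: %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = " ")))
  invisible(x)
}
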