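# Independent brute-force oracles used to validate the statistical kernels.

# Two-sided Fisher exact p by enumeration over all 2x2 tables with the
# observed margins: sum of probabilities of tables no more probable than the
# observed one (with the same relative-error guard R uses).
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
  }, 0)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric P(X >= k) by direct enumeration.
oracle_hyper_upper <- function(k, K, N, n) {
  xs <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(vapply(xs, function(x)
    choose(K, x) * choose(N - K, n - x) / choose(N, n), 0))
}

# Brute-force Degree / MNC / DMNC / MCC from an adjacency matrix (n <= 8):
# neighbour components by DFS, maximal cliques by subset enumeration.
oracle_centralities <- function(adj, eps = 1.7) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  subsets <- lapply(seq_len(2^n - 1), function(mask)
    which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0))
  is_clique <- vapply(subsets, function(s) {
    if (length(s) < 2) return(FALSE)
    all(adj[s, s][upper.tri(diag(length(s)))] == 1)
  }, TRUE)
  cl_sets <- subsets[is_clique]
  maximal <- vapply(seq_along(cl_sets), function(i) {
    s <- cl_sets[[i]]
    !any(vapply(cl_sets, function(t)
      length(t) > length(s) && all(s %in% t), TRUE))
  }, TRUE)
  max_cliques <- cl_sets[maximal]

  comp_of <- function(s) {             # connected components within subset s
    remaining <- s; comps <- list()
    while (length(remaining)) {
      stack <- remaining[1]; comp <- integer(0)
      while (length(stack)) {
        v <- stack[[1]]; stack <- stack[-1]
        if (v %in% comp) next
        comp <- c(comp, v)
        stack <- c(stack, intersect(which(adj[v, ] == 1), remaining))
      }
      comps[[length(comps) + 1]] <- comp
      remaining <- setdiff(remaining, comp)
    }
    comps
  }

  res <- data.frame(node = nodes, degree = 0, mnc = 0, dmnc = 0, mcc = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    res$degree[i] <- length(nb)
    if (length(nb)) {
      comps <- comp_of(nb)
      sizes <- lengths(comps)
      big <- comps[[which.max(sizes)]]
      res$mnc[i] <- length(big)
      e_big <- sum(adj[big, big]) / 2
      res$dmnc[i] <- e_big / length(big)^eps
    }
    mine <- Filter(function(s) i %in% s, max_cliques)
    res$mcc[i] <- sum(vapply(mine, function(s) factorial(length(s) - 1), 0))
  }
  res
}

# Direct O(N) running-sum enrichment score (full cumulative walk).
oracle_es <- function(scores_sorted_desc, hit, weight_exp = 0) {
  N <- length(hit)
  w <- abs(scores_sorted_desc)^weight_exp
  w[!hit] <- 0
  if (sum(w) == 0) w[hit] <- 1
  inc <- ifelse(hit, w / sum(w), -1 / (N - sum(hit)))
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

# Binomial-tail beta values of robust rank aggregation.
oracle_rra_beta <- function(r_sorted, L) {
  vapply(seq_len(L), function(k) {
    sum(vapply(k:L, function(j)
      choose(L, j) * r_sorted[k]^j * (1 - r_sorted[k])^(L - j), 0))
  }, 0)
}

# Hand step-up Benjamini-Hochberg.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  adj[o] <- rev(cummin(rev(pmin(sorted, 1))))
  adj
}

# Greedy Ward minimum-variance merging: at each step merge the pair of
# clusters with the smallest increase in total within-cluster sum of squares.
# Returns the partition (membership vector) after each merge.
oracle_ward_partitions <- function(x) {
  clusters <- as.list(seq_len(nrow(x)))
  partitions <- list()
  ess <- function(rows) {
    if (length(rows) == 1) return(0)
    sum(scale(x[rows, , drop = FALSE], scale = FALSE)^2)
  }
  while (length(clusters) > 1) {
    best <- NULL; best_cost <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in seq(i + 1, length(clusters))) {
        cost <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (cost < best_cost) { best_cost <- cost; best <- c(i, j) }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    mem <- integer(nrow(x))
    for (k in seq_along(clusters)) mem[clusters[[k]]] <- k
    partitions[[length(partitions) + 1]] <- mem
  }
  partitions
}

# Random simple graph on n named nodes as an adjacency matrix.
random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(letters[seq_len(n)], letters[seq_len(n)])
  adj
}

adjacency_to_edges <- function(adj) {
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  data.frame(gene_a = rownames(adj)[idx[, 1]],
             gene_b = rownames(adj)[idx[, 2]],
             weight = 1, stringsAsFactors = FALSE)
}
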