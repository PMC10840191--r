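#' Build a gene-interaction graph from a weighted edge list
#'
#' @param edges data frame with columns `gene_a`, `gene_b`, `weight`
#'   (confidence in (0, 1]). Self-loops and duplicate pairs are rejected.
#' @param min_weight optional confidence filter: edges below it are dropped.
#' @return an undirected `igraph` graph.
#' @export
as_gene_network <- function(edges, min_weight = 0) {
  need <- c("gene_a", "gene_b", "weight")
  if (!all(need %in% names(edges)))
    .stopf("'edges' must have columns: %s", paste(need, collapse = ", "))
  if (any(edges$gene_a == edges$gene_b)) .stopf("self-loops are not allowed")
  if (any(edges$weight <= 0 | edges$weight > 1))
    .stopf("edge weights must lie in (0, 1]")
  key <- paste(pmin(edges$gene_a, edges$gene_b), pmax(edges$gene_a, edges$gene_b))
  if (anyDuplicated(key)) .stopf("duplicate edges are not allowed")
  edges <- edges[edges$weight >= min_weight, , drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

.density_times_size <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  2 * igraph::ecount(g) / (n - 1)       # = density * n
}

# MCODE node weight: the core-clustering coefficient (density of the highest
# k-core of the closed neighbourhood) times that core number.
.mcode_weights <- function(g, degree_cutoff) {
  deg <- igraph::degree(g)
  vapply(igraph::V(g)$name, function(v) {
    if (deg[[v]] < degree_cutoff) return(0)
    nb <- c(v, igraph::neighbors(g, v)$name)
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    kc <- igraph::induced_subgraph(sub, names(core)[core >= kmax])
    igraph::edge_density(kc) * kmax
  }, 0)
}

#' MCODE-style dense module detection
#'
#' Finds locally dense modules in an interaction graph following the
#' molecular-complex-detection scheme: each node is weighted by the density
#' of the highest k-core of its closed neighbourhood times that core
#' number; modules grow greedily from the highest-weight unused seed,
#' admitting neighbours whose weight reaches `(1 - node_score_cutoff)`
#' times the seed weight; modules failing to contain a `k_core`-core are
#' discarded, and (with `haircut`) singly-connected nodes are trimmed.
#' Nodes belong to at most one module. Modules are scored density x size
#' and returned best first. Edge weights are not used by the algorithm
#' (apply a confidence filter in [as_gene_network()] instead).
#'
#' @param g an `igraph` graph (or edge data frame).
#' @param node_score_cutoff expansion tolerance below the seed weight.
#' @param k_core minimum core a module must contain.
#' @param degree_cutoff nodes below this degree get weight 0.
#' @param haircut trim singly-connected module nodes.
#' @param max_depth maximum expansion depth from the seed.
#' @return list of modules, each a list with `genes`, `score`, `n_nodes`,
#'   `density`, sorted by decreasing score.
#' @export
detect_modules <- function(g, node_score_cutoff = 0.2, k_core = 2L,
                           degree_cutoff = 2L, haircut = TRUE,
                           max_depth = 100L) {
  if (is.data.frame(g)) g <- as_gene_network(g)
  if (igraph::vcount(g) == 0L) return(list())
  w <- .mcode_weights(g, degree_cutoff)
  seen <- character(0)
  modules <- list()
  for (seed in names(sort(w, decreasing = TRUE))) {
    if (w[[seed]] <= 0 || seed %in% seen) next
    thresh <- w[[seed]] * (1 - node_score_cutoff)
    members <- seed
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < max_depth) {
      nxt <- character(0)
      for (v in frontier) {
        for (u in igraph::neighbors(g, v)$name) {
          if (u %in% members || u %in% seen) next
          if (w[[u]] >= thresh) {
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    sub <- igraph::induced_subgraph(g, members)
    if (max(igraph::coreness(sub)) < k_core) next
    if (haircut) {
      keep <- igraph::V(sub)$name[igraph::degree(sub) >= 2L]
      if (length(keep) < 2L) next
      sub <- igraph::induced_subgraph(sub, keep)
    }
    genes <- sort(igraph::V(sub)$name)
    seen <- c(seen, genes)
    modules[[length(modules) + 1L]] <- list(
      genes = genes,
      score = .density_times_size(sub),
      n_nodes = length(genes),
      density = igraph::edge_density(sub)
    )
  }
  ord <- order(-vapply(modules, `[[`, 0, "score"),
               -vapply(modules, `[[`, 0L, "n_nodes"))
  modules[ord]
}

#' Local node-importance centralities
#'
#' Computes, per node: `degree`; `mnc`, the size of the largest connected
#' component of the subgraph induced by the node's neighbours; `dmnc`, the
#' edge count of that component divided by its node count to the power
#' `eps`; and `mcc`, the sum over maximal cliques containing the node of
#' `(clique size - 1)!` (which equals the degree when the node participates
#' only in 2-cliques). Isolated nodes score 0 everywhere.
#'
#' @param g an `igraph` graph (or edge data frame); at least 2 nodes.
#' @param eps DMNC exponent.
#' @return data frame `node`, `degree`, `mnc`, `dmnc`, `mcc`.
#' @export
node_centralities <- function(g, eps = 1.7) {
  if (is.data.frame(g)) g <- as_gene_network(g)
  if (igraph::vcount(g) < 2L) .stopf("need at least 2 nodes")
  nodes <- igraph::V(g)$name
  deg <- igraph::degree(g)

  cliques <- igraph::max_cliques(g, min = 2L)
  mcc <- stats::setNames(rep(0, length(nodes)), nodes)
  for (cl in cliques) {
    nm <- cl$name
    mcc[nm] <- mcc[nm] + factorial(length(nm) - 1L)
  }

  mnc <- dmnc <- stats::setNames(rep(0, length(nodes)), nodes)
  for (v in nodes) {
    nb <- igraph::neighbors(g, v)$name
    if (!length(nb)) next
    sub <- igraph::induced_subgraph(g, nb)
    comp <- igraph::components(sub)
    big <- which.max(comp$csize)
    mem <- names(comp$membership)[comp$membership == big]
    mnc[v] <- length(mem)
    cs <- igraph::induced_subgraph(sub, mem)
    dmnc[v] <- igraph::ecount(cs) / igraph::vcount(cs)^eps
  }
  data.frame(node = nodes, degree = unname(deg[nodes]), mnc = unname(mnc),
             dmnc = unname(dmnc), mcc = unname(mcc),
             row.names = NULL, stringsAsFactors = FALSE)
}

# rho per row of a normalized-rank matrix (rows = items, cols = lists)
.rra_rho <- function(rmat) {
  L <- ncol(rmat)
  vapply(seq_len(nrow(rmat)), function(i) {
    r <- sort(rmat[i, ])
    min(vapply(seq_len(L), function(k)
      stats::pbinom(k - 1, L, r[k], lower.tail = FALSE), 0))
  }, 0)
}

#' Robust rank aggregation of ranked lists
#'
#' For each item, the normalized rank vector `r` (position / list length)
#' is sorted ascending and `beta_k = P(Binomial(L, r_k) >= k)` computed for
#' each of the `L` lists; `rho = min_k beta_k` and the final score is the
#' Bonferroni-corrected `min(1, rho * L)`. Smaller scores mean the item
#' ranks consistently high across lists.
#'
#' @param rank_lists list of character vectors, each a complete ranking of
#'   the same item universe (best first).
#' @return data frame `item`, `rho`, `score`, sorted ascending by score
#'   (ties by item id).
#' @export
robust_rank_aggregate <- function(rank_lists) {
  if (length(rank_lists) < 1L) .stopf("need at least one ranked list")
  items <- sort(rank_lists[[1L]])
  for (l in rank_lists) {
    if (!setequal(l, items) || length(l) != length(items))
      .stopf("all lists must be permutations of the same item universe")
  }
  L <- length(rank_lists)
  n <- length(items)
  rmat <- vapply(rank_lists, function(l) match(items, l) / n, numeric(n))
  rho <- .rra_rho(matrix(rmat, nrow = n))
  out <- data.frame(item = items, rho = rho, score = pmin(1, rho * L),
                    stringsAsFactors = FALSE)
  out[order(out$score, out$item), , drop = FALSE]
}

#' Hub genes of a module by aggregated centrality rank
#'
#' Ranks the module's nodes under each centrality (higher is better; tied
#' centrality values receive tied ranks) and aggregates the four normalized
#' rank vectors with the robust-rank-aggregation rho score, so nodes with
#' identical centrality profiles share a final rank. The top `n_hubs`
#' (default two) are flagged as hubs; ordering ties are broken by degree
#' (descending) then node id.
#'
#' @param centralities data frame from [node_centralities()].
#' @param n_hubs number of hubs to flag.
#' @return data frame `node`, `rho`, `score`, `final_rank`, `hub`.
#' @export
pick_hub_genes <- function(centralities, n_hubs = 2L) {
  if (nrow(centralities) == 1L)
    return(data.frame(node = centralities$node, rho = 1, score = 1,
                      final_rank = 1L, hub = TRUE, stringsAsFactors = FALSE))
  n <- nrow(centralities)
  rmat <- vapply(c("degree", "mnc", "dmnc", "mcc"), function(m)
    rank(-centralities[[m]], ties.method = "min") / n, numeric(n))
  rho <- .rra_rho(matrix(rmat, nrow = n))
  score <- pmin(1, rho * 4)
  ord <- order(score, -centralities$degree, centralities$node)
  out <- data.frame(node = centralities$node[ord], rho = rho[ord],
                    score = score[ord],
                    final_rank = as.integer(rank(score, ties.method = "min"))[ord],
                    hub = seq_len(n) <= min(n_hubs, n),
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}
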