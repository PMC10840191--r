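test_that("gene-network construction enforces simple-graph invariants", {
  ok <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                   weight = c(0.5, 0.9))
  g <- as_gene_network(ok)
  expect_equal(igraph::vcount(g), 3)
  expect_error(as_gene_network(
    data.frame(gene_a = "a", gene_b = "a", weight = 0.5)), "self-loops")
  expect_error(as_gene_network(
    data.frame(gene_a = c("a", "b"), gene_b = c("b", "a"),
               weight = c(0.5, 0.6))), "duplicate")
  expect_error(as_gene_network(
    data.frame(gene_a = "a", gene_b = "b", weight = 1.5)), "weights")
})

test_that("module detection scores a clique exactly and ignores isolated nodes", {
  k5 <- t(combn(paste0("k", 1:5), 2))
  edges <- data.frame(gene_a = k5[, 1], gene_b = k5[, 2], weight = 1)
  g <- as_gene_network(edges)
  g <- igraph::add_vertices(g, 10, name = paste0("iso", 1:10))
  mods <- detect_modules(g)
  expect_length(mods, 1)
  expect_setequal(mods[[1]]$genes, paste0("k", 1:5))
  expect_equal(mods[[1]]$score, 5)
  expect_equal(mods[[1]]$density, 1)
})

test_that("acyclic graphs produce no dense module (score bound 2)", {
  # exhaustive check on an 8-node tree: every connected subgraph scores <= 2
  tree <- data.frame(gene_a = c("a", "a", "b", "b", "c", "f", "f"),
                     gene_b = c("b", "c", "d", "e", "f", "g", "h"),
                     weight = 1)
  g <- as_gene_network(tree)
  nodes <- igraph::V(g)$name
  for (mask in seq_len(2^8 - 1)) {
    s <- nodes[bitwAnd(mask, 2^(0:7)) > 0]
    if (length(s) < 2) next
    sub <- igraph::induced_subgraph(g, s)
    if (igraph::components(sub)$no > 1) next
    score <- 2 * igraph::ecount(sub) / (igraph::vcount(sub) - 1)
    expect_lte(score, 2 + 1e-12)
  }
  mods <- detect_modules(g)
  expect_true(all(vapply(mods, `[[`, 0, "score") <= 2))
})

test_that("planted modules are recovered with high node overlap", {
  # planted 10-node clique over a p = 0.01 background
  cfg <- small_config(seed = 51L, ppi_module_sizes = 10L,
                      ppi_module_density = 1)
  net <- make_ppi_network(cfg)
  mods <- detect_modules(as_gene_network(net$edges))
  overlaps <- vapply(mods, function(m)
    length(intersect(m$genes, net$modules[[1]])) / 10, 0)
  expect_gte(max(overlaps), 0.9)

  # near-cliques (density 0.9) still dominate their best-matching module
  cfg2 <- small_config(seed = 51L, ppi_module_sizes = c(10L, 12L))
  net2 <- make_ppi_network(cfg2)
  mods2 <- detect_modules(as_gene_network(net2$edges))
  expect_gte(length(mods2), 2)
  for (planted in net2$modules) {
    overlaps <- vapply(mods2, function(m)
      length(intersect(m$genes, planted)) / length(planted), 0)
    expect_gte(max(overlaps), 0.7)
  }
})

test_that("centralities match hand-enumerated values on canonical graphs", {
  # triangle
  tri <- node_centralities(data.frame(gene_a = c("a", "a", "b"),
                                      gene_b = c("b", "c", "c"), weight = 1))
  expect_equal(tri$degree, rep(2, 3))
  expect_equal(tri$mnc, rep(2, 3))      # the two neighbours are connected
  expect_equal(tri$mcc, rep(2, 3))      # (3-1)! for the one maximal clique
  # path a-b-c: centre has disconnected neighbours, only 2-cliques
  path <- node_centralities(data.frame(gene_a = c("a", "b"),
                                       gene_b = c("b", "c"), weight = 1))
  b <- path[path$node == "b", ]
  expect_equal(b$mnc, 1)
  expect_equal(b$mcc, 2)                # equals its degree
  # star K1,4 centre
  star <- node_centralities(data.frame(gene_a = "hub",
                                       gene_b = paste0("l", 1:4), weight = 1))
  hub <- star[star$node == "hub", ]
  expect_equal(hub$degree, 4)
  expect_equal(hub$mnc, 1)
  expect_equal(hub$dmnc, 0)
  expect_equal(hub$mcc, 4)
})

test_that("centralities equal the brute-force oracle on small graphs", {
  # exhaustive over all 64 graphs on 4 nodes
  for (mask in 0:63) {
    adj <- matrix(0L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    bits <- as.integer(intToBits(mask))[1:6]
    adj[upper.tri(adj)] <- bits
    adj <- adj + t(adj)
    if (sum(adj) == 0) next
    edges <- adjacency_to_edges(adj)
    got <- node_centralities(edges)
    want <- oracle_centralities(adj)
    want <- want[match(got$node, want$node), ]
    expect_equal(got$degree, want$degree)
    expect_equal(got$mnc, want$mnc)
    expect_equal(got$dmnc, want$dmnc, tolerance = 1e-12)
    expect_equal(got$mcc, want$mcc)
  }
  # randomized graphs on 5-8 nodes
  withr::with_seed(52, {
    for (i in 1:150) {
      n <- sample(5:8, 1)
      adj <- random_adjacency(n, runif(1, 0.2, 0.8))
      if (sum(adj) == 0) next
      got <- node_centralities(adjacency_to_edges(adj))
      want <- oracle_centralities(adj)
      want <- want[match(got$node, want$node), ]
      expect_equal(got$degree, want$degree)
      expect_equal(got$mnc, want$mnc)
      expect_equal(got$dmnc, want$dmnc, tolerance = 1e-12)
      expect_equal(got$mcc, want$mcc)
    }
  })
})

test_that("robust rank aggregation reproduces the binomial-tail worked example", {
  items <- paste0("i", 1:10)
  lists <- list(c("i1", items[-1]),
                c("i1", sample(items[-1])),
                c("i1", rev(items[-1])))
  res <- robust_rank_aggregate(lists)
  top <- res[res$item == "i1", ]
  beta <- oracle_rra_beta(rep(0.1, 3), 3)
  expect_equal(beta, c(1 - 0.9^3, 3 * 0.01 * 0.9 + 0.001, 0.001),
               tolerance = 1e-12)
  expect_equal(top$rho, min(beta), tolerance = 1e-12)
  expect_equal(top$score, 3 * min(beta), tolerance = 1e-12)

  # item ranked last everywhere: rho ~ 1, score 1
  lists_last <- lapply(1:3, function(i) c(sample(items[-10]), "i10"))
  worst <- robust_rank_aggregate(lists_last)
  expect_equal(worst$score[worst$item == "i10"], 1)

  # single list reproduces its own order
  single <- robust_rank_aggregate(list(items))
  expect_equal(single$item, items)
  expect_equal(single$score, pmin(1, seq(0.1, 1, by = 0.1)), tolerance = 1e-12)

  # rho/beta against the direct-summation oracle on random rank vectors
  withr::with_seed(53, {
    for (i in 1:20) {
      L <- sample(2:5, 1)
      lists_r <- lapply(seq_len(L), function(j) sample(items))
      res <- robust_rank_aggregate(lists_r)
      for (it in c("i1", "i5")) {
        r <- sort(vapply(lists_r, function(l) match(it, l) / 10, 0))
        expect_equal(res$rho[res$item == it],
                     min(oracle_rra_beta(r, L)), tolerance = 1e-12)
      }
    }
  })
  expect_error(robust_rank_aggregate(list(items, items[-1])), "universe")
})

test_that("hub picking flags the top two with ties resolved lexicographically", {
  # K5: every node ties; hubs are the two smallest ids at shared rank 1
  k5 <- t(combn(paste0("k", 1:5), 2))
  cen <- node_centralities(data.frame(gene_a = k5[, 1], gene_b = k5[, 2],
                                      weight = 1))
  hubs <- pick_hub_genes(cen)
  expect_equal(hubs$node[hubs$hub], c("k1", "k2"))
  expect_true(all(hubs$final_rank == 1))

  # hub-and-spoke plus a triangle: the dominant centre is a hub
  edges <- data.frame(
    gene_a = c(rep("hub", 5), "s1", "s2", "s1"),
    gene_b = c(paste0("s", 1:5), "s2", "s3", "s3"),
    weight = 1)
  cen2 <- node_centralities(edges)
  hubs2 <- pick_hub_genes(cen2)
  expect_true("hub" %in% hubs2$node[hubs2$hub])
  expect_equal(sum(hubs2$hub), 2)
  # single-node module degenerates gracefully
  one <- pick_hub_genes(data.frame(node = "solo", degree = 0, mnc = 0,
                                   dmnc = 0, mcc = 0))
  expect_true(one$hub)
})
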