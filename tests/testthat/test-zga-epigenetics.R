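test_that("fuzzy c-means memberships are proper and the objective decreases", {
  withr::with_seed(61, {
    x <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
               matrix(rnorm(40, 4, 0.2), 20, 2))
    rownames(x) <- sprintf("g%02d", 1:40)
  })
  fit <- fuzzy_cmeans(x, c = 2, seed = 3)
  expect_true(all(abs(rowSums(fit$membership) - 1) < 1e-9))
  expect_true(all(fit$membership >= 0 & fit$membership <= 1))
  expect_true(all(diff(fit$objective) <= 1e-8))
  expect_true(fit$converged)
  # well-separated groups -> confident memberships
  hard <- max.col(fit$membership)
  expect_true(all(fit$membership[cbind(1:40, hard)] >= 0.9))
  expect_equal(length(unique(hard[1:20])), 1)
  expect_false(hard[1] == hard[40])
  # determinism
  expect_identical(fit, fuzzy_cmeans(x, c = 2, seed = 3))
  expect_error(fuzzy_cmeans(x, c = 40), "smaller")
})

test_that("in-package fuzzy c-means agrees with an independent implementation", {
  withr::with_seed(62, {
    x <- rbind(matrix(rnorm(60, 0, 0.3), 30, 2),
               matrix(rnorm(60, 5, 0.3), 30, 2))
    rownames(x) <- sprintf("g%02d", 1:60)
  })
  fit <- fuzzy_cmeans(x, c = 2, seed = 1)
  ref <- withr::with_seed(2, e1071::cmeans(x, centers = 2, m = 2))
  # same hard partition (up to label swap) and matching converged objective
  ours <- max.col(fit$membership)
  theirs <- as.integer(ref$cluster)
  expect_equal(length(unique(paste(ours, theirs))), 2)
  obj_ref <- sum(ref$membership^2 * as.matrix(dist(rbind(ref$centers, x)))[
    -(1:2), 1:2]^2)
  expect_equal(min(fit$objective), obj_ref, tolerance = 1e-4)
})

test_that("wave classification recovers planted stage-profile labels", {
  cfg <- synth_config(n_genes = 600, missing_rate = 0.02, seed = 63L)
  pd <- make_probe_data(cfg)
  es <- impute_missing(filter_and_collapse(pd$tables, pd$samples))
  esn <- qsmooth_normalize(es)
  ctrl <- esn$samples$treatment == "control"
  sm <- vapply(cfg$stages, function(s)
    rowMeans(esn$exprs[, ctrl & esn$samples$stage == s, drop = FALSE]),
    numeric(nrow(esn$exprs)))
  wc <- classify_waves(sm, c = 8, seed = 64)
  expect_true(all(abs(rowSums(attr(wc, "membership")) - 1) < 1e-9))
  truth <- pd$truth$wave[wc$gene]
  for (w in c("maternal", "minor_zga", "major_zga", "mga")) {
    expect_gte(mean(wc$wave[truth == w] == w), 0.9)
  }
  # manual cluster->wave map is honoured
  map <- attr(wc, "cluster_wave_map")
  wc2 <- classify_waves(sm, c = 8, cluster_wave_map = map, seed = 64)
  expect_equal(wc2$wave, wc$wave)
})

test_that("Fisher contingency p-values match exhaustive enumeration", {
  withr::with_seed(65, {
    for (i in 1:15) {
      n1 <- sample(20:100, 1); n2 <- sample(20:100, 1)
      up <- sprintf("u%03d", seq_len(n1))
      down <- sprintf("d%03d", seq_len(n2))
      wave <- c(sample(up, sample(0:n1, 1)), sample(down, sample(0:n2, 1)))
      ct <- zga_contingency_test(list(up = up, down = down), wave)
      expect_equal(ct$p_value,
                   oracle_fisher_two_sided(ct$a, ct$b, ct$c, ct$d),
                   tolerance = 1e-9)
      # invariance to transposing the table / swapping the roles
      ct_sw <- zga_contingency_test(list(up = down, down = up), wave)
      expect_equal(ct_sw$p_value, ct$p_value, tolerance = 1e-12)
    }
  })
  # identical rows: no association
  ct0 <- zga_contingency_test(list(up = c("a1", "a2", "a3", "a4"),
                                   down = c("b1", "b2", "b3", "b4")),
                              c("a1", "a2", "b1", "b2"))
  expect_equal(ct0$p_value, 1)
  expect_equal(ct0$odds_ratio, 1)
  expect_error(zga_contingency_test(list(up = character(0), down = "x"), "x"),
               "'up' is empty")
})

test_that("the group-total table construction reproduces k-out-of-n tests", {
  up <- sprintf("u%03d", 1:951)
  down <- sprintf("d%03d", 1:828)
  wave <- c(up[1:105], down[1:86])
  ct <- zga_contingency_test(list(up = up, down = down), wave,
                             table_style = "group_total")
  expect_equal(ct$b, 951)
  expect_equal(ct$d, 828)
  expect_equal(ct$p_value,
               fisher.test(matrix(c(105, 951, 86, 828), 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
})

test_that("promoter scores sum interval scores with overlap-fraction weights", {
  model <- data.frame(gene = c("gp", "gm"), chrom = c("chr1", "chr2"),
                      strand = c("+", "-"), tss = c(10000L, 50000L),
                      stringsAsFactors = FALSE)
  track <- data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr3"),
    start = c(9500L, 10800L, 49500L, 100L),
    end   = c(9700L, 11200L, 49900L, 200L),
    name  = c("in", "half", "minus", "elsewhere"),
    score = c(10, 10, 4, 99), stringsAsFactors = FALSE)
  s <- promoter_feature_scores(track, model, window = c(-1000, 1000))
  # fully inside: 10; half of [10800,11200) overlaps [9000,11000): +5
  expect_equal(unname(s["gp"]), 15)
  expect_equal(unname(s["gm"]), 4)
  # full-score mode counts any overlap completely
  sf <- promoter_feature_scores(track, model, mode = "full")
  expect_equal(unname(sf["gp"]), 20)

  # minus-strand gene with an asymmetric window: genomic [tss-100, tss+200)
  track2 <- data.frame(chrom = "chr2", start = 50100L, end = 50200L,
                       name = "x", score = 7, stringsAsFactors = FALSE)
  s2 <- promoter_feature_scores(track2, model, window = c(-200, 100))
  expect_equal(unname(s2["gm"]), 7)
  track3 <- data.frame(chrom = "chr2", start = 49700L, end = 49800L,
                       name = "x", score = 7, stringsAsFactors = FALSE)
  expect_equal(unname(promoter_feature_scores(track3, model,
                                              window = c(-200, 100))["gm"]), 0)
})

test_that("malformed BED input is rejected with its line number", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\ta\t1", "chr1\t300\t250\tb\t2"), path)
  expect_error(read_bed(path), "line 2")
  writeLines(c("chr1\t100\t200\ta"), path)
  expect_error(read_bed(path), "5 fields")
})

test_that("top-N feature enrichment flags planted marks and only those", {
  cfg <- synth_config(n_genes = 400, seed = 66L,
                      planted_mark_assoc = list(H3K27ac = "up"))
  pd <- make_probe_data(cfg)
  epi <- make_epigenome_tracks(cfg, truth = pd$truth)
  fs <- lapply(epi$tracks, promoter_feature_scores, gene_model = epi$gene_model)
  dt <- pd$truth$deg_table
  deg_sets <- list(up = unique(dt$gene[dt$direction == "up"]),
                   down = unique(dt$gene[dt$direction == "down"]))
  fe <- feature_enrichment(deg_sets, fs, universe = epi$gene_model$gene,
                           top_n = 100)
  expect_true(fe$significant[fe$deg_set == "up" & fe$mark == "H3K27ac"])
  expect_false(any(fe$significant[!(fe$deg_set == "up" & fe$mark == "H3K27ac")]))

  # degenerate overlaps
  uni <- sprintf("g%03d", 1:50)
  scores <- list(m = stats::setNames(seq(50, 1), uni))
  top10 <- uni[1:10]
  fe2 <- feature_enrichment(list(hit = top10, miss = uni[41:50]), scores,
                            uni, top_n = 10)
  expect_equal(fe2$overlap[fe2$deg_set == "hit"], 10)
  expect_equal(fe2$p[fe2$deg_set == "miss"], 1)
  expect_error(feature_enrichment(list(a = "g001"), scores, uni, top_n = 60),
               "universe")
})

test_that("unplanted configurations stay quiet in the contingency stages", {
  # Fisher on random DEG/wave splits: significant in at most 5% of seeds
  fisher_hits <- vapply(1:60, function(s) {
    withr::with_seed(7000 + s, {
      genes <- sprintf("g%03d", 1:300)
      up <- sample(genes, 60)
      down <- sample(setdiff(genes, up), 60)
      wave <- sample(genes, 50)
    })
    zga_contingency_test(list(up = up, down = down), wave)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(!fisher_hits), 0.95)

  # hypergeometric mark stage without planted associations
  hyper_hits <- vapply(1:40, function(s) {
    cfg <- synth_config(n_genes = 200, seed = 8000 + s)
    pd <- make_probe_data(cfg)
    epi <- make_epigenome_tracks(cfg, truth = pd$truth)
    fs <- lapply(epi$tracks, promoter_feature_scores,
                 gene_model = epi$gene_model)
    dt <- pd$truth$deg_table
    fe <- feature_enrichment(
      list(up = unique(dt$gene[dt$direction == "up"]),
           down = unique(dt$gene[dt$direction == "down"])),
      fs, universe = epi$gene_model$gene, top_n = 60)
    any(fe$significant)
  }, TRUE)
  expect_gte(mean(!hyper_hits), 0.95)
})
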