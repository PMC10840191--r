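# Small in-code fixtures shared across test files.

small_config <- function(seed = 1L, ppi_module_sizes = c(10L), ...) {
  synth_config(n_genes = 300, n_terms = 30, n_planted_terms = 6,
               ppi_module_sizes = ppi_module_sizes, seed = seed, ...)
}

# Tiny probe-table set: 2 conditions x 2 replicates, hand-written flags.
tiny_probe_tables <- function() {
  samples <- data.frame(
    sample = c("s1", "s2", "s3", "s4"),
    stage = c("A", "A", "B", "B"),
    treatment = "control",
    replicate = c(1L, 2L, 1L, 2L),
    stringsAsFactors = FALSE
  )
  ok <- "positive and significant"
  bad <- "not positive and significant"
  mk <- function(sig, flags) {
    data.frame(probe_id = c("p1", "p2", "p3", "p4"),
               gene_symbol = c("gA", "gA", "gB", "gC"),
               signal = sig, flag = flags, stringsAsFactors = FALSE)
  }
  tables <- list(
    s1 = mk(c(500, 800, 100, 50), c(ok, ok, ok, bad)),
    s2 = mk(c(510, 820, 110, 60), c(ok, ok, bad, bad)),
    s3 = mk(c(490, 790, 120, 70), c(bad, ok, ok, bad)),
    s4 = mk(c(505, 805, 130, 80), c(ok, ok, bad, bad))
  )
  list(tables = tables, samples = samples)
}

# Expression fixture with three planted treatment patterns at one stage.
planted_pattern_matrix <- function(n_per = 20, effect = 2, noise = 0.25,
                                   seed = 11L) {
  withr::with_seed(seed, {
    trts <- c("control", "T247", "MGCD0103")
    samples <- expand.grid(replicate = 1:3, treatment = trts,
                           stringsAsFactors = FALSE)
    pat <- rep(c("common", "T247", "MGCD0103"), each = n_per)
    dir <- rep(rep(c(1, -1), length.out = n_per), 3)
    genes <- sprintf("d%03d", seq_along(pat))
    base <- stats::rnorm(length(genes), 8, 1)
    x <- sapply(seq_len(nrow(samples)), function(j) {
      shift <- ifelse(samples$treatment[j] != "control" &
                        (pat == "common" | pat == samples$treatment[j]),
                      dir * effect, 0)
      base + shift + stats::rnorm(length(genes), sd = noise)
    })
    rownames(x) <- genes
    colnames(x) <- sprintf("%s_r%d", samples$treatment, samples$replicate)
    lfc <- cbind(
      T247 = rowMeans(x[, samples$treatment == "T247"]) -
        rowMeans(x[, samples$treatment == "control"]),
      MGCD0103 = rowMeans(x[, samples$treatment == "MGCD0103"]) -
        rowMeans(x[, samples$treatment == "control"])
    )
    list(x = x, lfc = lfc, pattern = stats::setNames(pat, genes),
         samples = samples)
  })
}

# Term fixture: two blocks of terms with high within-block gene overlap.
two_block_terms <- function(n_per_block = 6, seed = 5L) {
  withr::with_seed(seed, {
    core1 <- sprintf("x%02d", 1:20)
    core2 <- sprintf("y%02d", 1:20)
    sets <- c(
      lapply(seq_len(n_per_block), function(i)
        sample(core1, 16)),
      lapply(seq_len(n_per_block), function(i)
        sample(core2, 16))
    )
    ids <- sprintf("T%02d", seq_along(sets))
    names(sets) <- ids
    terms <- data.frame(term_id = ids,
                        name = paste("term", ids),
                        p = stats::runif(length(ids), 1e-6, 1e-3),
                        stringsAsFactors = FALSE)
    list(terms = terms, sets = sets,
         block = rep(c(1L, 2L), each = n_per_block))
  })
}
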