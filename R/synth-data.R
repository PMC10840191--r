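#' Generate probe-level signal tables with planted ground truth
#'
#' Emulates the raw input of a stage-by-treatment microarray study of pooled
#' embryos: one probe table per sample with linear-scale signals and Agilent
#' style detection flags. Gene baselines are drawn on the log2 scale so the
#' linear signals are log-normal; each gene follows its wave's stage-profile
#' template; planted DEGs are shifted by `effect_size` (log2) in treated
#' samples of `deg_stage`; spots are flagged invalid independently with
#' probability `missing_rate`.
#'
#' @param config a [synth_config()] object.
#' @return a list with elements `tables` (named list of probe tables),
#'   `samples` (sample metadata: `sample`, `stage`, `treatment`,
#'   `replicate`), and `truth` (planted ground truth: `deg_table` with one
#'   row per planted gene x affected treatment, `wave` labels per gene,
#'   `pattern` per planted DEG).
#' @export
make_probe_data <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  .with_seed(config$seed, {
    genes <- sprintf("g%05d", seq_len(config$n_genes))
    waves <- names(config$wave_fractions)
    n_wave <- floor(config$wave_fractions * config$n_genes)
    n_wave["other"] <- config$n_genes - sum(n_wave[names(n_wave) != "other"])
    wave <- sample(rep(waves, times = n_wave))
    names(wave) <- genes

    tmpl <- wave_templates(config$stages) * config$wave_amplitude /
      max(abs(wave_templates(config$stages)))
    baseline <- stats::rnorm(config$n_genes, mean = 8, sd = 1.2)
    names(baseline) <- genes

    # planted DEGs: pattern in {common, T247, MGCD0103-like single treatments}
    n_deg <- round(config$deg_fraction * config$n_genes)
    deg_genes <- sample(genes, n_deg)
    trt <- setdiff(config$treatments, "control")
    patterns <- c("common", trt)
    pattern <- sample(rep(patterns, length.out = n_deg))
    direction <- sample(rep(c("up", "down"), length.out = n_deg))
    deg_table <- do.call(rbind, lapply(seq_len(n_deg), function(i) {
      affected <- if (pattern[i] == "common") trt else pattern[i]
      data.frame(gene = deg_genes[i], stage = config$deg_stage,
                 treatment = affected, direction = direction[i],
                 pattern = pattern[i], stringsAsFactors = FALSE)
    }))
    if (n_deg == 0L)
      deg_table <- data.frame(gene = character(), stage = character(),
                              treatment = character(), direction = character(),
                              pattern = character(), stringsAsFactors = FALSE)

    # probe layout: probe 1 of each gene is the brightest (representative)
    n_probes <- sample(seq(config$n_probes_per_gene[1], config$n_probes_per_gene[2]),
                       config$n_genes, replace = TRUE)
    probe_gene <- rep(genes, times = n_probes)
    probe_rank <- unlist(lapply(n_probes, seq_len))
    probe_id <- sprintf("%s_p%d", probe_gene, probe_rank)
    probe_offset <- ifelse(probe_rank == 1L, 0, -stats::runif(length(probe_id), 0.3, 1.5))

    samples <- expand.grid(replicate = seq_len(config$n_replicates),
                           treatment = config$treatments,
                           stage = config$stages,
                           stringsAsFactors = FALSE)[, 3:1]
    samples$sample <- sprintf("%s_%s_r%d", samples$stage, samples$treatment,
                              samples$replicate)
    samples <- samples[c("sample", "stage", "treatment", "replicate")]

    shift <- matrix(0, nrow = config$n_genes,
                    ncol = length(config$treatments),
                    dimnames = list(genes, config$treatments))
    for (i in seq_len(nrow(deg_table))) {
      shift[deg_table$gene[i], deg_table$treatment[i]] <-
        ifelse(deg_table$direction[i] == "up", 1, -1) * config$effect_size
    }

    tables <- stats::setNames(vector("list", nrow(samples)), samples$sample)
    for (j in seq_len(nrow(samples))) {
      st <- samples$stage[j]; tr <- samples$treatment[j]
      mu <- baseline[probe_gene] + probe_offset +
        tmpl[wave[probe_gene], st] +
        if (st == config$deg_stage) shift[probe_gene, tr] else 0
      log2sig <- mu + stats::rnorm(length(probe_id), sd = config$noise_sd)
      invalid <- stats::runif(length(probe_id)) < config$missing_rate
      tables[[j]] <- data.frame(
        probe_id = probe_id,
        gene_symbol = probe_gene,
        signal = 2^log2sig,
        flag = ifelse(invalid, "not positive and significant",
                      "positive and significant"),
        stringsAsFactors = FALSE
      )
    }

    list(tables = tables, samples = samples,
         truth = list(deg_table = deg_table, wave = wave,
                      pattern = stats::setNames(pattern, deg_genes),
                      baseline = baseline))
  })
}

#' Generate a toy ontology with planted enriched terms
#'
#' Builds a directed acyclic is-a hierarchy of terms, each with a name and a
#' multi-word definition drawn from themed controlled vocabularies (so that
#' TF-IDF scoring over definitions and N-gram scoring over names are
#' exercised), and gene annotations that propagate to ancestors. When
#' `query_genes` is supplied, `n_planted_terms` terms draw most of their
#' genes from the query so downstream over-representation recovers them.
#'
#' @param config a [synth_config()] object.
#' @param query_genes optional character vector of genes to plant enrichment
#'   against.
#' @param parents optional named list overriding the generated is-a edges;
#'   checked for cycles.
#' @return an object of class `ontology`: list with `terms` (data frame:
#'   `term_id`, `name`, `definition`, `theme`), `parents`, `genes`
#'   (annotations after ancestor propagation), and `planted` (term ids
#'   planted as enriched).
#' @export
make_ontology <- function(config, query_genes = NULL, parents = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_terms < 2L) .stopf("need at least 2 terms")
  .with_seed(config$seed + 1L, {
    genes <- sprintf("g%05d", seq_len(config$n_genes))
    ids <- sprintf("T%04d", seq_len(config$n_terms))
    themes <- list(
      cell_cycle = c("cell", "cycle", "mitotic", "spindle", "division",
                     "checkpoint", "chromosome", "segregation"),
      rna_splicing = c("rna", "splicing", "spliceosome", "intron", "exon",
                       "transcript", "processing"),
      proteolysis = c("protein", "catabolic", "ubiquitin", "proteasome",
                      "degradation", "ligase"),
      stress_response = c("stress", "apoptotic", "signaling", "reticulum",
                          "damage", "repair", "response"),
      chromatin = c("chromatin", "histone", "acetylation", "methylation",
                    "nucleosome", "remodeling")
    )
    filler <- c("regulation", "positive", "negative", "pathway", "activity",
                "complex", "assembly", "organization", "involved", "during",
                "embryonic", "development", "nuclear", "cytoplasmic")
    theme <- sample(names(themes), config$n_terms, replace = TRUE)
    nm <- vapply(seq_len(config$n_terms), function(i) {
      paste(c(sample(themes[[theme[i]]], 2L), sample(filler, 1L)), collapse = " ")
    }, "")
    def <- vapply(seq_len(config$n_terms), function(i) {
      paste(c(sample(themes[[theme[i]]], 4L, replace = TRUE),
              sample(filler, 4L, replace = TRUE)), collapse = " ")
    }, "")

    if (is.null(parents)) {
      parents <- stats::setNames(vector("list", config$n_terms), ids)
      for (i in seq_along(ids)[-1]) {
        k <- stats::rbinom(1L, 2L, 0.3)
        if (k > 0L)
          parents[[ids[i]]] <- sample(ids[seq_len(i - 1L)], min(k, i - 1L))
      }
    } else {
      el <- do.call(rbind, lapply(names(parents), function(ch)
        if (length(parents[[ch]])) cbind(ch, parents[[ch]])))
      if (!is.null(el)) {
        g <- igraph::graph_from_edgelist(el, directed = TRUE)
        if (!igraph::is_dag(g)) .stopf("cyclic parent specification")
      }
      missing <- setdiff(ids, names(parents))
      parents <- c(parents, stats::setNames(vector("list", length(missing)), missing))
    }

    sizes <- sample(seq(config$term_genes_range[1], config$term_genes_range[2]),
                    config$n_terms, replace = TRUE)
    planted <- character(0)
    annot <- stats::setNames(vector("list", config$n_terms), ids)
    if (!is.null(query_genes) && config$n_planted_terms > 0L) {
      # leaves (no children) are preferred planting spots so propagation
      # does not dilute ancestors' planted signal
      planted <- sample(ids, min(config$n_planted_terms, config$n_terms))
    }
    for (i in seq_along(ids)) {
      id <- ids[i]
      if (id %in% planted) {
        k_in <- ceiling(0.7 * sizes[i])
        annot[[id]] <- unique(c(sample(query_genes, min(k_in, length(query_genes))),
                                sample(genes, sizes[i] - min(k_in, length(query_genes)))))
      } else {
        annot[[id]] <- sample(genes, sizes[i])
      }
    }

    # propagate annotations to ancestors (topological order: parents precede
    # children by construction only for generated DAGs, so iterate to fixpoint)
    repeat {
      changed <- FALSE
      for (id in ids) for (p in parents[[id]]) {
        new <- union(annot[[p]], annot[[id]])
        if (length(new) > length(annot[[p]])) {
          annot[[p]] <- new
          changed <- TRUE
        }
      }
      if (!changed) break
    }

    structure(list(
      terms = data.frame(term_id = ids, name = nm, definition = def,
                         theme = theme, stringsAsFactors = FALSE),
      parents = parents, genes = annot, planted = planted
    ), class = "ontology")
  })
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("ontology: %d terms, %d is-a edges, %d planted-enriched\n",
              nrow(x$terms), sum(lengths(x$parents)), length(x$planted)))
  invisible(x)
}

#' Generate a weighted gene-interaction network with planted dense modules
#'
#' A sparse Erdos-Renyi background over the gene universe plus planted
#' near-clique modules of configurable size and density, standing in for a
#' confidence-weighted protein-interaction subnetwork. Edge weights lie in
#' (0, 1]; module-internal edges carry higher confidence.
#'
#' @param config a [synth_config()] object.
#' @param n_nodes number of genes drawn into the network (default 200).
#' @return list with `edges` (data frame `gene_a`, `gene_b`, `weight`),
#'   `nodes`, and `modules` (list of planted module gene sets).
#' @export
make_ppi_network <- function(config, n_nodes = 200L) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_genes < 10L) .stopf("need at least 10 genes")
  if (any(config$ppi_module_sizes > n_nodes))
    .stopf("planted module size exceeds the number of network nodes")
  .with_seed(config$seed + 2L, {
    genes <- sprintf("g%05d", seq_len(config$n_genes))
    nodes <- sample(genes, min(n_nodes, config$n_genes))
    n <- length(nodes)

    pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < config$ppi_background_p
    edges <- data.frame(gene_a = nodes[pairs[keep, 1L]],
                        gene_b = nodes[pairs[keep, 2L]],
                        weight = stats::runif(sum(keep), 0.15, 0.9),
                        stringsAsFactors = FALSE)

    remaining <- nodes
    modules <- list()
    for (sz in config$ppi_module_sizes) {
      mod <- sort(sample(remaining, sz))
      remaining <- setdiff(remaining, mod)
      mp <- t(utils::combn(mod, 2L))
      sel <- stats::runif(nrow(mp)) <= config$ppi_module_density
      if (any(sel))
        edges <- rbind(edges, data.frame(gene_a = mp[sel, 1L], gene_b = mp[sel, 2L],
                                         weight = stats::runif(sum(sel), 0.6, 1),
                                         stringsAsFactors = FALSE))
      modules[[length(modules) + 1L]] <- mod
    }

    # drop duplicate pairs (background edge inside a planted module)
    key <- paste(pmin(edges$gene_a, edges$gene_b), pmax(edges$gene_a, edges$gene_b))
    edges <- edges[!duplicated(key), , drop = FALSE]
    rownames(edges) <- NULL
    list(edges = edges, nodes = nodes, modules = modules)
  })
}

#' Generate scored epigenome tracks and a gene model
#'
#' Produces a TSS/strand gene model over autosome-like chromosomes and, per
#' epigenetic mark, a scored interval track (BED semantics: 0-based,
#' half-open). Every gene receives low-score background intervals near its
#' TSS; for each planted `(mark, direction)` association the planted DEGs of
#' that direction receive additional high-score intervals inside the
#' promoter window (TSS +/- 1 kb, strand-aware), so the mark's top-scoring
#' gene set is enriched for that DEG direction.
#'
#' @param config a [synth_config()] object.
#' @param truth ground truth from [make_probe_data()]; required when
#'   `planted_mark_assoc` is non-empty.
#' @return list with `tracks` (named list of BED data frames per mark),
#'   `gene_model` (data frame `gene`, `chrom`, `strand`, `tss`), and
#'   `planted` (the association list).
#' @export
make_epigenome_tracks <- function(config, truth = NULL) {
  stopifnot(inherits(config, "synth_config"))
  assoc <- config$planted_mark_assoc
  if (length(assoc) && is.null(truth))
    .stopf("'truth' from make_probe_data() is required to plant mark associations")
  .with_seed(config$seed + 3L, {
    genes <- sprintf("g%05d", seq_len(config$n_genes))
    gene_model <- data.frame(
      gene = genes,
      chrom = sample(sprintf("chr%d", 1:19), config$n_genes, replace = TRUE),
      strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
      tss = sample.int(1e8, config$n_genes) + 1e4,
      stringsAsFactors = FALSE
    )
    tss <- stats::setNames(gene_model$tss, genes)
    chrom <- stats::setNames(gene_model$chrom, genes)

    one_track <- function(mark) {
      # background: one modest interval in each gene's promoter
      w <- sample(200:800, config$n_genes, replace = TRUE)
      off <- sample(-900:100, config$n_genes, replace = TRUE)
      bed <- data.frame(
        chrom = chrom[genes],
        start = pmax(0, tss[genes] + off),
        end = pmax(0, tss[genes] + off) + w,
        name = sprintf("%s_bg_%s", mark, genes),
        score = stats::rexp(config$n_genes, rate = 1),
        stringsAsFactors = FALSE
      )
      if (!is.null(assoc[[mark]])) {
        dt <- truth$deg_table
        hit <- unique(dt$gene[dt$direction == assoc[[mark]]])
        if (length(hit)) {
          w2 <- sample(400:900, length(hit), replace = TRUE)
          off2 <- sample(-800:-100, length(hit), replace = TRUE)
          bed <- rbind(bed, data.frame(
            chrom = chrom[hit],
            start = tss[hit] + off2,
            end = tss[hit] + off2 + w2,
            name = sprintf("%s_planted_%s", mark, hit),
            score = 25 + stats::rexp(length(hit), rate = 0.2),
            stringsAsFactors = FALSE
          ))
        }
      }
      rownames(bed) <- NULL
      bed
    }

    tracks <- stats::setNames(lapply(config$marks, one_track), config$marks)
    list(tracks = tracks, gene_model = gene_model, planted = assoc)
  })
}

#' Generate every synthetic input of the study in one call
#'
#' Convenience wrapper running [make_probe_data()], [make_ontology()],
#' [make_ppi_network()] and [make_epigenome_tracks()] with a shared
#' configuration. The ontology plants enrichment against the planted DEG
#' genes.
#'
#' @param config a [synth_config()] object.
#' @return list with `probes`, `ontology`, `ppi`, `epigenome`.
#' @export
make_synthetic_study <- function(config) {
  probes <- make_probe_data(config)
  ontology <- make_ontology(config, query_genes = unique(probes$truth$deg_table$gene))
  ppi <- make_ppi_network(config)
  epigenome <- make_epigenome_tracks(config, truth = probes$truth)
  list(probes = probes, ontology = ontology, ppi = ppi, epigenome = epigenome)
}
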