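#' Configuration for the synthetic study generator
#'
#' Describes the simulated study: a stage-by-treatment microarray design with
#' replicate samples of pooled embryos, planted differentially expressed
#' genes, planted programmed expression waves (maternal, minor ZGA, major
#' ZGA, MGA), a toy gene ontology with planted enriched terms, a gene
#' interaction network with planted dense modules, and scored epigenome
#' tracks with planted promoter-mark/DEG-direction associations. Every
#' generator is deterministic given `(config, seed)`.
#'
#' @param n_genes number of genes in the universe.
#' @param n_probes_per_gene integer range `c(min, max)`: each gene gets a
#'   uniformly drawn number of probes in this range.
#' @param stages ordered developmental stage labels. The wave templates
#'   assume the second stage is the minor-ZGA peak and the third the
#'   major-ZGA peak (MII, 1-cell, 2-cell, 4-cell by default).
#' @param treatments treatment labels; must contain `"control"`.
#' @param n_replicates biological replicates per stage x treatment.
#' @param deg_fraction fraction of genes planted as DEGs at `deg_stage`.
#' @param effect_size planted log2 fold change magnitude.
#' @param deg_stage stage at which DEGs are planted (default: third stage,
#'   the major-ZGA stage).
#' @param wave_fractions named proportions for
#'   `maternal`/`minor_zga`/`major_zga`/`mga`/`other`; must sum to 1.
#' @param missing_rate probability that a spot is flagged invalid.
#' @param noise_sd residual SD on the log2 scale.
#' @param wave_amplitude log2 half-range of the stage-profile templates.
#' @param n_terms,n_planted_terms ontology size and number of terms planted
#'   as enriched in the query gene set.
#' @param term_genes_range size range of per-term gene annotations.
#' @param ppi_background_p background edge probability of the interaction
#'   network.
#' @param ppi_module_sizes,ppi_module_density sizes and edge density of the
#'   planted near-clique modules.
#' @param marks epigenetic mark names for the track generator.
#' @param planted_mark_assoc named list `mark -> direction` (`"up"`/`"down"`)
#'   of planted promoter-mark/DEG associations.
#' @param seed integer seed; every generator derives its randomness from it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_genes = 2000,
                         n_probes_per_gene = c(1L, 3L),
                         stages = c("MII", "1cell", "2cell", "4cell"),
                         treatments = c("control", "T247", "MGCD0103"),
                         n_replicates = 3,
                         deg_fraction = 0.05,
                         effect_size = 2,
                         deg_stage = NULL,
                         wave_fractions = c(maternal = 0.20, minor_zga = 0.10,
                                            major_zga = 0.15, mga = 0.10,
                                            other = 0.45),
                         missing_rate = 0.05,
                         noise_sd = 0.3,
                         wave_amplitude = 1.5,
                         n_terms = 50,
                         n_planted_terms = 10,
                         term_genes_range = c(15L, 40L),
                         ppi_background_p = 0.01,
                         ppi_module_sizes = c(10L, 12L),
                         ppi_module_density = 0.9,
                         marks = c("H3K9ac", "H3K27ac", "H3K27me3"),
                         planted_mark_assoc = list(),
                         seed = 1L) {
  .check_count(n_genes, "n_genes")
  .check_count(n_replicates, "n_replicates")
  .check_count(n_terms, "n_terms", min = 2L)
  if (length(n_probes_per_gene) != 2L || any(n_probes_per_gene < 1L))
    .stopf("'n_probes_per_gene' must be a positive integer range c(min, max)")
  if (length(stages) < 2L) .stopf("'stages' must have at least 2 levels")
  if (!"control" %in% treatments) .stopf("'treatments' must contain \"control\"")
  .check_prob(deg_fraction, "deg_fraction")
  .check_prob(missing_rate, "missing_rate", allow_one = FALSE)
  if (noise_sd < 0) .stopf("'noise_sd' must be non-negative")
  if (effect_size < 0) .stopf("'effect_size' must be non-negative")
  waves <- c("maternal", "minor_zga", "major_zga", "mga", "other")
  if (!setequal(names(wave_fractions), waves))
    .stopf("'wave_fractions' must be named: %s", paste(waves, collapse = ", "))
  wave_fractions <- wave_fractions[waves]
  if (abs(sum(wave_fractions) - 1) > 1e-9)
    .stopf("'wave_fractions' must sum to 1 (got %.12f)", sum(wave_fractions))
  if (any(wave_fractions < 0)) .stopf("'wave_fractions' must be non-negative")
  deg_stage <- deg_stage %||% stages[min(3L, length(stages))]
  if (!deg_stage %in% stages) .stopf("'deg_stage' must be one of 'stages'")
  if (!all(names(planted_mark_assoc) %in% marks))
    .stopf("unknown mark name in 'planted_mark_assoc': %s",
           paste(setdiff(names(planted_mark_assoc), marks), collapse = ", "))
  if (length(planted_mark_assoc) &&
      !all(unlist(planted_mark_assoc) %in% c("up", "down")))
    .stopf("'planted_mark_assoc' directions must be \"up\" or \"down\"")
  if (any(ppi_module_sizes > n_genes))
    .stopf("'ppi_module_sizes' cannot exceed 'n_genes'")
  .check_prob(ppi_module_density, "ppi_module_density")
  structure(list(
    n_genes = as.integer(n_genes),
    n_probes_per_gene = as.integer(n_probes_per_gene),
    stages = stages, treatments = treatments,
    n_replicates = as.integer(n_replicates),
    deg_fraction = deg_fraction, effect_size = effect_size,
    deg_stage = deg_stage, wave_fractions = wave_fractions,
    missing_rate = missing_rate, noise_sd = noise_sd,
    wave_amplitude = wave_amplitude,
    n_terms = as.integer(n_terms), n_planted_terms = as.integer(n_planted_terms),
    term_genes_range = as.integer(term_genes_range),
    ppi_background_p = ppi_background_p,
    ppi_module_sizes = as.integer(ppi_module_sizes),
    ppi_module_density = ppi_module_density,
    marks = marks, planted_mark_assoc = planted_mark_assoc,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synthetic study configuration\n")
  cat(sprintf("  %d genes, %d-%d probes/gene, %d stages x %d treatments x %d replicates\n",
              x$n_genes, x$n_probes_per_gene[1], x$n_probes_per_gene[2],
              length(x$stages), length(x$treatments), x$n_replicates))
  cat(sprintf("  planted DEGs: %.1f%% at |LFC| = %.2g in stage %s; missing rate %.2g; noise sd %.2g\n",
              100 * x$deg_fraction, x$effect_size, x$deg_stage,
              x$missing_rate, x$noise_sd))
  invisible(x)
}

#' @rdname synth_config
#' @param path YAML file path.
#' @export
read_synth_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$wave_fractions <- unlist(x$wave_fractions)
  x$n_probes_per_gene <- as.integer(unlist(x$n_probes_per_gene))
  x$term_genes_range <- as.integer(unlist(x$term_genes_range))
  x$ppi_module_sizes <- as.integer(unlist(x$ppi_module_sizes))
  do.call(synth_config, x)
}

#' @rdname synth_config
#' @param config a `synth_config` object.
#' @export
write_synth_config <- function(config, path) {
  x <- unclass(config)
  x$wave_fractions <- as.list(x$wave_fractions)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Stage-profile templates of the programmed expression waves
#'
#' Piecewise templates over the ordered stages, on the standardized log2
#' scale: maternal transcripts decay monotonically from the oocyte; minor
#' ZGA peaks at the 1-cell stage (stage 2); major ZGA peaks at the 2-cell
#' stage (stage 3); MGA rises after the 2-cell stage; `other` is flat.
#'
#' @param stages ordered stage labels (>= 2).
#' @return a matrix, one row per wave, one column per stage.
#' @export
wave_templates <- function(stages) {
  s <- length(stages)
  if (s < 2L) .stopf("need at least 2 stages")
  idx <- seq_len(s)
  minor_peak <- min(2L, s)
  major_peak <- min(3L, s)
  mga <- rep(-0.8, s)
  mga[idx >= major_peak] <- seq(-0.1, 1.7,
                                length.out = sum(idx >= major_peak))
  tmpl <- rbind(
    maternal  = seq(1, -1, length.out = s),
    minor_zga = -0.6 + 1.9 * exp(-2 * (idx - minor_peak)^2),
    major_zga = -0.6 + 1.9 * exp(-2 * (idx - major_peak)^2),
    mga       = mga,
    other     = rep(0, s)
  )
  colnames(tmpl) <- stages
  tmpl
}
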