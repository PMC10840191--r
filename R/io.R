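#' Read and write the plain-text formats the pipeline consumes
#'
#' Probe tables are four-column TSVs (`probe_id`, `gene_symbol`, `signal`,
#' `flag`), one file per hybridized sample, matching an Agilent feature
#' extraction export after column selection. Gene-set collections use GMT
#' (term id, description, then member genes, tab-separated). Interaction
#' networks are three-column edge lists. Scored genomic intervals use
#' five-column BED (0-based, half-open). The gene model is a four-column TSV
#' (`gene`, `chrom`, `strand`, `tss`).
#'
#' @param path file path.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
read_probe_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "gene_symbol", "signal", "flag")
  if (!all(need %in% names(x)))
    .stopf("probe table '%s' must have columns: %s", path, paste(need, collapse = ", "))
  x[need]
}

#' @rdname pipeline-io
#' @param table data frame as returned by [read_probe_table()].
#' @export
write_probe_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) .stopf("GMT line with fewer than 3 fields")
    list(id = f[[1L]], description = f[[2L]], genes = f[-(1:2)])
  })
  sets <- lapply(out, `[[`, "genes")
  names(sets) <- vapply(out, `[[`, "", "id")
  attr(sets, "description") <- vapply(out, `[[`, "", "description")
  sets
}

#' @rdname pipeline-io
#' @param sets named list of character vectors (gene sets).
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_edge_list <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "weight")
  if (!all(need %in% names(x)))
    .stopf("edge list '%s' must have columns: %s", path, paste(need, collapse = ", "))
  x[need]
}

#' @rdname pipeline-io
#' @param edges data frame with columns `gene_a`, `gene_b`, `weight`.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 5L)
      .stopf("malformed BED line %d in '%s': expected 5 fields, got %d", i, path, length(f))
    s <- suppressWarnings(as.numeric(f[[2L]])); e <- suppressWarnings(as.numeric(f[[3L]]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s)
      .stopf("malformed BED line %d in '%s': bad interval [%s, %s)", i, path, f[[2L]], f[[3L]])
  }
  data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 2L)),
    end   = as.integer(vapply(fields, `[[`, "", 3L)),
    name  = vapply(fields, `[[`, "", 4L),
    score = as.numeric(vapply(fields, `[[`, "", 5L)),
    stringsAsFactors = FALSE
  )
}

#' @rdname pipeline-io
#' @param bed data frame with columns `chrom`, `start`, `end`, `name`, `score`.
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed[c("chrom", "start", "end", "name", "score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_gene_model <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "strand", "tss")
  if (!all(need %in% names(x)))
    .stopf("gene model '%s' must have columns: %s", path, paste(need, collapse = ", "))
  if (!all(x$strand %in% c("+", "-"))) .stopf("gene model strand must be '+' or '-'")
  x[need]
}

#' @rdname pipeline-io
#' @param model data frame with columns `gene`, `chrom`, `strand`, `tss`.
#' @export
write_gene_model <- function(model, path) {
  utils::write.table(model, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @description `read_ontology_tsv()`/`write_ontology_tsv()` use a long
#'   three-column format (`term`, `field`, `value`) with fields `name`,
#'   `definition`, `is_a` (one row per parent) and `gene` (one row per
#'   annotated gene).
#' @export
read_ontology_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  ids <- unique(x$term)
  pick <- function(id, field) x$value[x$term == id & x$field == field]
  terms <- data.frame(
    term_id = ids,
    name = vapply(ids, function(i) pick(i, "name")[1L], ""),
    definition = vapply(ids, function(i) pick(i, "definition")[1L], ""),
    stringsAsFactors = FALSE
  )
  structure(
    list(terms = terms,
         parents = stats::setNames(lapply(ids, pick, field = "is_a"), ids),
         genes = stats::setNames(lapply(ids, pick, field = "gene"), ids)),
    class = "ontology"
  )
}

#' @rdname pipeline-io
#' @param ontology an `ontology` object (see [make_ontology()]).
#' @export
write_ontology_tsv <- function(ontology, path) {
  rows <- do.call(rbind, lapply(ontology$terms$term_id, function(id) {
    i <- match(id, ontology$terms$term_id)
    rbind(
      data.frame(term = id, field = "name", value = ontology$terms$name[i]),
      data.frame(term = id, field = "definition", value = ontology$terms$definition[i]),
      if (length(ontology$parents[[id]]))
        data.frame(term = id, field = "is_a", value = ontology$parents[[id]]),
      if (length(ontology$genes[[id]]))
        data.frame(term = id, field = "gene", value = ontology$genes[[id]])
    )
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
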