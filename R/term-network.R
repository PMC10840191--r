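#' Build a Jaccard similarity network over enriched terms
#'
#' Computes the complete Jaccard adjacency `J(A,B) = |A n B| / |A u B|`
#' between the gene sets of the enriched terms and flags edges where one
#' term's gene set is contained in the other's (the Jaccard coefficient
#' alone cannot express full set inclusion).
#'
#' @param terms data frame with columns `term_id`, `name`, `p` (enrichment
#'   p-value used for node sizes).
#' @param gene_sets named list of gene sets covering every `term_id`.
#' @return an object of class `term_graph`: list with `terms` (plus
#'   `neglog10_p`), `jaccard` (symmetric matrix, unit diagonal), `subset`
#'   (logical matrix), `cluster` (filled by [cluster_term_graph()]),
#'   `layout` (filled by [layout_term_graph()]).
#' @export
build_term_graph <- function(terms, gene_sets) {
  need <- c("term_id", "name", "p")
  if (!all(need %in% names(terms)))
    .stopf("'terms' must have columns: %s", paste(need, collapse = ", "))
  if (nrow(terms) < 2L) .stopf("need at least 2 terms")
  ids <- terms$term_id
  if (!all(ids %in% names(gene_sets)))
    .stopf("gene_sets missing for: %s",
           paste(setdiff(ids, names(gene_sets)), collapse = ", "))
  sets <- gene_sets[ids]
  if (any(lengths(sets) == 0L)) .stopf("term with empty gene set")
  n <- length(ids)
  J <- diag(1, n); S <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    a <- sets[[i]]; b <- sets[[j]]
    J[i, j] <- J[j, i] <- .jaccard(a, b)
    S[i, j] <- S[j, i] <- all(a %in% b) || all(b %in% a)
  }
  dimnames(J) <- dimnames(S) <- list(ids, ids)
  terms$neglog10_p <- -log10(pmax(terms$p, .Machine$double.xmin))
  structure(list(terms = terms, gene_sets = sets, jaccard = J, subset = S,
                 cluster = NULL, layout = NULL, annotations = NULL),
            class = "term_graph")
}

#' @export
print.term_graph <- function(x, ...) {
  cat(sprintf("term_graph: %d terms; %s; %s\n", nrow(x$terms),
              if (is.null(x$cluster)) "unclustered"
              else sprintf("%d clusters", length(setdiff(unique(x$cluster), "not categorized"))),
              if (is.null(x$layout)) "no layout" else "laid out"))
  invisible(x)
}

#' Cluster the term network by k-medoids on Jaccard distance
#'
#' Checks clustering potential first: the Hopkins statistic of the rows of
#' the Jaccard-distance embedding must reach `hopkins_thresh`, otherwise
#' every node is labeled `"not categorized"` with a diagnostic message.
#' Otherwise k-medoids (PAM) partitions the nodes on `d = 1 - J`, with `k`
#' chosen by the elbow rule on the embedding unless supplied. Any cluster
#' whose mean pairwise Jaccard similarity falls below `merge_thresh` is
#' relabeled `"not categorized"` (singletons count as 0).
#'
#' @param graph a `term_graph`.
#' @param k number of clusters, or `NULL` to choose automatically.
#' @param seed integer seed.
#' @param merge_thresh mean within-cluster Jaccard below which a cluster is
#'   dissolved.
#' @param hopkins_thresh clustering-tendency gate.
#' @return the graph with `cluster` filled in (character labels per node).
#' @export
cluster_term_graph <- function(graph, k = NULL, seed = 1L,
                               merge_thresh = 0.05, hopkins_thresh = 0.75) {
  stopifnot(inherits(graph, "term_graph"))
  D <- 1 - graph$jaccard
  n <- nrow(D)
  if (!is.null(k) && k > n) .stopf("'k' cannot exceed the node count")
  emb <- D
  h <- tryCatch(hopkins_statistic(emb, seed = seed), error = function(e) NA_real_)
  if (!is.na(h) && h < hopkins_thresh) {
    message(sprintf("Hopkins statistic %.3f < %.2f: no cluster structure; all terms 'not categorized'",
                    h, hopkins_thresh))
    graph$cluster <- stats::setNames(rep("not categorized", n), rownames(D))
    return(graph)
  }
  if (is.null(k)) {
    k <- choose_cluster_number(emb, k_max = min(8L, n - 1L), method = "elbow",
                               seed = seed)
  }
  cl <- .with_seed(seed, cluster::pam(stats::as.dist(D), k = k,
                                      cluster.only = TRUE))
  lab <- as.character(cl)
  for (ci in unique(cl)) {
    members <- which(cl == ci)
    meanj <- if (length(members) < 2L) 0 else {
      sub <- graph$jaccard[members, members]
      mean(sub[upper.tri(sub)])
    }
    if (meanj < merge_thresh) lab[members] <- "not categorized"
  }
  graph$cluster <- stats::setNames(lab, rownames(D))
  graph
}

#' Force-directed layout of the term network
#'
#' Fruchterman-Reingold layout of the weighted term graph (Jaccard weights
#' as attraction strengths). Outlier nodes -- by default nodes with no
#' incident edge of Jaccard weight at least `outlier_thresh` -- receive `NA`
#' coordinates: they are removed from the drawn layout but kept in the data.
#'
#' @param graph a clustered `term_graph`.
#' @param seed integer seed.
#' @param outlier_thresh minimum incident edge weight that keeps a node in
#'   the layout.
#' @return the graph with `layout` filled (data frame `term_id`, `x`, `y`,
#'   `neglog10_p`, `cluster`, `in_layout`).
#' @export
layout_term_graph <- function(graph, seed = 1L, outlier_thresh = 0.05) {
  stopifnot(inherits(graph, "term_graph"))
  if (is.null(graph$cluster)) .stopf("cluster the graph first")
  J <- graph$jaccard
  ids <- rownames(J)
  off <- J; diag(off) <- 0
  keep <- apply(off, 1L, max) >= outlier_thresh
  xy <- matrix(NA_real_, length(ids), 2L)
  if (!any(keep)) {
    .warnf("all nodes are layout outliers; returning an empty layout")
  } else {
    sub <- off[keep, keep, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    coords <- .with_seed(seed, igraph::layout_with_fr(
      g, weights = igraph::E(g)$weight %||% numeric(0)))
    xy[keep, ] <- coords
  }
  graph$layout <- data.frame(
    term_id = ids, x = xy[, 1L], y = xy[, 2L],
    neglog10_p = graph$terms$neglog10_p,
    cluster = unname(graph$cluster[ids]),
    in_layout = keep, row.names = NULL, stringsAsFactors = FALSE
  )
  graph
}

# minimal English stop-word list plus ontology boilerplate
.term_stopwords <- c(
  "a", "an", "and", "any", "as", "at", "by", "for", "from", "in", "into",
  "is", "it", "its", "of", "on", "or", "that", "the", "this", "to", "via",
  "with", "which", "process", "involved", "during"
)

#' Stop words used by the cluster annotator
#' @return character vector.
#' @export
term_stopwords <- function() .term_stopwords

.tokenize <- function(x) {
  toks <- strsplit(tolower(gsub("[^a-z0-9 ]", " ", tolower(x))), "\\s+")[[1L]]
  toks[nzchar(toks)]
}

#' TF-IDF representative vocabulary of a document corpus
#'
#' Term frequency is the within-document token share; inverse document
#' frequency is `ln(N / df)` over the corpus.
#'
#' @param docs named character vector of documents.
#' @return data frame `doc`, `word`, `tf`, `idf`, `tf_idf`.
#' @export
tf_idf <- function(docs) {
  toks <- lapply(docs, .tokenize)
  N <- length(docs)
  df <- table(unlist(lapply(toks, unique)))
  rows <- lapply(names(docs), function(d) {
    tt <- table(toks[[d]])
    if (!length(tt)) return(NULL)
    tf <- as.numeric(tt) / sum(tt)
    idf <- log(N / as.numeric(df[names(tt)]))
    data.frame(doc = d, word = names(tt), tf = tf, idf = idf,
               tf_idf = tf * idf, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.ngrams <- function(words, n) {
  if (length(words) < n) return(character(0))
  vapply(seq_len(length(words) - n + 1L), function(i)
    paste(words[i:(i + n - 1L)], collapse = " "), "")
}

#' Annotate term-network clusters by TF-IDF and N-gram scoring
#'
#' For every cluster (except `"not categorized"`): (1) the corpus of term
#' definitions is TF-IDF scored and each term's top-scoring words become its
#' representative vocabulary; (2) candidate labels are the 1- and 2-gram
#' frequencies over the member term names (stop words removed); (3) each
#' candidate is re-scored as a weighted sum of three normalized features:
#' its name-frequency, `-log10` of the lowest enrichment p among member
#' terms whose name contains it, and whether it is a representative word of
#' any member term. The chosen label is the top of the top-3 candidates. A
#' cluster whose candidate list is empty after stop-word removal falls back
#' to the name of its lowest-p member term.
#'
#' @param graph a clustered `term_graph`.
#' @param corpus an `ontology` or data frame with `term_id` and `definition`
#'   covering every node.
#' @param n_top_words representative-vocabulary size per term.
#' @param weights numeric triple: feature weights for frequency, minimum-p,
#'   and representativeness.
#' @param stopwords words excluded from candidates.
#' @return the graph with `annotations` filled: one data frame row per
#'   (cluster, candidate) with the raw features, scores, candidate rank and
#'   chosen label.
#' @export
annotate_term_clusters <- function(graph, corpus, n_top_words = 5L,
                                   weights = c(freq = 0.5, minp = 0.3, repr = 0.2),
                                   stopwords = term_stopwords()) {
  stopifnot(inherits(graph, "term_graph"))
  if (is.null(graph$cluster)) .stopf("cluster the graph first")
  defs <- if (inherits(corpus, "ontology")) corpus$terms else corpus
  ids <- graph$terms$term_id
  if (!all(ids %in% defs$term_id))
    .stopf("corpus missing definitions for: %s",
           paste(setdiff(ids, defs$term_id), collapse = ", "))

  docs <- stats::setNames(defs$definition, defs$term_id)
  ti <- tf_idf(docs)
  repr_words <- lapply(split(ti, ti$doc), function(d)
    d$word[order(-d$tf_idf)][seq_len(min(n_top_words, nrow(d)))])

  clusters <- setdiff(unique(graph$cluster), "not categorized")
  rows <- lapply(clusters, function(cl) {
    members <- ids[graph$cluster[ids] == cl]
    name_toks <- lapply(graph$terms$name[match(members, ids)], .tokenize)
    unigrams <- unlist(lapply(name_toks, function(w) unique(setdiff(w, stopwords))))
    bigrams <- unlist(lapply(name_toks, function(w) {
      b <- .ngrams(w, 2L)
      unique(b[!vapply(strsplit(b, " "), function(p) any(p %in% stopwords), TRUE)])
    }))
    cand <- table(c(unigrams, bigrams))
    member_p <- stats::setNames(graph$terms$p[match(members, ids)], members)
    if (!length(cand)) {
      best <- members[which.min(member_p)]
      return(data.frame(cluster = cl, candidate = graph$terms$name[match(best, ids)],
                        freq = NA_real_, min_p = min(member_p), repr = NA,
                        score = NA_real_, rank = 1L,
                        chosen = graph$terms$name[match(best, ids)],
                        stringsAsFactors = FALSE))
    }
    freq <- as.numeric(cand) / length(members)
    names(freq) <- names(cand)
    member_names <- stats::setNames(
      vapply(name_toks, paste, "", collapse = " "), members)
    minp <- vapply(names(freq), function(w) {
      hit <- members[grepl(w, member_names, fixed = TRUE)]
      if (!length(hit)) min(member_p) else min(member_p[hit])
    }, 0)
    member_repr <- unique(unlist(repr_words[members]))
    repr <- vapply(strsplit(names(freq), " "), function(p)
      any(p %in% member_repr), TRUE)
    nl <- -log10(pmax(minp, .Machine$double.xmin))
    f1 <- freq / max(freq)
    f2 <- if (max(nl) > 0) nl / max(nl) else rep(0, length(nl))
    score <- weights[["freq"]] * f1 + weights[["minp"]] * f2 +
      weights[["repr"]] * as.numeric(repr)
    ord <- order(-score, names(freq))
    top <- utils::head(ord, 3L)
    data.frame(cluster = cl, candidate = names(freq)[top],
               freq = freq[top], min_p = minp[top], repr = repr[top],
               score = score[top], rank = seq_along(top),
               chosen = names(freq)[top[1L]],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  graph$annotations <- do.call(rbind, rows)
  graph
}

#' Export a term graph as node and edge tables
#'
#' @param graph a `term_graph`.
#' @param min_weight edges below this Jaccard weight are dropped.
#' @return list of data frames `nodes` (`term_id`, `name`, `neglog10_p`,
#'   `cluster`, `x`, `y`) and `edges` (`a`, `b`, `jaccard`, `subset`).
#' @export
export_term_graph <- function(graph, min_weight = 0) {
  stopifnot(inherits(graph, "term_graph"))
  ids <- graph$terms$term_id
  lay <- graph$layout
  nodes <- data.frame(
    term_id = ids, name = graph$terms$name,
    neglog10_p = graph$terms$neglog10_p,
    cluster = if (is.null(graph$cluster)) NA_character_ else unname(graph$cluster[ids]),
    x = if (is.null(lay)) NA_real_ else lay$x[match(ids, lay$term_id)],
    y = if (is.null(lay)) NA_real_ else lay$y[match(ids, lay$term_id)],
    stringsAsFactors = FALSE
  )
  idx <- which(upper.tri(graph$jaccard) & graph$jaccard > min_weight, arr.ind = TRUE)
  edges <- data.frame(
    a = ids[idx[, 1L]], b = ids[idx[, 2L]],
    jaccard = graph$jaccard[idx],
    subset = graph$subset[idx],
    stringsAsFactors = FALSE
  )
  list(nodes = nodes, edges = edges)
}
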