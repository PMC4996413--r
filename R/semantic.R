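# Semantic gene-centrality selection over a gene ontology graph.
#
# Genes are ranked by how many distinct, mutually non-redundant ontology
# terms they remain annotated to after a Resnik-distance pruning step: a
# gene's terms are iteratively thinned while any pair lies closer than a
# relaxation threshold on the normalized Resnik distance. The retained-term
# count is the gene's functional centrality; highly ranked genes sit at the
# crossroads of several distant functional modules. Selected genes map back
# to CpG probes through the array annotation.

#' Construct a gene ontology graph
#'
#' A directed acyclic graph of ontology terms with child-to-parent `is_a`
#' edges and a single root per aspect. Cycles are rejected with the offending
#' cycle listed; multiple roots are rejected.
#'
#' @param terms Data frame with columns `id`, `name`, `aspect`.
#' @param edges Data frame with columns `child`, `parent`.
#' @return An object of class `go_graph` with fields `terms`, `parents` and
#'   `children` (named lists of character vectors) and `root`.
#' @export
go_graph <- function(terms, edges) {
  stopifnot(all(c("id", "name", "aspect") %in% names(terms)),
            all(c("child", "parent") %in% names(edges)))
  if (anyDuplicated(terms$id)) stop("duplicate term ids")
  unknown <- setdiff(c(edges$child, edges$parent), terms$id)
  if (length(unknown))
    stop("edge references unknown term(s): ", paste(unknown, collapse = ", "))
  ids <- terms$id
  parents <- lapply(stats::setNames(ids, ids), function(i) character(0))
  children <- parents
  for (i in seq_len(nrow(edges))) {
    parents[[edges$child[i]]] <- union(parents[[edges$child[i]]], edges$parent[i])
    children[[edges$parent[i]]] <- union(children[[edges$parent[i]]], edges$child[i])
  }
  # cycle check via Kahn's algorithm; report a remaining cycle if any
  indeg <- vapply(parents, length, integer(1))
  queue <- names(indeg)[indeg == 0L]
  seen <- character(0)
  indeg_work <- indeg
  while (length(queue)) {
    t <- queue[1L]; queue <- queue[-1L]; seen <- c(seen, t)
    for (ch in children[[t]]) {
      indeg_work[ch] <- indeg_work[ch] - 1L
      if (indeg_work[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(seen) != length(ids)) {
    cyc <- setdiff(ids, seen)
    stop("cycle detected among terms: ", paste(cyc, collapse = " -> "))
  }
  roots <- ids[vapply(parents[ids], length, integer(1)) == 0L]
  if (length(roots) != 1L)
    stop("graph must have exactly one root, found: ",
         paste(roots, collapse = ", "))
  structure(list(terms = terms, parents = parents, children = children,
                 root = roots),
            class = "go_graph")
}

#' @export
print.go_graph <- function(x, ...) {
  cat(sprintf("go_graph: %d terms, root %s, aspect(s): %s\n",
              nrow(x$terms), x$root,
              paste(unique(x$terms$aspect), collapse = ", ")))
  invisible(x)
}

# All ancestors of a term (the term itself excluded), memoized over the graph.
.ancestors_map <- function(graph) {
  ids <- graph$terms$id
  anc <- vector("list", length(ids)); names(anc) <- ids
  visit <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    ps <- graph$parents[[t]]
    res <- ps
    for (p in ps) res <- union(res, visit(p))
    anc[[t]] <<- res
    res
  }
  for (t in ids) visit(t)
  anc
}

#' Construct an annotation corpus
#'
#' Holds direct gene-term associations together with their ancestor-closed
#' (propagated) counterpart. Associations to terms absent from the graph are
#' dropped with a warning reporting how many were dropped.
#'
#' @param annotations Data frame with columns `gene`, `term` (direct
#'   associations).
#' @param graph A `go_graph`.
#' @return An object of class `annotation_corpus` with fields `annotations`
#'   (the screened direct associations), `gene2terms`, `term2genes` (direct
#'   maps) and, after [propagate_annotations()], `gene2terms_prop`,
#'   `term2genes_prop` and `ic` (per-term information content).
#' @export
annotation_corpus <- function(annotations, graph) {
  stopifnot(all(c("gene", "term") %in% names(annotations)))
  annotations <- unique(annotations[, c("gene", "term")])
  bad <- !(annotations$term %in% graph$terms$id)
  if (any(bad)) {
    warning(sum(bad), " annotation(s) to unknown term(s) dropped")
    annotations <- annotations[!bad, , drop = FALSE]
  }
  if (!nrow(annotations)) stop("no valid annotations remain")
  rownames(annotations) <- NULL
  corpus <- structure(
    list(annotations = annotations,
         gene2terms = lapply(split(annotations$term, annotations$gene), unique),
         term2genes = lapply(split(annotations$gene, annotations$term), unique)),
    class = "annotation_corpus")
  propagate_annotations(graph, corpus)
}

#' Propagate annotations up the ontology (true-path closure)
#'
#' Closes every gene's annotation set under ancestors, recomputes the
#' term-to-gene map on the closed sets, and derives per-term information
#' content `IC(t) = -ln(n_t / n_root)` where `n_t` counts genes annotated to
#' `t` after propagation. Idempotent.
#'
#' @param graph A `go_graph`.
#' @param corpus An `annotation_corpus`.
#' @return The corpus with `gene2terms_prop`, `term2genes_prop`, `ic` and
#'   `ic_max` filled in.
#' @export
propagate_annotations <- function(graph, corpus) {
  anc <- .ancestors_map(graph)
  g2t <- lapply(corpus$gene2terms, function(ts) {
    res <- ts
    for (t in ts) res <- union(res, anc[[t]])
    sort(res)
  })
  pairs <- data.frame(
    gene = rep(names(g2t), lengths(g2t)),
    term = unlist(g2t, use.names = FALSE), stringsAsFactors = FALSE)
  t2g <- lapply(split(pairs$gene, pairs$term), unique)
  n_root <- length(t2g[[graph$root]])
  ic <- -log(vapply(t2g, length, integer(1)) / n_root)
  corpus$gene2terms_prop <- g2t
  corpus$term2genes_prop <- t2g
  corpus$ic <- ic
  corpus$ic_max <- max(ic)
  corpus$ancestors <- anc
  corpus
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf("annotation_corpus: %d genes, %d direct associations, %d annotated terms\n",
              length(x$gene2terms), nrow(x$annotations),
              length(x$term2genes_prop)))
  invisible(x)
}

#' Information content of a term
#'
#' `IC(t) = -ln(n_t / n_root)` over propagated annotation counts. The root
#' has IC 0; rarer, deeper terms have higher IC.
#'
#' @param term Term id.
#' @param corpus A propagated `annotation_corpus`.
#' @return Non-negative information content.
#' @export
information_content <- function(term, corpus) {
  if (is.null(corpus$ic)) stop("corpus is not propagated")
  ic <- corpus$ic[term]
  if (any(is.na(ic)))
    stop("term(s) without annotation: ",
         paste(term[is.na(ic)], collapse = ", "))
  unname(ic)
}

#' Normalized Resnik distance between two terms
#'
#' `d(t1, t2) = 1 - IC(MICA) / IC_max` where MICA is the common ancestor
#' (either term included) of maximal information content and `IC_max` the
#' corpus-wide maximum IC. The distance lies in `[0, 1]`: 0 means one term
#' subsumes the other at maximal specificity, 1 means the terms share only
#' the root. Normalizing by `IC_max` makes the relaxation threshold a small
#' unitless knob rather than a corpus-dependent raw-IC cut.
#'
#' @param t1,t2 Term ids.
#' @param corpus A propagated `annotation_corpus`.
#' @return Distance in `[0, 1]`.
#' @export
resnik_distance <- function(t1, t2, corpus) {
  if (is.null(corpus$ic)) stop("corpus is not propagated")
  common <- intersect(c(t1, corpus$ancestors[[t1]]),
                      c(t2, corpus$ancestors[[t2]]))
  common <- common[common %in% names(corpus$ic)]
  if (!length(common)) stop("terms share no common ancestor: ", t1, ", ", t2)
  if (corpus$ic_max <= 0) stop("degenerate corpus: IC_max is 0")
  1 - max(corpus$ic[common]) / corpus$ic_max
}

#' Expand genes to their functional cliques
#'
#' For each input gene, collects the genes directly annotated to any of its
#' terms or to those terms' immediate parents and children (the root is
#' excluded from the expansion). The result approximates the gene's
#' functional neighbourhood in the ontology.
#'
#' @param genes Character vector of gene ids.
#' @param graph A `go_graph`.
#' @param corpus A propagated `annotation_corpus`.
#' @return Named list mapping each annotated input gene to its expanded gene
#'   set; unannotated input genes are skipped with a warning.
#' @export
bubble_cliques <- function(genes, graph, corpus) {
  known <- genes %in% names(corpus$gene2terms)
  if (any(!known))
    warning("unannotated gene(s) skipped: ",
            paste(genes[!known], collapse = ", "))
  genes <- genes[known]
  out <- stats::setNames(vector("list", length(genes)), genes)
  for (g in genes) {
    terms <- corpus$gene2terms[[g]]
    hood <- terms
    for (t in terms)
      hood <- union(hood, c(graph$parents[[t]], graph$children[[t]]))
    hood <- setdiff(hood, graph$root)
    members <- character(0)
    for (t in hood)
      members <- union(members, corpus$term2genes[[t]])
    out[[g]] <- sort(members)
  }
  out
}

#' Semantic-selection configuration
#'
#' @param aspect Ontology aspect to probe (`BP`, `MF` or `CC`).
#' @param relaxation Distance threshold in `[0, 1]` under which two of a
#'   gene's terms are considered redundant (default 0.15).
#' @param metric Similarity metric tag; only `"resnik"` is implemented.
#' @return An object of class `semantic_config`.
#' @export
semantic_config <- function(aspect = "BP", relaxation = 0.15,
                            metric = "resnik") {
  if (relaxation < 0 || relaxation > 1) stop("'relaxation' must be in [0, 1]")
  aspect <- match.arg(aspect, c("BP", "MF", "CC"))
  metric <- match.arg(metric, "resnik")
  structure(list(aspect = aspect, relaxation = relaxation, metric = metric),
            class = "semantic_config")
}

#' Prune a gene's term set by Resnik redundancy
#'
#' Operates on the gene's *direct* annotations. While any pair of retained
#' terms lies at normalized Resnik distance below the relaxation, the closest
#' pair is located (ties broken by term id) and its lower-IC — more generic —
#' member dropped (IC ties broken by dropping the lexicographically larger
#' id). With relaxation 0 no pruning occurs.
#'
#' @param gene Gene id.
#' @param corpus A propagated `annotation_corpus`.
#' @param cfg A [semantic_config()].
#' @return Sorted character vector of retained term ids.
#' @export
prune_gene_terms <- function(gene, corpus, cfg = semantic_config()) {
  terms <- corpus$gene2terms[[gene]]
  if (is.null(terms)) stop("gene has no annotations: ", gene)
  terms <- sort(terms)
  if (cfg$relaxation <= 0 || length(terms) < 2L) return(terms)
  repeat {
    n <- length(terms)
    if (n < 2L) break
    best <- NULL; best_d <- Inf
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- resnik_distance(terms[i], terms[j], corpus)
      if (d < best_d - 1e-12) { best_d <- d; best <- c(i, j) }
    }
    if (best_d >= cfg$relaxation) break
    pair <- terms[best]
    ic <- corpus$ic[pair]
    drop <- if (abs(ic[1L] - ic[2L]) < 1e-12) max(pair) else pair[which.min(ic)]
    terms <- setdiff(terms, drop)
  }
  terms
}

#' Rank genes by semantic centrality
#'
#' Scores each input gene by the number of terms that survive
#' [prune_gene_terms()] — the count of distinct, highly non-overlapping
#' functional contexts the gene participates in — and returns the genes
#' sorted by score (descending), ties broken by gene id. The output is
#' restricted to the input list.
#'
#' @param genes Character vector of gene ids.
#' @param graph A `go_graph`.
#' @param corpus A propagated `annotation_corpus`.
#' @param cfg A [semantic_config()].
#' @return A data frame of class `gene_centrality_ranking` with columns
#'   `gene`, `score` and `terms` (semicolon-joined retained term ids).
#' @export
rank_gene_centrality <- function(genes, graph, corpus,
                                 cfg = semantic_config()) {
  genes <- sort(unique(genes))
  known <- genes %in% names(corpus$gene2terms)
  if (any(!known))
    warning("unannotated gene(s) skipped: ",
            paste(genes[!known], collapse = ", "))
  genes <- genes[known]
  retained <- lapply(genes, prune_gene_terms, corpus = corpus, cfg = cfg)
  df <- data.frame(gene = genes,
                   score = lengths(retained),
                   terms = vapply(retained, paste, character(1),
                                  collapse = ";"),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_centrality_ranking", "data.frame")
  df
}

#' Map selected genes back to CpG probes
#'
#' Returns the full probe set annotated to the gene list and, when a
#' pre-selection result is supplied, its intersection with each experiment's
#' pre-selected probe set (the per-experiment subsets later feed the
#' two-class classification tasks).
#'
#' @param genes Character vector of gene ids.
#' @param probe_annotation Data frame probe/gene/region (one row per link).
#' @param preselection Optional `preselection_result` from
#'   [union_preselect()].
#' @return List with `probes` (full sorted probe set) and `by_experiment`
#'   (named list of intersections; empty when no preselection given).
#' @export
genes_to_probes <- function(genes, probe_annotation, preselection = NULL) {
  genes <- unique(genes)
  hit <- probe_annotation$gene %in% genes
  no_probe <- setdiff(genes, probe_annotation$gene)
  if (length(no_probe))
    warning("gene(s) with no probes skipped: ",
            paste(sort(no_probe), collapse = ", "))
  probes <- sort(unique(probe_annotation$probe[hit]))
  by_exp <- list()
  if (!is.null(preselection)) {
    by_exp <- lapply(preselection$sets, function(s) intersect(probes, sort(s)))
  }
  list(probes = probes, by_experiment = by_exp)
}
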