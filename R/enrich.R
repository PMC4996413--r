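# Gene-set enrichment and genomic-region distribution reporting.
#
# Selected gene lists are tested for over-representation in term (or
# pathway) gene sets by the hypergeometric upper tail against a background
# universe — by default the chip's annotated gene universe, since selection
# operated on chip probes, not the genome. Raw p-values are reported by
# default; Benjamini-Hochberg adjustment and a gene-list resampling null
# are available as options.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= a)` for a hypergeometric draw of `n` genes from a population of
#' `N` containing `K` successes — the chance of seeing at least `a` hits by
#' luck.
#'
#' @param a Observed hits (`0 <= a <= min(K, n)`).
#' @param K Term (success) size in the population.
#' @param n Draw (gene-list) size.
#' @param N Population (universe) size.
#' @return Upper-tail probability in `(0, 1]`.
#' @export
hypergeom_tail <- function(a, K, n, N) {
  if (any(c(a, K, n, N) < 0) || K > N || n > N || a > min(K, n))
    stop("inconsistent hypergeometric counts")
  stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term-set enrichment of a gene list
#'
#' One row per term with at least one hit, sorted by p ascending (ties by
#' term id); terms with fewer than `min_size` genes in the universe are
#' skipped. The enrichment column is the conventional `a/K` string (list
#' hits over term size). Optionally, an empirical p-value from `n_null`
#' random same-size gene lists is appended, and raw p-values can be
#' Benjamini-Hochberg adjusted.
#'
#' @param genes Selected gene list (deduplicated; must intersect the
#'   universe).
#' @param universe Background gene universe.
#' @param term_sets Named list of term -> gene-id vectors.
#' @param descriptions Optional named term descriptions.
#' @param min_size Minimum term size in the universe (default 2).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param n_null Resampling-null draws (0 disables the empirical p).
#' @param seed Seed for the resampling null.
#' @return Data frame with columns `term`, `description`, `p_value`,
#'   `enrichment` (`"a/K"`), `a`, `K` and optionally `p_adjust` /
#'   `p_empirical`.
#' @export
enrich_term_sets <- function(genes, universe, term_sets,
                             descriptions = NULL, min_size = 2L,
                             adjust = c("none", "BH"), n_null = 0L,
                             seed = 1L) {
  adjust <- match.arg(adjust)
  genes <- unique(genes)
  universe <- unique(universe)
  genes <- intersect(genes, universe)
  if (!length(genes)) stop("gene list does not intersect the universe")
  N <- length(universe); n <- length(genes)
  sets <- lapply(term_sets, intersect, universe)
  K <- lengths(sets)
  keep <- K >= min_size
  sets <- sets[keep]; K <- K[keep]
  a <- vapply(sets, function(s) length(intersect(genes, s)), integer(1))
  hit <- a >= 1L
  sets <- sets[hit]; K <- K[hit]; a <- a[hit]
  if (!length(sets)) {
    return(data.frame(term = character(0), description = character(0),
                      p_value = numeric(0), enrichment = character(0),
                      a = integer(0), K = integer(0)))
  }
  p <- mapply(hypergeom_tail, a, K, MoreArgs = list(n = n, N = N))
  out <- data.frame(term = names(sets),
                    description = if (is.null(descriptions)) names(sets)
                                  else unname(descriptions[names(sets)]),
                    p_value = unname(p),
                    enrichment = sprintf("%d/%d", a, K),
                    a = unname(a), K = unname(K), stringsAsFactors = FALSE)
  if (adjust == "BH") out$p_adjust <- stats::p.adjust(out$p_value, "BH")
  if (n_null > 0L) {
    set.seed(seed)
    hits_null <- matrix(0L, nrow = nrow(out), ncol = n_null)
    for (b in seq_len(n_null)) {
      draw <- sample(universe, n)
      hits_null[, b] <- vapply(sets, function(s)
        length(intersect(draw, s)), integer(1))
    }
    out$p_empirical <- (1 + rowSums(hits_null >= out$a)) / (n_null + 1)
  }
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.region_groups <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body",
                    "3'UTR", "Intergenic")

#' Genomic-region distribution of a probe set
#'
#' Counts probes per the seven-category region vocabulary (the four
#' promoter subgroups TSS200, TSS1500, 5'UTR and 1stExon, plus Body, 3'UTR
#' and Intergenic); the promoter total is the sum of its subgroups. Probes
#' with regions outside the vocabulary are counted under `unknown` with a
#' warning.
#'
#' @param probes Probe ids.
#' @param probe_annotation Data frame probe/gene/region.
#' @return List with `counts` (named vector over the seven groups),
#'   `promoter_total`, `unknown` and `n_annotated`.
#' @export
region_distribution <- function(probes, probe_annotation) {
  probes <- unique(probes)
  ann <- probe_annotation[!duplicated(probe_annotation$probe), , drop = FALSE]
  ann <- ann[ann$probe %in% probes, , drop = FALSE]
  known <- ann$region %in% .region_groups
  if (any(!known))
    warning(sum(!known), " probe(s) with unknown region group")
  counts <- vapply(.region_groups, function(g) sum(ann$region == g),
                   integer(1))
  list(counts = counts,
       promoter_total = sum(counts[c("TSS200", "TSS1500", "5'UTR",
                                     "1stExon")]),
       unknown = sum(!known),
       n_annotated = nrow(ann))
}
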