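# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementation.

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws.
oracle_hypergeom_tail <- function(a, K, n, N) {
  pop <- c(rep(1L, K), rep(0L, N - K))
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2L, function(idx) sum(pop[idx]))
  mean(hits >= a)
}

# Distance-weighted k-NN by naive per-query loops.
oracle_knn <- function(train_x, train_y, query, k) {
  d <- apply(train_x, 1L, function(t) sqrt(sum((query - t)^2)))
  ord <- order(d)[seq_len(k)]
  w <- 1 / (d[ord] + 1e-9)
  votes <- tapply(w, train_y[ord], sum)
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) train_y[ord[1L]] else top
}

# Best Gini root split by exhaustive search over every feature and midpoint.
oracle_root_split <- function(X, y) {
  gini <- function(labels) {
    if (!length(labels)) return(0)
    p <- table(labels) / length(labels)
    1 - sum(p^2)
  }
  n <- nrow(X)
  best <- list(impurity = Inf)
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2L) next
    for (thr in (vals[-length(vals)] + vals[-1L]) / 2) {
      left <- X[, j] <= thr
      imp <- (sum(left) * gini(y[left]) + sum(!left) * gini(y[!left])) / n
      if (imp < best$impurity - 1e-12)
        best <- list(feature = j, threshold = thr, impurity = imp)
    }
  }
  best
}

# Resnik distance by explicit all-ancestor enumeration: ancestors collected
# by repeated parent hops, IC by counting genes through an independently
# computed propagation.
oracle_resnik <- function(t1, t2, graph, annotations) {
  all_ancestors <- function(t) {
    res <- t
    frontier <- t
    while (length(frontier)) {
      ps <- unique(unlist(graph$parents[frontier]))
      ps <- setdiff(ps, res)
      res <- c(res, ps)
      frontier <- ps
    }
    res
  }
  genes_at <- function(t) {
    hit <- vapply(unique(annotations$gene), function(g) {
      terms <- annotations$term[annotations$gene == g]
      any(vapply(terms, function(tt) t %in% all_ancestors(tt), logical(1)))
    }, logical(1))
    sum(hit)
  }
  n_root <- genes_at(graph$root)
  ic <- function(t) -log(genes_at(t) / n_root)
  annotated <- unique(unlist(lapply(unique(annotations$term), all_ancestors)))
  ic_all <- vapply(annotated, ic, numeric(1))
  ic_max <- max(ic_all)
  common <- intersect(all_ancestors(t1), all_ancestors(t2))
  1 - max(vapply(common, ic, numeric(1))) / ic_max
}

# A tiny hand-buildable methylation dataset: one chip unless stated, QC
# columns appended, M values supplied directly.
make_tiny_md <- function(M, classes, pairs = NULL, chips = NULL,
                         cohort = NULL) {
  n <- ncol(M)
  ids <- sprintf("s%02d", seq_len(n))
  sheet <- data.frame(
    sample_id = ids, class = classes,
    chip = if (is.null(chips)) rep("chip01", n) else chips,
    pair = if (is.null(pairs)) rep(NA_character_, n) else pairs,
    cohort = if (is.null(cohort))
      ifelse(classes == "QC", "QC", "BCCA") else cohort,
    split = ifelse(classes == "QC", NA, "train"),
    stringsAsFactors = FALSE)
  probes <- sprintf("cg%03d", seq_len(nrow(M)))
  dimnames(M) <- list(probes, ids)
  structure(list(probes = probes, samples = ids, M = M, I = M * 0 + 10,
                 sheet = sheet),
            class = "methylation_dataset")
}

# Standard small synthetic cohort reused by several tests.
tiny_cohort <- function(seed = 11, ...) {
  simulate_cohort(simulation_config(
    n_probes = 300, n_genes = 30, n_pairs_per_disease = 10, chip_size = 12,
    qc_per_chip = 1, n_planted = 10, effect_delta = 1.5, bias_slope = 0.3,
    bias_offset = 0.2, noise_sd = 0.05, seed = seed, ...))
}
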