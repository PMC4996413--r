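# Ontology containers, information content, Resnik distance against a
# brute-force oracle, clique expansion, pruning and centrality ranking.

# A hand-sized corpus used across blocks:
#   root R covers everything; branches A and B; A1, A2 under A; B1 under B.
#   Eight genes distributed so IC values are round numbers.
toy_graph <- function() {
  go_graph(data.frame(id = c("R", "A", "B", "A1", "A2", "B1"),
                      name = paste("term", 1:6), aspect = "BP",
                      stringsAsFactors = FALSE),
           data.frame(child = c("A", "B", "A1", "A2", "B1"),
                      parent = c("R", "R", "A", "A", "B"),
                      stringsAsFactors = FALSE))
}

toy_corpus <- function(graph = toy_graph()) {
  ann <- data.frame(
    gene = c("g1", "g2", "g3", "g4", "g5", "g6", "g7", "g8"),
    term = c("A1", "A1", "A2", "A2", "B1", "B1", "B1", "B1"),
    stringsAsFactors = FALSE)
  annotation_corpus(ann, graph)
}

test_that("annotation propagation closes over ancestors and is idempotent", {
  corpus <- toy_corpus()
  expect_setequal(corpus$gene2terms_prop$g1, c("A1", "A", "R"))
  expect_length(corpus$term2genes_prop$R, 8)       # root covers the universe
  again <- propagate_annotations(toy_graph(), corpus)
  expect_identical(again$gene2terms_prop, corpus$gene2terms_prop)
  expect_identical(again$ic, corpus$ic)
})

test_that("information content is monotone from parent to child", {
  ont <- generate_ontology_corpus(25, seed = 8)
  corpus <- ont$corpus
  for (t in names(corpus$ic)) {
    for (p in ont$graph$parents[[t]]) {
      if (p %in% names(corpus$ic))
        expect_gte(corpus$ic[[t]], corpus$ic[[p]])
    }
  }
})

test_that("information content follows annotation frequency", {
  corpus <- toy_corpus()
  expect_equal(information_content("R", corpus), 0)
  expect_equal(information_content("A", corpus), log(2))   # 4 of 8 genes
  expect_equal(information_content("B", corpus), log(2))
  expect_equal(information_content("A1", corpus), log(4))  # 2 of 8
  expect_equal(information_content("B1", corpus), log(2))
  expect_error(information_content("nope", corpus), "nope")
})

test_that("Resnik distance matches the brute-force all-ancestor oracle", {
  graph <- toy_graph(); corpus <- toy_corpus()
  ann <- corpus$annotations
  terms <- names(corpus$ic)
  for (i in seq_along(terms)) for (j in seq_len(i)) {
    expect_equal(resnik_distance(terms[i], terms[j], corpus),
                 oracle_resnik(terms[i], terms[j], graph, ann),
                 tolerance = 1e-12,
                 label = paste(terms[i], terms[j]))
    # symmetry
    expect_equal(resnik_distance(terms[i], terms[j], corpus),
                 resnik_distance(terms[j], terms[i], corpus))
  }
  # terms sharing only the root are maximally distant
  expect_equal(resnik_distance("A1", "B1", corpus), 1)
  # self-distance: 1 - IC(t)/IC_max
  expect_equal(resnik_distance("A1", "A1", corpus),
               1 - log(4) / max(corpus$ic))
  # the generated DAG agrees with the oracle too
  ont <- generate_ontology_corpus(12, seed = 6)
  annotated <- names(ont$corpus$ic)[ont$corpus$ic > 0]
  pick <- annotated[seq_len(min(6, length(annotated)))]
  for (t1 in pick) for (t2 in pick)
    expect_equal(resnik_distance(t1, t2, ont$corpus),
                 oracle_resnik(t1, t2, ont$graph, ont$corpus$annotations),
                 tolerance = 1e-12)
})

test_that("clique expansion walks one ontology step, excluding the root", {
  graph <- toy_graph(); corpus <- toy_corpus()
  expect_identical(bubble_cliques(character(0), graph, corpus),
                   structure(list(), names = character(0)))
  # g1 on A1: neighbourhood {A1, A} -> genes annotated to A1 or A (direct)
  cl <- bubble_cliques("g1", graph, corpus)
  expect_setequal(cl$g1, c("g1", "g2"))
  # direct annotation on a mid-level term reaches its children's genes
  ann2 <- rbind(corpus$annotations,
                data.frame(gene = "g9", term = "A"))
  corpus2 <- annotation_corpus(ann2, graph)
  cl2 <- bubble_cliques("g9", graph, corpus2)
  expect_setequal(cl2$g9, c("g1", "g2", "g3", "g4", "g9"))
  expect_warning(bubble_cliques(c("g1", "ghost"), graph, corpus), "ghost")
})

test_that("pruning drops the generic member of close pairs, never more", {
  graph <- toy_graph()
  # give one gene both a term and its own ancestor: d(A1, A) is small when
  # IC(A) is close enough to IC(A1) relative to the corpus maximum
  ann <- rbind(toy_corpus()$annotations,
               data.frame(gene = "gx", term = c("A1", "A")))
  corpus <- annotation_corpus(ann, graph)
  d <- resnik_distance("A1", "A", corpus)
  cfg_tight <- semantic_config(relaxation = d + 0.01)
  kept <- prune_gene_terms("gx", corpus, cfg_tight)
  expect_identical(kept, "A1")      # lower-IC ancestor A is dropped
  # relaxation 0: vacuous, nothing pruned
  cfg0 <- semantic_config(relaxation = 0)
  expect_setequal(prune_gene_terms("gx", corpus, cfg0), c("A", "A1"))
  # surviving sets are pairwise >= relaxation by construction
  ont <- generate_ontology_corpus(30, seed = 3)
  cfg <- semantic_config(relaxation = 0.15)
  for (g in utils::head(names(ont$corpus$gene2terms), 10)) {
    kept <- prune_gene_terms(g, ont$corpus, cfg)
    if (length(kept) > 1)
      for (i in seq_len(length(kept) - 1)) for (j in (i + 1):length(kept))
        expect_gte(resnik_distance(kept[i], kept[j], ont$corpus), 0.15)
  }
})

test_that("centrality ranking puts the designed hub first, deterministically", {
  ont <- generate_ontology_corpus(40, seed = 9)
  genes <- names(ont$corpus$gene2terms)
  rk <- rank_gene_centrality(genes, ont$graph, ont$corpus)
  expect_identical(rk$gene[1], "G001")
  expect_gte(rk$score[1], 5)
  expect_true(all(diff(rk$score) <= 0))
  # invariant to input order
  rk2 <- rank_gene_centrality(rev(genes), ont$graph, ont$corpus)
  expect_identical(rk, rk2)
  # relaxation 0 scores dominate relaxation 0.15 scores per gene
  rk0 <- rank_gene_centrality(genes, ont$graph, ont$corpus,
                              semantic_config(relaxation = 0))
  merged <- merge(rk0, rk, by = "gene")
  expect_true(all(merged$score.x >= merged$score.y))
  # single-term genes all score 1 and order by the tie-break
  graph <- toy_graph()
  corpus <- toy_corpus()
  rk1 <- rank_gene_centrality(c("g3", "g1", "g2"), graph, corpus)
  expect_identical(rk1$gene, c("g1", "g2", "g3"))
  expect_true(all(rk1$score == 1))
})

test_that("gene-to-probe mapping respects annotation and preselection", {
  pa <- data.frame(probe = c("cg1", "cg2", "cg3", "cg4"),
                   gene = c("gA", "gA", "gB", "gC"),
                   region = "Body", stringsAsFactors = FALSE)
  pre <- union_preselect(list(E1 = c("cg1", "cg3"), E2 = c("cg9")))
  expect_warning(out <- genes_to_probes(c("gA", "gB", "gZ"), pa, pre), "gZ")
  expect_identical(out$probes, c("cg1", "cg2", "cg3"))
  expect_identical(out$by_experiment$E1, c("cg1", "cg3"))
  expect_identical(out$by_experiment$E2, character(0))
  # union of per-experiment intersections stays within the full set
  expect_true(all(unlist(out$by_experiment) %in% out$probes))
})

test_that("graph construction rejects cycles and multiple roots", {
  expect_error(go_graph(data.frame(id = c("a", "b"), name = c("a", "b"),
                                   aspect = "BP"),
                        data.frame(child = c("a", "b"),
                                   parent = c("b", "a"))),
               "cycle")
  expect_error(go_graph(data.frame(id = c("a", "b"), name = c("a", "b"),
                                   aspect = "BP"),
                        data.frame(child = character(0),
                                   parent = character(0))),
               "root")
})
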