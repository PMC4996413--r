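# End-to-end pipeline on a synthetic cohort.
#
# Chains every stage on a seeded synthetic cohort: simulation, two-step
# QC normalization, per-experiment statistical pre-selection on the
# training split, GA wrapper selection over the pre-selected union for the
# three-class task, semantic gene-centrality selection of the pre-selected
# genes, the classifier suite on the independent test split, and enrichment
# plus region-distribution reporting of the selected gene sets. The whole
# run is a pure function of (config, parameters, seed): two invocations
# serialize byte-identically.

#' Run the full biomarker-discovery pipeline on a synthetic cohort
#'
#' @param config A [simulation_config()]; the cohort, planted truth and toy
#'   ontology are generated from it.
#' @param n_bins Intensity bins of the within-chip normalization.
#' @param boot_B Sign-flip bootstrap replicates of the pre-selection.
#' @param top_frac,cv_min Pre-selection thresholds.
#' @param ga GA settings as a [ga_config()]; `NULL` skips the GA stage.
#' @param centrality_top Number of top-centrality genes mapped back to
#'   probes in the semantic stage.
#' @param relaxation Semantic pruning relaxation.
#' @param ann_epochs ANN training epochs in the classifier suite.
#' @param seed Master seed of the analysis stages (the cohort uses
#'   `config$seed`).
#' @return A nested report list (class `pipeline_result`) with elements
#'   `config_echo`, `normalization`, `preselection`, `ga`, `semantic`,
#'   `classification` and `enrichment`; serialize with [write_report()].
#' @export
run_pipeline <- function(config, n_bins = 100L, boot_B = 200L,
                         top_frac = 0.01, cv_min = 1.0, ga = NULL,
                         centrality_top = 10L, relaxation = 0.15,
                         ann_epochs = 1000L, seed = 1L) {
  seed <- as.integer(seed)
  cohort <- simulate_cohort(config)
  norm <- normalize_dataset(cohort$biased, n_bins = n_bins)
  ds <- norm$ds

  pre <- preselect(ds, diseases = c("BCCA", "LYCA"),
                   cfg = bootstrap_config(boot_B, seed),
                   top_frac = top_frac, cv_min = cv_min, split = "train")
  features <- pre$result$union

  sheet <- ds$sheet
  study <- !is.na(sheet$split)
  train_ids <- sheet$sample_id[study & sheet$split == "train"]
  test_ids <- sheet$sample_id[study & sheet$split == "test"]
  X <- t(ds$M[features, , drop = FALSE])
  y <- stats::setNames(sheet$class, sheet$sample_id)
  train_x <- X[train_ids, , drop = FALSE]
  test_x <- X[test_ids, , drop = FALSE]

  ga_out <- NULL
  ga_features <- features
  if (!is.null(ga) && length(features) > 1L) {
    ga$seed <- seed + 11L
    if (ga$d_max > length(features)) ga$d_max <- length(features)
    ga_out <- evolve(train_x, y[train_ids], ga)
    ga_features <- features[ga_out$mask]
  }

  ann_df <- cohort$ontology$probe_annotation
  pre_genes <- sort(unique(ann_df$gene[ann_df$probe %in% features]))
  sem_cfg <- semantic_config(relaxation = relaxation)
  ranking <- rank_gene_centrality(pre_genes, cohort$ontology$graph,
                                  cohort$ontology$corpus, sem_cfg)
  top_genes <- utils::head(ranking$gene, centrality_top)
  sem_probes <- genes_to_probes(top_genes, ann_df, pre$result)

  suite <- evaluate_suite(train_x, y[train_ids], test_x, y[test_ids],
                          mask = features %in% ga_features,
                          seed = seed + 23L, epochs = ann_epochs)

  universe <- sort(unique(ann_df$gene))
  term_sets <- cohort$ontology$corpus$term2genes_prop
  enrich_or_empty <- function(genes) {
    if (!length(intersect(genes, universe)))
      return(data.frame(term = character(0), description = character(0),
                        p_value = numeric(0), enrichment = character(0),
                        a = integer(0), K = integer(0)))
    enrich_term_sets(genes, universe, term_sets)
  }
  enr_sem <- enrich_or_empty(top_genes)
  ga_genes <- sort(unique(ann_df$gene[ann_df$probe %in% ga_features]))
  enr_ga <- enrich_or_empty(ga_genes)
  regions <- region_distribution(sem_probes$probes, ann_df)

  structure(list(
    config_echo = unclass(config),
    seed = seed,
    normalization = norm$report,
    preselection = list(
      thresholds = pre$thresholds,
      sets = lapply(pre$result$sets, identity),
      union_size = length(features)),
    ga = if (is.null(ga_out)) NULL else list(
      n_selected = length(ga_features),
      features = ga_features,
      fitness = ga_out$fitness,
      log = ga_out$log),
    semantic = list(
      relaxation = relaxation,
      ranking = ranking,
      top_genes = top_genes,
      probes = sem_probes$probes,
      probes_by_experiment = sem_probes$by_experiment),
    classification = list(
      features_used = ga_features,
      table = suite$table,
      reports = lapply(suite$reports, unclass)),
    enrichment = list(
      semantic = enr_sem,
      ga = enr_ga,
      region_distribution = regions)),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Biomarker-discovery pipeline result\n")
  cat(sprintf("  pre-selected union: %d probes\n", x$preselection$union_size))
  if (!is.null(x$ga))
    cat(sprintf("  GA-selected: %d probes (fitness %.3f)\n",
                x$ga$n_selected, x$ga$fitness))
  cat(sprintf("  semantic top genes: %s\n",
              paste(x$semantic$top_genes, collapse = ", ")))
  cat("  independent-set performance (%):\n")
  print(round(x$classification$table, 2))
  invisible(x)
}
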