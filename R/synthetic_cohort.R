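# Seeded synthetic methylation cohorts with known planted truth.
#
# The generator emulates a matched case-control epidemiological design on a
# two-channel methylation array: two disease cohorts (breast cancer, "BCCA",
# and B-cell lymphoma, "LYCA"), each with its own matched control arm, samples
# distributed over chips that each carry replicates of one shared technical
# quality-control (QC) sample, chip-level technical bias acting on the M scale
# as a function of average intensity, and a configurable number of planted
# differentially-methylated probes per disease.

#' Simulation configuration for a synthetic methylation cohort
#'
#' Bundles and validates every knob of the synthetic-cohort generator. The
#' defaults describe the study conditions used throughout the package's own
#' simulation experiments: a desk-scale matched case-control design with two
#' disease arms, one QC replicate per chip, bimodal baseline methylation and a
#' planted case-vs-control shift on the M scale.
#'
#' @param n_probes Number of CpG probes on the simulated array.
#' @param n_genes Number of genes in the toy annotation/ontology.
#' @param n_pairs_per_disease Matched case-control pairs per disease arm.
#' @param chip_size Total samples per chip, QC replicates included.
#' @param qc_per_chip QC replicates placed on every chip.
#' @param n_planted Planted differentially-methylated probes per disease
#'   (the two diseases receive disjoint planted sets).
#' @param effect_delta Planted case-vs-control shift, in M-value units.
#' @param bias_slope,bias_offset Maximum-magnitude chip bias coefficients;
#'   chip `c` distorts M by `m_c * (bias_slope * I + bias_offset)` with
#'   deterministic per-chip multipliers `m_c` spread over `[-1, 1]`.
#' @param noise_sd Multiplicative channel noise scale (sd of the log-normal
#'   noise factor applied independently to each channel intensity).
#' @param train_fraction Fraction of matched pairs assigned to the training
#'   split (QC samples belong to neither split).
#' @param seed Integer seed; identical configurations give bit-identical
#'   cohorts.
#' @return An object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_probes = 2000, n_genes = 120,
                              n_pairs_per_disease = 30, chip_size = 12,
                              qc_per_chip = 1, n_planted = 50,
                              effect_delta = 1.5, bias_slope = 0,
                              bias_offset = 0, noise_sd = 0.05,
                              train_fraction = 0.5, seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes), n_genes = as.integer(n_genes),
              n_pairs_per_disease = as.integer(n_pairs_per_disease),
              chip_size = as.integer(chip_size),
              qc_per_chip = as.integer(qc_per_chip),
              n_planted = as.integer(n_planted),
              effect_delta = as.numeric(effect_delta),
              bias_slope = as.numeric(bias_slope),
              bias_offset = as.numeric(bias_offset),
              noise_sd = as.numeric(noise_sd),
              train_fraction = as.numeric(train_fraction),
              seed = as.integer(seed))
  counts <- c("n_probes", "n_genes", "n_pairs_per_disease", "chip_size",
              "qc_per_chip")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop(sprintf("'%s' must be a count >= 1", f))
  }
  if (cfg$n_planted < 0L) stop("'n_planted' must be >= 0")
  if (cfg$n_planted > cfg$n_probes) stop("'n_planted' exceeds 'n_probes'")
  if (cfg$chip_size <= cfg$qc_per_chip)
    stop("'chip_size' must exceed 'qc_per_chip'")
  if (cfg$noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1)
    stop("'train_fraction' must lie in (0, 1)")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  probes: %d  genes: %d  pairs/disease: %d  planted/disease: %d\n",
              x$n_probes, x$n_genes, x$n_pairs_per_disease, x$n_planted))
  cat(sprintf("  chip size: %d (QC %d)  effect: %.2f M  bias: slope %.2f offset %.2f  noise sd: %.3f\n",
              x$chip_size, x$qc_per_chip, x$effect_delta, x$bias_slope,
              x$bias_offset, x$noise_sd))
  invisible(x)
}

.sim_diseases <- c("BCCA", "LYCA")

# Number of chips needed to hold all study samples of a config.
.n_chips <- function(cfg) {
  study <- 4L * cfg$n_pairs_per_disease          # control + case, two arms
  slots <- cfg$chip_size - cfg$qc_per_chip
  as.integer(ceiling(study / slots))
}

#' Draw the planted ground truth of a synthetic cohort
#'
#' Draws baseline per-probe methylation fractions from a bimodal mixture
#' (equal-weight Beta(2,10) and Beta(10,2) components plus 10% Beta(2,2),
#' matching the bimodal marginal of array methylation), selects disjoint
#' planted differentially-methylated probe sets for the two diseases, and
#' assigns per-chip bias coefficients by spreading the configured maximum
#' slope/offset over chips with multipliers `seq(-1, 1)`.
#'
#' @param config A [simulation_config()] object.
#' @return An object of class `planted_truth` with fields `true_beta`
#'   (named per-probe baseline beta), `dm_probes` (list `BCCA`/`LYCA` of probe
#'   ids) and `chip_bias` (data frame chip/slope/offset).
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (2L * config$n_planted > config$n_probes)
    stop("cannot plant disjoint sets: 2 * n_planted exceeds n_probes")
  set.seed(config$seed)
  probes <- sprintf("cg%06d", seq_len(config$n_probes))

  comp <- sample(c(1L, 2L, 3L), config$n_probes, replace = TRUE,
                 prob = c(0.45, 0.45, 0.10))
  true_beta <- numeric(config$n_probes)
  true_beta[comp == 1L] <- stats::rbeta(sum(comp == 1L), 2, 10)
  true_beta[comp == 2L] <- stats::rbeta(sum(comp == 2L), 10, 2)
  true_beta[comp == 3L] <- stats::rbeta(sum(comp == 3L), 2, 2)
  names(true_beta) <- probes

  dm <- list(BCCA = character(0), LYCA = character(0))
  if (config$n_planted > 0L) {
    picked <- sample(probes, 2L * config$n_planted)
    dm$BCCA <- sort(picked[seq_len(config$n_planted)])
    dm$LYCA <- sort(picked[config$n_planted + seq_len(config$n_planted)])
  }

  k <- .n_chips(config)
  mult <- if (k == 1L) 1 else seq(-1, 1, length.out = k)
  chip_bias <- data.frame(chip = sprintf("chip%02d", seq_len(k)),
                          slope = config$bias_slope * mult,
                          offset = config$bias_offset * mult,
                          stringsAsFactors = FALSE)

  structure(list(true_beta = true_beta, dm_probes = dm,
                 chip_bias = chip_bias),
            class = "planted_truth")
}

#' Lay out matched pairs, chips and the train/test split
#'
#' Builds the sample sheet of a synthetic cohort: one matched control per case
#' in each disease arm (controls carry the cohort tag of their arm), samples
#' distributed over chips of `chip_size` with `qc_per_chip` QC replicates
#' each, and a pair-level stratified train/test split (both members of a pair
#' share a split so paired statistics stay within a split).
#'
#' @param config A [simulation_config()] object.
#' @return A `data.frame` sample sheet with columns `sample_id`, `class`
#'   (`control`, `BCCA`, `LYCA` or `QC`), `chip`, `pair` (`NA` for QC),
#'   `cohort` and `split` (`train`/`test`, `NA` for QC).
#' @export
generate_pairs_and_chips <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  np <- config$n_pairs_per_disease

  rows <- list()
  for (d in .sim_diseases) {
    pair_ids <- sprintf("%s_p%03d", d, seq_len(np))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("%s_ctrl%03d", d, seq_len(np)),
      class = "control", pair = pair_ids, cohort = d,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("%s_case%03d", d, seq_len(np)),
      class = d, pair = pair_ids, cohort = d,
      stringsAsFactors = FALSE)
  }
  sheet <- do.call(rbind, rows)

  # pair-level stratified split: both members of a pair share the split
  sheet$split <- NA_character_
  for (d in .sim_diseases) {
    pair_ids <- sprintf("%s_p%03d", d, seq_len(np))
    n_train <- max(1L, round(config$train_fraction * np))
    train_pairs <- sample(pair_ids, n_train)
    sheet$split[sheet$pair %in% train_pairs] <- "train"
    sheet$split[sheet$cohort == d & is.na(sheet$split)] <- "test"
  }

  # chip assignment: random permutation of study samples over chip slots
  k <- .n_chips(config)
  slots <- config$chip_size - config$qc_per_chip
  perm <- sample(nrow(sheet))
  chip_of <- character(nrow(sheet))
  chip_of[perm] <- sprintf("chip%02d", ((seq_len(nrow(sheet)) - 1L) %/% slots) + 1L)
  sheet$chip <- chip_of

  qc <- data.frame(
    sample_id = sprintf("QC_chip%02d_r%d",
                        rep(seq_len(k), each = config$qc_per_chip),
                        rep(seq_len(config$qc_per_chip), times = k)),
    class = "QC", pair = NA_character_, cohort = "QC",
    split = NA_character_,
    chip = sprintf("chip%02d", rep(seq_len(k), each = config$qc_per_chip)),
    stringsAsFactors = FALSE)

  sheet <- rbind(sheet[, c("sample_id", "class", "chip", "pair", "cohort", "split")],
                 qc[, c("sample_id", "class", "chip", "pair", "cohort", "split")])
  rownames(sheet) <- NULL
  validate_sample_sheet(sheet)
}

.logit2 <- function(beta) log2(beta / (1 - beta))
.expit2 <- function(x) 1 / (1 + 2^(-x))

#' Generate two-channel intensities for a synthetic cohort
#'
#' Per sample and probe, the effective methylation fraction is
#' `beta' = expit2(logit2(true_beta) + effect_delta)` for a case sample of a
#' disease at one of its planted probes, and `expit2(logit2(true_beta))`
#' otherwise (`logit2`/`expit2` are the base-2 logit and its inverse, so
#' `effect_delta` is an exact shift on the M scale). All QC replicates share
#' the fixed baseline profile with no biological shift. Total intensity is
#' drawn log-normal per probe and sample; each channel receives independent
#' multiplicative log-normal noise of scale `noise_sd`. Chip bias is *not*
#' applied here — see [inject_chip_bias()].
#'
#' @param config A [simulation_config()] object.
#' @param truth A [generate_truth()] result consistent with `config`.
#' @param sheet Optional sample sheet; defaults to
#'   [generate_pairs_and_chips()] on the same config.
#' @return An `intensity_dataset`: list with `probes`, `samples`, `meth`,
#'   `unmeth` (probes x samples matrices, all intensities >= 0) and `sheet`.
#' @export
generate_intensities <- function(config, truth, sheet = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "planted_truth"))
  if (length(truth$true_beta) != config$n_probes)
    stop("truth is inconsistent with config: probe count differs")
  if (is.null(sheet)) sheet <- generate_pairs_and_chips(config)
  set.seed(config$seed + 202L)

  probes <- names(truth$true_beta)
  samples <- sheet$sample_id
  P <- length(probes); S <- length(samples)

  base_m <- .logit2(truth$true_beta)
  eff_m <- matrix(base_m, nrow = P, ncol = S)
  for (d in .sim_diseases) {
    idx_s <- which(sheet$class == d)
    idx_p <- match(truth$dm_probes[[d]], probes)
    if (length(idx_s) && length(idx_p))
      eff_m[idx_p, idx_s] <- eff_m[idx_p, idx_s] + config$effect_delta
  }
  beta_eff <- .expit2(eff_m)

  total <- matrix(exp(stats::rnorm(P * S, mean = log(2000), sd = 0.6)),
                  nrow = P, ncol = S)
  eps1 <- matrix(exp(stats::rnorm(P * S, sd = config$noise_sd)), P, S)
  eps2 <- matrix(exp(stats::rnorm(P * S, sd = config$noise_sd)), P, S)

  meth <- total * beta_eff * eps1
  unmeth <- total * (1 - beta_eff) * eps2
  dimnames(meth) <- dimnames(unmeth) <- list(probes, samples)

  structure(list(probes = probes, samples = samples,
                 meth = meth, unmeth = unmeth, sheet = sheet),
            class = "intensity_dataset")
}

#' Inject chip-level technical bias on the M scale
#'
#' For every sample on chip `c`, the M-value of each probe is distorted by
#' `slope_c * I + offset_c` where `I` is the probe's average intensity in that
#' sample. The distortion is applied exactly on the M scale by rewriting the
#' two channels as `meth = 2^(I + M'/2)`, `unmeth = 2^(I - M'/2)`, which
#' preserves `I` exactly, so normalization recovery can be measured without
#' confounding. QC replicates are biased like any other sample on their chip.
#'
#' @param ds An `intensity_dataset`.
#' @param truth A `planted_truth` whose `chip_bias` covers every chip in the
#'   sheet.
#' @return The biased `intensity_dataset`.
#' @export
inject_chip_bias <- function(ds, truth) {
  stopifnot(inherits(ds, "intensity_dataset"), inherits(truth, "planted_truth"))
  bias <- truth$chip_bias
  unknown <- setdiff(unique(ds$sheet$chip), bias$chip)
  if (length(unknown))
    stop("unknown chip id(s) without bias coefficients: ",
         paste(unknown, collapse = ", "))
  meth <- pmax(ds$meth, 1); unmeth <- pmax(ds$unmeth, 1)
  M <- log2(meth / unmeth)
  I <- 0.5 * log2(meth * unmeth)
  for (i in seq_len(nrow(bias))) {
    cols <- which(ds$sheet$chip == bias$chip[i])
    if (!length(cols)) next
    M[, cols] <- M[, cols] + bias$slope[i] * I[, cols] + bias$offset[i]
  }
  ds$meth <- 2^(I + M / 2)
  ds$unmeth <- 2^(I - M / 2)
  dimnames(ds$meth) <- dimnames(ds$unmeth) <- list(ds$probes, ds$samples)
  ds
}

#' Generate a toy ontology, gene annotations and probe annotation
#'
#' Builds a single-aspect rooted DAG of depth four (root, branch, middle,
#' leaf layers), annotates genes to leaf-level terms, and designates the
#' first gene as a "hub" annotated to one leaf in each of five distinct
#' branches — terms whose only common ancestor is the root, hence mutually
#' maximally distant under Resnik distance. Every other gene is annotated to
#' one to three terms inside a single middle-term subtree. Each gene maps to
#' one to five probes carrying genomic-region labels drawn from the
#' seven-category array vocabulary (TSS200, TSS1500, 5'UTR, 1stExon, Body,
#' 3'UTR, Intergenic) with array-like proportions.
#'
#' @param n_genes Number of genes (>= 10).
#' @param seed Integer seed.
#' @param probe_ids Optional pool of probe ids to annotate (e.g. the cohort's
#'   probe universe); by default fresh probe ids are invented.
#' @return A list with `graph` (a `go_graph`), `corpus` (an
#'   `annotation_corpus` of direct gene-term links) and `probe_annotation`
#'   (data frame probe/gene/region).
#' @export
generate_ontology_corpus <- function(n_genes, seed = 1L, probe_ids = NULL) {
  if (n_genes < 10L) stop("'n_genes' must be >= 10")
  set.seed(seed + 303L)

  n_branch <- 6L; n_mid_per_branch <- 2L; n_leaf_per_mid <- 2L
  root <- "T:0000"
  branches <- sprintf("T:%04d", seq_len(n_branch))
  mids <- character(0); leaves <- character(0)
  parent <- list()
  for (b in seq_len(n_branch)) {
    parent[[branches[b]]] <- root
    for (m in seq_len(n_mid_per_branch)) {
      mid <- sprintf("T:%02d%02d", b, m)
      mids <- c(mids, mid); parent[[mid]] <- branches[b]
      for (l in seq_len(n_leaf_per_mid)) {
        leaf <- sprintf("T:%02d%02d%d", b, m, l)
        leaves <- c(leaves, leaf); parent[[leaf]] <- mid
      }
    }
  }
  terms <- c(root, branches, mids, leaves)
  edges <- data.frame(child = setdiff(terms, root),
                      parent = unlist(parent[setdiff(terms, root)]),
                      stringsAsFactors = FALSE)
  graph <- go_graph(terms = data.frame(id = terms, name = paste("term", terms),
                                       aspect = "BP", stringsAsFactors = FALSE),
                    edges = edges)

  genes <- sprintf("G%03d", seq_len(n_genes))
  hub <- genes[1L]
  # one leaf from each of five distinct branches: pairwise MICA is the root
  hub_terms <- sprintf("T:%02d011", 1:5)
  ann <- data.frame(gene = hub, term = hub_terms, stringsAsFactors = FALSE)
  mid_subtree <- function(mid) c(mid, names(parent)[vapply(parent, identical,
                                                           logical(1), mid)])
  for (g in genes[-1L]) {
    mid <- sample(mids, 1L)
    pool <- mid_subtree(mid)
    k <- sample(1:3, 1L)
    ann <- rbind(ann, data.frame(gene = g,
                                 term = sample(pool, min(k, length(pool))),
                                 stringsAsFactors = FALSE))
  }
  corpus <- annotation_corpus(ann, graph)

  regions <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR",
               "Intergenic")
  region_w <- c(0.129, 0.159, 0.102, 0.022, 0.309, 0.032, 0.247)
  n_probe_per_gene <- sample(1:5, n_genes, replace = TRUE)
  total_probes <- sum(n_probe_per_gene)
  if (is.null(probe_ids)) {
    pool <- sprintf("cg%06d", seq_len(total_probes))
  } else {
    if (length(probe_ids) < total_probes)
      pool <- rep_len(probe_ids, total_probes)  # small universes share probes
    else pool <- sample(probe_ids, total_probes)
  }
  probe_annotation <- data.frame(
    probe = pool[seq_len(total_probes)],
    gene = rep(genes, times = n_probe_per_gene),
    region = sample(regions, total_probes, replace = TRUE, prob = region_w),
    stringsAsFactors = FALSE)

  list(graph = graph, corpus = corpus, probe_annotation = probe_annotation)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper chaining [generate_truth()],
#' [generate_pairs_and_chips()], [generate_intensities()],
#' [inject_chip_bias()] and [generate_ontology_corpus()] (the ontology's
#' probe annotation is drawn from the cohort's probe universe so selected
#' probes map to genes).
#'
#' @param config A [simulation_config()] object.
#' @return A list with `config`, `truth`, `raw` (bias-free intensities),
#'   `biased` (intensities after chip bias), `sheet`, and `ontology`.
#' @export
simulate_cohort <- function(config) {
  truth <- generate_truth(config)
  sheet <- generate_pairs_and_chips(config)
  raw <- generate_intensities(config, truth, sheet)
  biased <- inject_chip_bias(raw, truth)
  ontology <- generate_ontology_corpus(config$n_genes, seed = config$seed,
                                       probe_ids = raw$probes)
  list(config = config, truth = truth, raw = raw, biased = biased,
       sheet = sheet, ontology = ontology)
}
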