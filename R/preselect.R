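# Statistical pre-selection of CpG sites.
#
# Two per-probe statistics are combined per case-control experiment:
# (i) the scaled coefficient of variation — the probe's CV over the pooled
# controls-and-cases samples divided by its CV across QC replicates, a
# measure of real inter-class variability beyond technical noise — and
# (ii) a paired t-test whose p-value is corrected by a sign-flip bootstrap
# against multiple-hypothesis bias. Probes in the top fraction of corrected
# p-values that also pass ScaledCV > 1 are pre-selected; the per-experiment
# sets are unioned with provenance retained.

# Samples of one experiment: matched pairs of a disease arm. Controls come
# from the arm's own cohort (control arms are kept separate per cohort).
.experiment_pairs <- function(sheet, disease, split = NULL) {
  rows <- sheet[!is.na(sheet$pair) & sheet$cohort == disease, , drop = FALSE]
  if (!is.null(split)) rows <- rows[rows$split %in% split, , drop = FALSE]
  ctrl <- rows[rows$class == "control", c("pair", "sample_id")]
  case <- rows[rows$class == disease, c("pair", "sample_id")]
  merged <- merge(ctrl, case, by = "pair", suffixes = c("_control", "_case"))
  merged[order(merged$pair), , drop = FALSE]
}

#' Scaled coefficient of variation per probe
#'
#' `ScaledCV(p) = CV_pool(p) / CV_QC(p)` with `CV = sd / |mean|` computed on
#' M-values; the pool is the union of controls and cases of the experiment,
#' the QC CV uses the replicated technical sample. Guards: when either mean
#' magnitude falls below `1e-8` the ratio degenerates (M-values cross zero),
#' so the probe falls back to the plain sd ratio `sd_pool / sd_QC` and is
#' flagged; when `sigma_QC` is 0 the ratio is `+Inf`, which passes the
#' `ScaledCV > 1` criterion by construction — real variability trivially
#' exceeds absent technical variability.
#'
#' @param ds A `methylation_dataset`.
#' @param disease Disease label of the experiment (cases of this class,
#'   matched controls of the same cohort).
#' @param split Optional split restriction (e.g. `"train"`).
#' @return Data frame probe / scaled_cv / cv_fallback (logical flag).
#' @export
scaled_cv <- function(ds, disease, split = NULL) {
  stopifnot(inherits(ds, "methylation_dataset"))
  pairs <- .experiment_pairs(ds$sheet, disease, split)
  pool_ids <- c(pairs$sample_id_control, pairs$sample_id_case)
  if (length(pool_ids) < 3L) stop("experiment pool has fewer than 3 samples")
  qc_ids <- ds$sheet$sample_id[ds$sheet$class == "QC"]
  if (length(qc_ids) < 2L) stop("scaled CV requires >= 2 QC replicates")
  Mp <- ds$M[, match(pool_ids, ds$samples), drop = FALSE]
  Mq <- ds$M[, match(qc_ids, ds$samples), drop = FALSE]
  sd_pool <- apply(Mp, 1L, stats::sd)
  m_pool <- abs(rowMeans(Mp))
  sd_qc <- apply(Mq, 1L, stats::sd)
  m_qc <- abs(rowMeans(Mq))
  fallback <- m_pool < 1e-8 | m_qc < 1e-8
  cv_pool <- ifelse(fallback, sd_pool, sd_pool / m_pool)
  cv_qc <- ifelse(fallback, sd_qc, sd_qc / m_qc)
  ratio <- ifelse(cv_qc == 0, Inf, cv_pool / cv_qc)
  data.frame(probe = ds$probes, scaled_cv = unname(ratio),
             cv_fallback = unname(fallback), stringsAsFactors = FALSE)
}

# Case-minus-control paired difference matrix (probes x pairs).
.paired_differences <- function(ds, disease, split = NULL) {
  pairs <- .experiment_pairs(ds$sheet, disease, split)
  if (nrow(pairs) < 2L) stop("fewer than 2 complete pairs")
  D <- ds$M[, match(pairs$sample_id_case, ds$samples), drop = FALSE] -
    ds$M[, match(pairs$sample_id_control, ds$samples), drop = FALSE]
  colnames(D) <- pairs$pair
  D
}

#' Paired t-test per probe
#'
#' For each probe, the case-minus-control differences over matched pairs
#' give `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom
#' and a two-sided p-value. Degenerate probes with `sd(d) = 0` get `p = 1`
#' when the mean is also 0, otherwise the smallest representable p with a
#' warning.
#'
#' @param ds A `methylation_dataset`.
#' @param disease Disease label of the experiment.
#' @param split Optional split restriction.
#' @return Data frame probe / t_stat / p_raw / df.
#' @export
paired_t <- function(ds, disease, split = NULL) {
  D <- .paired_differences(ds, disease, split)
  n <- ncol(D)
  m <- rowMeans(D)
  s <- sqrt(rowSums((D - m)^2) / (n - 1L))
  t_stat <- ifelse(s == 0, ifelse(m == 0, 0, sign(m) * Inf),
                   m / (s / sqrt(n)))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1L)
  degen <- s == 0 & m != 0
  if (any(degen)) {
    warning(sum(degen), " probe(s) with zero-variance nonzero differences: ",
            "p set to smallest representable value")
    p[degen] <- .Machine$double.xmin
  }
  p[s == 0 & m == 0] <- 1
  data.frame(probe = ds$probes, t_stat = unname(t_stat), p_raw = unname(p),
             df = n - 1L, stringsAsFactors = FALSE)
}

#' Bootstrap configuration
#'
#' @param B Number of sign-flip resamples (>= 100; default 1000 — the
#'   replicate count is a package choice, logged with every run).
#' @param seed Integer seed for the sign-flip draws.
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(B = 1000L, seed = 1L) {
  B <- as.integer(B)
  if (B < 100L) stop("'B' must be >= 100")
  structure(list(B = B, seed = as.integer(seed), scheme = "sign-flip"),
            class = "bootstrap_config")
}

#' Sign-flip bootstrap correction of paired-t p-values
#'
#' Null replicates are formed by randomly flipping the sign of each matched
#' pair's difference — exact under the symmetric null and respectful of the
#' matched design (unlike resampling with replacement). Per probe,
#' `p_boot = (1 + #\{b : p*_b <= p_raw\}) / (B + 1)`, evaluated equivalently
#' on the t scale as `|t*_b| >= |t|`. The corrected p-value is bounded below
#' by `1 / (B + 1)` and is monotone non-decreasing in `p_raw` for a fixed
#' null set.
#'
#' @param ds A `methylation_dataset`.
#' @param disease Disease label of the experiment.
#' @param cfg A [bootstrap_config()].
#' @param split Optional split restriction.
#' @param tt Optional precomputed [paired_t()] result (recomputed if NULL).
#' @return The [paired_t()] data frame with a `p_boot` column appended.
#' @export
signflip_bootstrap_correct <- function(ds, disease, cfg = bootstrap_config(),
                                       split = NULL, tt = NULL) {
  stopifnot(inherits(cfg, "bootstrap_config"))
  D <- .paired_differences(ds, disease, split)
  if (is.null(tt)) tt <- paired_t(ds, disease, split)
  n <- ncol(D)
  set.seed(cfg$seed)
  S <- matrix(sample(c(-1, 1), n * cfg$B, replace = TRUE), nrow = n)
  # sign flips leave d_i^2 unchanged: only the mean moves per replicate
  ss <- rowSums(D^2)
  Mb <- (D %*% S) / n                         # probes x B replicate means
  var_b <- pmax((ss - n * Mb^2) / (n - 1L), 0)
  Tb <- abs(Mb) / sqrt(var_b / n)
  Tb[var_b == 0 & abs(Mb) > 0] <- Inf
  Tb[var_b == 0 & Mb == 0] <- 0
  t_obs <- abs(tt$t_stat)
  exceed <- rowSums(Tb >= matrix(t_obs - 1e-12, nrow = length(t_obs),
                                 ncol = cfg$B))
  tt$p_boot <- (1 + exceed) / (cfg$B + 1)
  tt
}

#' Per-probe statistics of one experiment
#'
#' Convenience wrapper combining [scaled_cv()], [paired_t()] and
#' [signflip_bootstrap_correct()] into one `probe_statistics` data frame.
#'
#' @inheritParams signflip_bootstrap_correct
#' @return Data frame of class `probe_statistics`: probe, scaled_cv,
#'   t_stat, p_raw, p_boot.
#' @export
probe_statistics <- function(ds, disease, cfg = bootstrap_config(),
                             split = NULL) {
  cv <- scaled_cv(ds, disease, split)
  tt <- signflip_bootstrap_correct(ds, disease, cfg, split)
  out <- data.frame(probe = cv$probe, scaled_cv = cv$scaled_cv,
                    t_stat = tt$t_stat, p_raw = tt$p_raw,
                    p_boot = tt$p_boot, stringsAsFactors = FALSE)
  class(out) <- c("probe_statistics", "data.frame")
  out
}

#' Pre-select probes of one experiment
#'
#' Ranks probes by bootstrap-corrected p-value (ascending; ties broken by
#' smaller raw p, then probe id — deterministic and input-order free), keeps
#' the top `ceiling(top_frac * P)` ranks, and intersects with the probes
#' satisfying `ScaledCV > cv_min`. An empty result is returned with a
#' warning, not an error.
#'
#' @param stats A `probe_statistics` data frame.
#' @param top_frac Fraction of probes kept by the p-value rank cut
#'   (default 0.01, the top 1%).
#' @param cv_min Scaled-CV threshold (default 1).
#' @return Sorted character vector of selected probe ids.
#' @export
preselect_experiment <- function(stats, top_frac = 0.01, cv_min = 1.0) {
  P <- nrow(stats)
  k <- ceiling(top_frac * P)
  ord <- order(stats$p_boot, stats$p_raw, stats$probe)
  top <- stats$probe[ord][seq_len(min(k, P))]
  keep <- intersect(top, stats$probe[stats$scaled_cv > cv_min])
  if (!length(keep)) warning("pre-selection is empty for this experiment")
  sort(keep)
}

#' Union of per-experiment pre-selections
#'
#' Unions the per-experiment probe sets while retaining provenance — which
#' experiment(s) selected each probe — because the semantic-selection
#' subsets are later intersected per experiment.
#'
#' @param sets Named list of per-experiment probe-id vectors.
#' @return An object of class `preselection_result` with fields `sets`,
#'   `union` and `provenance` (named list probe -> experiments).
#' @export
union_preselect <- function(sets) {
  if (!length(sets)) stop("at least one experiment set is required")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be a named list")
  u <- sort(unique(unlist(sets)))
  prov <- lapply(stats::setNames(u, u), function(p)
    names(sets)[vapply(sets, function(s) p %in% s, logical(1))])
  structure(list(sets = lapply(sets, sort), union = u, provenance = prov),
            class = "preselection_result")
}

#' @export
print.preselection_result <- function(x, ...) {
  cat("preselection_result:\n")
  for (nm in names(x$sets))
    cat(sprintf("  %s: %d probes\n", nm, length(x$sets[[nm]])))
  cat(sprintf("  union: %d probes\n", length(x$union)))
  invisible(x)
}

#' Run pre-selection for several experiments
#'
#' @param ds A normalized `methylation_dataset`.
#' @param diseases Disease labels, one experiment each.
#' @param cfg A [bootstrap_config()].
#' @param top_frac,cv_min Thresholds passed to [preselect_experiment()].
#' @param split Optional split restriction (pre-selection normally runs on
#'   the training split only).
#' @return List with `stats` (per-experiment `probe_statistics`) and
#'   `result` (a `preselection_result`).
#' @export
preselect <- function(ds, diseases = c("BCCA", "LYCA"),
                      cfg = bootstrap_config(), top_frac = 0.01,
                      cv_min = 1.0, split = NULL) {
  stats_list <- list()
  sets <- list()
  for (i in seq_along(diseases)) {
    d <- diseases[i]
    exp_cfg <- bootstrap_config(cfg$B, cfg$seed + i - 1L)
    st <- probe_statistics(ds, d, exp_cfg, split)
    stats_list[[d]] <- st
    sets[[paste0("control_vs_", d)]] <-
      preselect_experiment(st, top_frac, cv_min)
  }
  list(stats = stats_list,
       result = union_preselect(sets),
       thresholds = list(top_frac = top_frac, cv_min = cv_min, B = cfg$B))
}
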