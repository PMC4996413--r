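# Signal summaries and the two-step QC-based normalization.
#
# Methylation is summarized per probe and sample by the beta fraction,
# the M-value (base-2 log channel ratio, approximately homoscedastic and
# preferred for statistics) and the average intensity I. Normalization then
# proceeds in two successive steps driven by the replicated technical QC
# sample: (i) within each chip, QC residuals against the cross-chip QC
# consensus are averaged inside average-intensity percentile bins and the
# bin error subtracted from every measurement on the chip; (ii) across
# probes, the per-probe QC replicate standard deviation is subtracted from
# every sample — a contrast-neutral shift retained mainly because the same
# sigma_QC feeds the scaled-CV statistic downstream.

#' Beta, M-value and average intensity
#'
#' `beta_value` is the methylated fraction `meth / (meth + unmeth)` in
#' `[0, 1]`. `m_value` is `log2(meth / unmeth)` and `avg_intensity` is
#' `0.5 * log2(meth * unmeth)`; for the latter two, intensities below 1 are
#' floored to 1 so logs stay finite while the ordering of informative
#' intensities is preserved. The identities `M = log2(beta / (1 - beta))`
#' and `beta = 2^M / (2^M + 1)` hold exactly on unfloored input.
#'
#' @param i_meth,i_unmeth Non-negative channel intensities (vectorized).
#' @return Numeric vector of the summary.
#' @export
beta_value <- function(i_meth, i_unmeth) {
  if (any(i_meth < 0) || any(i_unmeth < 0)) stop("intensities must be >= 0")
  tot <- i_meth + i_unmeth
  if (any(tot == 0)) stop("uninformative probe: both channels are 0")
  i_meth / tot
}

#' @rdname beta_value
#' @export
m_value <- function(i_meth, i_unmeth) {
  if (any(i_meth < 0) || any(i_unmeth < 0)) stop("intensities must be >= 0")
  log2(pmax(i_meth, 1) / pmax(i_unmeth, 1))
}

#' @rdname beta_value
#' @export
avg_intensity <- function(i_meth, i_unmeth) {
  if (any(i_meth < 0) || any(i_unmeth < 0)) stop("intensities must be >= 0")
  0.5 * log2(pmax(i_meth, 1) * pmax(i_unmeth, 1))
}

#' Build a methylation dataset from channel intensities
#'
#' @param ds An `intensity_dataset` with sheet attached.
#' @return A `methylation_dataset`: list with `probes`, `samples`, `M`, `I`
#'   (probes x samples matrices) and `sheet`.
#' @export
methylation_dataset <- function(ds) {
  stopifnot(inherits(ds, "intensity_dataset"))
  if (is.null(ds$sheet)) stop("intensity dataset has no sample sheet")
  M <- m_value(ds$meth, ds$unmeth)
  I <- avg_intensity(ds$meth, ds$unmeth)
  dim(M) <- dim(I) <- dim(ds$meth)
  dimnames(M) <- dimnames(I) <- dimnames(ds$meth)
  structure(list(probes = ds$probes, samples = ds$samples, M = M, I = I,
                 sheet = ds$sheet),
            class = "methylation_dataset")
}

.qc_cols <- function(ds) which(ds$sheet$class == "QC")

# Percentile bin edges with small bins (< min_pts points) merged into their
# right neighbour (leftmost kept open-ended).
.bin_edges <- function(values, n_bins, min_pts = 3L) {
  edges <- unique(stats::quantile(values, probs = seq(0, 1, length.out = n_bins + 1L),
                                  names = FALSE, type = 7))
  if (length(edges) < 2L) return(c(-Inf, Inf))
  edges[1L] <- -Inf; edges[length(edges)] <- Inf
  repeat {
    counts <- table(cut(values, edges))
    small <- which(counts < min_pts)
    if (!length(small) || length(edges) <= 2L) break
    i <- small[1L]                       # merge bin i with a neighbour
    drop <- if (i == length(counts)) i else i + 1L
    edges <- edges[-drop]
  }
  edges
}

#' Within-chip intensity-binned QC correction
#'
#' For every chip: QC residuals (QC replicate M minus the per-probe
#' cross-chip QC consensus) are pooled over the chip's QC measurements,
#' binned by their average intensity into `n_bins` percentile bins (bins
#' with fewer than 3 QC points merge with a neighbour), averaged per bin to
#' give the chip's intensity-resolved error, and that error is subtracted
#' from every measurement on the chip according to its own intensity.
#'
#' @param ds A `methylation_dataset` whose sheet flags QC samples.
#' @param n_bins Number of intensity percentile bins (default 100).
#' @return List with `ds` (the corrected dataset) and `qc` (a
#'   `probe_qc_stats` object carrying the QC consensus and per-chip bin
#'   errors; `sigma_qc` is filled by [across_probe_correct()]).
#' @export
within_chip_correct <- function(ds, n_bins = 100L) {
  stopifnot(inherits(ds, "methylation_dataset"))
  if (n_bins < 1L) stop("'n_bins' must be >= 1")
  qc_cols <- .qc_cols(ds)
  if (!length(qc_cols)) stop("dataset has no QC samples")
  chips <- unique(ds$sheet$chip)
  no_qc <- setdiff(chips, unique(ds$sheet$chip[qc_cols]))
  if (length(no_qc))
    stop("chip(s) without QC replicate: ", paste(no_qc, collapse = ", "))

  consensus <- rowMeans(ds$M[, qc_cols, drop = FALSE])
  M_corr <- ds$M
  bin_errors <- list()
  for (chip in chips) {
    cols <- which(ds$sheet$chip == chip)
    qc_chip <- intersect(cols, qc_cols)
    res <- ds$M[, qc_chip, drop = FALSE] - consensus
    ivals <- ds$I[, qc_chip, drop = FALSE]
    edges <- .bin_edges(as.vector(ivals), n_bins)
    bin_of_qc <- findInterval(as.vector(ivals), edges,
                              rightmost.closed = TRUE, all.inside = TRUE)
    err <- vapply(seq_len(length(edges) - 1L), function(b) {
      inb <- bin_of_qc == b
      if (any(inb)) mean(as.vector(res)[inb]) else 0
    }, numeric(1))
    bin_all <- findInterval(as.vector(ds$I[, cols, drop = FALSE]), edges,
                            rightmost.closed = TRUE, all.inside = TRUE)
    M_corr[, cols] <- ds$M[, cols, drop = FALSE] -
      matrix(err[bin_all], nrow = nrow(ds$M))
    bin_errors[[chip]] <- data.frame(lower = utils::head(edges, -1L),
                                     upper = edges[-1L], error = err)
  }
  ds$M <- M_corr
  qc <- structure(list(consensus = consensus, sigma_qc = NULL,
                       bin_errors = bin_errors, n_bins = n_bins),
                  class = "probe_qc_stats")
  list(ds = ds, qc = qc)
}

#' Across-probe correction
#'
#' Computes the per-probe sample standard deviation of M across all QC
#' replicates (`sigma_QC`, the probe-based technical error estimate) and
#' subtracts it from every sample's M for that probe. The shift is constant
#' per probe, so no paired difference or between-sample contrast changes;
#' `sigma_QC` is retained because it is the denominator of the scaled-CV
#' statistic. With a single QC replicate overall, `sigma_QC` is 0 with a
#' warning.
#'
#' @param ds A `methylation_dataset`.
#' @param qc A `probe_qc_stats` (from [within_chip_correct()]); may be
#'   missing, in which case a fresh one is created.
#' @return List with `ds` (corrected) and `qc` (with `sigma_qc` filled).
#' @export
across_probe_correct <- function(ds, qc = NULL) {
  stopifnot(inherits(ds, "methylation_dataset"))
  qc_cols <- .qc_cols(ds)
  if (!length(qc_cols)) stop("dataset has no QC samples")
  if (is.null(qc))
    qc <- structure(list(consensus = rowMeans(ds$M[, qc_cols, drop = FALSE]),
                         sigma_qc = NULL, bin_errors = list(), n_bins = NA),
                    class = "probe_qc_stats")
  if (length(qc_cols) < 2L) {
    warning("single QC replicate overall: sigma_QC set to 0")
    sigma <- rep(0, nrow(ds$M))
  } else {
    sigma <- apply(ds$M[, qc_cols, drop = FALSE], 1L, stats::sd)
  }
  names(sigma) <- ds$probes
  ds$M <- ds$M - sigma
  qc$sigma_qc <- sigma
  qc$qc_mean <- rowMeans(ds$M[, qc_cols, drop = FALSE]) + sigma  # pre-shift mean
  list(ds = ds, qc = qc)
}

#' Two-step QC-based normalization
#'
#' Composition of the signal summaries and the two correction steps:
#' M/I computation, within-chip intensity-binned correction, then the
#' across-probe correction. Sample order never changes. The returned report
#' logs the mean per-probe QC replicate variance before and after
#' correction — normalization must reduce it on chip-biased data.
#'
#' @param ds_raw An `intensity_dataset` with sheet.
#' @param n_bins Intensity bins for the within-chip step.
#' @return List with `ds` (the normalized `methylation_dataset`), `qc`
#'   (`probe_qc_stats`) and `report` (QC variance before/after, per step).
#' @export
normalize_dataset <- function(ds_raw, n_bins = 100L) {
  md <- methylation_dataset(ds_raw)
  qc_cols <- .qc_cols(md)
  if (!length(qc_cols)) stop("dataset has no QC samples")
  qc_var <- function(M) {
    if (length(qc_cols) < 2L) return(NA_real_)
    mean(apply(M[, qc_cols, drop = FALSE], 1L, stats::var))
  }
  v0 <- qc_var(md$M)
  step1 <- within_chip_correct(md, n_bins = n_bins)
  v1 <- qc_var(step1$ds$M)
  step2 <- across_probe_correct(step1$ds, step1$qc)
  v2 <- qc_var(step2$ds$M)
  list(ds = step2$ds, qc = step2$qc,
       report = list(n_bins = n_bins,
                     qc_variance = list(raw = v0, within_chip = v1,
                                        across_probe = v2)))
}
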