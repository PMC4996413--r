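# Synthetic-cohort generator: planted truth, channel model, chip bias,
# sample layout and the toy ontology.

test_that("planted truth draws disjoint per-disease sets and is reproducible", {
  cfg <- simulation_config(n_probes = 100, n_planted = 10, seed = 5)
  tr1 <- generate_truth(cfg)
  tr2 <- generate_truth(cfg)
  expect_identical(tr1, tr2)
  expect_length(tr1$dm_probes$BCCA, 10)
  expect_length(tr1$dm_probes$LYCA, 10)
  expect_length(intersect(tr1$dm_probes$BCCA, tr1$dm_probes$LYCA), 0)
  expect_true(all(unlist(tr1$dm_probes) %in% names(tr1$true_beta)))
  expect_true(all(tr1$true_beta >= 0 & tr1$true_beta <= 1))

  tr0 <- generate_truth(simulation_config(n_probes = 100, n_planted = 0))
  expect_length(tr0$dm_probes$BCCA, 0)
  expect_length(tr0$dm_probes$LYCA, 0)

  expect_error(generate_truth(simulation_config(n_probes = 10, n_planted = 6)),
               "disjoint")
})

test_that("noise-free channels invert exactly to the generating beta", {
  cfg <- simulation_config(n_probes = 50, n_pairs_per_disease = 4,
                           chip_size = 6, n_planted = 5, effect_delta = 1.2,
                           noise_sd = 0, seed = 3)
  truth <- generate_truth(cfg)
  ds <- generate_intensities(cfg, truth)
  beta_back <- ds$meth / (ds$meth + ds$unmeth)

  # controls and QC sit at the baseline profile
  ctrl <- ds$sheet$sample_id[ds$sheet$class == "control"]
  for (s in ctrl)
    expect_equal(unname(beta_back[, s]), unname(truth$true_beta),
                 tolerance = 1e-12)
  # planted probes of cases carry the M-scale shift exactly
  case <- ds$sheet$sample_id[ds$sheet$class == "BCCA"][1]
  p <- truth$dm_probes$BCCA[1]
  m_shift <- log2(beta_back[p, case] / (1 - beta_back[p, case])) -
    log2(truth$true_beta[p] / (1 - truth$true_beta[p]))
  expect_equal(unname(m_shift), 1.2, tolerance = 1e-9)

  # QC replicates share one profile: identical M columns
  qc <- ds$sheet$sample_id[ds$sheet$class == "QC"]
  M <- log2(ds$meth / ds$unmeth)
  for (s in qc[-1])
    expect_equal(unname(M[, s]), unname(M[, qc[1]]), tolerance = 1e-12)
})

test_that("null configuration leaves cases and controls identically distributed", {
  cfg <- simulation_config(n_probes = 40, n_pairs_per_disease = 30,
                           chip_size = 8, n_planted = 10, effect_delta = 0,
                           noise_sd = 0.05, seed = 17)
  truth <- generate_truth(cfg)
  ds <- generate_intensities(cfg, truth)
  M <- log2(pmax(ds$meth, 1) / pmax(ds$unmeth, 1))
  pvals <- vapply(seq_len(10), function(i) {
    p <- truth$dm_probes$BCCA[i]
    stats::ks.test(M[p, ds$sheet$class == "BCCA"],
                   M[p, ds$sheet$class == "control" &
                         ds$sheet$cohort == "BCCA"])$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.8)
})

test_that("chip bias is exact on the M scale and preserves intensity", {
  cfg <- simulation_config(n_probes = 60, n_pairs_per_disease = 4,
                           chip_size = 6, n_planted = 0, noise_sd = 0,
                           seed = 9)
  truth <- generate_truth(cfg)
  ds <- generate_intensities(cfg, truth)

  # zero coefficients: identity
  truth0 <- truth
  truth0$chip_bias$slope <- 0; truth0$chip_bias$offset <- 0
  ds0 <- inject_chip_bias(ds, truth0)
  expect_equal(ds0$meth, ds$meth, tolerance = 1e-12)

  # constant offset: every M shifted by +0.3, I unchanged
  truth_off <- truth
  truth_off$chip_bias$slope <- 0; truth_off$chip_bias$offset <- 0.3
  ds_off <- inject_chip_bias(ds, truth_off)
  M0 <- log2(ds$meth / ds$unmeth)
  M1 <- log2(ds_off$meth / ds_off$unmeth)
  expect_equal(unname(M1 - M0), matrix(0.3, nrow(M0), ncol(M0)),
               tolerance = 1e-9)
  I0 <- 0.5 * log2(ds$meth * ds$unmeth)
  I1 <- 0.5 * log2(ds_off$meth * ds_off$unmeth)
  expect_equal(I1, I0, tolerance = 1e-9)

  # pure slope: the M distortion tracks intensity within chip
  truth_sl <- truth
  truth_sl$chip_bias$slope <- 0.5; truth_sl$chip_bias$offset <- 0
  ds_sl <- inject_chip_bias(ds, truth_sl)
  M2 <- log2(ds_sl$meth / ds_sl$unmeth)
  chip1 <- ds$sheet$sample_id[ds$sheet$chip == "chip01"]
  dist <- as.vector((M2 - M0)[, chip1])
  expect_gt(stats::cor(dist, as.vector(I0[, chip1])), 0.99)

  # unknown chip rejected
  truth_bad <- truth
  truth_bad$chip_bias <- truth_bad$chip_bias[-1, ]
  expect_error(inject_chip_bias(ds, truth_bad), "unknown chip")
})

test_that("sample sheet layout honours pairing, chips and the split", {
  cfg <- simulation_config(n_pairs_per_disease = 10, chip_size = 12,
                           qc_per_chip = 2, seed = 21)
  sheet <- generate_pairs_and_chips(cfg)
  study <- sheet[!is.na(sheet$pair), ]
  expect_equal(nrow(study), 4 * 10)
  n_chips <- ceiling(nrow(study) / (12 - 2))
  expect_equal(sum(sheet$class == "QC"), 2 * n_chips)
  expect_equal(nrow(sheet), nrow(study) + 2 * n_chips)
  for (p in unique(study$pair)) {
    cls <- study$class[study$pair == p]
    expect_length(cls, 2)
    expect_equal(sum(cls == "control"), 1)
    expect_length(unique(study$split[study$pair == p]), 1)
  }
  expect_true(all(table(sheet$chip) <= 12))
  expect_identical(sheet, generate_pairs_and_chips(cfg))
})

test_that("toy ontology has a rooted DAG, a distant-term hub and array regions", {
  ont <- generate_ontology_corpus(40, seed = 2)
  graph <- ont$graph
  roots <- names(graph$parents)[lengths(graph$parents) == 0]
  expect_identical(roots, graph$root)

  hub_terms <- ont$corpus$gene2terms[["G001"]]
  expect_gte(length(hub_terms), 5)
  for (i in seq_len(length(hub_terms) - 1)) for (j in (i + 1):length(hub_terms))
    expect_gte(resnik_distance(hub_terms[i], hub_terms[j], ont$corpus), 0.5)

  vocab <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR",
             "Intergenic")
  expect_true(all(ont$probe_annotation$region %in% vocab))
  expect_true(all(table(ont$probe_annotation$gene) >= 1))
})

test_that("identical configuration gives byte-identical serialized cohorts", {
  cfg <- simulation_config(n_probes = 80, n_pairs_per_disease = 4,
                           chip_size = 6, n_planted = 5, seed = 13)
  f1 <- tempfile(); f2 <- tempfile()
  write_intensity_table(simulate_cohort(cfg)$biased, f1)
  write_intensity_table(simulate_cohort(cfg)$biased, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
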