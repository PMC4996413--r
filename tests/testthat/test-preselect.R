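# Scaled CV, paired t with sign-flip bootstrap correction, and the
# top-fraction pre-selection with cross-experiment union.

test_that("scaled CV matches hand arithmetic and its guards", {
  # pool M {1,1,3,3}: mean 2, sd 1.1547 -> CV 0.57735
  # QC M {1.9,2.1}: mean 2, sd 0.14142 -> CV 0.070711; ratio 8.1650
  M <- matrix(c(1, 1, 3, 3, 1.9, 2.1), nrow = 1)
  md <- make_tiny_md(M, classes = c("control", "control", "BCCA", "BCCA",
                                    "QC", "QC"),
                     pairs = c("p1", "p2", "p1", "p2", NA, NA))
  cv <- scaled_cv(md, "BCCA")
  expect_equal(cv$scaled_cv, 8.164966, tolerance = 1e-6)
  expect_false(cv$cv_fallback)

  # identical dispersion and mean in pool and QC -> exactly 1
  M2 <- matrix(c(1, 3, 1, 3, 1, 3, 1, 3), nrow = 1)
  md2 <- make_tiny_md(M2, classes = c("control", "control", "BCCA", "BCCA",
                                      "QC", "QC", "QC", "QC"),
                      pairs = c("p1", "p2", "p1", "p2", NA, NA, NA, NA))
  expect_equal(scaled_cv(md2, "BCCA")$scaled_cv, 1)

  # zero-crossing means fall back to the sd ratio, flagged
  M3 <- matrix(c(-1, 1, -1, 1, -0.1, 0.1), nrow = 1)
  md3 <- make_tiny_md(M3, classes = c("control", "control", "BCCA", "BCCA",
                                      "QC", "QC"),
                      pairs = c("p1", "p2", "p1", "p2", NA, NA))
  cv3 <- scaled_cv(md3, "BCCA")
  expect_true(cv3$cv_fallback)
  expect_equal(cv3$scaled_cv, sd(c(-1, 1, -1, 1)) / sd(c(-0.1, 0.1)),
               tolerance = 1e-12)

  # zero technical spread passes the criterion as +Inf
  M4 <- matrix(c(1, 2, 3, 4, 2, 2), nrow = 1)
  md4 <- make_tiny_md(M4, classes = c("control", "control", "BCCA", "BCCA",
                                      "QC", "QC"),
                      pairs = c("p1", "p2", "p1", "p2", NA, NA))
  expect_identical(scaled_cv(md4, "BCCA")$scaled_cv, Inf)
})

test_that("paired t equals the t-distribution reference and is exchangeable", {
  # differences {1,-1}: t = 0, p = 1
  M <- matrix(c(0, 0, 1, -1, 0, 0), nrow = 1)
  md <- make_tiny_md(M, classes = c("control", "control", "BCCA", "BCCA",
                                    "QC", "QC"),
                     pairs = c("p1", "p2", "p1", "p2", NA, NA))
  tt <- paired_t(md, "BCCA")
  expect_equal(tt$t_stat, 0)
  expect_equal(tt$p_raw, 1)

  # differences {1,2,3}: cross-checked against stats::t.test
  M2 <- matrix(c(0, 0, 0, 1, 2, 3, 0, 0), nrow = 1)
  md2 <- make_tiny_md(M2, classes = c("control", "control", "control",
                                      "BCCA", "BCCA", "BCCA", "QC", "QC"),
                      pairs = c("p1", "p2", "p3", "p1", "p2", "p3", NA, NA))
  tt2 <- paired_t(md2, "BCCA")
  ref <- stats::t.test(c(1, 2, 3))
  expect_equal(tt2$t_stat, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(tt2$p_raw, ref$p.value, tolerance = 1e-10)
  expect_equal(tt2$t_stat, 3.4641016, tolerance = 1e-6)
  expect_equal(tt2$df, 2)

  # permuting the pair order changes nothing
  md2p <- md2
  md2p$sheet <- md2p$sheet[c(3, 1, 2, 6, 4, 5, 7, 8), ]
  expect_equal(paired_t(md2p, "BCCA")$t_stat, tt2$t_stat)

  # zero-variance nonzero differences: smallest representable p + warning
  M3 <- matrix(c(0, 0, 1, 1, 0, 0), nrow = 1)
  md3 <- make_tiny_md(M3, classes = c("control", "control", "BCCA", "BCCA",
                                      "QC", "QC"),
                      pairs = c("p1", "p2", "p1", "p2", NA, NA))
  expect_warning(tt3 <- paired_t(md3, "BCCA"), "zero-variance")
  expect_equal(tt3$p_raw, .Machine$double.xmin)
})

test_that("sign-flip bootstrap p-values respect their bounds and monotonicity", {
  set.seed(4)
  n_probes <- 50; n_pairs <- 12
  M <- cbind(matrix(rnorm(n_probes * 2 * n_pairs), n_probes),
             matrix(rnorm(n_probes * 2, sd = 0.1), n_probes))
  # strong but non-degenerate probe: every null replicate is milder
  M[1, seq_len(n_pairs) + n_pairs] <- M[1, seq_len(n_pairs)] + 5 +
    rnorm(n_pairs, sd = 0.2)
  # flat probe: t = 0 can never beat a replicate, p_boot = 1
  M[2, ] <- 1
  classes <- c(rep("control", n_pairs), rep("BCCA", n_pairs), "QC", "QC")
  pairs <- c(sprintf("p%02d", 1:n_pairs), sprintf("p%02d", 1:n_pairs), NA, NA)
  md <- make_tiny_md(M, classes = classes, pairs = pairs)
  cfg <- bootstrap_config(B = 200, seed = 7)
  bt <- signflip_bootstrap_correct(md, "BCCA", cfg)
  expect_true(all(bt$p_boot >= 1 / 201 & bt$p_boot <= 1))
  expect_equal(bt$p_boot[1], 1 / 201)          # beats every null replicate
  expect_equal(bt$p_boot[2], 1)
  # reproducible under the same seed
  expect_identical(bt, signflip_bootstrap_correct(md, "BCCA", cfg))
  expect_error(bootstrap_config(B = 10), "100")
})

test_that("top-fraction pre-selection applies both criteria deterministically", {
  set.seed(9)
  st <- data.frame(probe = sprintf("cg%03d", 1:200),
                   scaled_cv = rep(2, 200),
                   t_stat = 0, p_raw = runif(200),
                   p_boot = runif(200), stringsAsFactors = FALSE)
  # top 1% of 200 probes = 2 ranks
  sel <- preselect_experiment(st)
  expect_length(sel, 2)
  expect_setequal(sel, st$probe[order(st$p_boot)][1:2])
  # one of the two fails the CV criterion
  st2 <- st
  st2$scaled_cv[order(st2$p_boot)[1]] <- 0.5
  expect_length(preselect_experiment(st2), 1)
  # invariant to row order
  expect_identical(preselect_experiment(st[sample(200), ]), sel)
  # empty result warns, does not error
  st3 <- st; st3$scaled_cv <- 0
  expect_warning(sel3 <- preselect_experiment(st3), "empty")
  expect_length(sel3, 0)
})

test_that("experiment union retains provenance", {
  u <- union_preselect(list(A = c("a", "b"), B = c("b", "c")))
  expect_identical(u$union, c("a", "b", "c"))
  expect_identical(u$provenance$b, c("A", "B"))
  expect_identical(u$provenance$a, "A")
  single <- union_preselect(list(A = c("x", "y")))
  expect_identical(single$union, c("x", "y"))
  disj <- union_preselect(list(A = "a", B = "b"))
  expect_length(disj$union, 2)
  expect_error(union_preselect(list()), "at least one")
})

test_that("recovery power grows with the planted effect size on matched seeds", {
  recovered <- vapply(c(0.6, 1.6), function(eff) {
    cfg <- simulation_config(n_probes = 1000, n_pairs_per_disease = 20,
                             chip_size = 12, n_planted = 20,
                             effect_delta = eff, noise_sd = 0.05, seed = 71)
    truth <- generate_truth(cfg)
    md <- methylation_dataset(generate_intensities(cfg, truth))
    st <- probe_statistics(md, "BCCA", bootstrap_config(B = 200, seed = 73))
    length(intersect(preselect_experiment(st), truth$dm_probes$BCCA))
  }, numeric(1))
  expect_gte(recovered[2], recovered[1])
  expect_gte(recovered[2], 8)   # 1.6 M-units is a strong planted signal
})

test_that("planted differential probes dominate nulls in scaled CV", {
  co <- tiny_cohort(seed = 44)
  norm <- normalize_dataset(co$biased, n_bins = 20)
  cv <- scaled_cv(norm$ds, "BCCA")
  planted <- cv$scaled_cv[cv$probe %in% co$truth$dm_probes$BCCA]
  null <- cv$scaled_cv[!cv$probe %in% unlist(co$truth$dm_probes)]
  expect_gt(stats::median(planted), 2 * stats::median(null))
})
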