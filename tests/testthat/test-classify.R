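# Classifier suite: weighted k-NN vs a brute-force oracle, the Gini tree vs
# exhaustive split search, ANN training behaviour, and both evaluation
# protocols.

test_that("weighted k-NN matches the brute-force oracle on random instances", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(5:20, 1); p <- sample(1:3, 1)
    k <- sample(seq_len(n), 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- sample(c("u", "v", "w"), n, replace = TRUE)
    q <- matrix(rnorm(p), 1, p)
    expect_identical(knn_weighted_predict(X, y, q, k),
                     oracle_knn(X, y, q[1, ], k))
  }
})

test_that("k-NN base cases: single neighbour and coincident queries", {
  X <- matrix(c(0, 0, 1, 1, 5, 5), ncol = 2, byrow = TRUE)
  y <- c("a", "a", "b")
  expect_identical(knn_weighted_predict(X, y, matrix(c(4.9, 5), 1), 1), "b")
  # query exactly on a training point: its 1/eps weight dominates
  expect_identical(knn_weighted_predict(X, y, matrix(c(5, 5), 1), 3), "b")
  expect_error(knn_weighted_predict(X, y, matrix(0, 1, 2), 4), "exceeds")
})

test_that("tree root split equals exhaustive search on small data", {
  set.seed(12)
  for (rep in 1:25) {
    n <- sample(10:50, 1); p <- sample(2:4, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    model <- gini_tree_fit(X, y)
    oracle <- oracle_root_split(X, y)
    if (model$tree$leaf) {
      # no impurity-reducing split exists
      base_gini <- 1 - sum((table(y) / n)^2)
      expect_gte(oracle$impurity, base_gini - 1e-12)
    } else {
      expect_equal(model$tree$feature, oracle$feature)
      expect_equal(model$tree$threshold, oracle$threshold, tolerance = 1e-12)
    }
  }
})

test_that("tree handles pure nodes and fits training data it can shatter", {
  X <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  y <- c("a", "a", "a", "b", "b", "b")
  m <- gini_tree_fit(X, y)
  expect_false(m$tree$leaf)
  expect_identical(predict(m, X), y)
  pure <- gini_tree_fit(X, rep("a", 6))
  expect_true(pure$tree$leaf)
  expect_identical(predict(pure, matrix(99)), "a")
})

test_that("the ANN respects the hidden-node rule and learns separable data", {
  expect_equal(ann_hidden_nodes(4, 2), 4L)
  expect_equal(ann_hidden_nodes(150, 3), 77L)
  expect_equal(ann_hidden_nodes(3, 2), 3L)   # floor of 2.5 + 1

  set.seed(13)
  n <- 40
  X <- rbind(matrix(rnorm(n / 2 * 4), n / 2),
             matrix(rnorm(n / 2 * 4, mean = 2.5), n / 2))
  y <- rep(c("a", "b"), each = n / 2)
  spec <- classifier_spec("ann", epochs = 200, seed = 5)
  m <- ann_fit(X, y, spec)
  expect_equal(m$hidden, ann_hidden_nodes(4, 2))
  expect_lt(m$loss[200], m$loss[1])
  expect_gte(mean(predict(m, X) == y), 0.95)
  # bit-identical refit under the same seed
  m2 <- ann_fit(X, y, spec)
  expect_identical(m$W1, m2$W1)
  expect_identical(m$W2, m2$W2)
  expect_error(ann_fit(matrix(c(1, NA), 1), "a", spec), "non-finite")
})

test_that("performance metrics follow their defining identities", {
  conf <- matrix(c(3, 1, 1, 2), 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("a", "b")))
  m <- performance_metrics(conf)
  expect_equal(m$total_accuracy, 100 * 5 / 7, tolerance = 1e-12)
  expect_equal(unname(m$sensitivity), c(75, 2 / 3 * 100), tolerance = 1e-12)
  # accuracy is the class-size-weighted mean of sensitivities
  w <- rowSums(conf) / sum(conf)
  expect_equal(m$total_accuracy, sum(w * m$sensitivity), tolerance = 1e-12)
  perfect <- diag(c(4, 6)); dimnames(perfect) <- dimnames(conf)
  expect_equal(performance_metrics(perfect)$total_accuracy, 100)
  expect_error(performance_metrics(matrix(0, 2, 2)), "empty")
})

test_that("leave-one-out predicts every sample once and separates 3 classes", {
  set.seed(14)
  per <- 15
  X <- rbind(matrix(rnorm(per * 5), per),
             matrix(rnorm(per * 5, mean = 4), per),
             matrix(rnorm(per * 5, mean = -4), per))
  y <- rep(c("a", "b", "c"), each = per)
  rep12 <- loo_evaluate(X, y, spec = classifier_spec("knn", k = 12))
  expect_equal(sum(rep12$confusion), 3 * per)
  expect_gte(rep12$total_accuracy, 90)
  # order invariance for the deterministic k-NN
  perm <- sample(nrow(X))
  rep_perm <- loo_evaluate(X[perm, ], y[perm],
                           spec = classifier_spec("knn", k = 12))
  expect_equal(rep_perm$confusion, rep12$confusion)
})

test_that("holdout evaluation guards against leakage and degenerate input", {
  set.seed(15)
  X <- matrix(rnorm(40), 20, 2,
              dimnames = list(sprintf("s%02d", 1:20), NULL))
  y <- rep(c("a", "b"), 10)
  expect_error(holdout_evaluate(X, y, X, y), "overlap")
  r <- holdout_evaluate(X[1:18, ], y[1:18], X[19:20, , drop = FALSE],
                        y[19:20], spec = classifier_spec("knn", k = 3))
  expect_true(r$total_accuracy %in% c(0, 50, 100))
  single <- holdout_evaluate(X[1:19, ], y[1:19], X[20, , drop = FALSE],
                             y[20], spec = classifier_spec("knn", k = 3))
  expect_true(single$total_accuracy %in% c(0, 100))
})

test_that("permuted labels drive k-NN accuracy to chance", {
  # light version; the full 20-seed, n = 150, all-classifier permutation
  # null runs with the acceptance-scale simulations
  set.seed(16)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5)
  X[1:30, 1:2] <- X[1:30, 1:2] + 2    # real structure, destroyed by permuting
  accs <- vapply(1:8, function(s) {
    set.seed(200 + s)
    yp <- sample(rep(c("a", "b"), each = n / 2))
    loo_evaluate(X, yp, spec = classifier_spec("knn", k = 6))$total_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 12)
})
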