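# Classifier suite and evaluation protocols.
#
# Three model families mirror a classical data-mining toolbox: distance-
# weighted k-nearest-neighbour voting (k = 1, 6 or 12), a binary CART-style
# decision tree split on the Gini index, and a one-hidden-layer feed-forward
# neural network trained by per-sample backpropagation with momentum.
# Evaluation is by leave-one-out resampling on the training set or by a
# single fit applied to an independent held-out set; both report total
# accuracy and per-class sensitivity from a pooled confusion matrix.

#' Classifier specification
#'
#' @param kind `"knn"`, `"tree"` or `"ann"`.
#' @param k Neighbour count for k-NN (1, 6 and 12 are the suite's standard
#'   settings).
#' @param learning_rate,momentum,epochs ANN backpropagation parameters
#'   (defaults 0.3, 0.2 and 1000).
#' @param hidden_nodes ANN hidden-layer size; `NULL` means the rule
#'   `floor((F + C) / 2) + 1` for F features and C classes.
#' @param standardize Standardize features with training-set statistics
#'   before k-NN/ANN (trees are scale-invariant and skip it).
#' @param seed Seed for ANN weight initialization.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("knn", "tree", "ann"), k = 12L,
                            learning_rate = 0.3, momentum = 0.2,
                            epochs = 1000L, hidden_nodes = NULL,
                            standardize = TRUE, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "knn" && k < 1L) stop("'k' must be >= 1")
  if (epochs < 1L) stop("'epochs' must be >= 1")
  structure(list(kind = kind, k = as.integer(k),
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs), hidden_nodes = hidden_nodes,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "classifier_spec")
}

# Training-set standardization; zero-sd features get scale 1.
.fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}
.apply_scaler <- function(X, sc) sweep(sweep(X, 2L, sc$mu), 2L, sc$sd, "/")

#' Distance-weighted k-NN prediction
#'
#' Euclidean distances from each query to all training samples; the k
#' nearest vote with weight `1 / (d + 1e-9)` and the class with the largest
#' summed weight wins. Weight ties are broken by the class of the single
#' nearest neighbour. No internal standardization — the evaluation
#' protocols standardize with training statistics when the spec asks.
#'
#' @param train_x Training matrix (samples x features).
#' @param train_y Training labels (character or factor).
#' @param query_x Query matrix (samples x features).
#' @param k Neighbour count (must not exceed the training size).
#' @return Character vector of predicted labels.
#' @export
knn_weighted_predict <- function(train_x, train_y, query_x, k) {
  train_x <- as.matrix(train_x); query_x <- as.matrix(query_x)
  n <- nrow(train_x)
  if (k > n) stop("k exceeds the number of training samples")
  train_y <- as.character(train_y)
  classes <- sort(unique(train_y))
  codes <- knn_weighted_vote(train_x, match(train_y, classes), query_x,
                             as.integer(k), length(classes))
  classes[codes]
}

# ---- Gini decision tree ----------------------------------------------------

# Best (feature, threshold) pair minimizing the weighted Gini impurity of the
# two children; thresholds at midpoints of sorted unique values. Returns NULL
# when no split decreases impurity.
.gini <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

.best_split <- function(X, y, classes) {
  n <- nrow(X)
  parent_counts <- table(factor(y, levels = classes))
  parent_imp <- .gini(parent_counts)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j])
    xs <- X[ord, j]; ys <- y[ord]
    # cumulative class counts below each candidate cut, all cuts at once
    cum <- vapply(classes, function(cl) cumsum(ys == cl),
                  numeric(length(ys)))
    if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1L)
    distinct <- which(diff(xs) > 0)
    if (!length(distinct)) next
    nl <- distinct
    left <- cum[distinct, , drop = FALSE]
    right <- rep(parent_counts, each = length(distinct)) - left
    gl <- 1 - rowSums((left / nl)^2)
    gr <- 1 - rowSums((right / (n - nl))^2)
    imp <- (nl * gl + (n - nl) * gr) / n
    i_best <- distinct[which.min(imp)]   # which.min: first index on ties
    imp_best <- min(imp)
    if (is.null(best) || imp_best < best$impurity - 1e-12) {
      best <- list(feature = j, threshold = (xs[i_best] + xs[i_best + 1L]) / 2,
                   impurity = imp_best)
    }
  }
  if (!is.null(best) && best$impurity < parent_imp - 1e-12) best else NULL
}

.majority <- function(y, classes) {
  counts <- table(factor(y, levels = classes))
  names(counts)[which.max(counts)]  # which.max is deterministic on ties
}

.grow_tree <- function(X, y, classes) {
  if (length(unique(y)) == 1L || nrow(X) < 2L)
    return(list(leaf = TRUE, label = .majority(y, classes)))
  sp <- .best_split(X, y, classes)
  if (is.null(sp))
    return(list(leaf = TRUE, label = .majority(y, classes)))
  go_left <- X[, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = .grow_tree(X[go_left, , drop = FALSE], y[go_left], classes),
       right = .grow_tree(X[!go_left, , drop = FALSE], y[!go_left], classes))
}

#' Fit a Gini-index decision tree
#'
#' Binary CART-style tree: every split exhaustively minimizes the weighted
#' Gini impurity over all feature/threshold candidates (thresholds at
#' midpoints of sorted unique feature values); nodes split while impurity
#' decreases and the node holds at least two samples; no pruning.
#' Single-class input yields a single leaf.
#'
#' @param train_x Training matrix (samples x features).
#' @param train_y Training labels.
#' @param spec A `classifier_spec` of kind `"tree"` (optional).
#' @return A `trained_model` (kind `"tree"`).
#' @export
gini_tree_fit <- function(train_x, train_y,
                          spec = classifier_spec("tree")) {
  train_x <- as.matrix(train_x)
  if (nrow(train_x) < 1L) stop("at least one training sample required")
  train_y <- as.character(train_y)
  classes <- sort(unique(train_y))
  tree <- .grow_tree(train_x, train_y, classes)
  structure(list(kind = "tree", tree = tree, classes = classes,
                 n_features = ncol(train_x), spec = spec),
            class = "trained_model")
}

.tree_predict_one <- function(node, x) {
  while (!node$leaf)
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  node$label
}

# ---- One-hidden-layer ANN --------------------------------------------------

.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Fit a one-hidden-layer feed-forward neural network
#'
#' Sigmoid hidden and output units, one-hot targets, squared-error loss,
#' per-sample (online) backpropagation with momentum for a fixed number of
#' epochs, in a fixed sample order for determinism. The hidden layer holds
#' `floor((F + C) / 2) + 1` nodes unless overridden. Inputs are standardized
#' with training statistics inside the model. Weights initialize uniformly
#' in `[-0.5, 0.5]` under the spec's seed.
#'
#' @param train_x Training matrix (samples x features), all finite.
#' @param train_y Training labels.
#' @param spec A `classifier_spec` of kind `"ann"`.
#' @return A `trained_model` (kind `"ann"`) carrying the weight matrices,
#'   scaler and the per-epoch training loss curve.
#' @export
ann_fit <- function(train_x, train_y, spec = classifier_spec("ann")) {
  train_x <- as.matrix(train_x)
  if (any(!is.finite(train_x))) stop("non-finite input to ann_fit")
  train_y <- as.character(train_y)
  classes <- sort(unique(train_y))
  C <- length(classes); F_ <- ncol(train_x); n <- nrow(train_x)
  H <- if (is.null(spec$hidden_nodes)) ann_hidden_nodes(F_, C)
       else as.integer(spec$hidden_nodes)
  sc <- if (spec$standardize) .fit_scaler(train_x) else
    list(mu = rep(0, F_), sd = rep(1, F_))
  X <- .apply_scaler(train_x, sc)
  Tg <- outer(train_y, classes, "==") * 1

  set.seed(spec$seed)
  W1 <- matrix(stats::runif((F_ + 1L) * H, -0.5, 0.5), F_ + 1L, H)
  W2 <- matrix(stats::runif((H + 1L) * C, -0.5, 0.5), H + 1L, C)
  V1 <- W1 * 0; V2 <- W2 * 0
  lr <- spec$learning_rate; mom <- spec$momentum
  loss <- numeric(spec$epochs)
  for (ep in seq_len(spec$epochs)) {
    ep_loss <- 0
    for (i in seq_len(n)) {
      x <- c(X[i, ], 1)
      h <- .sigmoid(drop(x %*% W1))
      hb <- c(h, 1)
      o <- .sigmoid(drop(hb %*% W2))
      err <- Tg[i, ] - o
      ep_loss <- ep_loss + sum(err^2)
      delta_o <- err * o * (1 - o)
      delta_h <- (W2[seq_len(H), , drop = FALSE] %*% delta_o)[, 1L] *
        h * (1 - h)
      V2 <- mom * V2 + lr * outer(hb, delta_o)
      V1 <- mom * V1 + lr * outer(x, delta_h)
      W2 <- W2 + V2
      W1 <- W1 + V1
    }
    loss[ep] <- ep_loss / n
  }
  structure(list(kind = "ann", W1 = W1, W2 = W2, classes = classes,
                 scaler = sc, n_features = F_, hidden = H, loss = loss,
                 spec = spec),
            class = "trained_model")
}

#' Hidden-layer size rule
#'
#' `floor((F + C) / 2) + 1` nodes for F features and C classes (the mean of
#' input and output widths, floored to stay integral, plus one).
#'
#' @param n_features,n_classes Integers.
#' @return Integer node count.
#' @export
ann_hidden_nodes <- function(n_features, n_classes) {
  as.integer(floor((n_features + n_classes) / 2) + 1L)
}

#' Predict from a trained model
#'
#' @param object A `trained_model` from [gini_tree_fit()] or [ann_fit()].
#' @param newdata Matrix (samples x features) on the model's own feature
#'   space.
#' @param ... Unused.
#' @return Character vector of predicted labels (ANN: argmax output unit).
#' @export
predict.trained_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("model was trained on ", object$n_features, " features, got ",
         ncol(newdata))
  switch(object$kind,
    tree = vapply(seq_len(nrow(newdata)), function(i)
      .tree_predict_one(object$tree, newdata[i, ]), character(1)),
    ann = {
      X <- .apply_scaler(newdata, object$scaler)
      H <- .sigmoid(cbind(X, 1) %*% object$W1)
      O <- .sigmoid(cbind(H, 1) %*% object$W2)
      object$classes[max.col(O, ties.method = "first")]
    },
    stop("unsupported model kind: ", object$kind))
}

# ---- Protocols -------------------------------------------------------------

# Fit-and-predict for one spec; test labels never enter.
.fit_predict <- function(train_x, train_y, test_x, spec) {
  switch(spec$kind,
    knn = {
      if (spec$standardize) {
        sc <- .fit_scaler(train_x)
        train_x <- .apply_scaler(train_x, sc)
        test_x <- .apply_scaler(test_x, sc)
      }
      knn_weighted_predict(train_x, train_y, test_x, spec$k)
    },
    tree = predict(gini_tree_fit(train_x, train_y, spec), test_x),
    ann = predict(ann_fit(train_x, train_y, spec), test_x))
}

#' Performance metrics from a confusion matrix
#'
#' Total accuracy is `100 * trace / sum`; per-class sensitivity is
#' `100 * diagonal / row sum` with true classes on rows.
#'
#' @param confusion Square non-negative integer matrix, true classes on
#'   rows, predicted on columns, identically labelled.
#' @return List with `total_accuracy` and named `sensitivity` (both %).
#' @export
performance_metrics <- function(confusion) {
  if (!length(confusion) || sum(confusion) == 0)
    stop("empty confusion matrix")
  if (any(confusion < 0)) stop("negative confusion counts")
  acc <- 100 * sum(diag(confusion)) / sum(confusion)
  sens <- 100 * diag(confusion) / rowSums(confusion)
  list(total_accuracy = acc, sensitivity = sens)
}

.assemble_report <- function(protocol, truth, predicted, classes, spec,
                             mask = NULL) {
  confusion <- table(factor(truth, levels = classes),
                     factor(predicted, levels = classes))
  m <- performance_metrics(confusion)
  structure(list(protocol = protocol, classifier = spec$kind,
                 k = if (spec$kind == "knn") spec$k else NA_integer_,
                 total_accuracy = m$total_accuracy,
                 sensitivity = as.list(m$sensitivity),
                 confusion = unclass(confusion),
                 n_features = if (is.null(mask)) NA_integer_ else sum(mask)),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("%s [%s%s]: total accuracy %.2f%%\n", x$protocol, x$classifier,
              if (!is.na(x$k)) paste0(" k=", x$k) else ""),
      sep = "")
  for (cl in names(x$sensitivity))
    cat(sprintf("  %s sensitivity: %.2f%%\n", cl, x$sensitivity[[cl]]))
  invisible(x)
}

#' Leave-one-out evaluation
#'
#' Each sample is predicted by a model trained on the remaining `n - 1`;
#' the report pools all n predictions into one confusion matrix.
#'
#' @param x Matrix (samples x features).
#' @param y Labels.
#' @param mask Optional logical/integer feature mask applied to columns.
#' @param spec A `classifier_spec`.
#' @return A `performance_report` (protocol `"LOO"`).
#' @export
loo_evaluate <- function(x, y, mask = NULL, spec = classifier_spec()) {
  x <- as.matrix(x)
  if (!is.null(mask)) x <- x[, as.logical(mask), drop = FALSE]
  y <- as.character(y)
  n <- nrow(x)
  if (n < 2L) stop("leave-one-out requires at least 2 samples")
  preds <- vapply(seq_len(n), function(i) {
    .fit_predict(x[-i, , drop = FALSE], y[-i], x[i, , drop = FALSE], spec)
  }, character(1))
  .assemble_report("LOO", y, preds, sort(unique(y)), spec, mask)
}

#' Independent-holdout evaluation
#'
#' A single fit on the training set applied once to the held-out set. Train
#' and test sample ids (rownames) must be disjoint; the test labels are
#' consulted only after all predictions are made.
#'
#' @param train_x,train_y Training data and labels.
#' @param test_x,test_y Held-out data and labels.
#' @param mask Optional feature mask applied to both sets.
#' @param spec A `classifier_spec`.
#' @return A `performance_report` (protocol `"independent"`).
#' @export
holdout_evaluate <- function(train_x, train_y, test_x, test_y, mask = NULL,
                             spec = classifier_spec()) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  ids_tr <- rownames(train_x); ids_te <- rownames(test_x)
  if (!is.null(ids_tr) && !is.null(ids_te)) {
    overlap <- intersect(ids_tr, ids_te)
    if (length(overlap))
      stop("train/test sample ids overlap: ",
           paste(utils::head(overlap, 5L), collapse = ", "))
  }
  if (!is.null(mask)) {
    train_x <- train_x[, as.logical(mask), drop = FALSE]
    test_x <- test_x[, as.logical(mask), drop = FALSE]
  }
  train_y <- as.character(train_y)
  preds <- .fit_predict(train_x, train_y, test_x, spec)
  test_y <- as.character(test_y)   # labels touched only after prediction
  .assemble_report("independent", test_y, preds,
                   sort(unique(c(train_y, test_y))), spec, mask)
}

#' Evaluate the full classifier suite
#'
#' Runs 1-NN, 6-NN, 12-NN, the Gini tree and the ANN under one protocol and
#' returns the reports in a named list plus a combined table (classifiers on
#' columns, total accuracy and per-class sensitivities on rows).
#'
#' @param train_x,train_y Training data.
#' @param test_x,test_y Held-out data (`NULL` for LOO on the training set).
#' @param mask Optional feature mask.
#' @param seed Seed forwarded to the ANN.
#' @param epochs ANN epochs (default 1000).
#' @return List with `reports` and `table`.
#' @export
evaluate_suite <- function(train_x, train_y, test_x = NULL, test_y = NULL,
                           mask = NULL, seed = 1L, epochs = 1000L) {
  specs <- list(
    `1-nn` = classifier_spec("knn", k = 1L),
    `6-nn` = classifier_spec("knn", k = 6L),
    `12-nn` = classifier_spec("knn", k = 12L),
    Tree = classifier_spec("tree"),
    ANN = classifier_spec("ann", seed = seed, epochs = epochs))
  reports <- lapply(specs, function(sp) {
    if (is.null(test_x)) loo_evaluate(train_x, train_y, mask, sp)
    else holdout_evaluate(train_x, train_y, test_x, test_y, mask, sp)
  })
  classes <- names(reports[[1L]]$sensitivity)
  tab <- sapply(reports, function(r)
    c(r$total_accuracy, unlist(r$sensitivity)))
  rownames(tab) <- c("Total Accuracy", paste(classes, "Sensitivity"))
  list(reports = reports, table = tab)
}
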