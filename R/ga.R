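# Genetic-algorithm wrapper feature selection.
#
# A chromosome is a binary inclusion mask over the candidate feature
# universe, its popcount bounded by a dimensionality threshold. Fitness is
# the pooled accuracy of a distance-weighted 12-NN classifier restricted to
# the masked features, estimated by stratified 3-fold cross-validation on
# folds fixed per run so every chromosome is scored on identical folds.
# Selection is fitness-proportional roulette, recombination is uniform
# crossover of consecutive parent pairs, mutation flips bits at rate 1/N,
# and a repair step restores the cardinality bounds. One elite chromosome
# is copied unchanged per generation, making best fitness monotone.

#' Genetic-algorithm configuration
#'
#' @param population_size Chromosomes per generation (default 500).
#' @param p_c Per-pair crossover probability (default 0.5).
#' @param p_m Per-bit mutation probability; `NULL` means `1/N`.
#' @param d_max Upper cardinality bound of a mask (150 and 400 are the
#'   standard dimensionality thresholds; the lower bound is 1).
#' @param max_generations Generation budget (default 50); no early stopping.
#' @param elitism Elite chromosomes copied unchanged (default 1).
#' @param k Embedded k-NN neighbour count (default 12).
#' @param cv_folds Cross-validation folds of the fitness (default 3).
#' @param seed Integer seed; identical data, config and seed give an
#'   identical final mask.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 500L, p_c = 0.5, p_m = NULL,
                      d_max = 150L, max_generations = 50L, elitism = 1L,
                      k = 12L, cv_folds = 3L, seed = 1L) {
  if (population_size < 2L) stop("'population_size' must be >= 2")
  if (p_c < 0 || p_c > 1) stop("'p_c' must be in [0, 1]")
  if (!is.null(p_m) && (p_m < 0 || p_m > 1)) stop("'p_m' must be in [0, 1]")
  if (d_max < 1L) stop("'d_max' must be >= 1")
  structure(list(population_size = as.integer(population_size), p_c = p_c,
                 p_m = p_m, d_max = as.integer(d_max),
                 max_generations = as.integer(max_generations),
                 elitism = as.integer(elitism), k = as.integer(k),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "ga_config")
}

#' Initialize a random chromosome population
#'
#' Each mask draws its cardinality uniformly from `[1, d_max]` and its set
#' bits uniformly without replacement, so with hundreds of chromosomes
#' essentially every feature index is represented somewhere in the initial
#' pool.
#'
#' @param cfg A [ga_config()].
#' @param n_features Length N of the masks.
#' @param seed Optional seed; `NULL` uses the current RNG stream (as inside
#'   [evolve()]).
#' @return Logical matrix (population x N).
#' @export
init_population <- function(cfg, n_features, seed = NULL) {
  if (cfg$d_max > n_features) stop("'d_max' exceeds the feature count")
  if (!is.null(seed)) set.seed(seed)
  pop <- matrix(FALSE, cfg$population_size, n_features)
  card <- sample.int(cfg$d_max, cfg$population_size, replace = TRUE)
  for (i in seq_len(cfg$population_size))
    pop[i, sample.int(n_features, card[i])] <- TRUE
  pop
}

#' Stratified cross-validation folds
#'
#' @param y Labels.
#' @param k Fold count; every class must have at least `k` members.
#' @param seed Optional seed.
#' @return Integer vector of fold assignments in `1..k`.
#' @export
stratified_folds <- function(y, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- as.character(y)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < k)
      stop(sprintf("class '%s' has fewer members (%d) than folds (%d)",
                   cl, length(idx), k))
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Embedded k-NN cross-validation fitness
#'
#' Pooled accuracy of the distance-weighted k-NN restricted to the masked
#' features under stratified cross-validation. Fold assignments are passed
#' in (fixed per run, independent of the mask) so all chromosomes are scored
#' on identical folds and fitnesses are comparable.
#'
#' @param mask Logical feature mask with at least one set bit.
#' @param x Matrix (samples x features).
#' @param y Labels.
#' @param cfg A [ga_config()] (supplies `k`).
#' @param folds Fold assignment from [stratified_folds()]; derived from
#'   `cfg` when missing.
#' @return Accuracy fraction in `[0, 1]`.
#' @export
knn_cv_fitness <- function(mask, x, y, cfg = ga_config(), folds = NULL) {
  mask <- as.logical(mask)
  if (!any(mask)) stop("mask must include at least one feature")
  if (is.null(folds)) folds <- stratified_folds(y, cfg$cv_folds, cfg$seed)
  x <- as.matrix(x)[, mask, drop = FALSE]
  y <- as.character(y)
  classes <- sort(unique(y))
  knn_cv_accuracy(x, match(y, classes), as.integer(folds),
                  as.integer(cfg$k), length(classes))
}

#' Roulette-wheel parent selection
#'
#' Samples masks with replacement, probability proportional to fitness.
#' An all-zero fitness vector falls back to uniform sampling.
#'
#' @param population Logical matrix (population x N).
#' @param fitnesses Non-negative fitness per row.
#' @param n_draws Number of parents to draw.
#' @param seed Optional seed.
#' @return Logical matrix of the drawn parents (n_draws x N).
#' @export
roulette_select <- function(population, fitnesses, n_draws, seed = NULL) {
  if (any(fitnesses < 0)) stop("fitnesses must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  prob <- if (sum(fitnesses) == 0) rep(1, length(fitnesses)) else fitnesses
  idx <- sample.int(nrow(population), n_draws, replace = TRUE, prob = prob)
  population[idx, , drop = FALSE]
}

#' Uniform crossover of two parent masks
#'
#' With probability `p_c` the pair is crossed: each bit position swaps
#' between the children independently with probability 0.5. Otherwise the
#' children are verbatim copies of the parents.
#'
#' @param parent_a,parent_b Equal-length logical masks.
#' @param p_c Crossover probability.
#' @param seed Optional seed.
#' @return List of two child masks.
#' @export
uniform_crossover <- function(parent_a, parent_b, p_c, seed = NULL) {
  if (length(parent_a) != length(parent_b)) stop("parent length mismatch")
  if (!is.null(seed)) set.seed(seed)
  if (stats::runif(1) >= p_c) return(list(parent_a, parent_b))
  swap <- stats::runif(length(parent_a)) < 0.5
  child_a <- parent_a; child_b <- parent_b
  child_a[swap] <- parent_b[swap]
  child_b[swap] <- parent_a[swap]
  list(child_a, child_b)
}

#' Bit-flip mutation
#'
#' Each bit flips independently with probability `p_m` (the standard rate is
#' `1/N`, one expected flip per chromosome).
#'
#' @param mask Logical mask.
#' @param p_m Per-bit flip probability.
#' @param seed Optional seed.
#' @return Mutated mask.
#' @export
bit_mutate <- function(mask, p_m, seed = NULL) {
  if (p_m < 0 || p_m > 1) stop("'p_m' must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  flip <- stats::runif(length(mask)) < p_m
  xor(mask, flip)
}

#' Repair a mask to its cardinality bounds
#'
#' Masks above `d_max` have surplus set bits cleared at random (the result
#' stays a subset of the input's set bits); an empty mask gets one random
#' bit set; in-range masks pass unchanged.
#'
#' @param mask Logical mask.
#' @param d_max Upper cardinality bound.
#' @param seed Optional seed.
#' @return Repaired mask with popcount in `[1, d_max]`.
#' @export
cardinality_repair <- function(mask, d_max, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ones <- which(mask)
  if (length(ones) > d_max) {
    drop <- sample(ones, length(ones) - d_max)
    mask[drop] <- FALSE
  } else if (!length(ones)) {
    mask[sample.int(length(mask), 1L)] <- TRUE
  }
  mask
}

# Deterministic best index: highest fitness, ties by smaller cardinality,
# then lexicographically smallest mask (prefer parsimony, then determinism).
.best_index <- function(population, fitnesses) {
  best <- which(fitnesses == max(fitnesses))
  if (length(best) > 1L) {
    card <- rowSums(population[best, , drop = FALSE])
    best <- best[card == min(card)]
    if (length(best) > 1L) {
      keys <- apply(population[best, , drop = FALSE], 1L, paste, collapse = "")
      best <- best[order(keys)]
    }
  }
  best[1L]
}

#' Run the genetic algorithm
#'
#' Full loop: fitness evaluation, roulette selection of a full-size parent
#' pool, uniform crossover of consecutive parent pairs, bit mutation at
#' `p_m` (default `1/N`), cardinality repair, and elitist replacement (the
#' best chromosome survives unchanged, so best fitness never decreases).
#' Runs a fixed generation budget and returns the best chromosome of the
#' final generation with a per-generation log.
#'
#' @param x Matrix (samples x features).
#' @param y Labels.
#' @param cfg A [ga_config()].
#' @return List with `mask` (logical), `fitness`, and `log` (data frame
#'   generation / best_fitness / mean_fitness / best_cardinality; generation
#'   0 is the initial population).
#' @export
evolve <- function(x, y, cfg = ga_config()) {
  x <- as.matrix(x)
  N <- ncol(x)
  p_m <- if (is.null(cfg$p_m)) 1 / N else cfg$p_m
  set.seed(cfg$seed)
  folds <- stratified_folds(y, cfg$cv_folds)
  pop <- init_population(cfg, N)
  fit <- apply(pop, 1L, knn_cv_fitness, x = x, y = y, cfg = cfg,
               folds = folds)
  log_rows <- list(data.frame(generation = 0L, best_fitness = max(fit),
                              mean_fitness = mean(fit),
                              best_cardinality = sum(pop[.best_index(pop, fit), ])))
  for (gen in seq_len(cfg$max_generations)) {
    elite_idx <- .best_index(pop, fit)
    elite <- pop[elite_idx, ]; elite_fit <- fit[elite_idx]
    parents <- roulette_select(pop, fit, cfg$population_size)
    children <- parents
    for (i in seq(1L, cfg$population_size - 1L, by = 2L)) {
      kids <- uniform_crossover(parents[i, ], parents[i + 1L, ], cfg$p_c)
      children[i, ] <- kids[[1L]]; children[i + 1L, ] <- kids[[2L]]
    }
    for (i in seq_len(cfg$population_size))
      children[i, ] <- cardinality_repair(bit_mutate(children[i, ], p_m),
                                          cfg$d_max)
    if (cfg$elitism > 0L) children[seq_len(cfg$elitism), ] <-
      matrix(elite, nrow = cfg$elitism, ncol = N, byrow = TRUE)
    pop <- children
    fit <- apply(pop, 1L, knn_cv_fitness, x = x, y = y, cfg = cfg,
                 folds = folds)
    if (cfg$elitism > 0L) fit[seq_len(cfg$elitism)] <- elite_fit
    bi <- .best_index(pop, fit)
    log_rows[[gen + 1L]] <- data.frame(generation = gen,
                                       best_fitness = fit[bi],
                                       mean_fitness = mean(fit),
                                       best_cardinality = sum(pop[bi, ]))
  }
  bi <- .best_index(pop, fit)
  list(mask = pop[bi, ], fitness = fit[bi], log = do.call(rbind, log_rows))
}
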