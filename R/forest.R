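#' @include classes.R
NULL

# Shared input checks for (X, y) training data. X is samples x features with
# unique feature ids in colnames; y is numeric (regression) or
# factor/character (classification).
checkTrainingData <- function(X, y) {
  if (!is.matrix(X) || !is.numeric(X))
    stop("X must be a numeric matrix (samples x features)")
  if (nrow(X) < 1 || ncol(X) < 1) stop("X must be non-empty")
  if (anyNA(X)) stop("X contains missing values; impute before fitting")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X))) stop("duplicate feature ids in X")
  if (length(y) != nrow(X))
    stop("length(y) must equal nrow(X)")
  if (anyNA(y)) stop("y contains missing values")
  X
}

taskOf <- function(y) {
  if (is.factor(y) || is.character(y) || is.logical(y)) "classification"
  else "regression"
}

defaultMtry <- function(p) max(1L, as.integer(floor(sqrt(p))))

defaultMinNodeSize <- function(task) {
  if (task == "regression") 5L else 1L
}

#' Derive a child seed deterministically
#'
#' Pure 64-bit hash combination of a master seed, a stream tag and an index,
#' used for per-tree, per-iteration and per-target seeds so that results are
#' reproducible and independent of scheduling.
#'
#' @param seed master seed (nonnegative number).
#' @param stream integer stream tag separating uses (trees vs iterations vs
#'   targets).
#' @param index nonnegative integer position within the stream.
#' @return a numeric seed, exactly representable (< 2^53).
#' @export
deriveSeed <- function(seed, stream, index) {
  cpp_derive_seed(as.numeric(seed), as.numeric(stream), as.numeric(index))
}

#' Sample candidate features from a weighted distribution
#'
#' Sequential weighted sampling without replacement: each draw selects a
#' feature with probability proportional to its weight among those not yet
#' drawn, then removes it. Features with weight zero are never returned.
#'
#' @param weights nonnegative numeric vector, one weight per feature; at
#'   least one entry must be positive.
#' @param mtry number of candidates requested (>= 1); if fewer features have
#'   positive weight, only those are returned.
#' @param seed RNG seed for the draws.
#' @return integer vector of distinct 1-based feature indices, length
#'   \code{min(mtry, number of positive-weight features)}.
#' @examples
#' sampleCandidateFeatures(c(3, 1), mtry = 1, seed = 42)
#' @export
sampleCandidateFeatures <- function(weights, mtry, seed = 1) {
  if (!is.numeric(weights) || length(weights) < 1 || anyNA(weights))
    stop("weights must be a nonnegative numeric vector")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (all(weights == 0)) stop("degenerate weights: all entries are zero")
  if (mtry < 1) stop("mtry must be >= 1")
  cpp_sample_candidates(as.numeric(weights), as.integer(mtry),
                        as.numeric(seed))
}

#' Best single split of a node
#'
#' Evaluates every candidate feature at every midpoint between consecutive
#' distinct sorted values and returns the split maximizing the impurity
#' decrease: the drop in sum of squared deviations for regression, the
#' node-proportion-weighted Gini decrease for classification. Ties break to
#' the lowest feature index, then the lowest threshold. Returns `NULL` (the
#' leaf signal) when no split has strictly positive decrease.
#'
#' @param X numeric matrix of node samples x features.
#' @param y node response (numeric, or factor for classification).
#' @param candidates 1-based indices of candidate features.
#' @return `NULL`, or a list with `feature`, `threshold`, `decrease`.
#' @export
bestSplit <- function(X, y, candidates = seq_len(ncol(X))) {
  X <- checkTrainingData(X, y)
  task <- taskOf(y)
  if (task == "classification") {
    yf <- as.factor(y)
    res <- cpp_best_split(X, as.integer(yf) - 1L, as.integer(candidates),
                          FALSE, nlevels(yf))
  } else {
    res <- cpp_best_split(X, as.numeric(y), as.integer(candidates),
                          TRUE, 0L)
  }
  if (isTRUE(res$leaf)) return(NULL)
  res$leaf <- NULL
  res
}

#' Plan per-tree seeds and their worker assignment
#'
#' Tree t's seed is a pure function of (masterSeed, t) only, never of the
#' worker count or partition layout, so a forest aggregated from any number
#' of sub-forests is bit-identical to the single-worker forest. Trees are
#' assigned to workers in contiguous chunks.
#'
#' @param nTrees number of trees (>= 1).
#' @param nWorkers number of workers (>= 1); affects only the `worker`
#'   column, never the seeds.
#' @param masterSeed master seed.
#' @return data.frame with columns `tree`, `worker`, `seed`.
#' @export
planSubforests <- function(nTrees, nWorkers = 1, masterSeed = 1) {
  if (nTrees < 1) stop("nTrees must be >= 1")
  if (nWorkers < 1) stop("nWorkers must be >= 1")
  trees <- seq_len(nTrees)
  data.frame(
    tree = trees,
    worker = sort(rep_len(seq_len(as.integer(nWorkers)), nTrees)),
    seed = vapply(trees, function(t) deriveSeed(masterSeed, 1, t), numeric(1))
  )
}

#' Grow a single CART tree
#'
#' Draws a bootstrap sample of the rows (m of m, with replacement) from
#' `treeSeed`, then recursively splits with a fresh weighted candidate set
#' per node until a node is smaller than `2 * minNodeSize`, its response is
#' constant, or no split yields a positive impurity decrease. Leaves predict
#' the node mean (regression) or majority class (classification).
#'
#' @inheritParams growForest
#' @param treeSeed seed for this tree's bootstrap and candidate draws.
#' @param bootstrap set `FALSE` to grow on the full sample (test hook used
#'   for oracle comparisons).
#' @return a [WeightedForest] containing one tree.
#' @export
growTree <- function(X, y, weights = NULL, mtry = NULL, minNodeSize = NULL,
                     treeSeed = 1, bootstrap = TRUE) {
  growForestSeeded(X, y, weights, seeds = as.numeric(treeSeed), mtry = mtry,
                   minNodeSize = minNodeSize, masterSeed = treeSeed,
                   bootstrap = bootstrap)
}

# Core fit used by growTree / growForest: seeds are already resolved.
growForestSeeded <- function(X, y, weights, seeds, mtry, minNodeSize,
                             masterSeed, bootstrap = TRUE) {
  X <- checkTrainingData(X, y)
  p <- ncol(X)
  task <- taskOf(y)
  if (is.null(weights)) weights <- rep(1, p)
  if (length(weights) != p) stop("weights length must equal ncol(X)")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (all(weights == 0)) stop("degenerate weights: all entries are zero")
  if (is.null(mtry)) mtry <- defaultMtry(p)
  if (is.null(minNodeSize)) minNodeSize <- defaultMinNodeSize(task)
  if (mtry < 1) stop("mtry must be >= 1")
  if (minNodeSize < 1) stop("minNodeSize must be >= 1")

  if (task == "classification") {
    yf <- as.factor(y)
    fit <- cpp_grow_forest(X, as.integer(yf) - 1L, FALSE, nlevels(yf),
                           as.numeric(weights), as.numeric(seeds),
                           as.integer(mtry), as.integer(minNodeSize),
                           bootstrap)
    levels <- levels(yf)
  } else {
    fit <- cpp_grow_forest(X, as.numeric(y), TRUE, 0L,
                           as.numeric(weights), as.numeric(seeds),
                           as.integer(mtry), as.integer(minNodeSize),
                           bootstrap)
    levels <- character()
  }
  new("WeightedForest",
      trees = fit$trees,
      nTrees = length(seeds),
      task = task,
      mtry = as.integer(mtry),
      minNodeSize = as.integer(minNodeSize),
      masterSeed = as.numeric(masterSeed),
      featureIds = colnames(X),
      classLevels = levels,
      importance = as.numeric(fit$importance))
}

#' Grow a random forest from deterministically seeded sub-forests
#'
#' Trees are grown per [planSubforests()]: each tree's seed depends only on
#' `(masterSeed, tree index)`, and aggregation is concatenation, so the
#' forest (and its importance vector) is identical for any `nWorkers`.
#'
#' @param X numeric matrix, samples x features (feature ids in colnames).
#' @param y response vector: numeric for regression, factor/character for
#'   classification.
#' @param weights optional nonnegative feature-sampling weights (default
#'   uniform). A feature with weight 0 is never considered at any node.
#' @param nTrees number of trees.
#' @param mtry candidate features per node; default `floor(sqrt(ncol(X)))`.
#' @param minNodeSize minimum node size; default 5 (regression) or
#'   1 (classification).
#' @param masterSeed master seed.
#' @param nWorkers worker count (partitioning only; never changes results).
#' @param bootstrap test hook; `FALSE` disables bootstrap resampling.
#' @return a [WeightedForest].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("g", 1:4)))
#' y <- X[, 1] + rnorm(50, sd = 0.1)
#' f <- growForest(X, y, nTrees = 50, masterSeed = 7)
#' impurityImportance(f)
#' @export
growForest <- function(X, y, weights = NULL, nTrees = 500, mtry = NULL,
                       minNodeSize = NULL, masterSeed = 1, nWorkers = 1,
                       bootstrap = TRUE) {
  plan <- planSubforests(nTrees, nWorkers, masterSeed)
  growForestSeeded(X, y, weights, seeds = plan$seed, mtry = mtry,
                   minNodeSize = minNodeSize, masterSeed = masterSeed,
                   bootstrap = bootstrap)
}

#' Predict from a weighted forest
#'
#' Mean of per-tree predictions for regression; majority vote (ties to the
#' first class level) for classification.
#'
#' @param object a [WeightedForest].
#' @param newdata numeric matrix with the training feature count (columns
#'   are matched by name when named).
#' @return numeric vector (regression) or factor (classification).
#' @export
setMethod("predict", "WeightedForest", function(object, newdata) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    missing <- setdiff(object@featureIds, colnames(newdata))
    if (length(missing))
      stop("newdata lacks training features: ", paste(missing, collapse = ", "))
    newdata <- newdata[, object@featureIds, drop = FALSE]
  } else if (ncol(newdata) != length(object@featureIds)) {
    stop(sprintf("newdata has %d columns; forest was trained on %d features",
                 ncol(newdata), length(object@featureIds)))
  }
  preds <- cpp_predict_trees(object@trees, newdata)
  if (object@task == "regression") return(rowMeans(preds))
  k <- length(object@classLevels)
  votes <- apply(preds, 1, function(row) {
    tab <- tabulate(as.integer(row) + 1L, nbins = k)
    which.max(tab)  # ties -> lowest class code
  })
  factor(object@classLevels[votes], levels = object@classLevels)
})

# Recompute total impurity decrease by traversing the stored trees; used to
# verify that the importance vector conserves the per-node decreases.
totalDecreaseByTraversal <- function(forest) {
  sum(vapply(forest@trees, function(t) sum(t$decrease), numeric(1)))
}
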