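#' @include irfnet-package.R
NULL

#' Weighted random forest
#'
#' An ensemble of CART trees grown with bootstrap resampling and weighted
#' candidate-feature sampling. Trees are stored as flat node tables (parallel
#' vectors of split variable, threshold, child pointers, leaf prediction and
#' impurity decrease); the forest is reproducible from the training data,
#' feature weights, parameters and \code{masterSeed} alone, independent of
#' how trees were partitioned across workers.
#'
#' @slot trees list of per-tree node tables.
#' @slot nTrees number of trees.
#' @slot task \code{"regression"} or \code{"classification"}.
#' @slot mtry number of candidate features sampled per node.
#' @slot minNodeSize minimum node size below which a node becomes a leaf.
#' @slot masterSeed integer master seed the tree seeds were derived from.
#' @slot featureIds character vector of training feature identifiers.
#' @slot classLevels class labels (classification only, else empty).
#' @slot importance per-feature impurity importance (mean impurity decrease
#'   per tree).
#'
#' @seealso [growForest()], [impurityImportance()], [predict,WeightedForest-method]
#' @export
setClass("WeightedForest",
  representation(
    trees = "list",
    nTrees = "integer",
    task = "character",
    mtry = "integer",
    minNodeSize = "integer",
    masterSeed = "numeric",
    featureIds = "character",
    classLevels = "character",
    importance = "numeric"
  )
)

setValidity("WeightedForest", function(object) {
  msg <- character()
  if (length(object@trees) != object@nTrees)
    msg <- c(msg, "length(trees) must equal nTrees")
  if (!object@task %in% c("regression", "classification"))
    msg <- c(msg, "task must be 'regression' or 'classification'")
  if (length(object@importance) != length(object@featureIds))
    msg <- c(msg, "importance length must match featureIds")
  if (any(object@importance < 0))
    msg <- c(msg, "importance scores must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Iterative random forest result
#'
#' @slot importanceHistory list of named importance vectors, one per
#'   iteration (iteration 1 is the unweighted forest).
#' @slot finalImportance named importance vector of the last iteration.
#' @slot weightsHistory list of the normalized feature weights fed into each
#'   iteration (element 1 is uniform).
#' @slot params list of run parameters (iterations, trees, mtry, minNodeSize,
#'   masterSeed, task).
#'
#' @seealso [runIRF()]
#' @export
setClass("IRFResult",
  representation(
    importanceHistory = "list",
    finalImportance = "numeric",
    weightsHistory = "list",
    params = "list"
  )
)

setValidity("IRFResult", function(object) {
  msg <- character()
  if (length(object@importanceHistory) < 1)
    msg <- c(msg, "at least one iteration required")
  if (any(object@finalImportance < 0))
    msg <- c(msg, "importance scores must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Predictive Expression Network (directed adjacency matrix)
#'
#' The n x n column-normalized importance matrix from iRF-LOOP. Entry (i, j)
#' is gene i's importance for predicting gene j; the diagonal is exactly
#' zero and every column sums to 1 or is all zero (a constant target gene).
#' The matrix is directed and generally asymmetric.
#'
#' @slot adjacency numeric matrix, genes x genes, dimnames = gene ids.
#'
#' @seealso [irfLoop()], [normalizeColumns()], [thresholdEdges()]
#' @export
setClass("PredictiveNetwork", representation(adjacency = "matrix"))

setValidity("PredictiveNetwork", function(object) {
  a <- object@adjacency
  msg <- character()
  if (nrow(a) != ncol(a)) msg <- c(msg, "adjacency must be square")
  if (is.null(rownames(a)) || is.null(colnames(a)) ||
      !identical(rownames(a), colnames(a)))
    msg <- c(msg, "adjacency must carry identical row and column gene ids")
  else if (anyDuplicated(rownames(a)))
    msg <- c(msg, "gene ids must be unique")
  if (any(a < 0)) msg <- c(msg, "entries must be nonnegative")
  if (nrow(a) > 0 && any(diag(a) != 0)) msg <- c(msg, "diagonal must be zero")
  cs <- colSums(a)
  if (any(cs > 0 & abs(cs - 1) > 1e-8))
    msg <- c(msg, "columns must sum to 1 or be all zero")
  if (length(msg)) msg else TRUE
})

#' Gene Ontology co-annotation network
#'
#' Undirected gene-gene edges: two genes are connected when they share at
#' least one GO term annotated to fewer than \code{maxTermSize} genes. An
#' edge inherits weight 1/(n-1) from a shared term of n genes; a pair
#' sharing several terms keeps the largest weight (i.e. the smallest shared
#' term dominates).
#'
#' @slot edges data.frame with columns \code{geneA}, \code{geneB} (with
#'   geneA < geneB lexicographically) and \code{weight} in (0, 1].
#' @slot nodes character vector of genes carrying at least one edge.
#' @slot maxTermSize the term-size cutoff used at construction.
#'
#' @seealso [buildGONetwork()], [intersectScore()]
#' @export
setClass("GONetwork",
  representation(edges = "data.frame", nodes = "character",
                 maxTermSize = "integer")
)

setValidity("GONetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("geneA", "geneB", "weight") %in% names(e)))
    msg <- c(msg, "edges must have columns geneA, geneB, weight")
  else {
    if (any(e$weight <= 0) || any(e$weight > 1))
      msg <- c(msg, "edge weights must lie in (0, 1]")
    if (any(e$geneA >= e$geneB))
      msg <- c(msg, "edges must be stored with geneA < geneB")
    if (anyDuplicated(paste(e$geneA, e$geneB, sep = "\r")))
      msg <- c(msg, "duplicate gene pairs")
  }
  if (length(msg)) msg else TRUE
})

#' Permutation-validation score report
#'
#' Holds the observed intersect score of a predicted network against a GO
#' co-annotation network, the node-label permutation null distribution, its
#' moments and the resulting t-statistic
#' (observed - null mean) / null s.d.
#'
#' @slot intersectScore observed intersect score.
#' @slot nullScores numeric vector of permuted scores.
#' @slot nullMean mean of the null scores.
#' @slot nullSd sample (n-1) standard deviation of the null scores.
#' @slot tStatistic the standardized observed score.
#' @slot nPermutations number of label permutations.
#' @slot seed seed used to generate the permutations.
#'
#' @seealso [scoreAgainstGO()], [tStatistic()]
#' @export
setClass("ScoreReport",
  representation(
    intersectScore = "numeric",
    nullScores = "numeric",
    nullMean = "numeric",
    nullSd = "numeric",
    tStatistic = "numeric",
    nPermutations = "integer",
    seed = "numeric"
  )
)

setValidity("ScoreReport", function(object) {
  msg <- character()
  if (object@intersectScore < 0) msg <- c(msg, "intersect score must be >= 0")
  if (object@nullSd > 0) {
    expected <- (object@intersectScore - object@nullMean) / object@nullSd
    if (abs(object@tStatistic - expected) > 1e-8 * max(1, abs(expected)))
      msg <- c(msg, "tStatistic inconsistent with (score - mean)/sd")
  }
  if (length(msg)) msg else TRUE
})

# ---- accessors ----

#' Per-feature impurity importance of a forest
#'
#' Sum over all trees of the impurity decrease of every node splitting on a
#' feature, divided by the number of trees. Features never used in a split
#' score exactly 0.
#'
#' @param forest a [WeightedForest].
#' @return named nonnegative numeric vector, one entry per training feature.
#' @export
impurityImportance <- function(forest) {
  stopifnot(is(forest, "WeightedForest"))
  stats::setNames(forest@importance, forest@featureIds)
}

#' @describeIn PredictiveNetwork-class the adjacency matrix.
#' @param x a \code{PredictiveNetwork}.
#' @export
adjacency <- function(x) {
  stopifnot(is(x, "PredictiveNetwork"))
  x@adjacency
}

#' @describeIn PredictiveNetwork-class the gene identifiers.
#' @export
geneIds <- function(x) {
  stopifnot(is(x, "PredictiveNetwork"))
  rownames(x@adjacency)
}

#' @describeIn GONetwork-class the edge table.
#' @param go a \code{GONetwork}.
#' @export
goEdges <- function(go) {
  stopifnot(is(go, "GONetwork"))
  go@edges
}

#' @describeIn GONetwork-class total edge weight (the maximum attainable
#'   intersect score).
#' @export
totalWeight <- function(go) {
  stopifnot(is(go, "GONetwork"))
  sum(go@edges$weight)
}

#' @describeIn ScoreReport-class the permutation null scores.
#' @param report a \code{ScoreReport}.
#' @export
nullScores <- function(report) {
  stopifnot(is(report, "ScoreReport"))
  report@nullScores
}

# ---- show methods ----

setMethod("show", "WeightedForest", function(object) {
  cat(sprintf("WeightedForest: %d %s trees, %d features (mtry = %d, min node size = %d, seed = %s)\n",
              object@nTrees, object@task, length(object@featureIds),
              object@mtry, object@minNodeSize,
              format(object@masterSeed, scientific = FALSE)))
})

setMethod("show", "IRFResult", function(object) {
  cat(sprintf("IRFResult: %d iterations of %d trees on %d features\n",
              length(object@importanceHistory), object@params$nTrees,
              length(object@finalImportance)))
  top <- sort(object@finalImportance, decreasing = TRUE)
  top <- top[top > 0]
  cat("  top features:", paste(head(names(top), 5), collapse = ", "), "\n")
})

setMethod("show", "PredictiveNetwork", function(object) {
  a <- object@adjacency
  cat(sprintf("PredictiveNetwork: %d genes, %d nonzero directed edges\n",
              nrow(a), sum(a > 0)))
})

setMethod("show", "GONetwork", function(object) {
  cat(sprintf("GONetwork: %d nodes, %d edges (term-size cutoff < %d), total weight %.4f\n",
              length(object@nodes), nrow(object@edges), object@maxTermSize,
              sum(object@edges$weight)))
})

setMethod("show", "ScoreReport", function(object) {
  cat(sprintf("ScoreReport: intersect score %.4f | null mean %.4f, s.d. %.4f (%d permutations) | t = %.2f\n",
              object@intersectScore, object@nullMean, object@nullSd,
              object@nPermutations, object@tStatistic))
})
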