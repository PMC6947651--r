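#' @include forest.R
NULL

#' Normalize an importance vector into sampling weights
#'
#' Divides by the vector sum so the weights sum to 1. An all-zero vector
#' falls back to uniform weights with a warning (nothing was learned, so the
#' next forest samples uniformly).
#'
#' @param v nonnegative numeric vector (names preserved).
#' @return numeric vector summing to 1.
#' @examples
#' normalizeImportance(c(2, 0, 6))
#' @export
normalizeImportance <- function(v) {
  if (anyNA(v)) stop("importance contains missing values")
  if (any(v < 0)) stop("importance scores must be nonnegative")
  s <- sum(v)
  if (s == 0) {
    warning("all importance scores are zero; falling back to uniform weights")
    return(rep(1 / length(v), length(v)) |> stats::setNames(names(v)))
  }
  v / s
}

#' Write / read feature weights
#'
#' Two-column tab-separated file (feature_id, weight) at full double
#' precision, the on-disk interchange format between iRF iterations.
#'
#' @param w named numeric vector of weights.
#' @param path file path.
#' @param comments optional '#' comment header lines.
#' @return `readWeights` returns the named numeric vector.
#' @export
writeWeights <- function(w, path, comments = character()) {
  if (is.null(names(w))) names(w) <- paste0("f", seq_along(w))
  lines <- c(comments, paste(names(w), sprintf("%.17g", w), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeWeights
#' @export
readWeights <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) stop("malformed weights file: ", path)
  w <- as.numeric(vapply(parts, `[`, character(1), 2))
  if (anyNA(w)) stop("non-numeric weight in: ", path)
  stats::setNames(w, vapply(parts, `[`, character(1), 1))
}

#' Run an iterative random forest
#'
#' Iteration 1 grows an unweighted forest; each later iteration uses the
#' sum-normalized importance of the previous forest as the candidate-feature
#' sampling weights. Features whose importance reaches zero are never
#' sampled again, so the feature set shrinks across iterations (a
#' Lasso-like elimination). Per-iteration forest seeds derive
#' deterministically from `(masterSeed, iteration)`.
#'
#' If `weightsPath` is given, the weights are written after each iteration
#' and re-read before the next, mirroring file-mediated weight passing; the
#' serialization is value-exact at full double precision.
#'
#' @inheritParams growForest
#' @param nIterations number of forests to chain (>= 1).
#' @param weightsPath optional path for the inter-iteration weights file.
#' @return an [IRFResult].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(500), 50, 10, dimnames = list(NULL, paste0("g", 1:10)))
#' y <- 2 * X[, 1] + rnorm(50, sd = 0.1)
#' res <- runIRF(X, y, nIterations = 3, nTrees = 100, masterSeed = 7)
#' sort(res@finalImportance, decreasing = TRUE)[1:3]
#' @export
runIRF <- function(X, y, nIterations = 3, nTrees = 500, mtry = NULL,
                   minNodeSize = NULL, masterSeed = 1, nWorkers = 1,
                   weightsPath = NULL) {
  if (nIterations < 1) stop("nIterations must be >= 1")
  X <- checkTrainingData(X, y)
  p <- ncol(X)
  weights <- stats::setNames(rep(1 / p, p), colnames(X))
  history <- vector("list", nIterations)
  whistory <- vector("list", nIterations)
  for (k in seq_len(nIterations)) {
    whistory[[k]] <- weights
    iterSeed <- deriveSeed(masterSeed, 2, k)
    forest <- growForest(X, y, weights = weights, nTrees = nTrees,
                         mtry = mtry, minNodeSize = minNodeSize,
                         masterSeed = iterSeed, nWorkers = nWorkers)
    imp <- impurityImportance(forest)
    history[[k]] <- imp
    if (k < nIterations) {
      weights <- normalizeImportance(imp)
      if (!is.null(weightsPath)) {
        writeWeights(weights, weightsPath)
        weights <- readWeights(weightsPath)
        if (length(weights) != p || !identical(names(weights), colnames(X)))
          stop("weights file round-trip changed the feature set: ", weightsPath)
      }
    }
  }
  new("IRFResult",
      importanceHistory = history,
      finalImportance = history[[nIterations]],
      weightsHistory = whistory,
      params = list(nIterations = nIterations, nTrees = nTrees,
                    mtry = mtry, minNodeSize = minNodeSize,
                    masterSeed = masterSeed, task = taskOf(y)))
}

#' Recommend a tree count for feature coverage
#'
#' Smallest number of trees T such that a given feature has at least
#' `coverage` probability of entering a candidate set within the first two
#' tree layers (3 decision nodes: root plus two children) of at least one
#' tree. Each node's candidate set includes a given feature with probability
#' mtry/nFeatures, so T solves the conservative rate form
#' 1 - exp(-3 T mtry / nFeatures) >= coverage, i.e.
#' T = ceiling(-log(1 - coverage) * nFeatures / (3 * mtry)).
#'
#' @param nFeatures total number of features.
#' @param mtry candidate features per node (1 <= mtry <= nFeatures).
#' @param coverage target inclusion probability in (0, 1); default 0.95.
#' @return integer tree count.
#' @examples
#' recommendTreeCount(1710000, 1308)  # ~ sqrt(p)-scale forests
#' @export
recommendTreeCount <- function(nFeatures, mtry, coverage = 0.95) {
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)")
  if (mtry < 1 || mtry > nFeatures) stop("mtry must be in [1, nFeatures]")
  as.integer(ceiling(-log(1 - coverage) * nFeatures / (3 * mtry)))
}
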