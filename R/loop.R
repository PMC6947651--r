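#' @include irf.R
NULL

#' Column-normalize a raw importance matrix
#'
#' Each column with positive sum is divided by that sum so importances are
#' comparable across target genes; all-zero columns (constant or
#' unpredictable targets) are left as zero. The diagonal must already be
#' zero: a gene's importance for predicting itself is removed before
#' normalization.
#'
#' @param raw square nonnegative numeric matrix with zero diagonal and gene
#'   ids as dimnames.
#' @return a [PredictiveNetwork].
#' @export
normalizeColumns <- function(raw) {
  if (!is.matrix(raw) || nrow(raw) != ncol(raw))
    stop("raw must be a square matrix")
  if (any(raw < 0)) stop("entries must be nonnegative")
  if (any(diag(raw) != 0)) stop("diagonal must be zero")
  if (is.null(rownames(raw)))
    dimnames(raw) <- rep(list(paste0("g", seq_len(nrow(raw)))), 2)
  cs <- colSums(raw)
  pos <- cs > 0
  raw[, pos] <- sweep(raw[, pos, drop = FALSE], 2, cs[pos], "/")
  new("PredictiveNetwork", adjacency = raw)
}

#' Build a Predictive Expression Network by leave-one-out iRF
#'
#' Runs one iRF per gene with that gene as the target and all others as
#' predictors, assembles the final importance vectors into an n x n matrix
#' (column j = importances for predicting gene j, entry (j, j) = 0), and
#' column-normalizes it. Per-target seeds derive from
#' `(masterSeed, target index)`, so targets may be computed in any order or
#' partition with identical results. Constant target genes yield an all-zero
#' column with a warning.
#'
#' @param X numeric expression matrix, samples x genes (>= 2 genes, gene ids
#'   in colnames).
#' @inheritParams runIRF
#' @return a [PredictiveNetwork].
#' @examples
#' sim <- simulateExpression(plantedChain(3), nSamples = 100, seed = 1)
#' pen <- irfLoop(sim$X, nIterations = 2, nTrees = 50, masterSeed = 1)
#' adjacency(pen)
#' @export
irfLoop <- function(X, nIterations = 3, nTrees = 500, mtry = NULL,
                    minNodeSize = NULL, masterSeed = 1, nWorkers = 1) {
  if (!is.matrix(X) || ncol(X) < 2)
    stop("X must be a matrix with at least 2 genes")
  if (is.null(colnames(X))) colnames(X) <- paste0("g", seq_len(ncol(X)))
  genes <- colnames(X)
  n <- length(genes)
  raw <- matrix(0, n, n, dimnames = list(genes, genes))
  for (j in seq_len(n)) {
    y <- X[, j]
    if (length(unique(y)) < 2) {
      warning("target gene '", genes[j], "' is constant; column left zero")
      next
    }
    res <- runIRF(X[, -j, drop = FALSE], y,
                  nIterations = nIterations, nTrees = nTrees, mtry = mtry,
                  minNodeSize = minNodeSize,
                  masterSeed = deriveSeed(masterSeed, 3, j),
                  nWorkers = nWorkers)
    raw[names(res@finalImportance), j] <- res@finalImportance
  }
  diag(raw) <- 0
  normalizeColumns(raw)
}

#' Threshold a network into its top edges
#'
#' Pools the strictly positive entries of the adjacency matrix, finds the
#' weight of the `ceiling(topFraction * count)`-th largest, and returns
#' every edge at or above that cutoff (ties at the cutoff are included, so
#' the edge count may slightly exceed the nominal fraction). Output is
#' sorted by descending weight, then source and target id.
#'
#' @param pen a [PredictiveNetwork] (or square nonnegative matrix).
#' @param topFraction fraction of nonzero edge scores to keep, in (0, 1].
#' @return data.frame with columns `source`, `target`, `weight`; zero rows
#'   (with a warning) when the network has no positive entries.
#' @examples
#' sim <- simulateExpression(plantedChain(4), nSamples = 100, seed = 1)
#' pen <- irfLoop(sim$X, nIterations = 2, nTrees = 50, masterSeed = 1)
#' thresholdEdges(pen, 0.10)
#' @export
thresholdEdges <- function(pen, topFraction) {
  a <- if (is(pen, "PredictiveNetwork")) adjacency(pen) else pen
  if (!is.matrix(a)) stop("pen must be a PredictiveNetwork or matrix")
  if (topFraction <= 0 || topFraction > 1)
    stop("topFraction must be in (0, 1]")
  keep <- which(a > 0, arr.ind = TRUE)
  if (nrow(keep) == 0) {
    warning("network has no positive edge scores")
    return(data.frame(source = character(), target = character(),
                      weight = numeric()))
  }
  w <- a[keep]
  cutoff <- sort(w, decreasing = TRUE)[ceiling(topFraction * length(w))]
  sel <- w >= cutoff
  edges <- data.frame(
    source = rownames(a)[keep[sel, "row"]],
    target = colnames(a)[keep[sel, "col"]],
    weight = w[sel]
  )
  edges[order(-edges$weight, edges$source, edges$target), , drop = FALSE] |>
    `rownames<-`(NULL)
}
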