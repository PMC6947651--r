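#' @include loop.R
NULL

#' Read gene-to-term annotations
#'
#' Accepts either a two-column tab-separated table (gene_id, term_id) or a
#' GAF 2.x file, from which the DB object symbol (column 3) and GO ID
#' (column 5) are taken. Comment lines starting with '#' or '!' are
#' skipped; duplicate records collapse.
#'
#' @param path file path.
#' @return data.frame with columns `gene`, `term`.
#' @export
readAnnotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & !startsWith(lines, "#") &
                   nzchar(lines)]
  if (length(lines) == 0) stop("no annotation records in: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (all(ncols >= 15)) {          # GAF 2.x
    ann <- data.frame(gene = vapply(parts, `[`, character(1), 3),
                      term = vapply(parts, `[`, character(1), 5))
  } else if (all(ncols == 2)) {
    ann <- data.frame(gene = vapply(parts, `[`, character(1), 1),
                      term = vapply(parts, `[`, character(1), 2))
  } else {
    stop("annotation file is neither 2-column TSV nor GAF: ", path)
  }
  unique(ann)
}

#' Build the GO co-annotation network
#'
#' Connects every pair of genes sharing a term. A term annotated to n genes
#' (2 <= n < `maxTermSize`) contributes all n(n-1)/2 pairs at weight
#' 1/(n-1), so rare, specific terms dominate broad ones; a pair sharing
#' several terms keeps the maximum weight. Terms with `maxTermSize` or more
#' genes are excluded entirely (broad categorizations carry little
#' functional signal).
#'
#' @param annotations data.frame whose first two columns are gene and term
#'   ids (duplicates collapse).
#' @param maxTermSize strict upper bound on usable term size; default 1000.
#' @return a [GONetwork].
#' @examples
#' ann <- data.frame(gene = c("A", "B", "C"), term = "GO:1")
#' goEdges(buildGONetwork(ann))  # three edges at weight 1/2
#' @export
buildGONetwork <- function(annotations, maxTermSize = 1000) {
  if (nrow(annotations) == 0) stop("annotations are empty")
  ann <- unique(data.frame(gene = as.character(annotations[[1]]),
                           term = as.character(annotations[[2]])))
  members <- split(ann$gene, ann$term)
  pieces <- lapply(members, function(g) {
    g <- sort(unique(g))
    n <- length(g)
    if (n < 2 || n >= maxTermSize) return(NULL)
    idx <- utils::combn(n, 2)
    data.table::data.table(geneA = g[idx[1, ]], geneB = g[idx[2, ]],
                           weight = 1 / (n - 1))
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0) {
    edges <- data.frame(geneA = character(), geneB = character(),
                        weight = numeric())
    return(new("GONetwork", edges = edges, nodes = character(),
               maxTermSize = as.integer(maxTermSize)))
  }
  all <- as.data.frame(data.table::rbindlist(pieces))
  key <- pairKey(all$geneA, all$geneB)
  w <- tapply(all$weight, key, max)
  ab <- strsplit(names(w), "\r", fixed = TRUE)
  edges <- data.frame(geneA = vapply(ab, `[`, character(1), 1),
                      geneB = vapply(ab, `[`, character(1), 2),
                      weight = as.numeric(w))
  edges <- edges[order(edges$geneA, edges$geneB), , drop = FALSE]
  rownames(edges) <- NULL
  new("GONetwork", edges = edges,
      nodes = sort(unique(c(edges$geneA, edges$geneB))),
      maxTermSize = as.integer(maxTermSize))
}

# Collapse a directed edge table to distinct unordered pairs.
collapsePairs <- function(edges) {
  a <- pmin(as.character(edges$source), as.character(edges$target))
  b <- pmax(as.character(edges$source), as.character(edges$target))
  keep <- a != b
  unique(data.frame(geneA = a[keep], geneB = b[keep]))
}

pairKey <- function(a, b) paste(a, b, sep = "\r")

#' Intersect score of a predicted network against the GO network
#'
#' The predicted (directed) network is collapsed to distinct unordered gene
#' pairs; the score is the sum of GO edge weights over the pairs present in
#' both networks. A pair with edges in both directions counts once; pairs
#' absent from the GO network contribute nothing.
#'
#' @param pen data.frame of directed edges with columns `source`, `target`
#'   (e.g. from [thresholdEdges()]).
#' @param go a [GONetwork].
#' @return nonnegative numeric scalar.
#' @export
intersectScore <- function(pen, go) {
  stopifnot(is(go, "GONetwork"))
  pairs <- collapsePairs(pen)
  if (nrow(pairs) == 0) return(0)
  w <- stats::setNames(go@edges$weight, pairKey(go@edges$geneA, go@edges$geneB))
  hit <- w[pairKey(pairs$geneA, pairs$geneB)]
  sum(hit, na.rm = TRUE)
}

#' Permutation null distribution of intersect scores
#'
#' Each replicate draws a uniform random bijection of the predicted
#' network's node labels onto themselves, relabels its (collapsed,
#' unordered) edges, and scores the relabeled network against the GO
#' network. The GO network is never permuted. Seeded and reproducible.
#'
#' @inheritParams intersectScore
#' @param nPermutations number of label permutations; default 1000.
#' @param seed RNG seed.
#' @return numeric vector of length `nPermutations`.
#' @export
nullDistribution <- function(pen, go, nPermutations = 1000, seed = 1) {
  stopifnot(is(go, "GONetwork"))
  if (nPermutations < 1) stop("nPermutations must be >= 1")
  pairs <- collapsePairs(pen)
  nodes <- sort(unique(c(pairs$geneA, pairs$geneB)))
  if (length(nodes) < 2) stop("predicted network must have >= 2 nodes")

  # integer coding over the union of PEN and GO genes for fast pair lookup
  universe <- sort(unique(c(nodes, go@nodes)))
  K <- length(universe) + 1
  goKey <- match(go@edges$geneA, universe) +
    K * match(go@edges$geneB, universe)
  goW <- go@edges$weight
  ai <- match(pairs$geneA, universe)
  bi <- match(pairs$geneB, universe)
  nodeIdx <- match(nodes, universe)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  vapply(seq_len(nPermutations), function(r) {
    relab <- integer(max(nodeIdx))
    relab[nodeIdx] <- nodeIdx[sample.int(length(nodeIdx))]
    pa <- relab[ai]
    pb <- relab[bi]
    key <- pmin(pa, pb) + K * pmax(pa, pb)
    sum(goW[match(key, goKey)], na.rm = TRUE)
  }, numeric(1))
}

#' t-statistic of an observed score against an empirical null
#'
#' `(observed - mean(null)) / sd(null)` with the sample (n-1) standard
#' deviation. The null may be given either as a vector of permuted scores
#' or directly as its moments (e.g. when standardizing against published
#' null summaries).
#'
#' @param observed observed score.
#' @param nullScores numeric vector of permuted scores (length >= 2).
#' @param nullMean,nullSd alternatively, the null mean and s.d.
#' @return numeric scalar.
#' @examples
#' tStatistic(213.28, nullMean = 9.6930, nullSd = 0.8720)
#' @export
tStatistic <- function(observed, nullScores = NULL, nullMean = NULL,
                       nullSd = NULL) {
  if (!is.null(nullScores)) {
    if (length(nullScores) < 2)
      stop("nullScores must have length >= 2")
    nullMean <- mean(nullScores)
    nullSd <- stats::sd(nullScores)
  }
  if (is.null(nullMean) || is.null(nullSd))
    stop("provide nullScores or both nullMean and nullSd")
  if (nullSd <= 0) stop("degenerate null: standard deviation is not positive")
  (observed - nullMean) / nullSd
}

#' Score a predicted network against the GO network with a permutation null
#'
#' Convenience wrapper: computes the observed [intersectScore()], the
#' [nullDistribution()], and the [tStatistic()], returned as a
#' [ScoreReport].
#'
#' @inheritParams nullDistribution
#' @return a [ScoreReport].
#' @export
scoreAgainstGO <- function(pen, go, nPermutations = 1000, seed = 1) {
  observed <- intersectScore(pen, go)
  nulls <- nullDistribution(pen, go, nPermutations = nPermutations,
                            seed = seed)
  new("ScoreReport",
      intersectScore = observed,
      nullScores = nulls,
      nullMean = mean(nulls),
      nullSd = stats::sd(nulls),
      tStatistic = tStatistic(observed, nulls),
      nPermutations = as.integer(nPermutations),
      seed = as.numeric(seed))
}

#' QQ diagnostic for a permutation null
#'
#' Normal quantile-quantile plot of the null scores, for checking that the
#' empirical null is close enough to normal for the t-statistic to be
#' meaningful.
#'
#' @param report a [ScoreReport] (or numeric vector of null scores).
#' @param ... passed to [stats::qqnorm()].
#' @return invisibly, the qqnorm coordinates.
#' @export
nullQQPlot <- function(report, ...) {
  scores <- if (is(report, "ScoreReport")) report@nullScores else report
  q <- stats::qqnorm(scores, main = "Permutation null vs normal", ...)
  stats::qqline(scores)
  invisible(q)
}

#' Pearson co-expression comparator network
#'
#' Computes pairwise Pearson correlation between genes over samples, ranks
#' the pairs by absolute correlation, and keeps the top fraction with ties
#' at the cutoff included (as in [thresholdEdges()]). Constant genes have
#' undefined correlation and are excluded with a warning. The output is
#' undirected (one record per pair); weights carry the signed correlation.
#'
#' @param X numeric matrix, samples x genes (>= 2 genes, >= 3 samples).
#' @param topFraction fraction of pairs to keep, in (0, 1].
#' @return data.frame with columns `source`, `target`, `weight` (= r),
#'   sorted by descending |r|.
#' @export
coexpressionNetwork <- function(X, topFraction) {
  if (!is.matrix(X) || ncol(X) < 2 || nrow(X) < 3)
    stop("X must be a samples x genes matrix with >= 2 genes and >= 3 samples")
  if (topFraction <= 0 || topFraction > 1)
    stop("topFraction must be in (0, 1]")
  if (is.null(colnames(X))) colnames(X) <- paste0("g", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant genes excluded from co-expression: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    if (ncol(X) < 2) return(data.frame(source = character(),
                                       target = character(),
                                       weight = numeric()))
  }
  r <- stats::cor(X)
  idx <- which(upper.tri(r), arr.ind = TRUE)
  w <- r[idx]
  absw <- abs(w)
  cutoff <- sort(absw, decreasing = TRUE)[ceiling(topFraction * length(absw))]
  sel <- absw >= cutoff
  edges <- data.frame(
    source = rownames(r)[idx[sel, "row"]],
    target = colnames(r)[idx[sel, "col"]],
    weight = w[sel]
  )
  edges[order(-abs(edges$weight), edges$source, edges$target), , drop = FALSE] |>
    `rownames<-`(NULL)
}
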