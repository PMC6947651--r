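#' @include go.R
NULL

# Seeds may be 53-bit hashes; fold into the 32-bit range set.seed accepts.
foldSeed <- function(seed) as.integer(seed %% 2147483647)

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(foldSeed(seed))
  expr
}

#' Specify a planted directed regulatory network
#'
#' Defines the ground truth for [simulateExpression()]: gene ids, directed
#' regulatory edges with nonzero effect sizes, and the child-gene noise
#' level. The edge set must be acyclic.
#'
#' @param genes character vector of gene ids.
#' @param edges data.frame with columns `parent`, `child`, `effect`
#'   (nonzero reals).
#' @param noiseSd standard deviation of the additive Gaussian noise on each
#'   child gene; default 0.2.
#' @return an object of class `plantedNetwork` (a validated list).
#' @export
plantedNetwork <- function(genes, edges, noiseSd = 0.2) {
  stopifnot(is.character(genes), !anyDuplicated(genes), noiseSd >= 0)
  edges <- data.frame(parent = as.character(edges$parent),
                      child = as.character(edges$child),
                      effect = as.numeric(edges$effect))
  if (nrow(edges) > 0) {
    if (!all(c(edges$parent, edges$child) %in% genes))
      stop("edge endpoints must be listed in genes")
    if (any(edges$effect == 0)) stop("effect sizes must be nonzero")
    g <- igraph::graph_from_data_frame(edges[, c("parent", "child")],
                                       vertices = genes)
    if (!igraph::is_dag(g)) stop("planted network must be acyclic")
  }
  structure(list(genes = genes, edges = edges, noiseSd = noiseSd),
            class = "plantedNetwork")
}

#' A simple regulatory chain g1 -> g2 -> ... -> gn
#'
#' @param n chain length (>= 2).
#' @param effect per-edge effect size; default 1.
#' @param noiseSd child noise; default 0.1.
#' @return a `plantedNetwork`.
#' @export
plantedChain <- function(n, effect = 1, noiseSd = 0.1) {
  stopifnot(n >= 2)
  genes <- paste0("g", seq_len(n))
  plantedNetwork(genes,
                 data.frame(parent = genes[-n], child = genes[-1],
                            effect = effect),
                 noiseSd = noiseSd)
}

#' A random planted directed acyclic network
#'
#' Genes are placed in a fixed topological order and `nEdges` forward edges
#' are sampled uniformly without replacement; effect magnitudes are uniform
#' in `effectRange` with random sign.
#'
#' @param nGenes number of genes.
#' @param nEdges number of true directed edges.
#' @param noiseSd child noise standard deviation; default 0.2.
#' @param effectRange magnitude range of effect sizes; default c(0.75, 1.25).
#' @param seed RNG seed.
#' @return a `plantedNetwork`.
#' @export
randomPlantedNetwork <- function(nGenes, nEdges, noiseSd = 0.2,
                                 effectRange = c(0.75, 1.25), seed = 1) {
  maxEdges <- nGenes * (nGenes - 1) / 2
  if (nEdges > maxEdges) stop("too many edges for an acyclic network")
  withSeed(seed, {
    genes <- paste0("g", seq_len(nGenes))
    pairs <- which(upper.tri(matrix(0, nGenes, nGenes)), arr.ind = TRUE)
    pick <- pairs[sample.int(nrow(pairs), nEdges), , drop = FALSE]
    effects <- runif(nEdges, effectRange[1], effectRange[2]) *
      sample(c(-1, 1), nEdges, replace = TRUE)
    plantedNetwork(genes,
                   data.frame(parent = genes[pick[, 1]],
                              child = genes[pick[, 2]],
                              effect = effects),
                   noiseSd = noiseSd)
  })
}

#' Simulate expression data from a planted network
#'
#' Root genes (no parents) are standard normal across samples; each child
#' gene is the effect-weighted sum of its parents plus Gaussian noise with
#' the network's `noiseSd`. Deterministic under `seed`.
#'
#' @param net a [plantedNetwork()].
#' @param nSamples number of samples (>= 2).
#' @param seed RNG seed.
#' @return list with `X` (samples x genes matrix) and `truth` (data.frame of
#'   the true directed edges: `source`, `target`, `effect`).
#' @examples
#' sim <- simulateExpression(plantedChain(3, noiseSd = 0), 5, seed = 1)
#' all.equal(sim$X[, "g2"], sim$X[, "g1"], check.attributes = FALSE)
#' @export
simulateExpression <- function(net, nSamples, seed = 1) {
  stopifnot(inherits(net, "plantedNetwork"), nSamples >= 2)
  genes <- net$genes
  edges <- net$edges
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges[, c("parent", "child")] else
      data.frame(parent = character(), child = character()),
    vertices = genes)
  order <- names(igraph::topo_sort(g))
  withSeed(seed, {
    X <- matrix(0, nSamples, length(genes),
                dimnames = list(paste0("s", seq_len(nSamples)), genes))
    for (gene in order) {
      parents <- edges[edges$child == gene, , drop = FALSE]
      if (nrow(parents) == 0) {
        X[, gene] <- rnorm(nSamples)
      } else {
        X[, gene] <- X[, parents$parent, drop = FALSE] %*% parents$effect +
          rnorm(nSamples, sd = net$noiseSd)
      }
    }
    list(X = X,
         truth = data.frame(source = edges$parent, target = edges$child,
                            effect = edges$effect))
  })
}

#' Generate term-structured GO annotations
#'
#' Creates synthetic terms of the requested sizes. With
#' `overlapFraction = 0` terms draw disjoint gene sets; otherwise roughly
#' that fraction of each term's members is re-drawn from genes already
#' annotated to earlier terms, creating inter-term overlap. Deterministic
#' under `seed`.
#'
#' @param genes character vector of available gene ids.
#' @param termSizes integer vector of term sizes (each >= 2).
#' @param overlapFraction fraction of each term (after the first) drawn from
#'   previously annotated genes; default 0.
#' @param seed RNG seed.
#' @return data.frame with columns `gene`, `term`.
#' @export
generateGOAnnotations <- function(genes, termSizes, overlapFraction = 0,
                                  seed = 1) {
  stopifnot(all(termSizes >= 2), overlapFraction >= 0, overlapFraction <= 1)
  if (any(termSizes > length(genes)))
    stop("term size exceeds the number of genes")
  withSeed(seed, {
    unused <- genes
    used <- character()
    records <- vector("list", length(termSizes))
    for (k in seq_along(termSizes)) {
      size <- termSizes[k]
      nOverlap <- min(round(overlapFraction * size), length(used))
      nFresh <- size - nOverlap
      if (nFresh > length(unused))
        stop("not enough unannotated genes for disjoint term of size ", size)
      fresh <- if (nFresh > 0) sample(unused, nFresh) else character()
      shared <- if (nOverlap > 0) sample(used, nOverlap) else character()
      members <- c(fresh, shared)
      unused <- setdiff(unused, fresh)
      used <- union(used, members)
      records[[k]] <- data.frame(gene = members,
                                 term = sprintf("GO:SYN%04d", k))
    }
    do.call(rbind, records)
  })
}

#' Generate a genotype panel with planted eQTL effects
#'
#' SNP dosages are drawn binomial(2, maf) with per-SNP minor-allele
#' frequency uniform in `mafRange`; the expression target is the
#' effect-weighted sum of the causal SNPs' dosages plus standard normal
#' noise. Missingness is applied after the target is formed, flagged as
#' `NA`.
#'
#' @param nSnps number of SNPs.
#' @param nSamples number of samples.
#' @param causal data.frame with columns `snp` (index) and `effect`, or
#'   NULL for a null panel.
#' @param mafRange range of minor-allele frequencies; default c(0.05, 0.5).
#' @param missingRate fraction of entries set missing; default 0.
#' @param seed RNG seed.
#' @return list with `genotypes` (SNPs x samples dosage matrix, NA =
#'   missing), `y` (length-`nSamples` expression target), and `maf`.
#' @export
generateEQTLDataset <- function(nSnps, nSamples, causal = NULL,
                                mafRange = c(0.05, 0.5), missingRate = 0,
                                seed = 1) {
  if (!is.null(causal) && nrow(causal) > 0 && any(causal$snp > nSnps))
    stop("causal SNP index exceeds nSnps")
  withSeed(seed, {
    maf <- runif(nSnps, mafRange[1], mafRange[2])
    G <- matrix(rbinom(nSnps * nSamples, 2, rep(maf, nSamples)),
                nrow = nSnps, ncol = nSamples,
                dimnames = list(sprintf("snp%05d", seq_len(nSnps)),
                                paste0("s", seq_len(nSamples))))
    y <- rnorm(nSamples)
    if (!is.null(causal) && nrow(causal) > 0)
      y <- y + as.numeric(crossprod(G[causal$snp, , drop = FALSE],
                                    causal$effect))
    if (missingRate > 0) {
      drop <- runif(length(G)) < missingRate
      G[drop] <- NA
    }
    list(genotypes = G, y = stats::setNames(y, colnames(G)), maf = maf)
  })
}

#' Filter a SNP dosage matrix on MAF and missingness
#'
#' Keeps SNPs whose minor allele frequency (computed from non-missing
#' dosages) is strictly greater than `mafMin` and whose missing fraction is
#' strictly less than `maxMissing`; remaining missing entries are imputed
#' to the SNP's rounded mean dosage. These are the standard biallelic-panel
#' filters (MAF > 0.01, < 10% missing) applied directly to the dosage
#' matrix.
#'
#' @param genotypes SNPs x samples dosage matrix in \{0, 1, 2, NA\}.
#' @param mafMin strict lower bound on MAF; default 0.01.
#' @param maxMissing strict upper bound on the missing fraction;
#'   default 0.10.
#' @return the filtered (and imputed) SNPs x samples matrix.
#' @export
filterGenotypes <- function(genotypes, mafMin = 0.01, maxMissing = 0.10) {
  if (!is.matrix(genotypes)) stop("genotypes must be a matrix")
  ok <- genotypes %in% c(0, 1, 2) | is.na(genotypes)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  missFrac <- rowMeans(is.na(genotypes))
  p <- rowMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # all-missing SNP
  keep <- maf > mafMin & missFrac < maxMissing
  if (!any(keep)) {
    warning("no SNPs pass the MAF/missingness filters")
    return(genotypes[keep, , drop = FALSE])
  }
  out <- genotypes[keep, , drop = FALSE]
  na <- which(is.na(out), arr.ind = TRUE)
  if (nrow(na) > 0) {
    fill <- round(rowMeans(out, na.rm = TRUE))
    out[na] <- fill[na[, "row"]]
  }
  out
}
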