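# Independent oracles and small data builders shared across the suite.

# Exhaustive best-split search for regression: every feature, every midpoint
# between consecutive distinct sorted values; impurity decrease is the drop
# in within-node sum of squared deviations. First maximum wins, i.e. lowest
# feature index then lowest threshold -- the package's declared tie-break.
bruteBestSplit <- function(X, y) {
  best <- NULL
  n <- length(y)
  for (f in seq_len(ncol(X))) {
    o <- order(X[, f])
    xs <- X[o, f]
    cy <- cumsum(y[o])
    S <- cy[n]
    for (i in seq_len(n - 1)) {
      if (xs[i + 1] <= xs[i]) next
      mid <- xs[i] + (xs[i + 1] - xs[i]) / 2
      if (mid <= xs[i] || mid >= xs[i + 1]) next
      dec <- cy[i] * cy[i] / i + (S - cy[i]) * (S - cy[i]) / (n - i) - S * S / n
      if (dec > 0 && (is.null(best) || dec > best$decrease))
        best <- list(feature = f, threshold = mid, decrease = dec)
    }
  }
  best
}

# Rank-based AUROC (Mann-Whitney): probability a true edge outranks a
# non-edge.
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  np <- sum(labels)
  nn <- sum(!labels)
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

# Ordered-pair scores and true-edge labels from a PEN and a truth edge list.
penEdgeScores <- function(pen, truth) {
  a <- adjacency(pen)
  genes <- rownames(a)
  idx <- which(row(a) != col(a))
  scores <- a[idx]
  key <- paste(genes[row(a)[idx]], genes[col(a)[idx]])
  labels <- key %in% paste(truth$source, truth$target)
  list(scores = scores, labels = labels)
}

# Deterministic dosage panel with exact per-SNP alternate-allele
# frequencies over `nSamples` samples (dosage counts chosen to hit 2*n*p
# alternate alleles using only 0/1 dosages).
panelWithMAFs <- function(mafs, nSamples = 100) {
  G <- t(vapply(mafs, function(p) {
    nAlt <- round(2 * nSamples * p)
    stopifnot(nAlt <= nSamples)  # representable with 0/1 dosages
    c(rep(1, nAlt), rep(0, nSamples - nAlt))
  }, numeric(nSamples)))
  rownames(G) <- sprintf("snp%d", seq_along(mafs))
  colnames(G) <- sprintf("s%d", seq_len(nSamples))
  G
}

# Regression data with k planted linear parents among noise features.
plantedSignalData <- function(nSamples, kSignal, nNoise, noiseSd, seed) {
  set.seed(seed)
  p <- kSignal + nNoise
  X <- matrix(rnorm(nSamples * p), nSamples, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- rowSums(X[, seq_len(kSignal), drop = FALSE]) +
    rnorm(nSamples, sd = noiseSd)
  list(X = X, y = y, signal = paste0("f", seq_len(kSignal)))
}

# Minimal VCF 4.2 text with 5 records, 2 of them multiallelic.
toyVCF <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\t.\tC\tT,G\t.\tPASS\t.\tGT\t0/1\t0/0\t0/2",
    "1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t0|1\t1|0\t./.",
    "2\t100\t.\tT\tC,A\t.\tPASS\t.\tGT\t1/1\t0/0\t0/1",
    "2\t200\t.\tA\tC\t.\tPASS\t.\tGT\t1/1\t.\t0/0"
  ), path)
  path
}
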