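test_that("GO network weights follow the 1/(n-1) shared-term law", {
  # one 3-gene term: three edges at weight 1/2
  go3 <- buildGONetwork(data.frame(gene = c("A", "B", "C"), term = "T1"))
  expect_equal(nrow(goEdges(go3)), 3)
  expect_true(all(goEdges(go3)$weight == 0.5))

  # a pair sharing terms of sizes 3 and 11 keeps max(1/2, 1/10)
  ann <- rbind(data.frame(gene = c("A", "B", "C"), term = "T3"),
               data.frame(gene = c("A", "B", paste0("x", 1:9)), term = "T11"))
  go <- buildGONetwork(ann)
  e <- goEdges(go)
  expect_equal(e$weight[e$geneA == "A" & e$geneB == "B"], 0.5)
  expect_equal(e$weight[e$geneA == "A" & e$geneB == "x1"], 0.1)

  # strict < cutoff: a term with exactly maxTermSize genes contributes nothing
  big <- data.frame(gene = paste0("g", 1:50), term = "BIG")
  expect_equal(nrow(goEdges(buildGONetwork(big, maxTermSize = 50))), 0)
  expect_equal(nrow(goEdges(buildGONetwork(big, maxTermSize = 51))),
               choose(50, 2))

  # single-gene terms and duplicate records contribute nothing extra
  dup <- rbind(go3 <- data.frame(gene = c("A", "B", "A"), term = "T1"),
               data.frame(gene = "Z", term = "SOLO"))
  expect_equal(nrow(goEdges(buildGONetwork(dup))), 1)
})

test_that("intersect scores sum shared-pair GO weights once per pair", {
  go <- new("GONetwork",
            edges = data.frame(geneA = c("D", "E"), geneB = c("E", "F"),
                               weight = c(0.05, 0.0214)),
            nodes = c("D", "E", "F"), maxTermSize = 1000L)

  # pairs D-E and F-E intersect; A-B is absent from GO
  pen <- data.frame(source = c("D", "F", "A"), target = c("E", "E", "B"),
                    weight = 1)
  expect_equal(intersectScore(pen, go), 0.0714)

  # disjoint node sets score zero
  far <- data.frame(source = "P", target = "Q", weight = 1)
  expect_equal(intersectScore(far, go), 0)

  # both directions of a pair count once
  both <- data.frame(source = c("D", "E"), target = c("E", "D"), weight = 1)
  expect_equal(intersectScore(both, go), 0.05)
})

test_that("the permutation null is seeded, nonnegative and label-invariant", {
  ann <- generateGOAnnotations(paste0("g", 1:30), c(4, 6, 8), seed = 2)
  go <- buildGONetwork(ann)

  pen <- data.frame(source = c("g1", "g2", "g5", "g9"),
                    target = c("g2", "g3", "g7", "g1"), weight = 1)
  n1 <- nullDistribution(pen, go, nPermutations = 100, seed = 42)
  n2 <- nullDistribution(pen, go, nPermutations = 100, seed = 42)
  expect_identical(n1, n2)
  expect_length(n1, 100)
  expect_true(all(n1 >= 0))

  # complete graph on its node set: relabeling cannot change the edge set
  nodes <- c("g1", "g2", "g3", "g4")
  cp <- t(combn(nodes, 2))
  complete <- data.frame(source = cp[, 1], target = cp[, 2], weight = 1)
  obs <- intersectScore(complete, go)
  nc <- nullDistribution(complete, go, nPermutations = 50, seed = 3)
  expect_true(all(nc == obs))

  expect_error(nullDistribution(pen, go, nPermutations = 0), "nPermutations")
})

test_that("intersect scores are bounded and invariant under joint relabeling", {
  set.seed(9)
  genes <- paste0("g", 1:40)
  ann <- generateGOAnnotations(genes, c(5, 10, 15), overlapFraction = 0.3,
                               seed = 4)
  go <- buildGONetwork(ann)
  pen <- data.frame(source = sample(genes, 30, replace = TRUE),
                    target = sample(genes, 30, replace = TRUE), weight = 1)
  pen <- pen[pen$source != pen$target, ]
  s <- intersectScore(pen, go)
  expect_gte(s, 0)
  expect_lte(s, totalWeight(go))

  # apply one bijection to both networks: score unchanged
  relab <- stats::setNames(sample(genes), genes)
  pen2 <- data.frame(source = relab[pen$source], target = relab[pen$target],
                     weight = 1)
  e2 <- goEdges(go)
  ann2 <- data.frame(gene = relab[ann$gene], term = ann$term)
  go2 <- buildGONetwork(ann2)
  expect_equal(intersectScore(pen2, go2), s)
})

test_that("t-statistics standardize against vector or moment nulls", {
  expect_equal(tStatistic(10, nullScores = c(8, 10, 12)), 0)
  expect_equal(tStatistic(5, nullMean = 3, nullSd = 2), 1)
  nulls <- c(1, 2, 3, 4)
  expect_equal(tStatistic(7, nulls), (7 - 2.5) / sd(nulls))
  expect_error(tStatistic(1, nullScores = rep(2, 5)), "degenerate")
  expect_error(tStatistic(1, nullScores = 3), "length")
  expect_error(tStatistic(1), "provide")
})

test_that("scoreAgainstGO assembles a consistent report with QQ hook", {
  ann <- generateGOAnnotations(paste0("g", 1:25), c(5, 5, 6), seed = 5)
  go <- buildGONetwork(ann)
  e <- goEdges(go)
  pen <- data.frame(source = e$geneA[1:6], target = e$geneB[1:6], weight = 1)
  rep <- scoreAgainstGO(pen, go, nPermutations = 200, seed = 6)
  expect_s4_class(rep, "ScoreReport")
  expect_equal(rep@intersectScore, intersectScore(pen, go))
  expect_equal(rep@tStatistic,
               (rep@intersectScore - rep@nullMean) / rep@nullSd)
  expect_length(nullScores(rep), 200)

  pdf(NULL)
  on.exit(dev.off())
  q <- nullQQPlot(rep)
  expect_length(q$x, 200)
})

test_that("the co-expression comparator ranks pairs by absolute correlation", {
  set.seed(10)
  X <- matrix(rnorm(300), 30, 10, dimnames = list(NULL, paste0("g", 1:10)))
  X[, 2] <- 2 * X[, 1]            # r = +1
  X[, 4] <- -X[, 3]               # r = -1, included under |r|
  top <- coexpressionNetwork(X, 2 / choose(10, 2))
  expect_setequal(paste(top$source, top$target), c("g1 g2", "g3 g4"))
  expect_equal(abs(top$weight), c(1, 1))
  expect_lt(top$weight[top$source == "g3"], 0)  # signed weight preserved

  # all pairs evaluated at topFraction = 1
  expect_equal(nrow(coexpressionNetwork(X, 1)), choose(10, 2))

  # constant genes are excluded with a warning
  Xc <- X
  Xc[, 5] <- 7
  expect_warning(all5 <- coexpressionNetwork(Xc, 1), "g5")
  expect_equal(nrow(all5), choose(9, 2))
})
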