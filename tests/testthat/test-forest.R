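test_that("weighted candidate sampling matches its analytic marginals", {
  # weights (3, 1), one draw: P(feature 1) = 3/4
  draws <- vapply(seq_len(10000),
                  function(i) sampleCandidateFeatures(c(3, 1), 1, seed = i),
                  integer(1))
  expect_equal(mean(draws == 1), 0.75, tolerance = 0.02 / 0.75)

  # mtry = p returns the full feature set; zero-weight features never appear
  expect_setequal(sampleCandidateFeatures(c(1, 1, 1, 1), 4, seed = 3), 1:4)
  for (s in 1:50) {
    expect_identical(sampleCandidateFeatures(c(0, 1, 0), 1, seed = s), 2L)
    got <- sampleCandidateFeatures(c(0.5, 0, 2, 0, 1), 3, seed = s)
    expect_false(any(got %in% c(2, 4)))
    expect_identical(anyDuplicated(got), 0L)
  }

  # more candidates requested than positive weights -> only the positive ones
  expect_setequal(sampleCandidateFeatures(c(0, 2, 0, 1), 4, seed = 1), c(2, 4))

  expect_error(sampleCandidateFeatures(c(0, 0), 1), "degenerate")
  expect_error(sampleCandidateFeatures(c(1, 1), 0), "mtry")
})

test_that("bestSplit reproduces hand-derived splits and the leaf signal", {
  X <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(NULL, "f1"))

  # constant target: zero impurity, leaf
  expect_null(bestSplit(X, c(5, 5, 5, 5)))

  # y = (0,0,10,10): SS(parent) = 100, both children pure
  sp <- bestSplit(X, c(0, 0, 10, 10))
  expect_equal(sp$feature, 1)
  expect_equal(sp$threshold, 2.5)
  expect_equal(sp$decrease, 100)

  # classification: parent Gini 0.5, both children pure
  spc <- bestSplit(matrix(c(0, 0, 1, 1), 4, 1, dimnames = list(NULL, "f1")),
                   factor(c("A", "A", "B", "B")))
  expect_equal(spc$threshold, 0.5)
  expect_equal(spc$decrease, 0.5)
})

test_that("bestSplit agrees with the exhaustive brute-force oracle", {
  for (i in 1:40) {
    set.seed(i)
    n <- sample(10:50, 1)
    p <- sample(2:5, 1)
    X <- matrix(round(runif(n * p), sample(1:3, 1)), n, p,
                dimnames = list(NULL, paste0("f", 1:p)))
    y <- round(rnorm(n), 2)
    got <- bestSplit(X, y)
    want <- bruteBestSplit(X, y)
    expect_equal(got, want, info = paste("instance", i))
  }
})

test_that("growTree is deterministic and honors the leaf rules", {
  set.seed(2)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))

  # constant target -> single-leaf tree predicting the constant
  t0 <- growTree(X, rep(7, 50), treeSeed = 11)
  expect_length(t0@trees[[1]]$split_var, 1)
  expect_true(is.na(t0@trees[[1]]$split_var[1]))
  expect_equal(predict(t0, X), rep(7, 50))

  # identical inputs -> structurally identical trees
  y <- X[, 1] + rnorm(50, sd = 0.3)
  t1 <- growTree(X, y, treeSeed = 5)
  t2 <- growTree(X, y, treeSeed = 5)
  expect_identical(t1@trees, t2@trees)

  # y = x1 exactly, all features candidates -> root splits on feature 1
  t3 <- growTree(X[, 1:2], X[, 1], mtry = 2, treeSeed = 9)
  expect_equal(t3@trees[[1]]$split_var[1], 1)
})

test_that("subforest plans are independent of the worker partition", {
  p1 <- planSubforests(10, nWorkers = 1, masterSeed = 7)
  p5 <- planSubforests(10, nWorkers = 5, masterSeed = 7)
  expect_identical(p1$seed, p5$seed)
  expect_identical(anyDuplicated(p1$seed), 0L)
  expect_equal(sort(unique(p5$worker)), 1:5)
  expect_true(all(diff(p5$worker) >= 0))  # contiguous chunks
  expect_error(planSubforests(0, 1, 1), "nTrees")

  set.seed(3)
  X <- matrix(rnorm(1000), 100, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- X[, 2] + rnorm(100, sd = 0.2)
  imp <- lapply(c(1, 2, 4), function(w)
    impurityImportance(growForest(X, y, nTrees = 40, masterSeed = 13,
                                  nWorkers = w)))
  expect_identical(imp[[1]], imp[[2]])
  expect_identical(imp[[1]], imp[[3]])

  f1 <- growForest(X, y, nTrees = 1, masterSeed = 21)
  t1 <- growTree(X, y, treeSeed = planSubforests(1, 1, 21)$seed[1])
  expect_identical(f1@trees, t1@trees)
})

test_that("zero-weight features never appear as split features", {
  set.seed(4)
  X <- matrix(rnorm(1500), 100, 15, dimnames = list(NULL, paste0("f", 1:15)))
  y <- X[, 1] + X[, 8] + rnorm(100, sd = 0.2)
  w <- rep(1, 15)
  w[c(1, 5, 12)] <- 0
  f <- growForest(X, y, weights = w, nTrees = 60, masterSeed = 2)
  used <- unlist(lapply(f@trees, function(t) t$split_var))
  expect_false(any(used %in% c(1, 5, 12)))
  expect_true(all(impurityImportance(f)[c(1, 5, 12)] == 0))
})

test_that("impurity importance conserves per-node decreases and symmetry", {
  set.seed(5)
  X <- matrix(rnorm(1200), 80, 15, dimnames = list(NULL, paste0("f", 1:15)))
  y <- 2 * X[, 3] + rnorm(80, sd = 0.2)
  f <- growForest(X, y, nTrees = 50, masterSeed = 31)

  # conservation: sum of scores == total decrease over all trees / nTrees
  expect_equal(sum(impurityImportance(f)),
               irfnet:::totalDecreaseByTraversal(f) / f@nTrees)
  expect_true(all(impurityImportance(f) >= 0))

  # features never split on score exactly zero
  used <- sort(unique(unlist(lapply(f@trees, function(t)
    t$split_var[!is.na(t$split_var)]))))
  unused <- setdiff(seq_len(15), used)
  expect_true(all(impurityImportance(f)[unused] == 0))

  # constant y -> single-leaf trees -> all-zero importance
  f0 <- growForest(X, rep(1, 80), nTrees = 10, masterSeed = 1)
  expect_true(all(impurityImportance(f0) == 0))

  # planted signal dominates pure noise
  set.seed(6)
  Xs <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("sig", "noise")))
  ys <- Xs[, 1]
  fs <- growForest(Xs, ys, nTrees = 200, mtry = 1, masterSeed = 3)
  imp <- impurityImportance(fs)
  expect_gt(imp["sig"], imp["noise"])

  # permutation symmetry, in the regime where a tree is a pure function of
  # the sample set (mtry = p, bootstrap off, continuous data): the fitted
  # partitions are invariant under feature relabeling, so training
  # predictions, the multiset of node decreases, and the dominant feature
  # all map across; per-feature scores permute except at exact impurity
  # ties, which break to the lowest feature index
  set.seed(7)
  Xp <- matrix(rnorm(900), 60, 15, dimnames = list(NULL, paste0("f", 1:15)))
  yp <- 3 * Xp[, 4] + rnorm(60, sd = 0.3)
  perm <- sample(15)
  fa <- growTree(Xp, yp, mtry = 15, treeSeed = 8, bootstrap = FALSE)
  fb <- growTree(Xp[, perm], yp, mtry = 15, treeSeed = 8, bootstrap = FALSE)
  expect_equal(predict(fb, Xp[, perm]), predict(fa, Xp))
  expect_equal(sum(impurityImportance(fb)), sum(impurityImportance(fa)))
  expect_identical(names(which.max(impurityImportance(fb))),
                   names(which.max(impurityImportance(fa))))
})

test_that("forest prediction aggregates trees correctly", {
  set.seed(8)
  X <- matrix(runif(400), 200, 2, dimnames = list(NULL, c("a", "b")))

  # constant training target -> constant predictions
  fc <- growForest(X, rep(3.5, 200), nTrees = 20, masterSeed = 1)
  expect_equal(predict(fc, X), rep(3.5, 200))

  # y = a on a dense grid: training R^2 > 0.9
  y <- X[, 1]
  f <- growForest(X, y, nTrees = 200, masterSeed = 2)
  expect_gt(cor(predict(f, X), y)^2, 0.9)

  # column mismatch is a shape error
  expect_error(predict(f, X[, 1, drop = FALSE]), "column|feature")

  # classification: majority vote recovers a separable labeling
  lab <- factor(ifelse(X[, 1] > 0.5, "hi", "lo"))
  fcl <- growForest(X, lab, nTrees = 50, masterSeed = 3)
  expect_equal(as.character(predict(fcl, X)), as.character(lab))
})
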