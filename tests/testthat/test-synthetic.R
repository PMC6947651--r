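test_that("expression simulation follows the planted linear model", {
  # zero noise, single edge A -> B with effect 2: column B is exactly 2A
  net <- plantedNetwork(c("A", "B"),
                        data.frame(parent = "A", child = "B", effect = 2),
                        noiseSd = 0)
  sim <- simulateExpression(net, 50, seed = 1)
  expect_equal(sim$X[, "B"], 2 * sim$X[, "A"])
  expect_identical(sim$truth$source, "A")

  # pure function of (parameters, seed)
  sim2 <- simulateExpression(net, 50, seed = 1)
  expect_identical(sim$X, sim2$X)
  sim3 <- simulateExpression(net, 50, seed = 2)
  expect_false(identical(sim$X, sim3$X))

  # root genes are approximately standard normal
  big <- simulateExpression(plantedChain(3), 2000, seed = 4)
  expect_equal(sd(big$X[, "g1"]), 1, tolerance = 0.1)
  expect_equal(mean(big$X[, "g1"]), 0, tolerance = 0.1)

  # cyclic specifications are rejected
  expect_error(plantedNetwork(c("A", "B"),
                              data.frame(parent = c("A", "B"),
                                         child = c("B", "A"),
                                         effect = 1)),
               "acyclic")
  expect_error(plantedNetwork("A", data.frame(parent = "A", child = "A",
                                              effect = 0)),
               "nonzero|acyclic")
})

test_that("random planted networks have the requested size and are acyclic", {
  net <- randomPlantedNetwork(20, 15, seed = 3)
  expect_length(net$genes, 20)
  expect_equal(nrow(net$edges), 15)
  expect_true(all(net$edges$effect != 0))
  g <- igraph::graph_from_data_frame(net$edges[, 1:2], vertices = net$genes)
  expect_true(igraph::is_dag(g))
  expect_identical(net$edges, randomPlantedNetwork(20, 15, seed = 3)$edges)
  expect_error(randomPlantedNetwork(4, 10), "acyclic|too many")
})

test_that("synthetic GO terms have the requested sizes and overlap", {
  genes <- paste0("g", 1:60)

  # one 3-gene term forces a 3-edge network at weight 1/2
  a3 <- generateGOAnnotations(genes, 3, seed = 1)
  go3 <- buildGONetwork(a3)
  expect_equal(nrow(goEdges(go3)), 3)
  expect_true(all(goEdges(go3)$weight == 0.5))

  # disjoint terms: total records = sum of term sizes
  sizes <- c(5, 8, 12)
  a <- generateGOAnnotations(genes, sizes, overlapFraction = 0, seed = 2)
  expect_equal(nrow(a), sum(sizes))
  expect_identical(anyDuplicated(a$gene), 0L)  # disjoint membership

  # overlapping terms reuse annotated genes
  ov <- generateGOAnnotations(genes, c(10, 10), overlapFraction = 0.5,
                              seed = 3)
  expect_gt(sum(duplicated(ov$gene)), 0)

  # a term at the default cutoff yields an empty network
  many <- paste0("G", seq_len(1000))
  a1000 <- generateGOAnnotations(many, 1000, seed = 4)
  expect_equal(nrow(goEdges(buildGONetwork(a1000))), 0)

  expect_error(generateGOAnnotations(genes, 61), "term size")
})

test_that("eQTL panels have the declared shapes and null behavior", {
  sim <- generateEQTLDataset(100, 40, causal = data.frame(snp = 1, effect = 1),
                             missingRate = 0.05, seed = 1)
  expect_identical(dim(sim$genotypes), c(100L, 40L))
  expect_length(sim$y, 40)
  expect_true(all(sim$genotypes %in% c(0, 1, 2) | is.na(sim$genotypes)))
  expect_gt(sum(is.na(sim$genotypes)), 0)

  # null panel: with no causal effects, no SNP correlates with y beyond a
  # Bonferroni bound at overall level 0.01 in at least 95% of seeds
  nSnps <- 100
  nSamp <- 200
  rBound <- tanh(qnorm(1 - 0.005 / nSnps) / sqrt(nSamp - 3))
  ok <- vapply(1:100, function(s) {
    null <- generateEQTLDataset(nSnps, nSamp, causal = NULL, seed = 300 + s)
    rmax <- max(abs(cor(t(null$genotypes), null$y)))
    rmax < rBound
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("causal SNPs are recovered by iRF importance across seeds", {
  hits <- vapply(1:10, function(s) {
    sim <- generateEQTLDataset(400, 300,
                               causal = data.frame(snp = c(5, 50, 200),
                                                   effect = 1),
                               seed = 400 + s)
    res <- runIRF(t(sim$genotypes), sim$y, nIterations = 3, nTrees = 150,
                  masterSeed = 400 + s)
    top3 <- names(sort(res@finalImportance, decreasing = TRUE))[1:3]
    setequal(top3, rownames(sim$genotypes)[c(5, 50, 200)])
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("genotype filtering applies strict MAF and missingness bounds", {
  G <- panelWithMAFs(c(0, 0.005, 0.02, 0.3, 0.5), nSamples = 100)

  # MAFs {0, 0.005} fail MAF > 0.01; {0.02, 0.3, 0.5} survive
  kept <- filterGenotypes(G)
  expect_equal(nrow(kept), 3)
  expect_setequal(rownames(kept), c("snp3", "snp4", "snp5"))

  # exactly 10% missing is removed (strict < 10%), 9% is kept
  Gm <- panelWithMAFs(c(0.3, 0.3), nSamples = 100)
  Gm[1, 1:10] <- NA
  Gm[2, 1:9] <- NA
  keptm <- filterGenotypes(Gm)
  expect_identical(rownames(keptm), "snp2")
  expect_false(anyNA(keptm))  # residual missingness imputed

  # imputation fills with the rounded mean dosage
  Gi <- rbind(snpA = c(2, 2, 2, 2, NA, rep(c(0, 2), 10)))
  colnames(Gi) <- paste0("s", 1:25)
  expect_equal(unname(filterGenotypes(Gi)[1, 5]),
               round(mean(Gi[1, -5])))

  expect_warning(none <- filterGenotypes(panelWithMAFs(c(0, 0.005))),
                 "no SNPs")
  expect_equal(nrow(none), 0)
})
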