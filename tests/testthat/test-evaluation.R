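# Exhaustive pairwise-counting oracle for AUROC (ties count one half).
aurocOracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

pearsonOracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

test_that("auroc equals the pairwise-counting oracle, ties included", {
  expect_identical(auroc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_identical(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_identical(auroc(c(0.9, 0.8, 0.1, 0.2), c(1, 0, 0, 1)), 0.75)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
  expect_error(auroc(1:3, c(1, 0)), "length")

  set.seed(123)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    # coarse grid of score values forces plenty of ties
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(auroc(scores, labels), aurocOracle(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("pearson and spearman match direct-formula oracles", {
  x <- c(-2, -1, 0, 1, 2)
  expect_equal(pearsonCor(x, x), 1.0)
  expect_equal(spearmanCor(x, -x), -1.0)
  # monotone nonlinear map: perfect rank correlation, imperfect linear
  expect_equal(spearmanCor(x, x^3), 1.0)
  expect_lt(pearsonCor(x, x^3), 1)
  expect_error(pearsonCor(c(1, 1, 1), 1:3), "zero variance")
  expect_error(spearmanCor(1:2, 1:2), "at least 3")

  set.seed(42)
  for (i in 1:100) {
    n <- sample(5:80, 1)
    a <- round(rnorm(n), 1)  # rounding creates ties
    b <- round(a + rnorm(n), 1)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(pearsonCor(a, b), pearsonOracle(a, b), tolerance = 1e-12)
    expect_equal(spearmanCor(a, b),
                 pearsonOracle(rank(a), rank(b)), tolerance = 1e-12)
  }
})

test_that("kfoldCV partitions rows disjointly and reports per fold", {
  set.seed(3)
  n <- 100
  x <- matrix(runif(n * 4), n, 4)
  y <- as.numeric(x[, 1] > stats::median(x[, 1]))  # exactly 50/50
  ds <- new("TowerDataset", features = x, labels = y,
            keys = data.frame(idA = sprintf("a%03d", 1:n),
                              idB = sprintf("b%03d", 1:n)),
            keySets = c("A", "B"), towerDims = c(A = 2L, B = 2L),
            task = "classification")
  rep <- kfoldCV(ds, predictorSpec("linear", seed = 1), folds = 5, seed = 9)
  expect_identical(nrow(perUnit(rep)), 5L)
  expect_equal(sum(perUnit(rep)$n), n)
  expect_true(all(perUnit(rep)$n == 20))
  expect_gt(metrics(rep)$auroc, 0.9)
  # determinism
  rep2 <- kfoldCV(ds, predictorSpec("linear", seed = 1), folds = 5, seed = 9)
  expect_identical(metrics(rep)$auroc, metrics(rep2)$auroc)
  expect_error(kfoldCV(ds, predictorSpec("linear"), folds = 1), "folds")
})

test_that("looNodes never leaks the held-out node into training", {
  spec <- smallSpec()
  sim <- simulateMultipartite(spec)
  syn <- simulateSynergyTriplets(spec, 400)
  embC <- toyEmbedding("Cells", nodeIds(sim$graph, "Cells"), 3, seed = 5)
  embD <- toyEmbedding("Drugs", nodeIds(sim$graph, "Drugs"), 3, seed = 6)
  ds <- assembleTripletDataset(embC, embD, syn$triplets,
                               task = "classification")
  rep <- looNodes(ds, 1L, predictorSpec("boosted", list(nrounds = 30),
                                        seed = 2))
  cells <- unique(rowKeys(ds)$cell)
  expect_identical(sort(perUnit(rep)$node), sort(cells))
  # test sets are disjoint and cover all rows
  expect_identical(sum(perUnit(rep)$n), nrow(features(ds)))
  # leakage check by construction: rows of each node only in its test set
  for (v in cells[1:3]) {
    test <- rowKeys(ds)$cell == v
    expect_identical(sum(perUnit(rep)$n[perUnit(rep)$node == v]), sum(test))
  }
  expect_true(metrics(rep)$macro_auroc >= 0 && metrics(rep)$macro_auroc <= 1)
})

test_that("looNodes treats drug towers jointly when leaving a drug out", {
  spec <- smallSpec()
  syn <- simulateSynergyTriplets(spec, 400)
  sim <- simulateMultipartite(spec)
  embC <- toyEmbedding("Cells", nodeIds(sim$graph, "Cells"), 3, seed = 5)
  embD <- toyEmbedding("Drugs", nodeIds(sim$graph, "Drugs"), 3, seed = 6)
  ds <- assembleTripletDataset(embC, embD, syn$triplets,
                               task = "classification")
  drug <- rowKeys(ds)$drugA[1]
  rep <- looNodes(ds, 2L, predictorSpec("boosted", list(nrounds = 10),
                                        seed = 2), nodes = drug)
  # rows with the drug in EITHER drug tower are excluded from training,
  # so the test count equals rows with it at position 2 only
  expect_identical(perUnit(rep)$n,
                   sum(rowKeys(ds)$drugA == drug))
})

test_that("gridSearch picks the sane setting and is deterministic", {
  set.seed(8)
  n <- 150
  x <- matrix(runif(n * 4), n, 4)
  y <- as.numeric(x[, 1] + x[, 3] > 1)
  ds <- new("TowerDataset", features = x, labels = y,
            keys = data.frame(idA = sprintf("a%03d", 1:n),
                              idB = sprintf("b%03d", 1:n)),
            keySets = c("A", "B"), towerDims = c(A = 2L, B = 2L),
            task = "classification")
  # degenerate setting (1 round, eta ~ 0) vs sane setting
  grid <- list(list(nrounds = 1, eta = 1e-4),
               list(nrounds = 100, eta = 0.1))
  res <- gridSearch(ds, "boosted", grid, folds = 3, seed = 4)
  expect_identical(res$spec@hyperparameters$nrounds, 100)
  res2 <- gridSearch(ds, "boosted", grid, folds = 3, seed = 4)
  expect_identical(res$table$metric, res2$table$metric)
  # a single-element grid returns that spec
  one <- gridSearch(ds, "boosted", grid[2], folds = 3, seed = 4)
  expect_identical(one$spec@hyperparameters, grid[[2]])
  expect_error(gridSearch(ds, "boosted", list(), folds = 3), "empty")
})

test_that("nmtfBaseline CV recovers a planted target and masks cleanly", {
  spec <- smallSpec(flip = 0)
  sim <- simulateMultipartite(spec)
  cfg <- fitConfig(ranks = 3, maxIter = 300, nRestarts = 2, seed = 5)
  rep <- nmtfBaseline(sim$graph, "Genes", "Drugs", "S", design = "cv",
                      cfg = cfg, seed = 5, folds = 5)
  expect_identical(rep@design, "nmtf_cv")
  expect_identical(nrow(perUnit(rep)), 5L)
  expect_gt(metrics(rep)$auroc, 0.8)
})

test_that("nmtfBaseline LOO is undefined without side data, defined with", {
  spec <- smallSpec()
  sim <- simulateMultipartite(spec)
  cfg <- fitConfig(ranks = 3, maxIter = 200, nRestarts = 1, seed = 5)
  # S config has no side layers: LOO over genes is undefined, not an error
  repS <- nmtfBaseline(sim$graph, "Genes", "Drugs", "S", design = "loo",
                       cfg = cfg, seed = 5, looSet = "Genes")
  expect_true(is.na(metrics(repS)$macro_auroc))
  expect_true(isTRUE(metrics(repS)$undefined))
  # G config has gene-side layers but no drug-side: LOO drugs undefined
  repG <- nmtfBaseline(sim$graph, "Genes", "Drugs", "G", design = "loo",
                       cfg = cfg, seed = 5, looSet = "Drugs")
  expect_true(is.na(metrics(repG)$macro_auroc))
  # G+D over a small node subset is defined
  nodes <- nodeIds(sim$graph, "Genes")[1:3]
  repGD <- nmtfBaseline(sim$graph, "Genes", "Drugs", "G+D", design = "loo",
                        cfg = cfg, seed = 5, looSet = "Genes", nodes = nodes)
  expect_identical(nrow(perUnit(repGD)), 3L)
  expect_false(is.na(metrics(repGD)$macro_auroc))
})

test_that("cold-start scores collapse to zero without side information", {
  spec <- smallSpec()
  sim <- simulateMultipartite(spec)
  cfg <- fitConfig(ranks = 3, maxIter = 100, nRestarts = 1, seed = 5)
  node <- nodeIds(sim$graph, "Genes")[4]
  sc <- coldStartScores(sim$graph, "Genes", "Drugs", node,
                        layersConfig = "S", cfg = cfg)
  expect_length(sc, length(nodeIds(sim$graph, "Drugs")))
  expect_lt(max(abs(sc)), 1e-8)
  # with side information the same node gets informative scores
  scGD <- coldStartScores(sim$graph, "Genes", "Drugs", node,
                          layersConfig = "G+D", cfg = cfg)
  expect_gt(max(scGD), 1e-3)
})
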