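test_that("dichotomizeZip maps positive scores to 1, the rest to 0", {
  expect_identical(dichotomizeZip(c(2.3, 0.0, -1.7)), c(1L, 0L, 0L))
  expect_identical(dichotomizeZip(5.1), 1L)
  expect_error(dichotomizeZip(NaN), "finite")
  expect_error(dichotomizeZip(NA_real_), "finite")
})

test_that("assemblePairDataset builds the labelled Cartesian product", {
  genes <- c("g1", "g2"); drugs <- c("d1", "d2")
  embA <- toyEmbedding("Genes", genes, 10, seed = 1)
  embB <- toyEmbedding("Drugs", drugs, 25, seed = 2)
  gs <- nodeSet("Genes", genes); ds_ <- nodeSet("Drugs", drugs)
  target <- buildAssociationMatrix(data.frame(row = "g1", col = "d2"),
                                   gs, ds_)
  ds <- assemblePairDataset(embA, embB, target)
  expect_identical(nrow(features(ds)), 4L)          # |A| * |B|
  expect_identical(ncol(features(ds)), 35L)         # k_A + k_B
  expect_identical(sum(labelValues(ds)), 1)
  hit <- which(labelValues(ds) == 1)
  expect_identical(rowKeys(ds)$idA[hit], "g1")
  expect_identical(rowKeys(ds)$idB[hit], "d2")
  # feature = concat(embA[x], embB[y]) in fixed (A, B) order
  expect_identical(unname(features(ds)[hit, ]),
                   c(embeddingMatrix(embA)["g1", ],
                     embeddingMatrix(embB)["d2", ]))

  # sampled negatives: positives count equals ratio * negatives
  sim <- simulateMultipartite(smallSpec())
  g <- sim$graph
  eg <- toyEmbedding("Genes", nodeIds(g, "Genes"), 3, seed = 3)
  ed <- toyEmbedding("Drugs", nodeIds(g, "Drugs"), 3, seed = 4)
  tm <- getLayer(g, "Genes", "Drugs")
  samp <- assemblePairDataset(eg, ed, tm,
                              negativePolicy = list(ratio = 1, seed = 5))
  expect_identical(sum(samp@labels == 1), sum(samp@labels == 0))
  expect_equal(sum(samp@labels == 1), sum(tm@values))

  expect_error(assemblePairDataset(ed, eg, tm), "do not match")
})

test_that("assembleTripletDataset concatenates three towers", {
  cells <- c("c1", "c2"); drugs <- c("d1", "d2", "d3")
  embC <- toyEmbedding("Cells", cells, 25, seed = 1)
  embD <- toyEmbedding("Drugs", drugs, 25, seed = 2)
  tt <- tripletTableFromRecords(
    data.frame(cell = c("c1", "c2", "c1"),
               drugA = c("d1", "d2", "d2"),
               drugB = c("d2", "d3", "d3"),
               zip = c(2.3, 0.0, -1.7)))
  reg <- assembleTripletDataset(embC, embD, tt, task = "regression")
  expect_identical(ncol(features(reg)), 75L)
  expect_identical(labelValues(reg), c(2.3, 0.0, -1.7))

  cls <- assembleTripletDataset(embC, embD, tt, task = "classification")
  expect_identical(labelValues(cls), c(1, 0, 0))

  sym <- assembleTripletDataset(embC, embD, tt, task = "regression",
                                symmetrize = TRUE)
  expect_identical(nrow(features(sym)), 6L)
  expect_identical(labelValues(sym)[1], labelValues(sym)[4])
  expect_identical(rowKeys(sym)$drugA[4], "d2")  # swapped ordering

  bad <- tripletTableFromRecords(
    data.frame(cell = "cX", drugA = "d1", drugB = "d2", zip = 1))
  expect_error(assembleTripletDataset(embC, embD, bad), "unresolved cell")
})

test_that("train/score honour the predictor contract for all families", {
  # linearly separable toy problem
  set.seed(9)
  n <- 120
  x <- cbind(matrix(runif(n * 2), n, 2), matrix(runif(n * 2), n, 2))
  y <- as.numeric(x[, 1] + x[, 3] > 1)
  keys <- data.frame(idA = sprintf("a%03d", 1:n), idB = sprintf("b%03d", 1:n))
  ds <- new("TowerDataset", features = x, labels = y, keys = keys,
            keySets = c("A", "B"),
            towerDims = c(A = 2L, B = 2L), task = "classification")
  for (family in c("linear", "forest", "boosted")) {
    spec <- predictorSpec(family, seed = 7)
    model <- trainPredictor(ds, spec)
    sc <- scorePredictor(model, ds)
    expect_gte(auroc(sc, y), 0.99)
    # determinism
    sc2 <- scorePredictor(trainPredictor(ds, spec), ds)
    expect_identical(sc, sc2)
  }
  # single-class input is rejected
  ds1 <- ds; ds1@labels <- rep(1, n)
  expect_error(trainPredictor(ds1, predictorSpec("boosted")), "single class")
  # tower order is part of the model: mismatched width rejected
  model <- trainPredictor(ds, predictorSpec("linear"))
  expect_error(scorePredictor(model, x[, 1:3]), "width")
  dsSwap <- ds; dsSwap@towerDims <- c(B = 2L, A = 2L)
  expect_error(scorePredictor(model, dsSwap), "tower order")
})

test_that("permuted labels give chance-level CV performance", {
  sim <- simulateMultipartite(smallSpec())
  g <- sim$graph
  eg <- toyEmbedding("Genes", nodeIds(g, "Genes"), 3, seed = 3)
  ed <- toyEmbedding("Drugs", nodeIds(g, "Drugs"), 3, seed = 4)
  ds <- assemblePairDataset(eg, ed, getLayer(g, "Genes", "Drugs"))
  set.seed(11)
  ds@labels <- sample(ds@labels)
  rep <- kfoldCV(ds, predictorSpec("boosted", seed = 2), folds = 5, seed = 2)
  expect_gt(rep@metrics$auroc, 0.43)
  expect_lt(rep@metrics$auroc, 0.57)
})

test_that("symmetrized training plus order-averaged scoring is symmetric", {
  spec <- smallSpec()
  sim <- simulateMultipartite(spec)
  syn <- simulateSynergyTriplets(spec, 300)
  embC <- toyEmbedding("Cells", nodeIds(sim$graph, "Cells"), 4, seed = 5)
  embD <- toyEmbedding("Drugs", nodeIds(sim$graph, "Drugs"), 4, seed = 6)
  ds <- assembleTripletDataset(embC, embD, syn$triplets,
                               task = "regression", symmetrize = TRUE)
  model <- trainPredictor(ds, predictorSpec("boosted", seed = 1))
  r <- syn$triplets@records[1:20, ]
  fwd <- assembleTripletDataset(embC, embD, tripletTableFromRecords(r),
                                task = "regression")
  rsw <- r; rsw$drugA <- r$drugB; rsw$drugB <- r$drugA
  bwd <- assembleTripletDataset(embC, embD, tripletTableFromRecords(rsw),
                                task = "regression")
  avg1 <- (scorePredictor(model, fwd) + scorePredictor(model, bwd)) / 2
  avg2 <- (scorePredictor(model, bwd) + scorePredictor(model, fwd)) / 2
  expect_identical(avg1, avg2)
})

test_that("rankNovelPredictions excludes known edges and breaks ties", {
  genes <- c("g1", "g2"); drugs <- c("d1", "d2")
  embA <- toyEmbedding("Genes", genes, 2, seed = 1)
  embB <- toyEmbedding("Drugs", drugs, 2, seed = 2)
  gs <- nodeSet("Genes", genes); ds_ <- nodeSet("Drugs", drugs)
  target <- buildAssociationMatrix(data.frame(row = "g1", col = "d1"),
                                   gs, ds_)
  ds <- assemblePairDataset(embA, embB, target)
  model <- trainPredictor(ds, predictorSpec("boosted", list(nrounds = 20), seed = 1))
  ranked <- rankNovelPredictions(model, embA, embB, target, topN = 10)
  expect_identical(nrow(ranked), 3L)  # 4 pairs minus 1 known edge
  expect_false(any(ranked$idA == "g1" & ranked$idB == "d1"))
  expect_true(all(diff(ranked$score) <= 0))

  # all pairs positive: nothing to rank
  full <- buildAssociationMatrix(
    expand.grid(row = genes, col = drugs, stringsAsFactors = FALSE),
    gs, ds_)
  expect_identical(nrow(rankNovelPredictions(model, embA, embB, full, 5)), 0L)

  expect_error(rankNovelPredictions(model, embA, embB, target, 0), "positive")

  # equal scores: lexicographic (idA, idB) order
  embAc <- embA; embAc@vectors[2, ] <- embAc@vectors[1, ]
  embBc <- embB; embBc@vectors[2, ] <- embBc@vectors[1, ]
  dsX <- assemblePairDataset(embAc, embBc, target)
  constModel <- trainPredictor(dsX, predictorSpec("forest", seed = 1))
  sc <- scorePredictor(constModel, dsX)
  expect_length(unique(sc), 1L)  # identical features everywhere
  rk <- rankNovelPredictions(constModel, embAc, embBc, target, 10)
  expect_identical(rk$idA, c("g1", "g2", "g2"))
  expect_identical(rk$idB, c("d2", "d1", "d2"))
})
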