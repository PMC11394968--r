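test_that("initFactors is deterministic, positive and rank-correct", {
  g <- chainGraph()
  cfg <- fitConfig(ranks = c(Genes = 4, Drugs = 5, ATC = 3), seed = 42)
  f1 <- initFactors(g, cfg)
  f2 <- initFactors(g, cfg)
  expect_identical(f1, f2)
  expect_true(all(vapply(f1@nodeFactors, function(m) all(m > 0), logical(1))))
  expect_identical(ncol(nodeFactor(f1, "Genes")), 4L)
  expect_identical(ncol(nodeFactor(f1, "Drugs")), 5L)
  expect_identical(dim(coreMatrix(f1, "Genes", "Drugs")), c(4L, 5L))

  expect_error(initFactors(g, fitConfig(ranks = 50)), "rank must be <")
})

test_that("nmtfLoss matches a brute-force recomputation", {
  # identity target with all-zero factors: loss = ||I||_F^2 = 2
  ns <- list(nodeSet("A", c("a1", "a2")), nodeSet("B", c("b1", "b2")))
  v <- diag(2); dimnames(v) <- list(ns[[1]]@ids, ns[[2]]@ids)
  m <- new("AssociationMatrix", rowSet = "A", colSet = "B", values = v,
           weighted = TRUE, relation = "", transposed = FALSE)
  g <- multipartiteGraph(ns, list(m))
  zero <- manualFactors(g, matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(nmtfLoss(g, zero), 2.0)

  # exact factorization: loss 0
  pl <- plantedBipartite(8, 6, 2, seed = 3)
  f <- manualFactors(pl$graph, pl$U, pl$S, pl$V)
  expect_equal(nmtfLoss(pl$graph, f), 0, tolerance = 1e-12)

  # two-layer graph vs elementwise oracle
  g2 <- chainGraph(seed = 9)
  cfg <- fitConfig(ranks = 3, seed = 1)
  f2 <- initFactors(g2, cfg)
  oracle <- 0
  for (key in names(g2@matrices)) {
    mm <- g2@matrices[[key]]
    rec <- f2@nodeFactors[[mm@rowSet]] %*% f2@cores[[key]] %*%
      t(f2@nodeFactors[[mm@colSet]])
    for (i in seq_len(nrow(rec)))
      for (j in seq_len(ncol(rec)))
        oracle <- oracle + (mm@values[i, j] - rec[i, j])^2
  }
  expect_equal(nmtfLoss(g2, f2), oracle, tolerance = 1e-12)
})

test_that("core update follows the printed multiplicative rule", {
  # 1x1 layer: R=4, U=2, V=1, S=1 -> S' = S * (U'RV)/(U'USV'V) = 8/4 = 2
  ns <- list(nodeSet("A", "a1"), nodeSet("B", "b1"))
  v <- matrix(4, 1, 1, dimnames = list("a1", "b1"))
  m <- new("AssociationMatrix", rowSet = "A", colSet = "B", values = v,
           weighted = TRUE, relation = "", transposed = FALSE)
  g <- multipartiteGraph(ns, list(m))
  f <- manualFactors(g, matrix(2, 1, 1), matrix(1, 1, 1), matrix(1, 1, 1))
  upd <- updateFactors(g, f, fitConfig(ranks = 1), which = "cores")
  expect_equal(upd@cores[[1]][1, 1], 2)
})

test_that("an exact factorization is a fixed point of one full sweep", {
  pl <- plantedBipartite(12, 9, 3, seed = 4)
  f <- manualFactors(pl$graph, pl$U, pl$S, pl$V)
  upd <- updateFactors(pl$graph, f, fitConfig(ranks = 3))
  for (s in names(f@nodeFactors))
    expect_lt(max(abs(upd@nodeFactors[[s]] - f@nodeFactors[[s]])), 1e-12)
  expect_lt(max(abs(upd@cores[[1]] - f@cores[[1]])), 1e-12)
})

test_that("a zero row in R drives that node's factor row to zero", {
  pl <- plantedBipartite(10, 8, 2, seed = 6)
  m <- pl$graph@matrices[[1]]
  m@values[3, ] <- 0
  g <- setLayer(pl$graph, m)
  cfg <- fitConfig(ranks = 2, seed = 2)
  f <- initFactors(g, cfg)
  norms <- numeric(50)
  for (i in 1:50) {
    f <- updateFactors(g, f, cfg)
    norms[i] <- sqrt(sum(f@nodeFactors[[m@rowSet]][3, ]^2))
  }
  expect_true(all(diff(norms) <= 1e-12))
  expect_lt(norms[50], 1e-8)
})

test_that("sweeps preserve non-negativity and exact zeros", {
  g <- chainGraph(seed = 11)
  cfg <- fitConfig(ranks = 3, seed = 8)
  f <- initFactors(g, cfg)
  f@nodeFactors$Drugs[2, 1] <- 0   # plant an exact zero
  for (i in 1:25) {
    f <- updateFactors(g, f, cfg)
    expect_true(all(vapply(f@nodeFactors, function(m) all(m >= 0),
                           logical(1))))
    expect_identical(unname(f@nodeFactors$Drugs[2, 1]), 0)
  }
})

test_that("the loss is non-increasing across sweeps on random graphs", {
  for (seed in 1:6) {
    g <- if (seed %% 2) chainGraph(seed = seed) else plantedBipartite(
      15, 10, 3, seed = seed)$graph
    cfg <- fitConfig(ranks = 3, seed = seed)
    f <- initFactors(g, cfg)
    prev <- nmtfLoss(g, f)
    for (i in 1:30) {
      f <- updateFactors(g, f, cfg)
      cur <- nmtfLoss(g, f)
      expect_lte(cur, prev * (1 + 1e-9))
      prev <- cur
    }
  }
})

test_that("fitNMTF recovers an exact planted low-rank layer", {
  pl <- plantedBipartite(25, 18, 3, seed = 10)
  cfg <- fitConfig(ranks = 3, maxIter = 1500, tol = 1e-10, seed = 1,
                   nRestarts = 5)
  fit <- fitNMTF(pl$graph, cfg)
  rec <- reconstruct(fit@factors, "Genes", "Drugs")
  relErr <- sum((pl$R - rec)^2) / sum(pl$R^2)
  expect_lt(relErr, 1e-3)
  expect_true(all(rec >= 0))
})

test_that("fitNMTF respects the stop criterion and is deterministic", {
  g <- chainGraph(seed = 2)
  # huge tolerance: stops at the first convergence check
  quick <- fitNMTF(g, fitConfig(ranks = 2, tol = 1, checkEvery = 10,
                                nRestarts = 1, seed = 3))
  expect_identical(quick@iterations, 10L)
  expect_true(quick@converged)

  cfg <- fitConfig(ranks = 2, maxIter = 60, nRestarts = 2, seed = 3)
  f1 <- fitNMTF(g, cfg)
  f2 <- fitNMTF(g, cfg)
  expect_identical(f1@lossTrace, f2@lossTrace)
  expect_identical(f1@factors, f2@factors)
  expect_true(all(diff(f1@lossTrace) <= 1e-9 * f1@lossTrace[1]))

  expect_error(fitNMTF(multipartiteGraph(list(nodeSet("A", "a1"))),
                       fitConfig()), "no association")
})

test_that("shared factors couple chained layers", {
  g <- chainGraph(seed = 13)
  cfg <- fitConfig(ranks = 3, maxIter = 50, nRestarts = 1, seed = 5)
  fit <- fitNMTF(g, cfg)
  f <- fit@factors
  # one object per node set: the V of Genes~Drugs IS the U of Drugs~ATC
  expect_identical(names(f@nodeFactors), c("Genes", "Drugs", "ATC"))
  recBefore <- reconstruct(f, "Drugs", "ATC")
  # perturb through the shared Drugs factor: both reconstructions change
  f2 <- f
  f2@nodeFactors$Drugs <- f2@nodeFactors$Drugs * 2
  expect_false(isTRUE(all.equal(reconstruct(f2, "Drugs", "ATC"), recBefore)))
  expect_false(isTRUE(all.equal(reconstruct(f2, "Genes", "Drugs"),
                                reconstruct(f, "Genes", "Drugs"))))
})

test_that("fitting is invariant to the stored orientation of a layer", {
  pl <- plantedBipartite(10, 8, 2, seed = 20)
  g1 <- pl$graph
  m <- g1@matrices[[1]]
  mT <- t(m)
  mT@transposed <- FALSE
  g2 <- multipartiteGraph(g1@nodeSets[c(2, 1)], list(mT))
  cfg <- fitConfig(ranks = 2, maxIter = 40, nRestarts = 1, seed = 9)
  f1 <- fitNMTF(g1, cfg)
  f2 <- fitNMTF(g2, cfg)
  expect_equal(f1@lossTrace, f2@lossTrace, tolerance = 1e-12)
})

test_that("reconstruct and predictScores expose matrix completion", {
  pl <- plantedBipartite(10, 8, 2, seed = 15)
  f <- manualFactors(pl$graph, pl$U, pl$S, pl$V)
  rec <- reconstruct(f, "Genes", "Drugs")
  expect_equal(unname(rec), unname(pl$R), tolerance = 1e-9)
  # zero factors -> zero matrix
  z <- manualFactors(pl$graph, pl$U * 0, pl$S * 0, pl$V * 0)
  expect_true(all(reconstruct(z, "Genes", "Drugs") == 0))
  # transposed query orientation
  expect_equal(reconstruct(f, "Drugs", "Genes"), t(rec))

  ids <- list(rownames(rec), colnames(rec))
  sc <- predictScores(f, "Genes", "Drugs",
                      data.frame(a = c(ids[[1]][1], ids[[1]][1]),
                                 b = c(ids[[2]][2], ids[[2]][2])))
  expect_identical(sc[1], sc[2])
  expect_equal(sc[1], rec[1, 2])
  expect_error(predictScores(f, "Genes", "Drugs",
                             data.frame(a = "nope", b = ids[[2]][1])),
               "unresolved")
  expect_error(reconstruct(f, "Genes", "Nope"), "unknown layer")
})
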