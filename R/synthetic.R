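#' Specify a planted low-rank synthetic multipartite graph
#'
#' The generator emulates the shape of a drug-discovery knowledge graph: a
#' binary gene-drug target layer, binary gene-side (e.g. ontology terms,
#' pathways) and drug-side (e.g. ATC codes, categories, classes)
#' annotation layers, a non-negative weighted cell-line x gene expression
#' layer, and a (cell, drug, drug) synergy score table. All binary layers
#' and the target are thresholded from products of the SAME planted
#' non-negative factors, so side layers are genuinely informative about
#' target edges — the property the embedding pipeline exploits.
#'
#' @param nGenes,nDrugs,nCells node-set sizes (defaults 120, 100, 15).
#' @param geneSide named sizes of the gene-side sets
#'   (default `c(GO = 50, Pathways = 30)`).
#' @param drugSide named sizes of the drug-side sets
#'   (default `c(ATC = 20, Categories = 30, Classes = 40)`).
#' @param rank planted rank (default 5); must be below every set size.
#' @param targetDensity binary target-layer density (default 0.15): dense
#'   enough that the planted structure, not the flip noise, dominates the
#'   positive class at desk scale.
#' @param sideDensity binary side-layer density (default 0.1).
#' @param flip fraction of binary entries flipped as label noise
#'   (default 0.05).
#' @param weightNoise additive Gaussian noise on the weighted layer,
#'   relative to its signal sd (default 0.1).
#' @param zipNoise additive Gaussian noise on ZIP scores relative to the
#'   planted signal sd; the default 0.484 gives a truth-vs-observed
#'   Pearson correlation of about 0.9.
#' @param seed integer seed.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nGenes = 120L, nDrugs = 100L, nCells = 15L,
                          geneSide = c(GO = 50L, Pathways = 30L),
                          drugSide = c(ATC = 20L, Categories = 30L,
                                       Classes = 40L),
                          rank = 5L, targetDensity = 0.15, sideDensity = 0.1,
                          flip = 0.05, weightNoise = 0.1, zipNoise = 0.484,
                          seed = 1L) {
  new("SyntheticSpec", nGenes = as.integer(nGenes),
      nDrugs = as.integer(nDrugs), nCells = as.integer(nCells),
      geneSide = stats::setNames(as.integer(geneSide), names(geneSide)),
      drugSide = stats::setNames(as.integer(drugSide), names(drugSide)),
      rank = as.integer(rank), targetDensity = targetDensity,
      sideDensity = sideDensity, flip = flip, weightNoise = weightNoise,
      zipNoise = zipNoise, seed = as.integer(seed))
}

#' Node-set sizes implied by a SyntheticSpec, in generation order
#' @keywords internal
.specSizes <- function(spec) {
  c(Genes = spec@nGenes, Drugs = spec@nDrugs,
    spec@geneSide, spec@drugSide, Cells = spec@nCells)
}

#' Draw the planted factors deterministically from the spec seed
#'
#' Both the graph and the synergy-triplet generators call this, so the
#' drug factors driving side layers, target edges and synergy scores are
#' one and the same planted truth.
#' @keywords internal
.plantedFactors <- function(spec) {
  sizes <- .specSizes(spec)
  r <- spec@rank
  set.seed(.substream(spec@seed, "planted-factors"))
  factors <- lapply(sizes, function(n) matrix(stats::rexp(n * r), n, r))
  prefixes <- c(Genes = "G", Drugs = "D", Cells = "C")
  for (nm in names(factors)) {
    pre <- if (nm %in% names(prefixes)) prefixes[[nm]]
           else paste0(substr(nm, 1, 2), "_")
    rownames(factors[[nm]]) <- sprintf("%s%03d", pre, seq_len(sizes[[nm]]))
  }
  layers <- c("Genes~Drugs",
              paste0("Genes~", names(spec@geneSide)),
              paste0("Drugs~", names(spec@drugSide)),
              "Cells~Genes")
  cores <- stats::setNames(
    lapply(layers, function(x) matrix(stats::rexp(r * r), r, r)), layers)
  list(factors = factors, cores = cores)
}

#' Threshold a continuous score matrix at a target density, then flip
#' @keywords internal
.binarizeLayer <- function(scores, density, flip) {
  thr <- stats::quantile(scores, 1 - density, names = FALSE)
  if (thr <= min(scores) || thr >= max(scores))
    stop("degenerate density/quantile: thresholding produced a constant layer")
  b <- (scores > thr) * 1
  if (flip > 0) {
    nFlip <- round(flip * length(b))
    idx <- sample(length(b), nFlip)
    b[idx] <- 1 - b[idx]
  }
  b
}

#' Simulate a planted low-rank multipartite graph
#'
#' Draws i.i.d. exponential planted factors per node set (via the spec
#' seed), forms each layer's continuous scores `U S V'`, thresholds binary
#' layers at the quantile matching the requested density, flips a `flip`
#' fraction of entries, and adds truncated Gaussian noise to the weighted
#' cell x gene layer. Returns the graph alongside the planted truth
#' (factors, cores and the continuous target scores) for use as a test
#' oracle.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with elements `graph` ([MultipartiteGraph-class]) and
#'   `truth` (list: `factors`, `cores`, `targetScores`).
#' @examples
#' sim <- simulateMultipartite(syntheticSpec(nGenes = 30, nDrugs = 20,
#'   nCells = 5, geneSide = c(GO = 10), drugSide = c(ATC = 10), rank = 3))
#' sim$graph
#' @export
simulateMultipartite <- function(spec) {
  planted <- .plantedFactors(spec)
  fac <- planted$factors
  sizes <- .specSizes(spec)
  nodeSetList <- lapply(names(sizes), function(nm)
    nodeSet(nm, rownames(fac[[nm]])))
  names(nodeSetList) <- names(sizes)

  set.seed(.substream(spec@seed, "layer-noise"))
  mats <- list()
  mkBinary <- function(a, b, density) {
    key <- paste0(a, "~", b)
    sc <- fac[[a]] %*% planted$cores[[key]] %*% t(fac[[b]])
    v <- .binarizeLayer(sc, density, spec@flip)
    dimnames(v) <- list(rownames(fac[[a]]), rownames(fac[[b]]))
    new("AssociationMatrix", rowSet = a, colSet = b, values = v,
        weighted = FALSE, relation = paste0(a, "-", b), transposed = FALSE)
  }
  mats[[length(mats) + 1L]] <- mkBinary("Genes", "Drugs", spec@targetDensity)
  for (nm in names(spec@geneSide))
    mats[[length(mats) + 1L]] <- mkBinary("Genes", nm, spec@sideDensity)
  for (nm in names(spec@drugSide))
    mats[[length(mats) + 1L]] <- mkBinary("Drugs", nm, spec@sideDensity)

  wsc <- fac[["Cells"]] %*% planted$cores[["Cells~Genes"]] %*% t(fac[["Genes"]])
  w <- pmax(wsc + stats::rnorm(length(wsc), sd = spec@weightNoise * stats::sd(wsc)), 0)
  dimnames(w) <- list(rownames(fac[["Cells"]]), rownames(fac[["Genes"]]))
  mats[[length(mats) + 1L]] <- new("AssociationMatrix", rowSet = "Cells",
                                   colSet = "Genes", values = w,
                                   weighted = TRUE, relation = "expression",
                                   transposed = FALSE)

  g <- multipartiteGraph(nodeSetList, mats)
  tkey <- "Genes~Drugs"
  truth <- list(factors = fac, cores = planted$cores,
                targetScores = fac[["Genes"]] %*% planted$cores[[tkey]] %*%
                  t(fac[["Drugs"]]))
  dimnames(truth$targetScores) <- list(rownames(fac[["Genes"]]),
                                       rownames(fac[["Drugs"]]))
  list(graph = g, truth = truth)
}

#' Simulate a planted synergy triplet table
#'
#' Samples unordered (cell, drug pair) combinations without replacement
#' and assigns `ZIP(c, a, b) = <w_c, u_a * u_b> - beta + noise`, where w
#' and u are the SAME planted cell and drug factors used by
#' [simulateMultipartite()] under the same spec, `*` is the elementwise
#' product, and beta centres the planted score distribution at zero so
#' both synergistic (positive) and antagonistic (non-positive) scores
#' occur. The noiseless truth is symmetric in the two drugs by
#' construction.
#'
#' @param spec a [SyntheticSpec-class].
#' @param nTriplets number of triplets; at most
#'   `nCells * nDrugs * (nDrugs - 1) / 2`.
#' @return list with elements `triplets` ([TripletTable-class]) and
#'   `truth` (data.frame of noiseless scores aligned to the records).
#' @export
simulateSynergyTriplets <- function(spec, nTriplets = 5000L) {
  maxN <- spec@nCells * spec@nDrugs * (spec@nDrugs - 1) / 2
  if (nTriplets > maxN)
    stop(sprintf("nTriplets exceeds the number of distinct triplets (%d)",
                 maxN))
  planted <- .plantedFactors(spec)
  W <- planted$factors[["Cells"]]; U <- planted$factors[["Drugs"]]
  cells <- rownames(W); drugs <- rownames(U)
  set.seed(.substream(spec@seed, "synergy-sampling"))
  idx <- sample.int(maxN, nTriplets)
  # decode flat index -> (cell, unordered drug pair)
  nPairs <- spec@nDrugs * (spec@nDrugs - 1) / 2
  ci <- (idx - 1L) %/% nPairs + 1L
  pi_ <- (idx - 1L) %% nPairs + 1L
  pairIdx <- utils::combn(spec@nDrugs, 2)
  ai <- pairIdx[1, pi_]; bi <- pairIdx[2, pi_]
  signal <- rowSums(W[ci, , drop = FALSE] * U[ai, , drop = FALSE] *
                      U[bi, , drop = FALSE])
  beta <- mean(signal)
  truthScore <- signal - beta
  zip <- truthScore + stats::rnorm(nTriplets,
                                   sd = spec@zipNoise * stats::sd(truthScore))
  rec <- data.frame(cell = cells[ci], drugA = drugs[ai], drugB = drugs[bi],
                    zip = zip, stringsAsFactors = FALSE)
  list(triplets = tripletTableFromRecords(rec, cellSet = "Cells",
                                          drugSet = "Drugs"),
       truth = data.frame(cell = rec$cell, drugA = rec$drugA,
                          drugB = rec$drugB, zipTruth = truthScore,
                          stringsAsFactors = FALSE))
}

#' Permutation null for a binary target layer
#'
#' Returns a copy of the graph whose target-layer entries are permuted
#' uniformly at random (edge count conserved, degree structure and any
#' factor structure destroyed); all other layers are untouched. Serves as
#' a negative control: any pipeline evaluated on the null graph should
#' score at chance.
#'
#' @param g a [MultipartiteGraph-class].
#' @param targetA,targetB node-set names of the binary target layer.
#' @param seed integer seed for the permutation.
#' @return a [MultipartiteGraph-class].
#' @export
permutedNull <- function(g, targetA, targetB, seed = 1L) {
  m <- getLayer(g, targetA, targetB)
  if (m@weighted) stop("target layer must be binary")
  set.seed(.substream(seed, "null-permutation"))
  v <- m@values
  v[] <- v[sample(length(v))]
  m@values <- v
  setLayer(g, m)
}
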