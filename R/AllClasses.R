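#' @import methods
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' NodeSet: one semantic category of nodes
#'
#' A named, ordered collection of unique node identifiers. The position of
#' an id in `ids` is its (1-based) row/column index in every association
#' matrix, factor matrix and embedding table referring to this set; the
#' mapping is frozen at construction time so that factor and embedding rows
#' are reproducibly aligned.
#'
#' @slot name single string labelling the semantic category (e.g. "Genes").
#' @slot ids character vector of unique node identifiers.
#' @export
setClass("NodeSet",
  representation(name = "character", ids = "character"))

setValidity("NodeSet", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@ids) == 0L)
    msg <- c(msg, "'ids' must be non-empty")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "node ids must be unique within a set")
  if (any(is.na(object@ids)) || any(!nzchar(object@ids)))
    msg <- c(msg, "node ids must be non-missing, non-empty strings")
  if (length(msg)) msg else TRUE
})

#' AssociationMatrix: one bipartite layer of a multipartite graph
#'
#' A non-negative |row set| x |col set| matrix. Unweighted layers are
#' binary adjacency matrices (entries in {0,1}); weighted layers carry
#' arbitrary non-negative values (e.g. expression levels). Row and column
#' names are the node ids of the two sets, in frozen NodeSet order.
#'
#' @slot rowSet name of the NodeSet indexing rows.
#' @slot colSet name of the NodeSet indexing columns.
#' @slot values numeric matrix of non-negative values with dimnames set to
#'   the node ids.
#' @slot weighted logical; `FALSE` means entries are constrained to {0,1}.
#' @slot relation free-text semantic label of the edge type.
#' @slot transposed logical orientation metadata: `TRUE` if this object was
#'   produced by transposing the originally stored layer (see
#'   [orientToTarget()]).
#' @export
setClass("AssociationMatrix",
  representation(rowSet = "character", colSet = "character",
                 values = "matrix", weighted = "logical",
                 relation = "character", transposed = "logical"),
  prototype(weighted = FALSE, relation = "", transposed = FALSE))

setValidity("AssociationMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "'values' must be numeric")
  if (any(!is.finite(v))) msg <- c(msg, "'values' must be finite")
  else if (any(v < 0)) msg <- c(msg, "association values must be non-negative")
  if (!object@weighted && length(v) && !all(v %in% c(0, 1)))
    msg <- c(msg, "unweighted layer must have entries in {0,1}")
  if (object@rowSet == object@colSet)
    msg <- c(msg, "row and column node sets must differ")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "'values' must carry node ids as dimnames")
  if (length(msg)) msg else TRUE
})

#' TripletTable: (cell line, drug A, drug B, ZIP) hyperedges
#'
#' Real-valued synergy hyperedges between one cell line and an unordered
#' pair of drugs. ZIP (zero interaction potency) scores are centred around
#' zero: positive values indicate synergism, non-positive values indicate
#' no synergy or antagonism. Pairs are stored as given; symmetrisation is
#' handled downstream when assembling predictor datasets.
#'
#' @slot cellSet name of the cell-line NodeSet.
#' @slot drugSet name of the drug NodeSet.
#' @slot records data.frame with columns `cell`, `drugA`, `drugB` (ids) and
#'   `zip` (finite numeric, may be negative).
#' @export
setClass("TripletTable",
  representation(cellSet = "character", drugSet = "character",
                 records = "data.frame"))

setValidity("TripletTable", function(object) {
  msg <- character()
  r <- object@records
  need <- c("cell", "drugA", "drugB", "zip")
  if (!all(need %in% names(r)))
    return(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  if (nrow(r)) {
    if (any(r$drugA == r$drugB))
      msg <- c(msg, "drugA and drugB must differ within a record")
    if (any(!is.finite(r$zip)))
      msg <- c(msg, "zip scores must be finite")
  }
  if (length(msg)) msg else TRUE
})

setClassUnion("TripletTableOrNULL", c("TripletTable", "NULL"))

#' MultipartiteGraph: typed node sets joined by association matrices
#'
#' The central container: a collection of pairwise-disjoint [NodeSet]s and,
#' for some unordered pairs of sets, one [AssociationMatrix] layer. The
#' graph is represented entirely by its non-null association matrices; an
#' optional [TripletTable] carries synergy hyperedges.
#'
#' @slot nodeSets named list of NodeSet objects (names equal set names).
#' @slot matrices named list of AssociationMatrix objects keyed by the
#'   canonical unordered pair key (see [matrixKey()]).
#' @slot triplets TripletTable or NULL.
#' @export
setClass("MultipartiteGraph",
  representation(nodeSets = "list", matrices = "list",
                 triplets = "TripletTableOrNULL"),
  prototype(triplets = NULL))

setValidity("MultipartiteGraph", function(object) {
  msg <- character()
  ns <- object@nodeSets
  if (!length(ns)) return("graph must contain at least one node set")
  nm <- vapply(ns, function(s) s@name, character(1))
  if (!identical(names(ns), unname(nm)))
    msg <- c(msg, "nodeSets list names must equal the NodeSet names")
  if (anyDuplicated(nm)) msg <- c(msg, "node-set names must be unique")
  for (m in object@matrices) {
    if (!all(c(m@rowSet, m@colSet) %in% nm)) {
      msg <- c(msg, sprintf("layer %s~%s references unknown node sets",
                            m@rowSet, m@colSet))
      next
    }
    if (nrow(m@values) != length(ns[[m@rowSet]]@ids) ||
        ncol(m@values) != length(ns[[m@colSet]]@ids))
      msg <- c(msg, sprintf("layer %s~%s has wrong shape", m@rowSet, m@colSet))
  }
  keys <- vapply(object@matrices, function(m) matrixKey(m@rowSet, m@colSet),
                 character(1))
  if (length(keys) && !identical(names(object@matrices), unname(keys)))
    msg <- c(msg, "matrices must be keyed by their canonical pair key")
  if (anyDuplicated(keys))
    msg <- c(msg, "at most one matrix per unordered node-set pair")
  if (length(msg)) msg else TRUE
})

#' FitConfig: settings for an NMTF fit
#'
#' @slot ranks named integer vector mapping node-set name to its factor
#'   rank k, or a single unnamed value used for every set. Every rank must
#'   be strictly smaller than the corresponding set size.
#' @slot maxIter maximum number of multiplicative-update sweeps.
#' @slot tol relative loss-change tolerance used as the stop criterion.
#' @slot checkEvery sweeps between convergence checks (loss evaluations).
#' @slot seed integer seed; all initialisation randomness derives from it.
#' @slot nRestarts random restarts; the lowest-loss fit is kept.
#' @slot matrixWeights named non-negative per-layer weights (canonical pair
#'   keys); unnamed layers default to 1.
#' @slot eps small positive stabiliser: update denominators are floored at
#'   `eps` so multiplicative rules are always well defined.
#' @slot normalizeWeights if TRUE, each layer's weight is divided by its
#'   squared Frobenius norm, counteracting the dominance of large layers.
#' @slot logTransform if TRUE, weighted layers are log1p-transformed before
#'   factorization.
#' @export
setClass("FitConfig",
  representation(ranks = "numeric", maxIter = "integer", tol = "numeric",
                 checkEvery = "integer", seed = "integer",
                 nRestarts = "integer", matrixWeights = "numeric",
                 eps = "numeric", normalizeWeights = "logical",
                 logTransform = "logical"))

setValidity("FitConfig", function(object) {
  msg <- character()
  if (any(object@ranks < 1)) msg <- c(msg, "ranks must be >= 1")
  if (object@maxIter < 1L) msg <- c(msg, "maxIter must be >= 1")
  if (object@tol <= 0) msg <- c(msg, "tol must be > 0")
  if (object@eps <= 0) msg <- c(msg, "eps must be > 0")
  if (object@checkEvery < 1L) msg <- c(msg, "checkEvery must be >= 1")
  if (object@nRestarts < 1L) msg <- c(msg, "nRestarts must be >= 1")
  if (any(object@matrixWeights < 0)) msg <- c(msg, "matrixWeights must be >= 0")
  if (length(msg)) msg else TRUE
})

#' FactorSet: shared NMTF factors of a multipartite graph
#'
#' One non-negative factor matrix per node set and one core matrix per
#' association layer. A node set's single factor matrix plays the role of U
#' when the set indexes rows of a layer and of V when it indexes columns;
#' this one-object-per-set representation enforces all factor-sharing
#' constraints of joint multipartite NMTF by construction.
#'
#' @slot nodeFactors named list: node-set name -> |set| x k non-negative
#'   matrix with node ids as rownames.
#' @slot cores named list: canonical pair key -> k_row x k_col core matrix,
#'   stored in the layer's storage orientation.
#' @slot orientation named list: canonical pair key -> c(rowSet, colSet) of
#'   the stored layer (so cores can be interpreted without the graph).
#' @slot ranks named numeric vector of per-set ranks.
#' @export
setClass("FactorSet",
  representation(nodeFactors = "list", cores = "list",
                 orientation = "list", ranks = "numeric"))

setValidity("FactorSet", function(object) {
  msg <- character()
  for (nm in names(object@nodeFactors)) {
    g <- object@nodeFactors[[nm]]
    if (any(!is.finite(g)) || any(g < 0)) {
      msg <- c(msg, sprintf("factor for set '%s' must be finite and non-negative", nm))
    }
    if (!is.na(object@ranks[nm]) && ncol(g) != object@ranks[nm])
      msg <- c(msg, sprintf("factor for set '%s' has wrong rank", nm))
  }
  for (key in names(object@cores)) {
    s <- object@cores[[key]]
    if (any(!is.finite(s)) || any(s < 0))
      msg <- c(msg, sprintf("core for layer '%s' must be finite and non-negative", key))
  }
  if (!identical(sort(names(object@cores)), sort(names(object@orientation))))
    msg <- c(msg, "cores and orientation must cover the same layers")
  if (length(msg)) msg else TRUE
})

#' FitResult: outcome of an NMTF fit
#'
#' @slot factors the fitted [FactorSet].
#' @slot lossTrace numeric vector of loss values at convergence checks
#'   (non-increasing up to numerical slack).
#' @slot converged TRUE if the relative-change stop criterion fired before
#'   `maxIter`.
#' @slot iterations number of sweeps actually performed.
#' @slot seedUsed the seed of the restart that produced `factors`.
#' @export
setClass("FitResult",
  representation(factors = "FactorSet", lossTrace = "numeric",
                 converged = "logical", iterations = "integer",
                 seedUsed = "integer"))

#' EmbeddingTable: dense per-node vectors for one node set
#'
#' Rows are aligned to the NodeSet's frozen id order. NMTF embeddings are
#' rows of the shared V factor (non-negative); SVD embeddings are scaled
#' right singular vectors (may be negative).
#'
#' @slot nodeSet name of the embedded node set.
#' @slot k embedding dimension.
#' @slot vectors |set| x k numeric matrix with node ids as rownames.
#' @slot method "nmtf" or "svd".
#' @slot provenance list snapshot of the configuration that produced it.
#' @export
setClass("EmbeddingTable",
  representation(nodeSet = "character", k = "integer", vectors = "matrix",
                 method = "character", provenance = "list"))

setValidity("EmbeddingTable", function(object) {
  msg <- character()
  if (any(!is.finite(object@vectors))) msg <- c(msg, "embeddings must be finite")
  if (ncol(object@vectors) != object@k) msg <- c(msg, "vector width must equal k")
  if (is.null(rownames(object@vectors))) msg <- c(msg, "vectors must have node ids as rownames")
  if (object@method == "nmtf" && length(object@vectors) && any(object@vectors < 0))
    msg <- c(msg, "nmtf embeddings must be non-negative")
  if (length(msg)) msg else TRUE
})

#' TowerDataset: concatenated-embedding feature table
#'
#' Each row is one tuple of nodes (a pair for link prediction, a triplet
#' for synergy); its feature vector is the concatenation of the towers'
#' embeddings in a fixed, recorded order, and its label is a binary edge
#' indicator or a real-valued target (ZIP score).
#'
#' @slot features n x sum(towerDims) numeric matrix.
#' @slot labels numeric vector; in {0,1} for classification.
#' @slot keys data.frame of per-row node ids, one column per tower.
#' @slot keySets character: node-set name behind each key column (used by
#'   leave-one-node-out splitting to find every row involving a node).
#' @slot towerDims named integer vector of per-tower embedding widths, in
#'   tower order; part of the model contract checked at scoring time.
#' @slot task "classification" or "regression".
#' @export
setClass("TowerDataset",
  representation(features = "matrix", labels = "numeric", keys = "data.frame",
                 keySets = "character", towerDims = "integer", task = "character"))

setValidity("TowerDataset", function(object) {
  msg <- character()
  if (ncol(object@features) != sum(object@towerDims))
    msg <- c(msg, "feature width must equal the sum of tower dimensions")
  if (nrow(object@features) != length(object@labels) ||
      nrow(object@features) != nrow(object@keys))
    msg <- c(msg, "features, labels and keys must have equal row counts")
  if (length(object@keySets) != ncol(object@keys))
    msg <- c(msg, "keySets must name the node set of every key column")
  if (object@task == "classification" && length(object@labels) &&
      !all(object@labels %in% c(0, 1)))
    msg <- c(msg, "classification labels must be in {0,1}")
  if (anyDuplicated(do.call(paste, c(object@keys, sep = "\r"))))
    msg <- c(msg, "row keys must be unique")
  if (length(msg)) msg else TRUE
})

#' PredictorSpec: family and hyperparameters of a tower predictor
#'
#' @slot family "linear" (regularised logistic / linear model),
#'   "forest" (random forest) or "boosted" (gradient-boosted trees).
#' @slot hyperparameters named list understood by the family (see
#'   [trainPredictor()]).
#' @slot seed integer seed for stochastic families.
#' @export
setClass("PredictorSpec",
  representation(family = "character", hyperparameters = "list",
                 seed = "integer"))

setValidity("PredictorSpec", function(object) {
  if (!object@family %in% c("linear", "forest", "boosted"))
    return("family must be one of 'linear', 'forest', 'boosted'")
  TRUE
})

#' TowerPredictor: a trained N-tower model
#'
#' Wraps the fitted model together with the tower-order contract it was
#' trained under; scoring verifies feature width and tower order.
#'
#' @slot spec the [PredictorSpec] used.
#' @slot task "classification" or "regression".
#' @slot model the fitted backend model object.
#' @slot towerDims named integer vector copied from the training dataset.
#' @export
setClass("TowerPredictor",
  representation(spec = "PredictorSpec", task = "character", model = "ANY",
                 towerDims = "integer"))

#' EvalReport: result of an evaluation design
#'
#' @slot design "full_cv", "loo_nodes", "nmtf_cv" or "nmtf_loo".
#' @slot metrics named list of pooled/aggregate metric values.
#' @slot perUnit data.frame of per-fold or per-node metrics.
#' @slot config list snapshot of the evaluation configuration.
#' @slot seed integer seed used.
#' @export
setClass("EvalReport",
  representation(design = "character", metrics = "list",
                 perUnit = "data.frame", config = "list", seed = "integer"))

#' SyntheticSpec: parameters of the planted low-rank generator
#'
#' Describes a synthetic semantic multipartite graph: a gene-drug target
#' layer, gene-side and drug-side binary annotation layers all generated
#' from the same planted non-negative factors, one weighted cell x gene
#' layer, and a cell/drug-pair synergy score table with planted bilinear
#' structure.
#'
#' @slot nGenes,nDrugs,nCells node-set sizes.
#' @slot geneSide named integer vector of gene-side set sizes.
#' @slot drugSide named integer vector of drug-side set sizes.
#' @slot rank planted rank r (must be < every set size).
#' @slot targetDensity,sideDensity edge densities of the binary layers.
#' @slot flip fraction of binary entries flipped (label noise), in [0, 0.5).
#' @slot weightNoise additive Gaussian noise scale for the weighted layer,
#'   relative to the layer's signal standard deviation.
#' @slot zipNoise additive noise scale for ZIP scores, relative to the
#'   planted signal standard deviation.
#' @slot seed integer seed.
#' @export
setClass("SyntheticSpec",
  representation(nGenes = "integer", nDrugs = "integer", nCells = "integer",
                 geneSide = "integer", drugSide = "integer", rank = "integer",
                 targetDensity = "numeric", sideDensity = "numeric",
                 flip = "numeric", weightNoise = "numeric",
                 zipNoise = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  sizes <- c(object@nGenes, object@nDrugs, object@nCells,
             object@geneSide, object@drugSide)
  if (object@rank >= min(sizes))
    msg <- c(msg, "rank must be smaller than every node-set size")
  for (d in c(object@targetDensity, object@sideDensity))
    if (d <= 0 || d >= 1) msg <- c(msg, "densities must lie in (0,1)")
  if (object@flip < 0 || object@flip >= 0.5)
    msg <- c(msg, "flip fraction must lie in [0, 0.5)")
  if (is.null(names(object@geneSide)) || is.null(names(object@drugSide)))
    msg <- c(msg, "side-set sizes must be named")
  if (length(msg)) msg else TRUE
})
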