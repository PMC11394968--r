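#' Dichotomize a ZIP synergy score
#'
#' Maps a ZIP score to a binary synergy label: 1 for strictly positive
#' scores (synergism), 0 for non-positive scores (no synergy or
#' antagonism).
#'
#' @param zip numeric vector of finite ZIP scores.
#' @return integer vector of 0/1 labels.
#' @examples
#' dichotomizeZip(c(2.3, 0, -1.7))
#' @export
dichotomizeZip <- function(zip) {
  if (any(is.na(zip)) || any(!is.finite(zip)))
    stop("zip scores must be finite and non-missing")
  as.integer(zip > 0)
}

#' Assemble a two-tower pair dataset
#'
#' Builds the link-prediction dataset: one row per (A node, B node) pair,
#' feature vector the concatenation of the two embeddings in fixed (A, B)
#' order, label 1 if the pair is connected in the binary target layer and
#' 0 otherwise.
#'
#' @param embA,embB [EmbeddingTable-class]s for the target layer's row and
#'   column sets respectively.
#' @param target binary [AssociationMatrix-class] with `rowSet` matching
#'   `embA` and `colSet` matching `embB`.
#' @param negativePolicy `"all"` (full Cartesian product; the default) or a
#'   list `list(ratio =, seed =)` keeping all positives plus
#'   `ratio x positives` negatives sampled without replacement.
#' @return a classification [TowerDataset-class].
#' @export
assemblePairDataset <- function(embA, embB, target, negativePolicy = "all") {
  if (target@weighted) stop("target layer must be binary")
  if (embA@nodeSet != target@rowSet || embB@nodeSet != target@colSet)
    stop(sprintf("embedding sets (%s, %s) do not match target layer (%s, %s)",
                 embA@nodeSet, embB@nodeSet, target@rowSet, target@colSet))
  idsA <- rownames(embA@vectors); idsB <- rownames(embB@vectors)
  if (!identical(idsA, rownames(target@values)) ||
      !identical(idsB, colnames(target@values)))
    stop("embedding node order does not match the target layer")
  grid <- expand.grid(b = seq_along(idsB), a = seq_along(idsA),
                      KEEP.OUT.ATTRS = FALSE)  # a varies slowest
  grid <- grid[, c("a", "b")]
  lab <- target@values[cbind(grid$a, grid$b)]
  if (!identical(negativePolicy, "all")) {
    if (!is.list(negativePolicy) || is.null(negativePolicy$ratio))
      stop("negativePolicy must be \"all\" or list(ratio=, seed=)")
    pos <- which(lab == 1); neg <- which(lab == 0)
    nNeg <- min(length(neg), round(negativePolicy$ratio * length(pos)))
    set.seed(.substream(negativePolicy$seed %||% 1L, "negative-sampling"))
    take <- sort(c(pos, sample(neg, nNeg)))
    grid <- grid[take, , drop = FALSE]
    lab <- lab[take]
  }
  feat <- cbind(embA@vectors[grid$a, , drop = FALSE],
                embB@vectors[grid$b, , drop = FALSE])
  colnames(feat) <- c(paste0(embA@nodeSet, ".", seq_len(embA@k)),
                      paste0(embB@nodeSet, ".", seq_len(embB@k)))
  rownames(feat) <- NULL
  keys <- data.frame(idA = idsA[grid$a], idB = idsB[grid$b],
                     stringsAsFactors = FALSE)
  new("TowerDataset", features = feat, labels = as.numeric(lab), keys = keys,
      keySets = c(embA@nodeSet, embB@nodeSet),
      towerDims = stats::setNames(c(embA@k, embB@k),
                                  c(embA@nodeSet, embB@nodeSet)),
      task = "classification")
}

#' Assemble a three-tower synergy dataset
#'
#' One row per (cell, drug A, drug B) triplet; feature vector is the
#' concatenation of the cell embedding and the two drug embeddings. The
#' target is the raw ZIP score (regression) or its dichotomization
#' (classification). With `symmetrize = TRUE` every record is duplicated
#' with the drug order swapped and the same target, teaching the predictor
#' the pair symmetry.
#'
#' @param embCell,embDrug [EmbeddingTable-class]s for cells and drugs.
#' @param triplets a [TripletTable-class].
#' @param task "regression" or "classification".
#' @param symmetrize logical; add the swapped-drug ordering of each record.
#' @return a [TowerDataset-class].
#' @export
assembleTripletDataset <- function(embCell, embDrug, triplets,
                                   task = c("regression", "classification"),
                                   symmetrize = FALSE) {
  task <- match.arg(task)
  r <- triplets@records
  if (symmetrize) {
    sw <- r; sw$drugA <- r$drugB; sw$drugB <- r$drugA
    r <- rbind(r, sw)
  }
  ci <- match(r$cell, rownames(embCell@vectors))
  ai <- match(r$drugA, rownames(embDrug@vectors))
  bi <- match(r$drugB, rownames(embDrug@vectors))
  if (any(is.na(ci))) stop("unresolved cell id(s) in triplet table")
  if (any(is.na(ai)) || any(is.na(bi)))
    stop("unresolved drug id(s) in triplet table")
  feat <- cbind(embCell@vectors[ci, , drop = FALSE],
                embDrug@vectors[ai, , drop = FALSE],
                embDrug@vectors[bi, , drop = FALSE])
  colnames(feat) <- c(paste0("cell.", seq_len(embCell@k)),
                      paste0("drugA.", seq_len(embDrug@k)),
                      paste0("drugB.", seq_len(embDrug@k)))
  rownames(feat) <- NULL
  y <- if (task == "regression") r$zip else as.numeric(dichotomizeZip(r$zip))
  keys <- data.frame(cell = r$cell, drugA = r$drugA, drugB = r$drugB,
                     stringsAsFactors = FALSE)
  new("TowerDataset", features = feat, labels = y, keys = keys,
      keySets = c(embCell@nodeSet, embDrug@nodeSet, embDrug@nodeSet),
      towerDims = stats::setNames(c(embCell@k, embDrug@k, embDrug@k),
                                  c("cell", "drugA", "drugB")),
      task = task)
}

#' @rdname accessors
#' @export
setMethod("features", "TowerDataset", function(x) x@features)

#' @rdname accessors
#' @export
setMethod("labelValues", "TowerDataset", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("rowKeys", "TowerDataset", function(x) x@keys)

setMethod("dim", "TowerDataset", function(x) dim(x@features))

setMethod("show", "TowerDataset", function(object) {
  cat(sprintf("TowerDataset (%s): %d rows, %d towers (%s), width %d\n",
              object@task, nrow(object@features), length(object@towerDims),
              paste(names(object@towerDims), collapse = "+"),
              ncol(object@features)))
  if (object@task == "classification")
    cat(sprintf("  positives: %d / %d\n", sum(object@labels == 1),
                length(object@labels)))
})

#' Subset the rows of a TowerDataset
#' @keywords internal
.subsetDataset <- function(ds, idx) {
  new("TowerDataset", features = ds@features[idx, , drop = FALSE],
      labels = ds@labels[idx], keys = ds@keys[idx, , drop = FALSE],
      keySets = ds@keySets, towerDims = ds@towerDims, task = ds@task)
}

#' Create a predictor specification
#'
#' @param family "linear" (glmnet ridge logistic/linear regression),
#'   "forest" (ranger random forest) or "boosted" (xgboost).
#' @param hyperparameters named list. linear: `lambda` (regularisation
#'   strength, default 0.1). forest: `num.trees` (300), `max.depth`
#'   (0 = unlimited). boosted: `nrounds` (150), `max_depth` (6), `eta`
#'   (0.1).
#' @param seed integer seed for stochastic families.
#' @return a [PredictorSpec-class].
#' @export
predictorSpec <- function(family = c("boosted", "forest", "linear"),
                          hyperparameters = list(), seed = 1L) {
  family <- match.arg(family)
  new("PredictorSpec", family = family, hyperparameters = hyperparameters,
      seed = as.integer(seed))
}

#' Default hyperparameter grid for a predictor family
#'
#' Grids used by [gridSearch()]: linear sweeps the regularisation strength
#' {0.01, 0.1, 1, 10}; forest sweeps trees {100, 300} x depth
#' {unlimited, 8, 16}; boosted sweeps trees {100, 300} x depth {3, 6} x
#' learning rate {0.05, 0.1}.
#'
#' @param family predictor family name.
#' @return list of hyperparameter lists.
#' @export
defaultGrid <- function(family = c("boosted", "forest", "linear")) {
  family <- match.arg(family)
  grid <- switch(family,
    linear = expand.grid(lambda = c(0.01, 0.1, 1, 10)),
    forest = expand.grid(num.trees = c(100, 300), max.depth = c(0, 8, 16)),
    boosted = expand.grid(nrounds = c(100, 300), max_depth = c(3, 6),
                          eta = c(0.05, 0.1)))
  lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train an N-tower predictor
#'
#' Fits the requested family on a [TowerDataset-class]. The returned
#' [TowerPredictor-class] records the tower dimensions and order, which are
#' verified at scoring time. Classification scores are monotone in the
#' predicted probability of the positive class; regression scores are
#' predicted targets. Deterministic given the spec's seed.
#'
#' @param ds a [TowerDataset-class]; for classification both classes must
#'   be present.
#' @param spec a [PredictorSpec-class].
#' @return a [TowerPredictor-class].
#' @export
trainPredictor <- function(ds, spec) {
  x <- ds@features; y <- ds@labels
  hp <- spec@hyperparameters
  classify <- ds@task == "classification"
  if (classify && length(unique(y)) < 2L)
    stop("classification dataset has a single class")
  model <- switch(spec@family,
    linear = {
      glmnet::glmnet(x, y, family = if (classify) "binomial" else "gaussian",
                     alpha = 0, lambda = hp$lambda %||% 0.1)
    },
    forest = {
      yy <- if (classify) factor(y, levels = c(0, 1)) else y
      ranger::ranger(x = as.data.frame(x), y = yy,
                     num.trees = hp$num.trees %||% 300,
                     max.depth = hp$max.depth %||% 0,
                     probability = classify,
                     seed = spec@seed, num.threads = 1)
    },
    boosted = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      params <- list(objective = if (classify) "binary:logistic"
                                 else "reg:squarederror",
                     max_depth = hp$max_depth %||% 6,
                     eta = hp$eta %||% 0.1,
                     nthread = 1, seed = spec@seed)
      xgboost::xgb.train(params = params, data = dtrain,
                         nrounds = hp$nrounds %||% 150, verbose = 0)
    })
  new("TowerPredictor", spec = spec, task = ds@task, model = model,
      towerDims = ds@towerDims)
}

#' Score feature rows with a trained tower predictor
#'
#' @param pred a [TowerPredictor-class].
#' @param newdata a feature matrix or a [TowerDataset-class]; its width and
#'   tower order must match the training contract.
#' @return numeric vector of scores.
#' @export
scorePredictor <- function(pred, newdata) {
  if (is(newdata, "TowerDataset")) {
    if (!identical(newdata@towerDims, pred@towerDims))
      stop("tower order/dimensions do not match the trained model")
    x <- newdata@features
  } else {
    x <- as.matrix(newdata)
    if (ncol(x) != sum(pred@towerDims))
      stop(sprintf("feature width %d does not match model width %d",
                   ncol(x), sum(pred@towerDims)))
  }
  switch(pred@spec@family,
    linear = as.numeric(stats::predict(pred@model, newx = x,
                                       type = "response")),
    forest = {
      p <- stats::predict(pred@model, data = as.data.frame(x),
                          num.threads = 1)$predictions
      if (pred@task == "classification") as.numeric(p[, "1"]) else as.numeric(p)
    },
    boosted = as.numeric(stats::predict(pred@model, xgboost::xgb.DMatrix(x))))
}

setMethod("show", "TowerPredictor", function(object) {
  cat(sprintf("TowerPredictor: %s %s, towers %s (width %d)\n",
              object@spec@family, object@task,
              paste(names(object@towerDims), collapse = "+"),
              sum(object@towerDims)))
})

#' Rank novel link predictions
#'
#' Scores every pair NOT positive in the binary target layer with a
#' trained two-tower predictor and returns the `topN` highest-scoring
#' candidates. Ties are broken lexicographically by (row id, column id).
#'
#' @param pred a trained [TowerPredictor-class] (classification).
#' @param embA,embB embeddings of the layer's row and column sets.
#' @param target binary [AssociationMatrix-class] of known links.
#' @param topN number of candidates to return (> 0).
#' @return data.frame with columns `rank`, `idA`, `idB`, `score`.
#' @export
rankNovelPredictions <- function(pred, embA, embB, target, topN = 10L) {
  if (topN <= 0) stop("topN must be positive")
  ds <- assemblePairDataset(embA, embB, target, negativePolicy = "all")
  novel <- ds@labels == 0
  if (!any(novel))
    return(data.frame(rank = integer(), idA = character(),
                      idB = character(), score = numeric()))
  sub <- .subsetDataset(ds, which(novel))
  sc <- scorePredictor(pred, sub)
  ord <- order(-sc, sub@keys$idA, sub@keys$idB, method = "radix")
  take <- utils::head(ord, topN)
  data.frame(rank = seq_along(take), idA = sub@keys$idA[take],
             idB = sub@keys$idB[take], score = sc[take],
             stringsAsFactors = FALSE)
}
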