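#' Area under the ROC curve
#'
#' Computed via the rank (Mann-Whitney) formulation: the probability that
#' a random positive outscores a random negative, with ties counting one
#' half. Exact for tied scores.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels of equal length; both classes must be present.
#' @return AUROC in [0, 1].
#' @examples
#' auroc(c(0.9, 0.8, 0.1, 0.2), c(1, 0, 0, 1))  # 0.75
#' @export
auroc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pearson correlation with degenerate-input checks
#'
#' @param x,y equal-length numeric vectors (length >= 3, nonzero variance).
#' @return product-moment correlation in [-1, 1].
#' @export
pearsonCor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  stats::cor(x, y, method = "pearson")
}

#' Spearman rank correlation (average ranks for ties)
#'
#' @inheritParams pearsonCor
#' @return rank correlation in [-1, 1].
#' @export
spearmanCor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  stats::cor(x, y, method = "spearman")
}

#' @rdname accessors
#' @export
setMethod("metrics", "EvalReport", function(x) x@metrics)

#' @rdname accessors
#' @export
setMethod("perUnit", "EvalReport", function(x) x@perUnit)

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (%s):\n", object@design))
  for (nm in names(object@metrics)) {
    v <- object@metrics[[nm]]
    if (is.numeric(v) && length(v) == 1)
      cat(sprintf("  %-22s %s\n", nm, format(v, digits = 4)))
  }
})

#' Stratified fold assignment
#' @keywords internal
.foldAssign <- function(labels, folds, seed, stratify) {
  n <- length(labels)
  set.seed(.substream(seed, "cv-folds"))
  fold <- integer(n)
  if (stratify) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(folds), n))
  }
  fold
}

#' k-fold cross-validation of a tower predictor
#'
#' Row-level partition of the dataset into `folds` folds (stratified by
#' label for classification); each fold is scored by a model trained on
#' the remaining folds. Reports per-fold and pooled metrics (AUROC for
#' classification; Pearson and Spearman correlation for regression), the
#' pooled value computed on the concatenated held-out scores.
#'
#' @param ds a [TowerDataset-class].
#' @param spec a [PredictorSpec-class].
#' @param folds number of folds (>= 2).
#' @param seed integer seed driving the partition.
#' @return an [EvalReport-class] with design "full_cv". The held-out
#'   scores are returned in `perUnit`'s attributes via `metrics$scores`.
#' @export
kfoldCV <- function(ds, spec, folds = 5L, seed = 1L) {
  if (folds < 2) stop("folds must be >= 2")
  classify <- ds@task == "classification"
  fold <- .foldAssign(ds@labels, folds, seed, stratify = classify)
  scores <- numeric(length(ds@labels))
  per <- vector("list", folds)
  for (kf in seq_len(folds)) {
    test <- which(fold == kf); train <- which(fold != kf)
    if (classify && length(unique(ds@labels[train])) < 2L)
      stop(sprintf("degenerate fold %d: single-class training data", kf))
    stopifnot(length(intersect(train, test)) == 0L)
    model <- trainPredictor(.subsetDataset(ds, train), spec)
    sc <- scorePredictor(model, .subsetDataset(ds, test))
    scores[test] <- sc
    per[[kf]] <- if (classify) {
      data.frame(fold = kf, n = length(test),
                 auroc = if (length(unique(ds@labels[test])) == 2L)
                   auroc(sc, ds@labels[test]) else NA_real_)
    } else {
      data.frame(fold = kf, n = length(test),
                 pearson = pearsonCor(sc, ds@labels[test]),
                 spearman = spearmanCor(sc, ds@labels[test]))
    }
  }
  per <- do.call(rbind, per)
  mets <- if (classify) {
    list(auroc = auroc(scores, ds@labels))
  } else {
    list(pearson = pearsonCor(scores, ds@labels),
         spearman = spearmanCor(scores, ds@labels))
  }
  mets$scores <- scores
  new("EvalReport", design = "full_cv", metrics = mets, perUnit = per,
      config = list(folds = folds, family = spec@family,
                    hyperparameters = spec@hyperparameters),
      seed = as.integer(seed))
}

#' Leave-one-node-out evaluation of a tower predictor
#'
#' Cold-start design: for each distinct node at the chosen tower position,
#' a model is trained on every row NOT involving that node (in any key
#' column of the same node set) and scores the rows that do involve it.
#' Per-node AUROC (classification) or correlations (regression) are
#' macro-averaged over nodes where they are defined; nodes with
#' single-class or degenerate test sets are reported but excluded from the
#' average.
#'
#' @param ds a [TowerDataset-class].
#' @param nodePosition index of the key column whose nodes are left out.
#' @param spec a [PredictorSpec-class].
#' @param nodes optional character subset of node ids to leave out
#'   (default: all distinct nodes at that position).
#' @return an [EvalReport-class] with design "loo_nodes".
#' @export
looNodes <- function(ds, nodePosition, spec, nodes = NULL) {
  if (nodePosition < 1 || nodePosition > ncol(ds@keys))
    stop("nodePosition out of range")
  classify <- ds@task == "classification"
  sameSet <- which(ds@keySets == ds@keySets[nodePosition])
  all_nodes <- unique(ds@keys[[nodePosition]])
  if (is.null(nodes)) nodes <- all_nodes
  else nodes <- intersect(nodes, all_nodes)
  per <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    involved <- Reduce(`|`, lapply(sameSet, function(j) ds@keys[[j]] == v))
    test <- which(ds@keys[[nodePosition]] == v)
    train <- which(!involved)
    if (!length(test)) next
    stopifnot(length(intersect(train, test)) == 0L)
    model <- trainPredictor(.subsetDataset(ds, train), spec)
    sc <- scorePredictor(model, .subsetDataset(ds, test))
    if (classify) {
      ok <- length(unique(ds@labels[test])) == 2L
      per[[i]] <- data.frame(node = v, n = length(test),
                             auroc = if (ok) auroc(sc, ds@labels[test])
                                     else NA_real_)
    } else {
      ok <- length(test) >= 3 && stats::sd(ds@labels[test]) > 0 &&
        stats::sd(sc) > 0
      per[[i]] <- data.frame(node = v, n = length(test),
                             pearson = if (ok) pearsonCor(sc, ds@labels[test])
                                       else NA_real_,
                             spearman = if (ok) spearmanCor(sc, ds@labels[test])
                                        else NA_real_,
                             auroc = if (length(unique(ds@labels[test] > 0)) == 2L)
                               auroc(sc, as.numeric(ds@labels[test] > 0))
                               else NA_real_)
    }
  }
  per <- do.call(rbind, per)
  mets <- if (classify) {
    list(macro_auroc = mean(per$auroc, na.rm = TRUE),
         n_undefined = sum(is.na(per$auroc)))
  } else {
    list(macro_pearson = mean(per$pearson, na.rm = TRUE),
         macro_spearman = mean(per$spearman, na.rm = TRUE),
         macro_auroc = mean(per$auroc, na.rm = TRUE),
         n_undefined = sum(is.na(per$auroc)))
  }
  new("EvalReport", design = "loo_nodes", metrics = mets, perUnit = per,
      config = list(nodePosition = nodePosition, family = spec@family,
                    hyperparameters = spec@hyperparameters,
                    nodes = nodes),
      seed = spec@seed)
}

#' Grid search over predictor hyperparameters
#'
#' Exhaustively evaluates each hyperparameter setting by [kfoldCV()] on
#' the supplied (training) dataset and returns the best spec by pooled
#' metric (AUROC for classification, Pearson for regression). Ties are
#' broken by grid order. Intended to be nested inside an outer split: pass
#' only the training portion.
#'
#' @param ds a [TowerDataset-class] (training data only).
#' @param family predictor family.
#' @param grid list of hyperparameter lists; default [defaultGrid()].
#' @param folds inner CV folds.
#' @param seed integer seed (inner partition and model seeds).
#' @return list with elements `spec` (best [PredictorSpec-class]),
#'   `report` (its inner-CV [EvalReport-class]) and `table` (per-setting
#'   metric data.frame).
#' @export
gridSearch <- function(ds, family, grid = defaultGrid(family), folds = 5L,
                       seed = 1L) {
  if (!length(grid)) stop("empty hyperparameter grid")
  best <- NULL; bestMetric <- -Inf; rows <- vector("list", length(grid))
  metricName <- if (ds@task == "classification") "auroc" else "pearson"
  for (i in seq_along(grid)) {
    spec <- predictorSpec(family, hyperparameters = grid[[i]], seed = seed)
    rep <- kfoldCV(ds, spec, folds = folds, seed = seed)
    val <- rep@metrics[[metricName]]
    rows[[i]] <- cbind(data.frame(setting = i), as.data.frame(grid[[i]]),
                       metric = val)
    if (val > bestMetric) {
      bestMetric <- val; best <- list(spec = spec, report = rep)
    }
  }
  c(best, list(table = do.call(rbind, rows)))
}

#' NMTF matrix-completion baseline evaluation
#'
#' Evaluates plain joint-NMTF matrix completion of a binary target layer
#' under four side-information configurations: "S" (target layer only),
#' "G" (plus layers incident to the target's row set), "D" (plus layers
#' incident to the column set), "G+D" (all incident layers).
#'
#' CV design: positive entries are split into `folds` folds; each fold's
#' positives are set to 0, the graph refit, and the reconstructed scores
#' of the masked positives compared (AUROC) against an equal-size seeded
#' sample of true-zero entries.
#'
#' LOO design: for each left-out node, all of its target-layer entries are
#' zeroed, the graph refit, and the node's reconstructed row scored
#' against its true edges; per-node AUROCs are macro-averaged. A
#' configuration with no side layers on the left-out axis cannot inform a
#' zeroed node at all, so the result is reported as undefined (NA) rather
#' than an error — matching the blank baseline cells of cold-start
#' comparisons.
#'
#' @param g a [MultipartiteGraph-class].
#' @param targetA,targetB node-set names of the binary target layer;
#'   `targetA` is the "G"/row side, `targetB` the "D"/column side.
#' @param layersConfig one of "S", "G", "D", "G+D".
#' @param design "cv" or "loo".
#' @param cfg a [FitConfig-class] for the NMTF fits.
#' @param seed integer seed (fold/negative sampling).
#' @param folds CV folds.
#' @param looSet node-set name to leave out (design = "loo").
#' @param nodes optional id subset for LOO.
#' @return an [EvalReport-class] with design "nmtf_cv" or "nmtf_loo".
#' @export
nmtfBaseline <- function(g, targetA, targetB,
                         layersConfig = c("S", "G", "D", "G+D"),
                         design = c("cv", "loo"), cfg = fitConfig(),
                         seed = 1L, folds = 5L, looSet = NULL,
                         nodes = NULL) {
  layersConfig <- match.arg(layersConfig)
  design <- match.arg(design)
  targetKey <- matrixKey(targetA, targetB)
  target <- getLayer(g, targetA, targetB)
  if (target@weighted) stop("target layer must be binary")
  keep <- list()
  for (key in names(g@matrices)) {
    m <- g@matrices[[key]]
    if (key == targetKey) { keep[[key]] <- m; next }
    touchesA <- targetA %in% c(m@rowSet, m@colSet)
    touchesB <- targetB %in% c(m@rowSet, m@colSet)
    wanted <- switch(layersConfig,
                     "S" = FALSE,
                     "G" = touchesA,
                     "D" = touchesB,
                     "G+D" = touchesA || touchesB)
    if (wanted) keep[[key]] <- m
  }
  gsub_ <- subGraph(g, unname(keep))
  cfgSnapshot <- list(layersConfig = layersConfig, folds = folds,
                      target = targetKey, layers = names(keep))

  if (design == "cv") {
    vals <- getLayer(gsub_, targetA, targetB)@values
    pos <- which(vals == 1)
    zero <- which(vals == 0)
    set.seed(.substream(seed, "baseline-folds"))
    fold <- sample(rep_len(seq_len(folds), length(pos)))
    scoresPos <- numeric(length(pos))
    per <- vector("list", folds)
    allScores <- c(); allLabels <- c()
    for (kf in seq_len(folds)) {
      masked <- pos[fold == kf]
      gm <- gsub_
      tm <- getLayer(gm, targetA, targetB)
      tv <- tm@values
      tv[masked] <- 0
      stopifnot(all(tv[masked] == 0))
      tm@values <- tv
      gm <- setLayer(gm, tm)
      fit <- fitNMTF(gm, cfg)
      rec <- reconstruct(fit@factors, tm@rowSet, tm@colSet)
      set.seed(.substream(seed + kf, "baseline-negatives"))
      negs <- sample(zero, min(length(zero), length(masked)))
      sc <- c(rec[masked], rec[negs])
      lb <- c(rep(1, length(masked)), rep(0, length(negs)))
      per[[kf]] <- data.frame(fold = kf, n = length(sc),
                              auroc = auroc(sc, lb))
      allScores <- c(allScores, sc); allLabels <- c(allLabels, lb)
    }
    per <- do.call(rbind, per)
    return(new("EvalReport", design = "nmtf_cv",
               metrics = list(auroc = auroc(allScores, allLabels),
                              mean_fold_auroc = mean(per$auroc)),
               perUnit = per, config = cfgSnapshot, seed = as.integer(seed)))
  }

  # LOO design
  if (is.null(looSet)) stop("looSet must be given for design = 'loo'")
  if (!looSet %in% c(targetA, targetB))
    stop("looSet must be one of the target layer's node sets")
  sideKeys <- setdiff(names(keep), targetKey)
  hasSide <- any(vapply(keep[sideKeys], function(m)
    looSet %in% c(m@rowSet, m@colSet), logical(1)))
  if (!hasSide) {
    return(new("EvalReport", design = "nmtf_loo",
               metrics = list(macro_auroc = NA_real_,
                              undefined = TRUE,
                              reason = sprintf(
                                "configuration %s has no side information for '%s'",
                                layersConfig, looSet)),
               perUnit = data.frame(), config = cfgSnapshot,
               seed = as.integer(seed)))
  }
  tm0 <- getLayer(gsub_, targetA, targetB)
  onRows <- tm0@rowSet == looSet
  ids <- if (onRows) rownames(tm0@values) else colnames(tm0@values)
  if (is.null(nodes)) nodes <- ids else nodes <- intersect(nodes, ids)
  per <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    gm <- gsub_
    tm <- getLayer(gm, targetA, targetB)
    tv <- tm@values
    truth <- if (onRows) tv[v, ] else tv[, v]
    if (onRows) tv[v, ] <- 0 else tv[, v] <- 0
    tm@values <- tv
    gm <- setLayer(gm, tm)
    fit <- fitNMTF(gm, cfg)
    rec <- reconstruct(fit@factors, tm@rowSet, tm@colSet)
    sc <- if (onRows) rec[v, ] else rec[, v]
    ok <- length(unique(truth)) == 2L
    per[[i]] <- data.frame(node = v, n = length(truth),
                           auroc = if (ok) auroc(sc, truth) else NA_real_)
  }
  per <- do.call(rbind, per)
  new("EvalReport", design = "nmtf_loo",
      metrics = list(macro_auroc = mean(per$auroc, na.rm = TRUE),
                     n_undefined = sum(is.na(per$auroc))),
      perUnit = per, config = c(cfgSnapshot, list(looSet = looSet)),
      seed = as.integer(seed))
}

#' Cold-start reconstruction scores for a masked node
#'
#' Zeroes every target-layer entry of one node, refits NMTF under the
#' chosen side-information configuration, and returns the node's
#' reconstructed scores. With the target-only ("S") configuration the
#' masked node's factor row receives a zero multiplicative numerator at
#' the first sweep, so all of its predicted scores collapse to (numerical)
#' zero — the cold-start failure mode of plain matrix completion.
#'
#' @inheritParams nmtfBaseline
#' @param node id of the node to mask (must belong to `targetA` or
#'   `targetB`).
#' @return named numeric vector of reconstructed scores for the node's
#'   row/column of the target layer.
#' @export
coldStartScores <- function(g, targetA, targetB, node,
                            layersConfig = "S", cfg = fitConfig()) {
  targetKey <- matrixKey(targetA, targetB)
  keep <- list()
  for (key in names(g@matrices)) {
    m <- g@matrices[[key]]
    if (key == targetKey) { keep[[key]] <- m; next }
    touchesA <- targetA %in% c(m@rowSet, m@colSet)
    touchesB <- targetB %in% c(m@rowSet, m@colSet)
    wanted <- switch(layersConfig, "S" = FALSE, "G" = touchesA,
                     "D" = touchesB, "G+D" = touchesA || touchesB)
    if (wanted) keep[[key]] <- m
  }
  gm <- subGraph(g, unname(keep))
  tm <- getLayer(gm, targetA, targetB)
  tv <- tm@values
  if (node %in% rownames(tv)) { tv[node, ] <- 0; onRows <- TRUE }
  else if (node %in% colnames(tv)) { tv[, node] <- 0; onRows <- FALSE }
  else stop(sprintf("node '%s' not found in the target layer", node))
  tm@values <- tv
  gm <- setLayer(gm, tm)
  fit <- fitNMTF(gm, cfg)
  rec <- reconstruct(fit@factors, tm@rowSet, tm@colSet)
  if (onRows) rec[node, ] else rec[, node]
}
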