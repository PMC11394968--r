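#' Isolate the one-hop star of a target node set
#'
#' Builds the sub-graph containing only the association matrices incident
#' to `target`, minus any layer linking the target to a set listed in
#' `exclude` (typically the other target set, so embeddings never see the
#' edges they will later be asked to predict). All retained layers are
#' oriented with the target set on columns, so the target's shared factor
#' plays the V role in every factorization.
#'
#' @param g a [MultipartiteGraph-class].
#' @param target node-set name to embed.
#' @param exclude character vector of set names whose layers with the
#'   target are dropped.
#' @return a [MultipartiteGraph-class] star (triplets dropped).
#' @export
isolateTargetStar <- function(g, target, exclude = character()) {
  mats <- orientToTarget(g, target)
  keep <- Filter(function(m) !(m@rowSet %in% exclude), mats)
  if (!length(keep))
    stop(sprintf("no side information for target '%s' after exclusions", target))
  subGraph(g, keep)
}

#' Learn shared-V NMTF embeddings for a target set
#'
#' Runs joint NMTF on a target star: because every layer has the target on
#' columns, all factorizations share the exact same V matrix — the
#' target's node factor — which fuses the information of all side layers.
#' Its rows (one per node, in frozen NodeSet order) are the embeddings.
#'
#' @param star a star graph from [isolateTargetStar()].
#' @param target the embedded node-set name.
#' @param k embedding dimension (must be < target set size).
#' @param cfg a [FitConfig-class]; its `ranks` entry is overridden to `k`
#'   for the target set. Side sets default to rank `k` as well unless the
#'   config names them explicitly. The default config enables
#'   `normalizeWeights`: side layers of very different scale (binary
#'   annotations next to continuous expression) would otherwise contribute
#'   to the shared V in proportion to their squared Frobenius norm rather
#'   than their information.
#' @return an [EmbeddingTable-class] with `method = "nmtf"`.
#' @export
fitSharedEmbeddings <- function(star, target, k,
                                cfg = fitConfig(normalizeWeights = TRUE)) {
  if (!target %in% names(star@nodeSets))
    stop(sprintf("unknown target set '%s'", target))
  sets <- names(star@nodeSets)
  sizes <- vapply(star@nodeSets, length, integer(1))
  ranks <- stats::setNames(rep(as.numeric(k), length(sets)), sets)
  if (!is.null(names(cfg@ranks))) {
    known <- intersect(names(cfg@ranks), sets)
    ranks[known] <- cfg@ranks[known]
  }
  ranks[target] <- k
  # side sets smaller than k+1 get the largest admissible rank
  ranks <- pmin(ranks, sizes - 1)
  if (ranks[target] < k) stop("k must be smaller than the target set size")
  cfg@ranks <- ranks
  fit <- fitNMTF(star, cfg)
  vectors <- fit@factors@nodeFactors[[target]]
  new("EmbeddingTable", nodeSet = target, k = as.integer(k),
      vectors = vectors, method = "nmtf",
      provenance = list(seed = cfg@seed, nRestarts = cfg@nRestarts,
                        maxIter = cfg@maxIter, tol = cfg@tol,
                        finalLoss = utils::tail(fit@lossTrace, 1),
                        converged = fit@converged,
                        layers = names(star@matrices)))
}

#' Truncated-SVD embeddings for a target set
#'
#' Baseline embedding method: stacks all star layers row-wise into one
#' matrix with the target on columns, computes the rank-k truncated SVD,
#' and takes the right singular vectors scaled by their singular values as
#' embeddings. Signs are fixed by making the largest-magnitude loading of
#' each component positive, so repeated runs are byte-identical.
#'
#' @param star a star graph from [isolateTargetStar()].
#' @param target the embedded node-set name.
#' @param k embedding dimension; must not exceed either dimension of the
#'   stacked matrix.
#' @return an [EmbeddingTable-class] with `method = "svd"`.
#' @export
svdEmbeddings <- function(star, target, k) {
  mats <- orientToTarget(star, target)
  stacked <- do.call(rbind, lapply(mats, function(m) m@values))
  if (k > min(dim(stacked)))
    stop(sprintf("k = %d exceeds the stacked matrix dimensions (%d x %d)",
                 k, nrow(stacked), ncol(stacked)))
  dec <- svd(stacked, nu = 0, nv = k)
  v <- dec$v
  for (j in seq_len(k)) {
    lead <- which.max(abs(v[, j]))
    if (v[lead, j] < 0) v[, j] <- -v[, j]
  }
  vectors <- v %*% diag(dec$d[seq_len(k)], k)
  rownames(vectors) <- colnames(stacked)
  new("EmbeddingTable", nodeSet = target, k = as.integer(k),
      vectors = vectors, method = "svd",
      provenance = list(layers = names(star@matrices)))
}

#' @rdname accessors
#' @export
setMethod("embeddingMatrix", "EmbeddingTable", function(x) x@vectors)

#' @rdname accessors
#' @export
setMethod("nodeIds", "EmbeddingTable", function(x, ...) rownames(x@vectors))

setMethod("show", "EmbeddingTable", function(object) {
  cat(sprintf("EmbeddingTable: %d nodes of '%s', k = %d (%s)\n",
              nrow(object@vectors), object@nodeSet, object@k, object@method))
})
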