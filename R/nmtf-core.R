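#' Create an NMTF fit configuration
#'
#' @param ranks per-node-set factor ranks: a single value applied to every
#'   set, or a named vector. Each rank must be below the set size.
#' @param maxIter maximum multiplicative-update sweeps (default 1000).
#' @param tol relative loss-change stop tolerance (default 1e-6).
#' @param checkEvery sweeps between convergence checks (default 10).
#' @param seed integer seed for random initialisation.
#' @param nRestarts number of random restarts; lowest final loss wins.
#' @param matrixWeights optional named per-layer weights (canonical pair
#'   keys, see [matrixKey()]); unspecified layers weigh 1.
#' @param eps denominator floor for the multiplicative rules.
#' @param normalizeWeights divide each layer's weight by its squared
#'   Frobenius norm (counteracts large layers dominating the loss).
#' @param logTransform apply log1p to weighted layers before fitting.
#' @return a [FitConfig-class].
#' @export
fitConfig <- function(ranks = 10, maxIter = 1000L, tol = 1e-6,
                      checkEvery = 10L, seed = 1L, nRestarts = 5L,
                      matrixWeights = numeric(), eps = 1e-10,
                      normalizeWeights = FALSE, logTransform = FALSE) {
  new("FitConfig", ranks = ranks, maxIter = as.integer(maxIter), tol = tol,
      checkEvery = as.integer(checkEvery), seed = as.integer(seed),
      nRestarts = as.integer(nRestarts), matrixWeights = matrixWeights,
      eps = eps, normalizeWeights = normalizeWeights,
      logTransform = logTransform)
}

#' Resolve the per-set ranks of a config against a graph
#' @keywords internal
.resolveRanks <- function(g, cfg) {
  sets <- names(g@nodeSets)
  if (is.null(names(cfg@ranks))) {
    if (length(cfg@ranks) != 1L)
      stop("unnamed 'ranks' must be a single global value")
    ranks <- stats::setNames(rep(cfg@ranks, length(sets)), sets)
  } else {
    missing <- setdiff(sets, names(cfg@ranks))
    if (length(missing))
      stop(sprintf("no rank given for node set(s): %s",
                   paste(missing, collapse = ", ")))
    ranks <- cfg@ranks[sets]
  }
  sizes <- vapply(g@nodeSets, length, integer(1))
  bad <- ranks >= sizes
  if (any(bad))
    stop(sprintf("rank must be < set size; violated for: %s",
                 paste(sets[bad], collapse = ", ")))
  ranks
}

#' Resolve effective per-layer weights
#' @keywords internal
.resolveWeights <- function(g, cfg) {
  keys <- names(g@matrices)
  w <- stats::setNames(rep(1, length(keys)), keys)
  if (length(cfg@matrixWeights)) {
    known <- intersect(names(cfg@matrixWeights), keys)
    w[known] <- cfg@matrixWeights[known]
  }
  if (cfg@normalizeWeights) {
    for (key in keys) {
      f2 <- sum(g@matrices[[key]]@values^2)
      if (f2 > 0) w[key] <- w[key] / f2
    }
  }
  w
}

#' Apply the configured pre-transform to weighted layers
#' @keywords internal
.preTransform <- function(g, cfg) {
  if (!cfg@logTransform) return(g)
  for (key in names(g@matrices)) {
    m <- g@matrices[[key]]
    if (m@weighted) {
      m@values <- log1p(m@values)
      g@matrices[[key]] <- m
    }
  }
  g
}

#' Randomly initialise an NMTF factor set
#'
#' Every factor and core entry is drawn i.i.d. uniform on (0,1); each node
#' factor is then scaled by sqrt(mean(R)/k) over its incident layers so
#' initial reconstructions match the data's magnitude. Core matrices are
#' drawn in the canonical (alphabetical) orientation of their pair key and
#' transposed into storage orientation, so initialisation is invariant to
#' how a layer happens to be stored. Fully deterministic given `cfg@seed`.
#'
#' @param g a valid [MultipartiteGraph-class].
#' @param cfg a [FitConfig-class]; ranks must be below set sizes.
#' @return a [FactorSet-class].
#' @export
initFactors <- function(g, cfg) {
  ranks <- .resolveRanks(g, cfg)
  set.seed(.substream(cfg@seed, "nmtf-init"))
  # draw in sorted-name order so initialisation (and hence the whole fit)
  # does not depend on how the graph happens to order its sets or layers
  sets <- sort(names(g@nodeSets))
  nodeFactors <- list()
  for (s in sets) {
    n <- length(g@nodeSets[[s]]@ids)
    k <- ranks[[s]]
    f <- matrix(stats::runif(n * k), n, k)
    inc <- Filter(function(m) m@rowSet == s || m@colSet == s, g@matrices)
    if (length(inc)) {
      mn <- mean(unlist(lapply(inc, function(m) mean(m@values))))
      f <- f * sqrt(mn / k)
    }
    rownames(f) <- g@nodeSets[[s]]@ids
    nodeFactors[[s]] <- f
  }
  nodeFactors <- nodeFactors[names(g@nodeSets)]
  cores <- list(); orientation <- list()
  for (key in sort(names(g@matrices))) {
    m <- g@matrices[[key]]
    canon <- sort(c(m@rowSet, m@colSet))
    s <- matrix(stats::runif(ranks[[canon[1]]] * ranks[[canon[2]]]),
                ranks[[canon[1]]], ranks[[canon[2]]])
    if (m@rowSet != canon[1]) s <- t(s)
    cores[[key]] <- s
    orientation[[key]] <- c(m@rowSet, m@colSet)
  }
  cores <- cores[names(g@matrices)]
  orientation <- orientation[names(g@matrices)]
  new("FactorSet", nodeFactors = nodeFactors, cores = cores,
      orientation = orientation, ranks = ranks)
}

#' @rdname accessors
#' @export
setMethod("nodeFactor", "FactorSet", function(x, set) {
  f <- x@nodeFactors[[set]]
  if (is.null(f)) stop(sprintf("no factor for node set '%s'", set))
  f
})

#' @rdname accessors
#' @export
setMethod("coreMatrix", "FactorSet", function(x, a, b) {
  s <- x@cores[[matrixKey(a, b)]]
  if (is.null(s)) stop(sprintf("no core for layer '%s'", matrixKey(a, b)))
  s
})

setMethod("show", "FactorSet", function(object) {
  cat(sprintf("FactorSet: %d node factors, %d cores\n",
              length(object@nodeFactors), length(object@cores)))
  for (s in names(object@nodeFactors))
    cat(sprintf("  %-12s %5d x %d\n", s, nrow(object@nodeFactors[[s]]),
                ncol(object@nodeFactors[[s]])))
})

#' Joint NMTF reconstruction loss
#'
#' Sum over layers of the weighted squared Frobenius reconstruction error
#' `w_i * ||R_i - U_i S_i V_i'||^2`, where U_i and V_i are the shared node
#' factors of the layer's row and column sets.
#'
#' @param g a [MultipartiteGraph-class].
#' @param f a [FactorSet-class] with factors for all sets in `g`.
#' @param weights optional named per-layer weights; default all 1.
#' @return non-negative scalar loss.
#' @export
nmtfLoss <- function(g, f, weights = NULL) {
  total <- 0
  for (key in names(g@matrices)) {
    m <- g@matrices[[key]]
    w <- if (is.null(weights)) 1 else weights[[key]]
    if (is.null(w)) w <- 1
    rec <- f@nodeFactors[[m@rowSet]] %*% f@cores[[key]] %*%
      t(f@nodeFactors[[m@colSet]])
    total <- total + w * sum((m@values - rec)^2)
  }
  total
}

#' One multiplicative-update sweep
#'
#' Applies the joint-NMTF multiplicative rules once: for each node set X
#' (in graph order), its factor is multiplied elementwise by the ratio of
#' aggregated numerator and denominator terms over ALL layers incident to
#' X, the factor playing the U role where X indexes rows and the V role
#' where X indexes columns; then every core S_XY is updated by
#' `S <- S * (U' R V) / (U' U S V' V)`. Denominators are floored at
#' `cfg@eps`, which leaves exact fixed points untouched while keeping the
#' rules defined where a denominator vanishes. Per-layer weights multiply
#' each layer's contribution to both numerator and denominator.
#' Non-negativity and exact zeros of the factors are preserved.
#'
#' @param g a [MultipartiteGraph-class].
#' @param f current [FactorSet-class] (non-negative).
#' @param cfg a [FitConfig-class] (supplies `eps` and layer weights).
#' @param weights optional resolved per-layer weights; computed from `cfg`
#'   when NULL.
#' @param which update `"both"` (default), only `"nodes"`, or only
#'   `"cores"`.
#' @return the updated [FactorSet-class].
#' @export
updateFactors <- function(g, f, cfg, weights = NULL,
                          which = c("both", "nodes", "cores")) {
  which <- match.arg(which)
  if (is.null(weights)) weights <- .resolveWeights(g, cfg)
  eps <- cfg@eps
  keys <- sort(names(g@matrices))
  if (which %in% c("both", "nodes")) {
    for (s in sort(names(f@nodeFactors))) {
      G <- f@nodeFactors[[s]]
      num <- matrix(0, nrow(G), ncol(G))
      den <- matrix(0, nrow(G), ncol(G))
      touched <- FALSE
      for (key in keys) {
        m <- g@matrices[[key]]
        if (m@rowSet == s) {          # U role: R = G S Gy'
          Gy <- f@nodeFactors[[m@colSet]]
          S <- f@cores[[key]]
          w <- weights[[key]]
          num <- num + w * (m@values %*% Gy %*% t(S))
          den <- den + w * (G %*% (S %*% crossprod(Gy) %*% t(S)))
          touched <- TRUE
        } else if (m@colSet == s) {   # V role: R = Gy S G'
          Gy <- f@nodeFactors[[m@rowSet]]
          S <- f@cores[[key]]
          w <- weights[[key]]
          num <- num + w * (crossprod(m@values, Gy) %*% S)
          den <- den + w * (G %*% (t(S) %*% crossprod(Gy) %*% S))
          touched <- TRUE
        }
      }
      if (!touched) next
      G <- G * num / pmax(den, eps)
      if (any(!is.finite(G)))
        stop(sprintf("numerical error: non-finite values in factor for set '%s'", s))
      f@nodeFactors[[s]] <- G
    }
  }
  if (which %in% c("both", "cores")) {
    for (key in keys) {
      m <- g@matrices[[key]]
      U <- f@nodeFactors[[m@rowSet]]
      V <- f@nodeFactors[[m@colSet]]
      S <- f@cores[[key]]
      num <- crossprod(U, m@values %*% V)
      den <- crossprod(U) %*% S %*% crossprod(V)
      S <- S * num / pmax(den, eps)
      if (any(!is.finite(S)))
        stop(sprintf("numerical error: non-finite values in core for layer '%s'", key))
      f@cores[[key]] <- S
    }
  }
  f
}

#' Fit joint NMTF on a multipartite graph
#'
#' Random initialisation followed by multiplicative-update sweeps until
#' the relative change of the total loss between consecutive checks falls
#' below `tol` or `maxIter` is reached. With `nRestarts > 1`, independent
#' seeded restarts are run and the one with lowest final loss is returned.
#'
#' @param g a valid [MultipartiteGraph-class] with at least one layer.
#' @param cfg a [FitConfig-class].
#' @param init optional [FactorSet-class] initial point; when supplied,
#'   restarts are disabled and the fit is fully deterministic in `init`.
#' @return a [FitResult-class].
#' @examples
#' spec <- syntheticSpec(nGenes = 20, nDrugs = 15, nCells = 5,
#'                       geneSide = c(GO = 8), drugSide = c(ATC = 8),
#'                       rank = 2, seed = 7)
#' g <- simulateMultipartite(spec)$graph
#' fit <- fitNMTF(g, fitConfig(ranks = 2, maxIter = 50, nRestarts = 1, seed = 7))
#' utils::tail(lossTrace(fit), 1)
#' @export
fitNMTF <- function(g, cfg, init = NULL) {
  if (!length(g@matrices)) stop("graph has no association matrices")
  g <- .preTransform(g, cfg)
  weights <- .resolveWeights(g, cfg)
  runOne <- function(seed, f0) {
    f <- if (is.null(f0)) {
      c1 <- cfg; c1@seed <- as.integer(seed)
      initFactors(g, c1)
    } else f0
    trace <- nmtfLoss(g, f, weights)
    iter <- 0L
    converged <- FALSE
    while (iter < cfg@maxIter) {
      nSweeps <- min(cfg@checkEvery, cfg@maxIter - iter)
      for (i in seq_len(nSweeps)) f <- updateFactors(g, f, cfg, weights)
      iter <- iter + nSweeps
      cur <- nmtfLoss(g, f, weights)
      trace <- c(trace, cur)
      prev <- trace[length(trace) - 1L]
      if (abs(prev - cur) / max(prev, cfg@eps) < cfg@tol) {
        converged <- TRUE
        break
      }
    }
    list(f = f, trace = trace, converged = converged, iter = iter,
         seed = as.integer(seed))
  }
  if (!is.null(init)) {
    best <- runOne(cfg@seed, init)
  } else {
    best <- NULL
    for (r in seq_len(cfg@nRestarts)) {
      res <- runOne(cfg@seed + r - 1L, NULL)
      if (is.null(best) ||
          res$trace[length(res$trace)] < best$trace[length(best$trace)])
        best <- res
    }
  }
  new("FitResult", factors = best$f, lossTrace = best$trace,
      converged = best$converged, iterations = best$iter,
      seedUsed = best$seed)
}

#' @rdname accessors
#' @export
setMethod("lossTrace", "FitResult", function(x) x@lossTrace)

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: %d sweeps, %sconverged, final loss %.6g (seed %d)\n",
              object@iterations, if (object@converged) "" else "NOT ",
              utils::tail(object@lossTrace, 1), object@seedUsed))
})

#' Reconstruct one layer from fitted factors
#'
#' Returns the matrix-completion estimate `U S V'` of a layer. Entries at
#' positions that were zero in the data are the model's predictions for
#' unobserved associations.
#'
#' @param f a [FactorSet-class] (e.g. `fit@factors`).
#' @param a,b node-set names of the layer (order irrelevant; the result is
#'   oriented with `a` on rows).
#' @return non-negative numeric matrix with node ids as dimnames.
#' @export
reconstruct <- function(f, a, b) {
  key <- matrixKey(a, b)
  S <- f@cores[[key]]
  if (is.null(S)) stop(sprintf("unknown layer '%s'", key))
  ori <- f@orientation[[key]]
  rec <- f@nodeFactors[[ori[1]]] %*% S %*% t(f@nodeFactors[[ori[2]]])
  if (ori[1] != a) rec <- t(rec)
  rec
}

#' Predict association scores for node pairs
#'
#' Looks up reconstructed values `R~[x, y]` for a list of (row id, col id)
#' pairs of a fitted layer; output order matches input order.
#'
#' @param f a [FactorSet-class].
#' @param a,b node-set names of the layer; pair ids are interpreted as
#'   (`a` id, `b` id).
#' @param pairs data.frame or 2-column matrix of (row id, col id).
#' @return numeric vector of scores.
#' @export
predictScores <- function(f, a, b, pairs) {
  rec <- reconstruct(f, a, b)
  pairs <- as.data.frame(pairs)
  ri <- match(as.character(pairs[[1]]), rownames(rec))
  ci <- match(as.character(pairs[[2]]), colnames(rec))
  if (any(is.na(ri)))
    stop(sprintf("unresolved id(s) in set '%s': %s", a,
                 paste(utils::head(unique(pairs[[1]][is.na(ri)]), 5), collapse = ", ")))
  if (any(is.na(ci)))
    stop(sprintf("unresolved id(s) in set '%s': %s", b,
                 paste(utils::head(unique(pairs[[2]][is.na(ci)]), 5), collapse = ", ")))
  rec[cbind(ri, ci)]
}
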