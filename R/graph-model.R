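#' Create a NodeSet
#'
#' @param name semantic category label (e.g. "Genes").
#' @param ids character vector of unique node identifiers; their order is
#'   frozen and defines matrix row/column positions.
#' @return a [NodeSet-class] object.
#' @examples
#' genes <- nodeSet("Genes", c("g1", "g2", "g3"))
#' nodeIds(genes)
#' @export
nodeSet <- function(name, ids) {
  new("NodeSet", name = name, ids = as.character(ids))
}

#' @rdname accessors
#' @export
setMethod("nodeIds", "NodeSet", function(x, ...) x@ids)

setMethod("length", "NodeSet", function(x) length(x@ids))

setMethod("show", "NodeSet", function(object) {
  cat(sprintf("NodeSet '%s' with %d nodes\n", object@name, length(object@ids)))
})

#' Canonical key for an unordered node-set pair
#'
#' Layers are stored once per unordered pair; the key is the two set names
#' sorted and joined by "~", so `matrixKey("Genes","Drugs")` and
#' `matrixKey("Drugs","Genes")` coincide.
#'
#' @param a,b node-set names.
#' @return single string key.
#' @export
matrixKey <- function(a, b) paste(sort(c(a, b)), collapse = "~")

#' Build an association matrix from an edge list
#'
#' @param edges data.frame with columns `row`, `col` and optionally
#'   `weight` (default 1). Each row is one edge. Duplicate (row, col) pairs
#'   collapse to a single entry, last occurrence winning, with a warning.
#' @param rows,cols [NodeSet-class] objects indexing rows and columns.
#' @param weighted logical; if `FALSE` all weights must be 0 or 1.
#' @param relation free-text semantic label for the edge type.
#' @return an [AssociationMatrix-class].
#' @examples
#' g <- nodeSet("Genes", c("g1", "g2")); d <- nodeSet("Drugs", "d1")
#' m <- buildAssociationMatrix(data.frame(row = "g1", col = "d1"), g, d)
#' layerValues(m)
#' @export
buildAssociationMatrix <- function(edges, rows, cols, weighted = FALSE,
                                   relation = "") {
  stopifnot(is.data.frame(edges))
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  if (nrow(edges)) {
    badr <- setdiff(edges$row, rows@ids)
    if (length(badr))
      stop(sprintf("unknown id(s) in row set '%s': %s", rows@name,
                   paste(utils::head(badr, 5), collapse = ", ")))
    badc <- setdiff(edges$col, cols@ids)
    if (length(badc))
      stop(sprintf("unknown id(s) in column set '%s': %s", cols@name,
                   paste(utils::head(badc, 5), collapse = ", ")))
    if (any(edges$weight < 0)) stop("edge weights must be non-negative")
    if (!weighted && !all(edges$weight %in% c(0, 1)))
      stop("unweighted layer accepts only weights 0 or 1")
  }
  v <- matrix(0, length(rows@ids), length(cols@ids),
              dimnames = list(rows@ids, cols@ids))
  if (nrow(edges)) {
    dup <- duplicated(edges[, c("row", "col")], fromLast = TRUE)
    if (any(dup)) {
      warning(sprintf("%d duplicate edge(s) collapsed (last occurrence kept)",
                      sum(dup)))
      edges <- edges[!dup, , drop = FALSE]
    }
    v[cbind(match(edges$row, rows@ids), match(edges$col, cols@ids))] <-
      edges$weight
  }
  new("AssociationMatrix", rowSet = rows@name, colSet = cols@name,
      values = v, weighted = weighted, relation = relation,
      transposed = FALSE)
}

#' @rdname accessors
#' @export
setMethod("layerValues", "AssociationMatrix", function(x, ...) x@values)

setMethod("dim", "AssociationMatrix", function(x) dim(x@values))

setMethod("show", "AssociationMatrix", function(object) {
  cat(sprintf("AssociationMatrix %s x %s (%d x %d), %s%s, %d nonzero\n",
              object@rowSet, object@colSet, nrow(object@values),
              ncol(object@values),
              if (object@weighted) "weighted" else "binary",
              if (object@transposed) ", transposed" else "",
              sum(object@values != 0)))
})

#' Transpose an association layer
#'
#' Swaps row and column sets; the `transposed` orientation flag is toggled
#' so a double transpose restores the original metadata.
#' @param x an [AssociationMatrix-class].
#' @export
setMethod("t", "AssociationMatrix", function(x) {
  new("AssociationMatrix", rowSet = x@colSet, colSet = x@rowSet,
      values = t(x@values), weighted = x@weighted, relation = x@relation,
      transposed = !x@transposed)
})

#' Create a TripletTable
#'
#' @param records data.frame with columns `cell`, `drugA`, `drugB`, `zip`.
#' @param cellSet,drugSet node-set names the ids belong to.
#' @return a [TripletTable-class].
#' @export
tripletTableFromRecords <- function(records, cellSet = "Cells",
                                    drugSet = "Drugs") {
  records <- as.data.frame(records)
  records$cell <- as.character(records$cell)
  records$drugA <- as.character(records$drugA)
  records$drugB <- as.character(records$drugB)
  records$zip <- as.numeric(records$zip)
  new("TripletTable", cellSet = cellSet, drugSet = drugSet,
      records = records)
}

setMethod("show", "TripletTable", function(object) {
  cat(sprintf("TripletTable (%s, %s, %s): %d records\n", object@cellSet,
              object@drugSet, object@drugSet, nrow(object@records)))
})

#' Assemble a multipartite graph
#'
#' @param nodeSetList list of [NodeSet-class] objects.
#' @param matrixList list of [AssociationMatrix-class] layers (at most one
#'   per unordered set pair).
#' @param triplets optional [TripletTable-class].
#' @return a [MultipartiteGraph-class].
#' @export
multipartiteGraph <- function(nodeSetList, matrixList = list(),
                              triplets = NULL) {
  names(nodeSetList) <- vapply(nodeSetList, function(s) s@name, character(1))
  names(matrixList) <- vapply(matrixList,
                              function(m) matrixKey(m@rowSet, m@colSet),
                              character(1))
  if (!is.null(triplets)) {
    ns <- names(nodeSetList)
    if (!all(c(triplets@cellSet, triplets@drugSet) %in% ns))
      stop("triplet table references unknown node sets")
    r <- triplets@records
    if (nrow(r)) {
      if (!all(r$cell %in% nodeSetList[[triplets@cellSet]]@ids))
        stop("triplet table contains unknown cell ids")
      if (!all(c(r$drugA, r$drugB) %in% nodeSetList[[triplets@drugSet]]@ids))
        stop("triplet table contains unknown drug ids")
    }
  }
  new("MultipartiteGraph", nodeSets = nodeSetList, matrices = matrixList,
      triplets = triplets)
}

#' @rdname accessors
#' @export
setMethod("nodeSets", "MultipartiteGraph", function(x) x@nodeSets)

#' @rdname accessors
#' @export
setMethod("nodeSetNames", "MultipartiteGraph", function(x) names(x@nodeSets))

#' @rdname accessors
#' @export
setMethod("associationMatrices", "MultipartiteGraph", function(x) x@matrices)

#' @rdname accessors
#' @export
setMethod("tripletTable", "MultipartiteGraph", function(x) x@triplets)

#' @rdname accessors
#' @export
setMethod("nodeIds", "MultipartiteGraph", function(x, set) {
  if (!set %in% names(x@nodeSets)) stop(sprintf("unknown node set '%s'", set))
  x@nodeSets[[set]]@ids
})

#' Retrieve one layer of a graph
#'
#' @param g a [MultipartiteGraph-class].
#' @param a,b node-set names of the layer (order irrelevant).
#' @return the stored [AssociationMatrix-class].
#' @export
getLayer <- function(g, a, b) {
  key <- matrixKey(a, b)
  m <- g@matrices[[key]]
  if (is.null(m)) stop(sprintf("no layer between '%s' and '%s'", a, b))
  m
}

#' Replace one layer of a graph
#'
#' @param g a [MultipartiteGraph-class].
#' @param m the replacement [AssociationMatrix-class]; the pair must
#'   already exist (or be new) and reference sets in the graph.
#' @export
setLayer <- function(g, m) {
  g@matrices[[matrixKey(m@rowSet, m@colSet)]] <- m
  validObject(g)
  g
}

setMethod("show", "MultipartiteGraph", function(object) {
  cat(sprintf("MultipartiteGraph: %d node sets, %d layers%s\n",
              length(object@nodeSets), length(object@matrices),
              if (is.null(object@triplets)) ""
              else sprintf(", %d synergy triplets", nrow(object@triplets@records))))
  for (s in object@nodeSets)
    cat(sprintf("  %-12s %5d nodes\n", s@name, length(s@ids)))
  for (m in object@matrices)
    cat(sprintf("  layer %s~%s: %d x %d, %s\n", m@rowSet, m@colSet,
                nrow(m@values), ncol(m@values),
                if (m@weighted) "weighted" else "binary"))
})

#' Validate a multipartite graph
#'
#' Reporting counterpart of the class validity check: collects all
#' violations (duplicate set names, shape mismatches, negative entries,
#' non-binary unweighted layers, unresolved triplet ids) instead of
#' erroring, so callers can inspect or escalate.
#'
#' @param g a [MultipartiteGraph-class] (validity not assumed).
#' @return character vector of violation messages; empty iff valid.
#' @export
validateGraph <- function(g) {
  out <- character()
  nm <- vapply(g@nodeSets, function(s) s@name, character(1))
  if (anyDuplicated(nm))
    out <- c(out, sprintf("duplicate node-set name(s): %s",
                          paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  for (s in g@nodeSets)
    if (anyDuplicated(s@ids))
      out <- c(out, sprintf("duplicate ids within node set '%s'", s@name))
  for (m in g@matrices) {
    lab <- sprintf("%s~%s", m@rowSet, m@colSet)
    if (!all(c(m@rowSet, m@colSet) %in% nm)) {
      out <- c(out, sprintf("layer %s references unknown node set(s)", lab))
      next
    }
    if (nrow(m@values) != length(g@nodeSets[[m@rowSet]]@ids) ||
        ncol(m@values) != length(g@nodeSets[[m@colSet]]@ids))
      out <- c(out, sprintf("layer %s has wrong shape", lab))
    if (any(m@values < 0))
      out <- c(out, sprintf("layer %s has negative entries", lab))
    if (!m@weighted && !all(m@values %in% c(0, 1)))
      out <- c(out, sprintf("binary layer %s has non-binary entries", lab))
  }
  if (!is.null(g@triplets)) {
    r <- g@triplets@records
    cs <- g@triplets@cellSet; ds <- g@triplets@drugSet
    if (!all(c(cs, ds) %in% nm)) {
      out <- c(out, "triplet table references unknown node sets")
    } else if (nrow(r)) {
      if (!all(r$cell %in% g@nodeSets[[cs]]@ids))
        out <- c(out, "triplet table has unresolved cell ids")
      if (!all(c(r$drugA, r$drugB) %in% g@nodeSets[[ds]]@ids))
        out <- c(out, "triplet table has unresolved drug ids")
      if (any(r$drugA == r$drugB))
        out <- c(out, "triplet table has records with drugA == drugB")
    }
  }
  out
}

#' Orient all layers incident to a target set
#'
#' Returns every association matrix touching `target`, transposed where
#' necessary so the target set indexes columns in all of them (the
#' rearrangement used before learning target embeddings, where every
#' associated set sits on the left of the target). The graph itself is not
#' modified; the `transposed` flag on each returned layer records whether
#' a transpose occurred.
#'
#' @param g a [MultipartiteGraph-class].
#' @param target node-set name.
#' @return list of [AssociationMatrix-class], all with `colSet == target`.
#' @export
orientToTarget <- function(g, target) {
  if (!target %in% names(g@nodeSets))
    stop(sprintf("unknown node set '%s'", target))
  out <- list()
  for (m in g@matrices) {
    if (m@colSet == target) out[[length(out) + 1L]] <- m
    else if (m@rowSet == target) out[[length(out) + 1L]] <- t(m)
  }
  if (!length(out))
    stop(sprintf("isolated target set '%s': no incident association matrix",
                 target))
  out
}

#' Prune low-degree nodes from one axis of a layer
#'
#' Removes nodes on the chosen axis with fewer than `minDegree` nonzero
#' entries (e.g. keeping only drugs linked to at least one target gene);
#' the other axis is untouched and kept ids preserve original order.
#'
#' @param m an [AssociationMatrix-class].
#' @param axis "rows" or "cols".
#' @param minDegree non-negative integer degree threshold.
#' @return list with elements `matrix` (pruned layer) and `kept`
#'   (character ids retained, in original order).
#' @export
pruneMinDegree <- function(m, axis = c("rows", "cols"), minDegree = 1L) {
  axis <- match.arg(axis)
  stopifnot(minDegree >= 0)
  deg <- if (axis == "rows") rowSums(m@values != 0) else colSums(m@values != 0)
  keep <- deg >= minDegree
  if (!any(keep)) stop("empty matrix after pruning")
  v <- if (axis == "rows") m@values[keep, , drop = FALSE]
       else m@values[, keep, drop = FALSE]
  list(matrix = new("AssociationMatrix", rowSet = m@rowSet, colSet = m@colSet,
                    values = v, weighted = m@weighted, relation = m@relation,
                    transposed = m@transposed),
       kept = names(deg)[keep])
}

#' Restrict a graph to a subset of node sets and layers
#'
#' @param g a [MultipartiteGraph-class].
#' @param matrixList list of [AssociationMatrix-class] to retain; node sets
#'   are restricted to those referenced. Triplets are dropped.
#' @keywords internal
subGraph <- function(g, matrixList) {
  used <- unique(unlist(lapply(matrixList, function(m) c(m@rowSet, m@colSet))))
  multipartiteGraph(g@nodeSets[used], matrixList)
}
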