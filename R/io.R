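# Format doubles with enough digits for exact round-trips through text.
.fmtNum <- function(x) sprintf("%.17g", x)

#' Write a multipartite graph as TSV files
#'
#' Writes `nodes.tsv` (`set_name`, `node_id`; row order is the frozen
#' node order), `edges.tsv` (`row_set`, `row_id`, `col_set`, `col_id`,
#' `weight`), `layers.tsv` (per-layer `row_set`, `col_set`, `weighted`,
#' `relation`) and, when present, `triplets.tsv` (`cell_id`, `drug_a`,
#' `drug_b`, `zip`). [readGraphTSV()] reloads the directory
#' value-identically.
#'
#' @param g a [MultipartiteGraph-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeGraphTSV <- function(g, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nodes <- do.call(rbind, lapply(g@nodeSets, function(s)
    data.frame(set_name = s@name, node_id = s@ids, stringsAsFactors = FALSE)))
  utils::write.table(nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  edges <- do.call(rbind, lapply(g@matrices, function(m) {
    nz <- which(m@values != 0, arr.ind = TRUE)
    if (!nrow(nz)) return(NULL)
    nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
    data.frame(row_set = m@rowSet, row_id = rownames(m@values)[nz[, 1]],
               col_set = m@colSet, col_id = colnames(m@values)[nz[, 2]],
               weight = .fmtNum(m@values[nz]), stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(row_set = character(), row_id = character(),
                        col_set = character(), col_id = character(),
                        weight = numeric())
  utils::write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  layers <- do.call(rbind, lapply(g@matrices, function(m)
    data.frame(row_set = m@rowSet, col_set = m@colSet,
               weighted = m@weighted, relation = m@relation,
               stringsAsFactors = FALSE)))
  if (is.null(layers))
    layers <- data.frame(row_set = character(), col_set = character(),
                         weighted = logical(), relation = character())
  utils::write.table(layers, file.path(dir, "layers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(g@triplets)) {
    r <- g@triplets@records
    utils::write.table(
      data.frame(cell_id = r$cell, drug_a = r$drugA, drug_b = r$drugB,
                 zip = .fmtNum(r$zip), stringsAsFactors = FALSE),
      file.path(dir, "triplets.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(dir)
}

#' Read a multipartite graph from a TSV directory
#'
#' Counterpart of [writeGraphTSV()]; also accepts hand-built directories.
#' `layers.tsv` is optional: without it every observed (row_set, col_set)
#' pair in `edges.tsv` becomes an unweighted layer (weighted if any edge
#' weight is not 0/1). A missing `weight` column defaults to 1.
#'
#' @param dir directory containing `nodes.tsv` and `edges.tsv`.
#' @param tripletCells,tripletDrugs node-set names for `triplets.tsv`.
#' @return a [MultipartiteGraph-class].
#' @export
readGraphTSV <- function(dir, tripletCells = "Cells",
                         tripletDrugs = "Drugs") {
  nodes <- utils::read.delim(file.path(dir, "nodes.tsv"),
                             colClasses = "character")
  edges <- utils::read.delim(file.path(dir, "edges.tsv"),
                             colClasses = c(row_set = "character",
                                            row_id = "character",
                                            col_set = "character",
                                            col_id = "character"))
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  sets <- lapply(split(nodes$node_id, factor(nodes$set_name,
                                             levels = unique(nodes$set_name))),
                 identity)
  nodeSetList <- lapply(names(sets), function(nm) nodeSet(nm, sets[[nm]]))
  names(nodeSetList) <- names(sets)
  layersPath <- file.path(dir, "layers.tsv")
  if (file.exists(layersPath)) {
    layers <- utils::read.delim(layersPath,
                                colClasses = c(row_set = "character",
                                               col_set = "character",
                                               weighted = "logical",
                                               relation = "character"))
  } else {
    layers <- unique(edges[, c("row_set", "col_set")])
    layers$weighted <- vapply(seq_len(nrow(layers)), function(i) {
      w <- edges$weight[edges$row_set == layers$row_set[i] &
                          edges$col_set == layers$col_set[i]]
      !all(w %in% c(0, 1))
    }, logical(1))
    layers$relation <- ""
  }
  mats <- lapply(seq_len(nrow(layers)), function(i) {
    e <- edges[edges$row_set == layers$row_set[i] &
                 edges$col_set == layers$col_set[i], , drop = FALSE]
    buildAssociationMatrix(
      data.frame(row = e$row_id, col = e$col_id, weight = e$weight,
                 stringsAsFactors = FALSE),
      nodeSetList[[layers$row_set[i]]], nodeSetList[[layers$col_set[i]]],
      weighted = layers$weighted[i], relation = layers$relation[i])
  })
  triplets <- NULL
  tripletsPath <- file.path(dir, "triplets.tsv")
  if (file.exists(tripletsPath)) {
    tr <- utils::read.delim(tripletsPath,
                            colClasses = c(cell_id = "character",
                                           drug_a = "character",
                                           drug_b = "character"))
    triplets <- tripletTableFromRecords(
      data.frame(cell = tr$cell_id, drugA = tr$drug_a, drugB = tr$drug_b,
                 zip = tr$zip, stringsAsFactors = FALSE),
      cellSet = tripletCells, drugSet = tripletDrugs)
  }
  multipartiteGraph(nodeSetList, mats, triplets)
}

#' Write an embedding table as TSV with a JSON manifest
#'
#' @param emb an [EmbeddingTable-class].
#' @param path output TSV path (`node_id` column plus k numeric columns);
#'   a sidecar `<path>.manifest.json` records set, method, k and
#'   provenance.
#' @export
writeEmbeddingTSV <- function(emb, path) {
  df <- data.frame(node_id = rownames(emb@vectors),
                   apply(emb@vectors, 2, .fmtNum),
                   stringsAsFactors = FALSE, check.names = FALSE)
  colnames(df) <- c("node_id", paste0("e", seq_len(emb@k)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(node_set = emb@nodeSet, k = emb@k, method = emb@method,
         provenance = emb@provenance),
    paste0(path, ".manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an embedding table written by [writeEmbeddingTSV()]
#'
#' @param path TSV path; the sidecar manifest must exist.
#' @return an [EmbeddingTable-class].
#' @export
readEmbeddingTSV <- function(path) {
  df <- utils::read.delim(path, colClasses = c(node_id = "character"))
  man <- jsonlite::read_json(paste0(path, ".manifest.json"),
                             simplifyVector = TRUE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$node_id
  colnames(v) <- NULL
  new("EmbeddingTable", nodeSet = man$node_set, k = as.integer(man$k),
      vectors = v, method = man$method,
      provenance = as.list(man$provenance))
}

#' Serialise a FactorSet to a directory of TSV matrices
#'
#' One `<set>.factor.tsv` per node set, one `<key>.core.tsv` per layer
#' (with `~` replaced by `__` in filenames) and a `manifest.json`
#' recording ranks and layer orientations.
#'
#' @param f a [FactorSet-class].
#' @param dir output directory.
#' @export
writeFactorSetTSV <- function(f, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(f@nodeFactors)) {
    m <- f@nodeFactors[[s]]
    df <- data.frame(node_id = rownames(m), apply(m, 2, .fmtNum),
                     check.names = FALSE)
    colnames(df) <- c("node_id", paste0("f", seq_len(ncol(m))))
    utils::write.table(df, file.path(dir, paste0(s, ".factor.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (key in names(f@cores)) {
    utils::write.table(apply(f@cores[[key]], 2, .fmtNum),
                       file.path(dir, paste0(gsub("~", "__", key), ".core.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  jsonlite::write_json(
    list(ranks = as.list(f@ranks), orientation = f@orientation),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a FactorSet written by [writeFactorSetTSV()]
#'
#' @param dir directory written by [writeFactorSetTSV()].
#' @return a [FactorSet-class].
#' @export
readFactorSetTSV <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  ranks <- unlist(man$ranks)
  nodeFactors <- list()
  for (s in names(ranks)) {
    df <- utils::read.delim(file.path(dir, paste0(s, ".factor.tsv")),
                            colClasses = c(node_id = "character"))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$node_id
    colnames(m) <- NULL
    nodeFactors[[s]] <- m
  }
  orientation <- lapply(man$orientation, as.character)
  cores <- list()
  for (key in names(orientation)) {
    cores[[key]] <- as.matrix(utils::read.delim(
      file.path(dir, paste0(gsub("~", "__", key), ".core.tsv")),
      header = FALSE))
    dimnames(cores[[key]]) <- NULL
  }
  new("FactorSet", nodeFactors = nodeFactors, cores = cores,
      orientation = orientation, ranks = ranks)
}

#' Export one layer in MatrixMarket format
#'
#' Writes the sparse layer as `<path>` (MatrixMarket coordinate format)
#' plus two sidecar id files `<path>.rows` and `<path>.cols`.
#'
#' @param m an [AssociationMatrix-class].
#' @param path output `.mtx` path.
#' @export
writeMatrixMarket <- function(m, path) {
  sm <- methods::as(Matrix::Matrix(m@values, sparse = TRUE), "dMatrix")
  Matrix::writeMM(sm, path)
  writeLines(rownames(m@values), paste0(path, ".rows"))
  writeLines(colnames(m@values), paste0(path, ".cols"))
  invisible(path)
}

#' Write an EvalReport as JSON plus a flat per-unit TSV
#'
#' @param report an [EvalReport-class].
#' @param path output JSON path; the per-fold/per-node table goes to
#'   `<path base>.tsv`.
#' @export
writeEvalReport <- function(report, path) {
  scalar <- Filter(function(v) is.atomic(v) && length(v) == 1,
                   report@metrics)
  jsonlite::write_json(
    list(design = report@design, metrics = scalar, config = report@config,
         seed = report@seed),
    path, auto_unbox = TRUE, digits = NA)
  utils::write.table(report@perUnit,
                     paste0(sub("\\.json$", "", path), ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a TowerDataset as TSV
#'
#' Columns: the key columns, the feature columns, then `label`.
#'
#' @param ds a [TowerDataset-class].
#' @param path output TSV path.
#' @export
writeTowerDatasetTSV <- function(ds, path) {
  df <- cbind(ds@keys,
              as.data.frame(apply(ds@features, 2, .fmtNum)),
              label = .fmtNum(ds@labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
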