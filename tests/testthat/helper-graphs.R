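# Shared fixtures: tiny graphs built in code.

# A minimal two-set graph with one binary layer.
tinyBipartite <- function() {
  genes <- nodeSet("Genes", c("g1", "g2", "g3"))
  drugs <- nodeSet("Drugs", c("d1", "d2"))
  m <- buildAssociationMatrix(
    data.frame(row = c("g1", "g2"), col = c("d1", "d2")), genes, drugs,
    relation = "targets")
  multipartiteGraph(list(genes, drugs), list(m))
}

# Three-set chain Genes - Drugs - ATC (shared Drugs factor).
chainGraph <- function(seed = 1) {
  set.seed(seed)
  genes <- nodeSet("Genes", sprintf("g%02d", 1:12))
  drugs <- nodeSet("Drugs", sprintf("d%02d", 1:10))
  atc <- nodeSet("ATC", sprintf("a%02d", 1:8))
  rnd <- function(n, m) matrix(rbinom(n * m, 1, 0.3), n, m)
  mk <- function(v, a, b) {
    dimnames(v) <- list(a@ids, b@ids)
    new("AssociationMatrix", rowSet = a@name, colSet = b@name, values = v,
        weighted = FALSE, relation = "", transposed = FALSE)
  }
  multipartiteGraph(list(genes, drugs, atc),
                    list(mk(rnd(12, 10), genes, drugs),
                         mk(rnd(10, 8), drugs, atc)))
}

# Exact low-rank single-layer graph: R = U S V' with planted factors.
plantedBipartite <- function(n = 20, m = 15, r = 3, seed = 1,
                             setA = "Genes", setB = "Drugs") {
  set.seed(seed)
  U <- matrix(rexp(n * r), n, r)
  V <- matrix(rexp(m * r), m, r)
  S <- matrix(rexp(r * r), r, r)
  R <- U %*% S %*% t(V)
  a <- nodeSet(setA, sprintf("%s%03d", tolower(substr(setA, 1, 1)), 1:n))
  b <- nodeSet(setB, sprintf("%s%03d", tolower(substr(setB, 1, 1)), 1:m))
  dimnames(R) <- list(a@ids, b@ids)
  mat <- new("AssociationMatrix", rowSet = setA, colSet = setB, values = R,
             weighted = TRUE, relation = "planted", transposed = FALSE)
  list(graph = multipartiteGraph(list(a, b), list(mat)),
       U = U, S = S, V = V, R = R)
}

# FactorSet built directly from given matrices (single layer).
manualFactors <- function(g, U, S, V) {
  key <- names(g@matrices)[1]
  m <- g@matrices[[key]]
  rownames(U) <- rownames(m@values)
  rownames(V) <- colnames(m@values)
  nf <- list(U, V)
  names(nf) <- c(m@rowSet, m@colSet)
  new("FactorSet", nodeFactors = nf,
      cores = stats::setNames(list(S), key),
      orientation = stats::setNames(list(c(m@rowSet, m@colSet)), key),
      ranks = stats::setNames(c(ncol(U), ncol(V)), c(m@rowSet, m@colSet)))
}

# Small embedding table with deterministic values.
toyEmbedding <- function(set, ids, k, seed = 1, method = "nmtf") {
  set.seed(seed)
  v <- matrix(runif(length(ids) * k), length(ids), k)
  rownames(v) <- ids
  new("EmbeddingTable", nodeSet = set, k = as.integer(k), vectors = v,
      method = method, provenance = list())
}

# Small synthetic spec for fast end-to-end tests.
smallSpec <- function(seed = 7, ...) {
  syntheticSpec(nGenes = 40L, nDrugs = 30L, nCells = 8L,
                geneSide = c(GO = 15L, Pathways = 12L),
                drugSide = c(ATC = 10L, Categories = 12L),
                rank = 3L, seed = seed, ...)
}
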