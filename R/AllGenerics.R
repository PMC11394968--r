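#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers, following the
#' usual accessor-over-slot convention.
#'
#' @param x,object an object of the relevant class.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x, ...) standardGeneric("nodeIds"))

#' @rdname accessors
#' @export
setGeneric("nodeSets", function(x) standardGeneric("nodeSets"))

#' @rdname accessors
#' @export
setGeneric("nodeSetNames", function(x) standardGeneric("nodeSetNames"))

#' @rdname accessors
#' @export
setGeneric("associationMatrices", function(x) standardGeneric("associationMatrices"))

#' @rdname accessors
#' @export
setGeneric("tripletTable", function(x) standardGeneric("tripletTable"))

#' @rdname accessors
#' @export
setGeneric("layerValues", function(x, ...) standardGeneric("layerValues"))

#' @rdname accessors
#' @export
setGeneric("nodeFactor", function(x, set) standardGeneric("nodeFactor"))

#' @rdname accessors
#' @export
setGeneric("coreMatrix", function(x, a, b) standardGeneric("coreMatrix"))

#' @rdname accessors
#' @export
setGeneric("lossTrace", function(x) standardGeneric("lossTrace"))

#' @rdname accessors
#' @export
setGeneric("embeddingMatrix", function(x) standardGeneric("embeddingMatrix"))

#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname accessors
#' @export
setGeneric("labelValues", function(x) standardGeneric("labelValues"))

#' @rdname accessors
#' @export
setGeneric("rowKeys", function(x) standardGeneric("rowKeys"))

#' @rdname accessors
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))

#' @rdname accessors
#' @export
setGeneric("perUnit", function(x) standardGeneric("perUnit"))
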