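#' Slide identifier of an object
#' @param x a slide-scoped object
#' @return single character id
#' @export
setGeneric("slideId", function(x) standardGeneric("slideId"))

#' @rdname slideId
#' @export
setMethod("slideId", "SlideSource", function(x) x@slideId)
#' @rdname slideId
#' @export
setMethod("slideId", "PatchSet", function(x) x@slideId)
#' @rdname slideId
#' @export
setMethod("slideId", "EmbeddingMatrix", function(x) x@slideId)
#' @rdname slideId
#' @export
setMethod("slideId", "TissueGraph", function(x) x@slideId)

#' Patch manifest of a PatchSet
#' @param x a `PatchSet`
#' @return data.frame with one row per surviving patch
#' @export
patchManifest <- function(x) {
  stopifnot(is(x, "PatchSet"))
  x@manifest
}

#' Patch rasters of a PatchSet (manifest order)
#' @param x a `PatchSet`
#' @return list of side_px x side_px x 3 arrays
#' @export
patchRasters <- function(x) {
  stopifnot(is(x, "PatchSet"))
  x@patches
}

#' Embedding values
#' @param x an `EmbeddingMatrix`
#' @return N x d numeric matrix with unit-norm rows
#' @export
embeddingValues <- function(x) {
  stopifnot(is(x, "EmbeddingMatrix"))
  x@values
}

#' Grid coordinates of an EmbeddingMatrix or TissueGraph
#' @param x an `EmbeddingMatrix` or `TissueGraph`
#' @return data.frame with `grid_row`, `grid_col`
#' @export
gridCoords <- function(x) {
  if (is(x, "EmbeddingMatrix")) return(x@coords)
  if (is(x, "TissueGraph")) return(x@nodes[, c("grid_row", "grid_col")])
  stop("gridCoords: unsupported class ", class(x)[1])
}

#' Node features of a TissueGraph
#' @param x a `TissueGraph`
#' @return |V| x d numeric matrix
#' @export
nodeFeatures <- function(x) {
  stopifnot(is(x, "TissueGraph"))
  x@features
}

#' Adjacency matrix of a TissueGraph
#' @param x a `TissueGraph`
#' @return sparse symmetric 0/1 Matrix without self-loops
#' @export
adjacency <- function(x) {
  stopifnot(is(x, "TissueGraph"))
  x@adjacency
}

#' Connected-component labels of a TissueGraph
#' @param x a `TissueGraph`
#' @return integer vector, one label per node
#' @export
componentIds <- function(x) {
  stopifnot(is(x, "TissueGraph"))
  x@componentId
}

#' Confusion matrix of an EvalReport
#' @param x an `EvalReport`
#' @return C x C integer matrix (rows = truth, columns = prediction)
#' @export
reportConfusion <- function(x) {
  stopifnot(is(x, "EvalReport"))
  x@confusion
}
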