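#' @import methods
#' @importFrom Matrix sparseMatrix t rowSums
NULL

#' SlideSource: a (possibly pyramidal) slide image
#'
#' Holds one slide as a list of raster levels ordered by decreasing
#' resolution, with an objective-equivalent magnification per level.
#' Flat toy images are single-level slides at a declared magnification.
#'
#' @slot slideId single character slide identifier.
#' @slot levels list of numeric arrays (height x width x 3, values in
#'   `[0, 1]`) ordered by decreasing resolution.
#' @slot magnifications numeric vector, objective-equivalent magnification
#'   of each level (e.g. 40, 20, 10); strictly decreasing.
#' @slot mpp microns per pixel at level 0, or `NA` when unknown.
#' @export
setClass("SlideSource",
  representation(
    slideId = "character",
    levels = "list",
    magnifications = "numeric",
    mpp = "numeric"
  ),
  prototype(mpp = NA_real_)
)

setValidity("SlideSource", function(object) {
  msg <- character()
  if (length(object@slideId) != 1L || is.na(object@slideId) ||
      !nzchar(object@slideId))
    msg <- c(msg, "slideId must be a single non-empty string")
  if (length(object@levels) == 0L)
    msg <- c(msg, "slide must have at least one level")
  if (length(object@magnifications) != length(object@levels))
    msg <- c(msg, "one magnification per level is required")
  for (lv in object@levels) {
    if (!is.array(lv) || length(dim(lv)) != 3L || dim(lv)[3] != 3L)
      msg <- c(msg, "each level must be an H x W x 3 array")
    else if (any(dim(lv)[1:2] <= 0L))
      msg <- c(msg, "level dimensions must be positive")
  }
  mags <- object@magnifications
  if (length(mags) > 1L && any(diff(mags) >= 0))
    msg <- c(msg, "magnifications must be strictly decreasing across levels")
  if (any(!is.finite(mags)) || any(mags <= 0))
    msg <- c(msg, "magnifications must be positive finite numbers")
  if (length(msg)) msg else TRUE
})

#' PatchSet: tiled patches of one slide
#'
#' The tiling of a slide into non-overlapping grid patches at a working
#' magnification, after the tissue-content filter. The manifest carries one
#' row per surviving patch with its grid coordinates, level-0 pixel origin,
#' side length and tissue fraction; `patches` optionally carries the patch
#' rasters in manifest order.
#'
#' @slot slideId single character slide identifier.
#' @slot manifest data.frame with columns `slide_id`, `grid_row`,
#'   `grid_col`, `origin_x`, `origin_y`, `side_px`, `tissue_fraction`.
#' @slot patches list of patch rasters (side_px x side_px x 3) in manifest
#'   order, or an empty list when rasters were not retained.
#' @export
setClass("PatchSet",
  representation(
    slideId = "character",
    manifest = "data.frame",
    patches = "list"
  )
)

.manifest_cols <- c("slide_id", "grid_row", "grid_col", "origin_x",
                    "origin_y", "side_px", "tissue_fraction")

setValidity("PatchSet", function(object) {
  m <- object@manifest
  msg <- character()
  if (!all(.manifest_cols %in% names(m)))
    msg <- c(msg, paste("manifest must have columns:",
                        paste(.manifest_cols, collapse = ", ")))
  else {
    if (nrow(m) > 0) {
      if (any(m$grid_row < 0) || any(m$grid_col < 0))
        msg <- c(msg, "grid coordinates must be nonnegative")
      if (anyDuplicated(m[, c("grid_row", "grid_col")]))
        msg <- c(msg, "grid coordinates must be unique per slide")
      if (any(m$tissue_fraction < 0 | m$tissue_fraction > 1))
        msg <- c(msg, "tissue_fraction must lie in [0, 1]")
    }
    if (length(object@patches) &&
        length(object@patches) != nrow(m))
      msg <- c(msg, "patches, when present, must match manifest rows")
  }
  if (length(msg)) msg else TRUE
})

#' EmbeddingMatrix: per-slide patch feature matrix
#'
#' One row per surviving patch in manifest order; each row is an
#' L2-normalized feature vector (512-dimensional by default, matching the
#' downstream graph input).
#'
#' @slot slideId single character slide identifier.
#' @slot coords data.frame with `grid_row`, `grid_col` in row order.
#' @slot values numeric matrix, N x d, unit-norm rows.
#' @export
setClass("EmbeddingMatrix",
  representation(
    slideId = "character",
    coords = "data.frame",
    values = "matrix"
  )
)

setValidity("EmbeddingMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (nrow(v) != nrow(object@coords))
    msg <- c(msg, "one coordinate row per embedding row is required")
  if (!all(c("grid_row", "grid_col") %in% names(object@coords)))
    msg <- c(msg, "coords needs grid_row and grid_col")
  if (nrow(v) > 0) {
    norms <- sqrt(rowSums(v^2))
    if (any(abs(norms - 1) > 1e-6))
      msg <- c(msg, "every embedding row must have unit L2 norm (tol 1e-6)")
  }
  if (length(msg)) msg else TRUE
})

#' TissueGraph: spatial patch graph of one slide
#'
#' Nodes are surviving patches at their grid coordinates, edges connect
#' patches at Chebyshev grid distance 1 (8-neighbour adjacency, so degree
#' is at most 8), and `componentId` labels connected tissue pieces.
#'
#' @slot slideId single character slide identifier.
#' @slot nodes data.frame with `grid_row`, `grid_col` (row-major order).
#' @slot features numeric matrix |V| x d of node features.
#' @slot adjacency symmetric sparse 0/1 adjacency without self-loops.
#' @slot componentId integer vector, one component label per node.
#' @export
setClass("TissueGraph",
  representation(
    slideId = "character",
    nodes = "data.frame",
    features = "matrix",
    adjacency = "Matrix",
    componentId = "integer"
  )
)

setValidity("TissueGraph", function(object) {
  msg <- character()
  n <- nrow(object@nodes)
  A <- object@adjacency
  if (!all(c("grid_row", "grid_col") %in% names(object@nodes)))
    msg <- c(msg, "nodes needs grid_row and grid_col")
  if (nrow(A) != n || ncol(A) != n)
    msg <- c(msg, "adjacency must be |V| x |V|")
  else if (n > 0) {
    if (!Matrix::isSymmetric(A))
      msg <- c(msg, "adjacency must be symmetric")
    if (any(Matrix::diag(A) != 0))
      msg <- c(msg, "adjacency must have no self-loops")
    if (any(Matrix::rowSums(A != 0) > 8))
      msg <- c(msg, "degree must not exceed 8")
    ij <- Matrix::which(A != 0, arr.ind = TRUE)
    if (nrow(ij)) {
      dr <- abs(object@nodes$grid_row[ij[, 1]] - object@nodes$grid_row[ij[, 2]])
      dc <- abs(object@nodes$grid_col[ij[, 1]] - object@nodes$grid_col[ij[, 2]])
      if (any(pmax(dr, dc) != 1))
        msg <- c(msg, "edges must join nodes at Chebyshev grid distance 1")
    }
  }
  if (nrow(object@features) != n)
    msg <- c(msg, "one feature row per node is required")
  if (length(object@componentId) != n)
    msg <- c(msg, "one component id per node is required")
  if (length(msg)) msg else TRUE
})

#' EvalReport: classification metrics for one evaluation
#'
#' Per-class sensitivity/specificity and one-vs-rest AUC, balanced
#' accuracy, and the confusion matrix (rows = true class, columns =
#' predicted class). Rates are percentages in `[0, 100]`; AUC in `[0, 1]`.
#'
#' @slot confusion integer C x C matrix of counts.
#' @slot sensitivity per-class sensitivity in percent.
#' @slot specificity per-class specificity in percent.
#' @slot balancedAccuracy balanced accuracy in percent.
#' @slot auc per-class one-vs-rest AUC (may be NA when undefined).
#' @slot nSlides number of evaluated slides.
#' @export
setClass("EvalReport",
  representation(
    confusion = "matrix",
    sensitivity = "numeric",
    specificity = "numeric",
    balancedAccuracy = "numeric",
    auc = "numeric",
    nSlides = "numeric"
  )
)

setValidity("EvalReport", function(object) {
  msg <- character()
  cm <- object@confusion
  if (nrow(cm) != ncol(cm)) msg <- c(msg, "confusion matrix must be square")
  if (any(cm < 0)) msg <- c(msg, "confusion counts must be nonnegative")
  rates <- c(object@sensitivity, object@specificity, object@balancedAccuracy)
  if (any(rates < -1e-9 | rates > 100 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "rates must lie in [0, 100]")
  if (any(object@auc < -1e-9 | object@auc > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "AUC must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn SlideSource-class show method
#' @param object a `SlideSource`
#' @export
setMethod("show", "SlideSource", function(object) {
  d <- vapply(object@levels, function(x) paste(dim(x)[2:1], collapse = "x"),
              character(1))
  cat("SlideSource '", object@slideId, "': ", length(object@levels),
      " level(s)\n", sep = "")
  cat("  mag: ", paste(object@magnifications, collapse = ", "),
      "  dims(WxH): ", paste(d, collapse = ", "), "\n", sep = "")
})

#' @describeIn PatchSet-class show method
#' @param object a `PatchSet`
#' @export
setMethod("show", "PatchSet", function(object) {
  cat("PatchSet '", object@slideId, "': ", nrow(object@manifest),
      " patch(es)", if (length(object@patches)) " (+rasters)", "\n", sep = "")
})

#' @describeIn EmbeddingMatrix-class show method
#' @param object an `EmbeddingMatrix`
#' @export
setMethod("show", "EmbeddingMatrix", function(object) {
  cat("EmbeddingMatrix '", object@slideId, "': ", nrow(object@values),
      " x ", ncol(object@values), " (unit rows)\n", sep = "")
})

#' @describeIn TissueGraph-class show method
#' @param object a `TissueGraph`
#' @export
setMethod("show", "TissueGraph", function(object) {
  cat("TissueGraph '", object@slideId, "': ", nrow(object@nodes),
      " node(s), ", sum(object@adjacency != 0) / 2, " edge(s), ",
      length(unique(object@componentId)), " component(s)\n", sep = "")
})

#' @describeIn EvalReport-class show method
#' @param object an `EvalReport`
#' @export
setMethod("show", "EvalReport", function(object) {
  cat("EvalReport over", object@nSlides, "slides\n")
  cat(sprintf("  balanced accuracy: %.2f%%\n", object@balancedAccuracy))
  cat("  per-class sensitivity (%):",
      paste(sprintf("%.1f", object@sensitivity), collapse = ", "), "\n")
  cat("  per-class specificity (%):",
      paste(sprintf("%.1f", object@specificity), collapse = ", "), "\n")
  cat("  one-vs-rest AUC:",
      paste(sprintf("%.3f", object@auc), collapse = ", "), "\n")
})
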