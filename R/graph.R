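# Spatial tissue graphs: 8-neighbour adjacency over the surviving patch
# grid, with one connected component per disjoint tissue piece.

#' Build the 8-neighbour adjacency of a patch layout
#'
#' Two patches are connected iff they touch by an edge or a corner, i.e.
#' their grid coordinates are at Chebyshev distance 1; a patch therefore
#' has at most 8 neighbours.
#'
#' @param coords data.frame with unique (`grid_row`, `grid_col`) pairs.
#' @return sparse symmetric 0/1 adjacency (`Matrix::sparseMatrix`) without
#'   self-loops, in the row order of `coords`.
#' @export
buildAdjacency <- function(coords) {
  stopifnot(all(c("grid_row", "grid_col") %in% names(coords)))
  n <- nrow(coords)
  if (anyDuplicated(coords[, c("grid_row", "grid_col")]))
    stop("duplicate grid coordinates")
  key <- paste(coords$grid_row, coords$grid_col)
  lookup <- stats::setNames(seq_len(n), key)
  from <- integer(); to <- integer()
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (k in seq_len(nrow(offs))) {
    nb <- paste(coords$grid_row + offs$dr[k], coords$grid_col + offs$dc[k])
    j <- lookup[nb]
    hit <- which(!is.na(j))
    from <- c(from, hit)
    to <- c(to, j[hit])
  }
  Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(n, n))
}

#' Assemble a TissueGraph from embeddings
#'
#' Orders nodes row-major by (`grid_row`, `grid_col`), builds the
#' 8-neighbour adjacency and labels connected components (the same
#' 8-neighbour relation defines connectivity).
#'
#' @param emb an [EmbeddingMatrix-class], or a data.frame of coordinates
#'   when `features` is given separately.
#' @param features optional |V| x d matrix when `emb` is a data.frame.
#' @param slide_id slide id when `emb` is a data.frame.
#' @return a [TissueGraph-class].
#' @export
buildTissueGraph <- function(emb, features = NULL, slide_id = "slide") {
  if (is(emb, "EmbeddingMatrix")) {
    coords <- emb@coords
    features <- emb@values
    slide_id <- emb@slideId
  } else coords <- emb
  if (nrow(coords) == 0L) stop("cannot build a graph without nodes")
  if (is.null(features)) features <- matrix(0, nrow(coords), 0)
  ord <- order(coords$grid_row, coords$grid_col)
  coords <- coords[ord, , drop = FALSE]
  rownames(coords) <- NULL
  features <- features[ord, , drop = FALSE]
  A <- buildAdjacency(coords)
  comp <- .components8(A)
  new("TissueGraph", slideId = slide_id,
      nodes = data.frame(grid_row = as.integer(coords$grid_row),
                         grid_col = as.integer(coords$grid_col)),
      features = features, adjacency = A, componentId = comp)
}

# connected components of a sparse adjacency (igraph)
.components8 <- function(A) {
  if (nrow(A) == 1L) return(1L)
  g <- igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected")
  as.integer(igraph::components(g)$membership)
}

#' Split a tissue graph into its connected components
#'
#' One subgraph per disjoint tissue piece; within each subgraph the node
#' order of the parent graph is preserved and features are partitioned
#' accordingly. The union of the components reconstructs the input.
#'
#' @param graph a [TissueGraph-class] with at least one node.
#' @return list of `TissueGraph`s, ordered by component id.
#' @export
splitComponents <- function(graph) {
  stopifnot(is(graph, "TissueGraph"))
  if (nrow(graph@nodes) == 0L) stop("cannot split an empty graph")
  ids <- sort(unique(graph@componentId))
  lapply(ids, function(cid) {
    keep <- which(graph@componentId == cid)
    new("TissueGraph", slideId = graph@slideId,
        nodes = graph@nodes[keep, , drop = FALSE],
        features = graph@features[keep, , drop = FALSE],
        adjacency = graph@adjacency[keep, keep, drop = FALSE],
        componentId = rep(1L, length(keep)))
  })
}

#' Write a tissue graph to CSV (nodes + edges)
#'
#' Nodes CSV: `slide_id,node_idx,grid_row,grid_col,component_id` (0-based
#' `node_idx`); edges CSV: `slide_id,u,v` with `u < v`, 0-based.
#'
#' @param graph a [TissueGraph-class].
#' @param nodes_path,edges_path output CSV paths.
#' @return invisibly, a list with the two paths.
#' @export
writeGraph <- function(graph, nodes_path, edges_path) {
  stopifnot(is(graph, "TissueGraph"))
  n <- nrow(graph@nodes)
  nodes <- data.frame(slide_id = rep(graph@slideId, n),
                      node_idx = seq_len(n) - 1L,
                      grid_row = graph@nodes$grid_row,
                      grid_col = graph@nodes$grid_col,
                      component_id = graph@componentId)
  data.table::fwrite(nodes, nodes_path)
  ij <- Matrix::which(graph@adjacency != 0, arr.ind = TRUE)
  ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
  edges <- data.frame(slide_id = rep(graph@slideId, nrow(ij)),
                      u = ij[, 1] - 1L, v = ij[, 2] - 1L)
  data.table::fwrite(edges, edges_path)
  invisible(list(nodes = nodes_path, edges = edges_path))
}
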