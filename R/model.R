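# Graph-transformer classification head: grid max-pooling, a graph-
# convolution block to 128 dimensions, and a six-block transformer with a
# learned slide-level aggregation token ending in a softmax.

#' GraphTransformer: parameters and configuration of the head
#'
#' @slot params named list of numeric parameter arrays.
#' @slot config list, see [modelConfig()].
#' @export
setClass("GraphTransformer", representation(params = "list", config = "list"))

#' @describeIn GraphTransformer-class show method
#' @param object a `GraphTransformer`
#' @export
setMethod("show", "GraphTransformer", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@params, length, numeric(1)))
  cat("GraphTransformer: ", cfg$in_dim, " -> GCN ", cfg$gcn_dim, "-d, ",
      cfg$n_blocks, " blocks x ", cfg$n_heads, " heads, ", cfg$n_classes,
      " classes, pool factor ", cfg$pool_factor, ", ",
      format(np, big.mark = ","), " parameters\n", sep = "")
})

#' Head configuration
#'
#' @param n_classes number of slide classes (2, 3 or 5 for the tasks here,
#'   but any positive count is accepted).
#' @param in_dim node feature width entering the head (512 by default,
#'   matching the encoder output).
#' @param gcn_dim graph-convolution output width (default 128).
#' @param n_blocks number of transformer blocks (default 6).
#' @param n_heads attention heads; must divide `gcn_dim`.
#' @param mlp_dim hidden width of the per-block and final MLPs.
#' @param pool_factor side of the grid max-pooling block (default 2;
#'   1 disables pooling).
#' @param max_pos_bins learned positional-embedding table size per axis;
#'   grid coordinates are clipped into `[0, max_pos_bins - 1]`.
#' @return config list.
#' @export
modelConfig <- function(n_classes, in_dim = 512L, gcn_dim = 128L,
                        n_blocks = 6L, n_heads = 8L, mlp_dim = 256L,
                        pool_factor = 2L, max_pos_bins = 64L) {
  stopifnot(n_classes >= 2, in_dim > 0, gcn_dim > 0, n_blocks > 0,
            n_heads > 0, mlp_dim > 0, pool_factor >= 1)
  if (gcn_dim %% n_heads != 0)
    stop("n_heads must divide gcn_dim")
  list(n_classes = as.integer(n_classes), in_dim = as.integer(in_dim),
       gcn_dim = as.integer(gcn_dim), n_blocks = as.integer(n_blocks),
       n_heads = as.integer(n_heads), mlp_dim = as.integer(mlp_dim),
       pool_factor = as.integer(pool_factor),
       max_pos_bins = as.integer(max_pos_bins))
}

#' Initialize a graph-transformer head
#'
#' @param config a [modelConfig()].
#' @param seed integer seed.
#' @return a [GraphTransformer-class].
#' @export
initGraphTransformer <- function(config, seed = 1L) {
  set.seed(seed)
  d <- config$gcn_dim
  p <- list(
    gcn_W = .init_mat(config$in_dim, d),
    gcn_b = numeric(d),
    pos_row = matrix(stats::rnorm(config$max_pos_bins * d, sd = 0.02),
                     config$max_pos_bins, d),
    pos_col = matrix(stats::rnorm(config$max_pos_bins * d, sd = 0.02),
                     config$max_pos_bins, d),
    cls = matrix(stats::rnorm(d, sd = 0.02), 1, d)
  )
  for (i in seq_len(config$n_blocks)) {
    pf <- paste0("blk", i, "_")
    p[[paste0(pf, "ln1_g")]] <- rep(1, d)
    p[[paste0(pf, "ln1_b")]] <- numeric(d)
    for (w in c("Wq", "Wk", "Wv", "Wo"))
      p[[paste0(pf, w)]] <- .init_mat(d, d)
    for (b in c("bq", "bk", "bv", "bo"))
      p[[paste0(pf, b)]] <- numeric(d)
    p[[paste0(pf, "ln2_g")]] <- rep(1, d)
    p[[paste0(pf, "ln2_b")]] <- numeric(d)
    p[[paste0(pf, "W1")]] <- .init_mat(d, config$mlp_dim)
    p[[paste0(pf, "b1")]] <- numeric(config$mlp_dim)
    p[[paste0(pf, "W2")]] <- .init_mat(config$mlp_dim, d)
    p[[paste0(pf, "b2")]] <- numeric(d)
  }
  p$lnf_g <- rep(1, d)
  p$lnf_b <- numeric(d)
  p$head_W1 <- .init_mat(d, config$mlp_dim)
  p$head_b1 <- numeric(config$mlp_dim)
  p$head_W2 <- .init_mat(config$mlp_dim, config$n_classes)
  p$head_b2 <- numeric(config$n_classes)
  new("GraphTransformer", params = p, config = config)
}

# ---- grid max-pooling -------------------------------------------------

#' Max-pool a tissue graph over grid blocks
#'
#' Groups grid cells into `pool_factor` x `pool_factor` blocks; a pooled
#' node exists iff the block holds at least one node, its feature is the
#' elementwise maximum over the members, its grid coordinate is the block
#' coordinate, and the adjacency is rebuilt on the pooled grid. Spatial
#' positions are thereby preserved through pooling.
#'
#' @param graph a [TissueGraph-class].
#' @param pool_factor block side, >= 1 (1 returns the graph unchanged).
#' @return a pooled `TissueGraph`.
#' @export
maxpoolGraph <- function(graph, pool_factor = 2L) {
  stopifnot(is(graph, "TissueGraph"))
  if (pool_factor < 1) stop("pool_factor must be >= 1")
  if (pool_factor == 1L) return(graph)
  br <- graph@nodes$grid_row %/% pool_factor
  bc <- graph@nodes$grid_col %/% pool_factor
  key <- paste(br, bc)
  groups <- split(seq_along(key), key)
  coords <- do.call(rbind, lapply(groups, function(ix)
    c(br[ix[1]], bc[ix[1]])))
  feats <- do.call(rbind, lapply(groups, function(ix) {
    if (length(ix) == 1L) graph@features[ix, ]
    else apply(graph@features[ix, , drop = FALSE], 2, max)
  }))
  buildTissueGraph(data.frame(grid_row = coords[, 1], grid_col = coords[, 2]),
                   features = feats, slide_id = graph@slideId)
}

# symmetric-normalized adjacency with self-loops: D^{-1/2}(A+I)D^{-1/2}
.norm_adjacency <- function(A) {
  n <- nrow(A)
  Ahat <- A + Matrix::Diagonal(n)
  dinv <- 1 / sqrt(Matrix::rowSums(Ahat))
  Matrix::Diagonal(n, dinv) %*% Ahat %*% Matrix::Diagonal(n, dinv)
}

#' Graph-convolution block
#'
#' `H' = relu(Ahat H W + b)` with `Ahat = D^(-1/2) (A + I) D^(-1/2)`:
#' each node aggregates its 8-neighbourhood (plus itself) before the
#' linear reduction to `gcn_dim` (128 by default) dimensions.
#'
#' @param graph a [TissueGraph-class] whose feature width matches `W`.
#' @param W in_dim x out_dim weight matrix.
#' @param b optional bias (default zero).
#' @return |V| x out_dim matrix of node embeddings.
#' @export
gcnBlock <- function(graph, W, b = NULL) {
  stopifnot(is(graph, "TissueGraph"))
  H <- graph@features
  if (ncol(H) != nrow(W))
    stop("feature width ", ncol(H), " does not match W (", nrow(W), " rows)")
  if (is.null(b)) b <- numeric(ncol(W))
  Ahat <- .norm_adjacency(graph@adjacency)
  pre <- as.matrix(Ahat %*% H) %*% W
  pre <- sweep(pre, 2, b, "+")
  pmax(pre, 0)
}

# ---- transformer forward / backward ----------------------------------

.pos_bins <- function(coords, max_bins) {
  list(r = pmin(pmax(coords$grid_row, 0L), max_bins - 1L) + 1L,
       c = pmin(pmax(coords$grid_col, 0L), max_bins - 1L) + 1L)
}

# X: T x d tokens (aggregation token first); returns probs (+cache)
.transformerForward <- function(p, cfg, X, keep_cache = FALSE) {
  caches <- list()
  for (i in seq_len(cfg$n_blocks)) {
    pf <- paste0("blk", i, "_")
    ln1 <- .layernormForward(X, p[[paste0(pf, "ln1_g")]],
                             p[[paste0(pf, "ln1_b")]])
    att <- .mhaForward(ln1$out, p, pf, cfg$n_heads)
    X1 <- X + att$out
    ln2 <- .layernormForward(X1, p[[paste0(pf, "ln2_g")]],
                             p[[paste0(pf, "ln2_b")]])
    l1 <- .linearForward(ln2$out, p[[paste0(pf, "W1")]],
                         p[[paste0(pf, "b1")]])
    a1 <- .reluForward(l1$out)
    l2 <- .linearForward(a1$out, p[[paste0(pf, "W2")]],
                         p[[paste0(pf, "b2")]])
    X2 <- X1 + l2$out
    if (keep_cache)
      caches[[i]] <- list(ln1 = ln1$cache, att = att$cache, ln2 = ln2$cache,
                          l1 = l1$cache, a1 = a1$cache, l2 = l2$cache)
    X <- X2
  }
  lnf <- .layernormForward(X, p$lnf_g, p$lnf_b)
  cls <- lnf$out[1, , drop = FALSE]
  h1 <- .linearForward(cls, p$head_W1, p$head_b1)
  ha <- .reluForward(h1$out)
  h2 <- .linearForward(ha$out, p$head_W2, p$head_b2)
  logits <- as.vector(h2$out)
  probs <- exp(logits - max(logits))
  probs <- probs / sum(probs)
  if (!keep_cache) return(list(probs = probs, logits = logits))
  list(probs = probs, logits = logits,
       cache = list(blocks = caches, lnf = lnf$cache, h1 = h1$cache,
                    ha = ha$cache, h2 = h2$cache, n_tokens = nrow(X)))
}

.transformerBackward <- function(dlogits, cache, p, cfg) {
  grads <- list()
  b2 <- .linearBackward(matrix(dlogits, 1), cache$h2)
  grads$head_W2 <- b2$dW; grads$head_b2 <- b2$db
  dha <- .reluBackward(b2$dX, cache$ha)
  b1 <- .linearBackward(dha, cache$h1)
  grads$head_W1 <- b1$dW; grads$head_b1 <- b1$db
  dlnf_out <- matrix(0, cache$n_tokens, cfg$gcn_dim)
  dlnf_out[1, ] <- b1$dX
  lb <- .layernormBackward(dlnf_out, cache$lnf)
  grads$lnf_g <- lb$dg; grads$lnf_b <- lb$db
  dX <- lb$dX
  for (i in rev(seq_len(cfg$n_blocks))) {
    pf <- paste0("blk", i, "_")
    ck <- cache$blocks[[i]]
    bl2 <- .linearBackward(dX, ck$l2)
    grads[[paste0(pf, "W2")]] <- bl2$dW
    grads[[paste0(pf, "b2")]] <- bl2$db
    da1 <- .reluBackward(bl2$dX, ck$a1)
    bl1 <- .linearBackward(da1, ck$l1)
    grads[[paste0(pf, "W1")]] <- bl1$dW
    grads[[paste0(pf, "b1")]] <- bl1$db
    ln2b <- .layernormBackward(bl1$dX, ck$ln2)
    grads[[paste0(pf, "ln2_g")]] <- ln2b$dg
    grads[[paste0(pf, "ln2_b")]] <- ln2b$db
    dX1 <- dX + ln2b$dX                      # residual around the MLP
    attb <- .mhaBackward(dX1, ck$att)
    for (nm in names(attb$grads)) grads[[nm]] <- attb$grads[[nm]]
    ln1b <- .layernormBackward(attb$dX, ck$ln1)
    grads[[paste0(pf, "ln1_g")]] <- ln1b$dg
    grads[[paste0(pf, "ln1_b")]] <- ln1b$db
    dX <- dX1 + ln1b$dX                      # residual around attention
  }
  list(grads = grads, dTokens = dX)
}

#' Run the transformer head on prepared node tokens
#'
#' Adds learned positional embeddings (from the binned grid coordinates)
#' to the node tokens, prepends the learned slide-level aggregation token,
#' applies the pre-norm transformer blocks, and maps the normalized
#' aggregation token through the final MLP and softmax.
#'
#' @param model a [GraphTransformer-class].
#' @param tokens |V| x gcn_dim matrix of node embeddings (e.g. the
#'   [gcnBlock()] output).
#' @param coords data.frame with `grid_row`, `grid_col` for each token.
#' @return numeric probability vector of length `n_classes` (sums to 1).
#' @export
transformerHead <- function(model, tokens, coords) {
  stopifnot(is(model, "GraphTransformer"))
  if (nrow(tokens) == 0L) stop("transformer head needs at least one token")
  cfg <- model@config
  p <- model@params
  pb <- .pos_bins(coords, cfg$max_pos_bins)
  X <- tokens + p$pos_row[pb$r, , drop = FALSE] +
    p$pos_col[pb$c, , drop = FALSE]
  X <- rbind(p$cls, X)
  .transformerForward(p, cfg, X)$probs
}

# full head forward over a slide's components with cache for training
.headForward <- function(p, cfg, comps, keep_cache = FALSE) {
  pooled <- lapply(comps, maxpoolGraph, pool_factor = cfg$pool_factor)
  agg <- list(); masks <- list(); toks <- list(); binlist <- list()
  for (k in seq_along(pooled)) {
    g <- pooled[[k]]
    Ahat <- .norm_adjacency(g@adjacency)
    AH <- as.matrix(Ahat %*% g@features)
    pre <- sweep(AH %*% p$gcn_W, 2, p$gcn_b, "+")
    mask <- pre > 0
    toks[[k]] <- pmax(pre, 0)
    agg[[k]] <- AH
    masks[[k]] <- mask
    binlist[[k]] <- .pos_bins(g@nodes, cfg$max_pos_bins)
  }
  T0 <- do.call(rbind, toks)
  rbin <- unlist(lapply(binlist, `[[`, "r"))
  cbin <- unlist(lapply(binlist, `[[`, "c"))
  X <- T0 + p$pos_row[rbin, , drop = FALSE] + p$pos_col[cbin, , drop = FALSE]
  X <- rbind(p$cls, X)
  tf <- .transformerForward(p, cfg, X, keep_cache = keep_cache)
  if (!keep_cache) return(list(probs = tf$probs, logits = tf$logits))
  list(probs = tf$probs, logits = tf$logits,
       cache = list(tf = tf$cache, agg = agg, masks = masks,
                    rbin = rbin, cbin = cbin,
                    sizes = vapply(toks, nrow, integer(1))))
}

.headBackward <- function(dlogits, cache, p, cfg) {
  tb <- .transformerBackward(dlogits, cache$tf, p, cfg)
  grads <- tb$grads
  dX <- tb$dTokens
  grads$cls <- dX[1, , drop = FALSE]
  dTok <- dX[-1, , drop = FALSE]
  d <- cfg$gcn_dim
  grads$pos_row <- matrix(0, cfg$max_pos_bins, d)
  grads$pos_col <- matrix(0, cfg$max_pos_bins, d)
  for (b in unique(cache$rbin))
    grads$pos_row[b, ] <- colSums(dTok[cache$rbin == b, , drop = FALSE])
  for (b in unique(cache$cbin))
    grads$pos_col[b, ] <- colSums(dTok[cache$cbin == b, , drop = FALSE])
  grads$gcn_W <- matrix(0, cfg$in_dim, d)
  grads$gcn_b <- numeric(d)
  off <- 0L
  for (k in seq_along(cache$sizes)) {
    n <- cache$sizes[k]
    dpre <- dTok[off + seq_len(n), , drop = FALSE] * cache$masks[[k]]
    grads$gcn_W <- grads$gcn_W + crossprod(cache$agg[[k]], dpre)
    grads$gcn_b <- grads$gcn_b + colSums(dpre)
    off <- off + n
  }
  grads
}

#' Slide-level prediction from tissue components
#'
#' Pools and graph-convolves each connected tissue piece, concatenates all
#' components' node tokens into a single sequence with one shared
#' aggregation token, and returns the slide-level class probabilities.
#' Positions come from grid coordinates, so the output is invariant to the
#' order in which components are passed.
#'
#' @param model a [GraphTransformer-class].
#' @param components nonempty list of [TissueGraph-class] components.
#' @return numeric probability vector of length `n_classes`.
#' @export
predictWsi <- function(model, components) {
  stopifnot(is(model, "GraphTransformer"))
  if (length(components) == 0L) stop("no components to classify")
  .headForward(model@params, model@config, components)$probs
}

# softmax cross-entropy on logits; y is 1-based class index
.ceLossGrad <- function(logits, y) {
  m <- max(logits)
  p <- exp(logits - m)
  p <- p / sum(p)
  g <- p
  g[y] <- g[y] - 1
  list(loss = -log(p[y]), dlogits = g, probs = p)
}

#' Save / load a graph-transformer checkpoint
#'
#' Opaque parameter blob plus a JSON sidecar with the configuration.
#'
#' @param model a [GraphTransformer-class].
#' @param path checkpoint file path.
#' @return `saveModel` returns `path` invisibly; `loadModel` returns the
#'   [GraphTransformer-class].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "GraphTransformer"))
  raw <- serialize(list(params = model@params, config = model@config),
                   connection = NULL, version = 3L)
  writeBin(raw, path)
  jsonlite::write_json(list(config = model@config, sha1 = .raw_hash(raw)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- unserialize(readBin(path, "raw", file.info(path)$size))
  new("GraphTransformer", params = obj$params, config = obj$config)
}
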