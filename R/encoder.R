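# Contrastive (SimCLR-style) patch encoder: a small residual convolutional
# backbone producing 512-dimensional features, a projection head used only
# during pretraining, and the normalized-temperature cross-entropy
# (NT-Xent) loss over augmented view pairs.

#' EncoderState: parameters and configuration of the patch encoder
#'
#' @slot params named list of numeric parameter arrays (backbone and
#'   projection head).
#' @slot buffers named list of non-trainable state: the running mean and
#'   variance of the pooled texture features (batch-normalization
#'   statistics frozen at inference, so a patch's embedding never depends
#'   on its batch).
#' @slot config list: `input_side`, `channels`, `embedding_dim` (512),
#'   `proj_dim`, `proj_hidden`.
#' @export
setClass("EncoderState",
         representation(params = "list", buffers = "list", config = "list"))

#' @describeIn EncoderState-class show method
#' @param object an `EncoderState`
#' @export
setMethod("show", "EncoderState", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@params, length, numeric(1)))
  cat("EncoderState: input ", cfg$input_side, "px, stages [",
      paste(cfg$channels, collapse = ", "), "], embedding ",
      cfg$embedding_dim, "-d, ", format(np, big.mark = ","),
      " parameters\n", sep = "")
})

#' Encoder configuration
#'
#' The backbone is a residual convolutional network: one 3x3 convolution +
#' ReLU + 2x average pooling per stage, each stage followed by a two-
#' convolution residual block; the final map is summarized by per-channel
#' spatial mean and standard deviation (texture pooling), batch-normalized,
#' and mapped linearly to the 512-dimensional embedding.
#' `variant = "small"` (two stages on 32 px inputs) is the CPU-scale
#' default; `variant = "deep"` gives an 18-layer-class network on 224 px
#' inputs.
#'
#' @param variant "small" or "deep", or NULL when `channels` is given.
#' @param input_side input image side in pixels.
#' @param channels integer vector of stage widths.
#' @param embedding_dim backbone output width; fixed at 512 to match the
#'   downstream graph input.
#' @param proj_hidden,proj_dim projection-head widths (pretraining only).
#' @return config list.
#' @export
encoderConfig <- function(variant = c("small", "deep"), input_side = NULL,
                          channels = NULL, embedding_dim = 512L,
                          proj_hidden = 64L, proj_dim = 32L) {
  if (is.null(channels)) {
    variant <- match.arg(variant)
    if (variant == "small") {
      channels <- c(8L, 16L)
      if (is.null(input_side)) input_side <- 32L
    } else {
      channels <- c(64L, 128L, 256L, 512L)
      if (is.null(input_side)) input_side <- 224L
    }
  }
  if (is.null(input_side)) input_side <- 32L
  if (input_side %% 2^length(channels) != 0)
    stop("input_side must be divisible by 2^(number of stages)")
  list(input_side = as.integer(input_side), channels = as.integer(channels),
       embedding_dim = as.integer(embedding_dim),
       proj_hidden = as.integer(proj_hidden), proj_dim = as.integer(proj_dim))
}

#' Initialize an encoder
#'
#' He-normal initialization of all weights; reproducible under `seed`.
#'
#' @param config an [encoderConfig()].
#' @param seed integer seed.
#' @return an [EncoderState-class].
#' @export
initEncoder <- function(config = encoderConfig(), seed = 1L) {
  set.seed(seed)
  ch <- config$channels
  p <- list()
  prev <- 3L
  for (i in seq_along(ch)) {
    p[[paste0("s", i, "_W")]] <- .init_mat(9L * prev, ch[i])
    p[[paste0("s", i, "_b")]] <- numeric(ch[i])
    p[[paste0("r", i, "_W1")]] <- .init_mat(9L * ch[i], ch[i])
    p[[paste0("r", i, "_b1")]] <- numeric(ch[i])
    p[[paste0("r", i, "_W2")]] <- .init_mat(9L * ch[i], ch[i])
    p[[paste0("r", i, "_b2")]] <- numeric(ch[i])
    prev <- ch[i]
  }
  p$bn_g <- rep(1, 2L * prev)
  p$bn_b <- numeric(2L * prev)
  p$fc_W <- .init_mat(2L * prev, config$embedding_dim)
  p$fc_b <- numeric(config$embedding_dim)
  p$proj_W1 <- .init_mat(config$embedding_dim, config$proj_hidden)
  p$proj_b1 <- numeric(config$proj_hidden)
  p$proj_W2 <- .init_mat(config$proj_hidden, config$proj_dim)
  p$proj_b2 <- numeric(config$proj_dim)
  buf <- list(run_mean = numeric(2L * prev), run_var = rep(1, 2L * prev))
  new("EncoderState", params = p, buffers = buf, config = config)
}

# Convolutional stages + texture pooling for one image: each stage is
# conv-ReLU-avgpool followed by a two-convolution residual block; the
# pooled descriptor is the per-channel spatial mean and standard
# deviation (blob-like textures differ mainly in spatial variance, which
# a pure mean pool would discard).
.stagesForward <- function(img, p, config, keep_cache = FALSE) {
  caches <- list()
  x <- img
  for (i in seq_along(config$channels)) {
    cv <- .conv2dForward(x, p[[paste0("s", i, "_W")]],
                         p[[paste0("s", i, "_b")]], 3L, 1L, 1L)
    rl <- .reluForward(cv$out)
    pl <- .avgpoolForward(rl$out, 2L)
    c1 <- .conv2dForward(pl$out, p[[paste0("r", i, "_W1")]],
                         p[[paste0("r", i, "_b1")]], 3L, 1L, 1L)
    r1 <- .reluForward(c1$out)
    c2 <- .conv2dForward(r1$out, p[[paste0("r", i, "_W2")]],
                         p[[paste0("r", i, "_b2")]], 3L, 1L, 1L)
    sum_ <- c2$out + pl$out                 # residual connection
    r2 <- .reluForward(sum_)
    if (keep_cache)
      caches[[i]] <- list(cv = cv$cache, rl = rl$cache, pl = pl$cache,
                          c1 = c1$cache, r1 = r1$cache, c2 = c2$cache,
                          r2 = r2$cache)
    x <- r2$out
  }
  d <- dim(x)
  mu <- apply(x, 3, mean)
  va <- apply(x, 3, function(s) stats::var(as.vector(s)))
  sdv <- sqrt(va + 1e-8)
  pooled <- c(mu, sdv)
  if (!keep_cache) return(list(pooled = pooled))
  list(pooled = pooled,
       cache = list(stages = caches, x_last = x, mu = mu, sdv = sdv,
                    dimx = d))
}

.stagesBackward <- function(dpooled, cache, p, config) {
  grads <- list()
  d <- cache$dimx
  C <- d[3]
  n_px <- d[1] * d[2]
  dmu <- dpooled[seq_len(C)]
  dsd <- dpooled[C + seq_len(C)]
  dx <- array(rep(dmu, each = n_px) / n_px, d)
  for (ch in seq_len(C)) {
    # d sd / dx = (x - mu) / ((n - 1) sd), sample-variance convention
    dx[, , ch] <- dx[, , ch] + dsd[ch] *
      (cache$x_last[, , ch] - cache$mu[ch]) / ((n_px - 1) * cache$sdv[ch])
  }
  for (i in rev(seq_along(config$channels))) {
    st <- cache$stages[[i]]
    dsum <- .reluBackward(dx, st$r2)
    b2 <- .conv2dBackward(dsum, st$c2)
    grads[[paste0("r", i, "_W2")]] <- b2$dW
    grads[[paste0("r", i, "_b2")]] <- b2$db
    dr1 <- .reluBackward(b2$dx, st$r1)
    b1 <- .conv2dBackward(dr1, st$c1)
    grads[[paste0("r", i, "_W1")]] <- b1$dW
    grads[[paste0("r", i, "_b1")]] <- b1$db
    dpl <- b1$dx + dsum                     # skip path
    drl <- .avgpoolBackward(dpl, st$pl)
    dcv <- .reluBackward(drl, st$rl)
    bc <- .conv2dBackward(dcv, st$cv)
    grads[[paste0("s", i, "_W")]] <- bc$dW
    grads[[paste0("s", i, "_b")]] <- bc$db
    dx <- bc$dx
  }
  grads
}

.bn_eps <- 1e-5
.bn_momentum <- 0.9

# batch-normalization over the pooled descriptors (training mode):
# standardizes each feature across the batch, the step that keeps the
# contrastive embeddings from collapsing onto a common direction.
.bnTrainForward <- function(P, g, b) {
  B <- nrow(P)
  mu <- colMeans(P)
  xc <- sweep(P, 2, mu)
  v <- colMeans(xc^2)                       # population variance
  istd <- 1 / sqrt(v + .bn_eps)
  xhat <- sweep(xc, 2, istd, "*")
  out <- sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
  list(out = out, cache = list(xhat = xhat, istd = istd, g = g, B = B),
       batch_mean = mu, batch_var = v)
}

.bnTrainBackward <- function(dout, cache) {
  g <- cache$g; xhat <- cache$xhat; B <- cache$B
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- sweep(dout, 2, g, "*")
  s1 <- colMeans(dxhat)
  s2 <- colMeans(dxhat * xhat)
  dP <- sweep(dxhat, 2, s1) - xhat * matrix(s2, B, length(s2), byrow = TRUE)
  dP <- sweep(dP, 2, cache$istd, "*")
  list(dP = dP, dg = dg, db = db)
}

# inference-mode backbone: pooled descriptor standardized with the
# running statistics, then the linear map to the 512-d embedding
.backboneForward <- function(img, p, buffers, config) {
  pooled <- .stagesForward(img, p, config)$pooled
  xhat <- (pooled - buffers$run_mean) / sqrt(buffers$run_var + .bn_eps)
  h <- as.vector((xhat * p$bn_g + p$bn_b) %*% p$fc_W) + p$fc_b
  list(h = h)
}

# ---- NT-Xent ----------------------------------------------------------

#' Normalized-temperature cross-entropy (NT-Xent) contrastive loss
#'
#' For a batch of 2N unit-normalized embeddings where rows `i` and `i + N`
#' are the two views of the same patch, the loss is the mean over all 2N
#' anchors of `-log( exp(sim(a, pos)/tau) / sum_{k != a} exp(sim(a, k)/tau) )`
#' with cosine similarity.
#'
#' @param Z 2N x d numeric matrix with unit-norm rows.
#' @param tau temperature, > 0.
#' @return scalar loss (nonnegative).
#' @export
ntxentLoss <- function(Z, tau = 0.5) {
  .ntxent(Z, tau, with_grad = FALSE)$loss
}

.ntxent <- function(Z, tau, with_grad = TRUE) {
  if (!is.matrix(Z) || nrow(Z) %% 2L != 0L)
    stop("Z must be a 2N x d matrix of paired embeddings")
  n2 <- nrow(Z)
  N <- n2 %/% 2L
  if (N < 2L) stop("NT-Xent needs at least N = 2 pairs")
  if (tau <= 0) stop("temperature must be positive")
  norms <- sqrt(rowSums(Z^2))
  if (any(abs(norms - 1) > 1e-6))
    stop("embeddings must be unit-normalized rows")
  S <- Z %*% t(Z) / tau
  pos <- c((N + 1L):n2, 1L:N)               # index of each anchor's positive
  E <- exp(S - apply(S, 1, max))
  diag(E) <- 0                              # self excluded from denominator
  P <- E / rowSums(E)
  loss_i <- -log(P[cbind(seq_len(n2), pos)])
  loss <- mean(loss_i)
  if (!with_grad) return(list(loss = loss))
  G <- P / n2
  G[cbind(seq_len(n2), pos)] <- G[cbind(seq_len(n2), pos)] - 1 / n2
  G <- G / tau
  diag(G) <- 0
  dZ <- (G + t(G)) %*% Z
  list(loss = loss, dZ = dZ)
}

# backward through row L2-normalization z = u / |u|
.l2norm_rows <- function(U) {
  n <- sqrt(rowSums(U^2))
  list(Z = U / n, n = n)
}

.l2normBackward <- function(dZ, Z, n) {
  (dZ - Z * rowSums(dZ * Z)) / n
}

# ---- pretraining ------------------------------------------------------

#' Pretrain the encoder with the contrastive objective
#'
#' SGD over NT-Xent on augmented view pairs with the Adam optimizer. Fully
#' reproducible under `seed`; `steps = 0` returns the freshly initialized
#' state untouched.
#'
#' @param patches list of patch rasters (the pretraining corpus).
#' @param policy an [augmentationPolicy()] whose `output_side` matches the
#'   encoder input.
#' @param steps number of optimization steps.
#' @param tau NT-Xent temperature (default 0.5).
#' @param batch_size patches per step (N; the batch holds 2N views),
#'   must be >= 2.
#' @param lr Adam learning rate.
#' @param config an [encoderConfig()].
#' @param seed integer seed controlling initialization, batch sampling and
#'   augmentation.
#' @return list with `encoder` ([EncoderState-class]) and `history`
#'   (per-step loss).
#' @export
pretrainEncoder <- function(patches, policy = augmentationPolicy(),
                            steps = 200L, tau = 0.5, batch_size = 8L,
                            lr = 1e-3, config = encoderConfig(),
                            seed = 1L) {
  if (length(patches) == 0L) stop("pretraining corpus is empty")
  if (batch_size < 2L) stop("batch_size must be >= 2 (loss undefined)")
  if (steps < 0L) stop("steps must be >= 0")
  enc <- initEncoder(config, seed = seed)
  if (steps == 0L) return(list(encoder = enc, history = numeric()))
  p <- enc@params
  buf <- enc@buffers
  opt <- .adamInit(p)
  history <- numeric(steps)
  for (step in seq_len(steps)) {
    take <- sample.int(length(patches), batch_size,
                       replace = length(patches) < batch_size)
    views <- vector("list", 2L * batch_size)
    for (i in seq_along(take)) {
      vp <- makeViewPair(patches[[take[i]]], policy)
      views[[i]] <- vp[[1]]
      views[[i + batch_size]] <- vp[[2]]
    }
    stg <- lapply(views, .stagesForward, p = p, config = config,
                  keep_cache = TRUE)
    P <- do.call(rbind, lapply(stg, `[[`, "pooled"))
    bn <- .bnTrainForward(P, p$bn_g, p$bn_b)
    buf$run_mean <- .bn_momentum * buf$run_mean +
      (1 - .bn_momentum) * bn$batch_mean
    buf$run_var <- .bn_momentum * buf$run_var +
      (1 - .bn_momentum) * bn$batch_var
    fc <- .linearForward(bn$out, p$fc_W, p$fc_b)
    l1 <- .linearForward(fc$out, p$proj_W1, p$proj_b1)
    a1 <- .reluForward(l1$out)
    l2 <- .linearForward(a1$out, p$proj_W2, p$proj_b2)
    nz <- .l2norm_rows(l2$out)
    res <- .ntxent(nz$Z, tau)
    history[step] <- res$loss
    dU <- .l2normBackward(res$dZ, nz$Z, nz$n)
    grads <- .param_zeros(p)
    b2 <- .linearBackward(dU, l2$cache)
    grads$proj_W2 <- b2$dW; grads$proj_b2 <- b2$db
    da1 <- .reluBackward(b2$dX, a1$cache)
    b1 <- .linearBackward(da1, l1$cache)
    grads$proj_W1 <- b1$dW; grads$proj_b1 <- b1$db
    bfc <- .linearBackward(b1$dX, fc$cache)
    grads$fc_W <- bfc$dW; grads$fc_b <- bfc$db
    bb <- .bnTrainBackward(bfc$dX, bn$cache)
    grads$bn_g <- bb$dg; grads$bn_b <- bb$db
    for (i in seq_along(views)) {
      gb <- .stagesBackward(bb$dP[i, ], stg[[i]]$cache, p, config)
      for (nm in names(gb)) grads[[nm]] <- grads[[nm]] + gb[[nm]]
    }
    upd <- .adamStep(p, grads, opt, lr)
    p <- upd$params
    opt <- upd$state
  }
  enc@params <- p
  enc@buffers <- buf
  list(encoder = enc, history = history)
}

#' Embed patches into unit-norm 512-dimensional features
#'
#' Applies the frozen backbone (the projection head is not applied; the
#' exported features are the L2-normalized backbone outputs) to each patch
#' in manifest order. Each patch's embedding depends only on that patch.
#'
#' @param encoder an [EncoderState-class].
#' @param x a [PatchSet-class] with rasters, or a plain list of rasters.
#' @param coords optional data.frame (`grid_row`, `grid_col`) when `x` is
#'   a list.
#' @param slide_id slide id when `x` is a list.
#' @return an [EmbeddingMatrix-class].
#' @export
embedPatches <- function(encoder, x, coords = NULL, slide_id = "slide") {
  stopifnot(is(encoder, "EncoderState"))
  if (is(x, "PatchSet")) {
    rasters <- x@patches
    if (length(rasters) == 0L && nrow(x@manifest) > 0L)
      stop("PatchSet holds no rasters; re-tile with keep_rasters = TRUE")
    coords <- x@manifest[, c("grid_row", "grid_col")]
    slide_id <- x@slideId
  } else rasters <- x
  if (is.null(coords))
    coords <- data.frame(grid_row = rep(NA_integer_, length(rasters)),
                         grid_col = rep(NA_integer_, length(rasters)))
  cfg <- encoder@config
  V <- matrix(0, length(rasters), cfg$embedding_dim)
  for (i in seq_along(rasters)) {
    img <- rasters[[i]]
    d <- dim(img)
    if (d[1] != cfg$input_side || d[2] != cfg$input_side)
      img <- resizeArea(img, cfg$input_side, cfg$input_side)
    h <- .backboneForward(img, encoder@params, encoder@buffers, cfg)$h
    nh <- sqrt(sum(h^2))
    if (nh == 0)
      stop("zero-norm backbone output for patch ", i, " of '", slide_id, "'")
    V[i, ] <- h / nh
  }
  new("EmbeddingMatrix", slideId = slide_id,
      coords = as.data.frame(coords), values = V)
}

# ---- feature persistence ---------------------------------------------

#' Write / read per-slide feature matrices as CSV
#'
#' Columns: `slide_id`, `grid_row`, `grid_col`, `f0` .. `f<d-1>`. The
#' round-trip preserves row order and values to better than 1e-9.
#'
#' @param matrix an [EmbeddingMatrix-class].
#' @param path CSV file path.
#' @param expected_dim feature width enforced on read (default 512).
#' @return `writeFeatures` returns `path` invisibly; `readFeatures`
#'   returns an `EmbeddingMatrix`.
#' @export
writeFeatures <- function(matrix, path) {
  stopifnot(is(matrix, "EmbeddingMatrix"))
  V <- matrix@values
  df <- data.frame(slide_id = rep(matrix@slideId, nrow(V)),
                   grid_row = matrix@coords$grid_row,
                   grid_col = matrix@coords$grid_col)
  feat <- as.data.frame(V)
  names(feat) <- paste0("f", seq_len(ncol(V)) - 1L)
  if (nrow(V) == 0L) {
    # header-only file for an empty matrix
    hdr <- c("slide_id", "grid_row", "grid_col",
             paste0("f", seq_len(ncol(V)) - 1L))
    writeLines(paste(hdr, collapse = ","), path)
    return(invisible(path))
  }
  data.table::fwrite(cbind(df, feat), path)
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path, expected_dim = 512L) {
  dt <- data.table::fread(path)
  fcols <- grep("^f[0-9]+$", names(dt), value = TRUE)
  if (length(fcols) != expected_dim)
    stop("feature file ", path, " has ", length(fcols),
         " feature columns, expected ", expected_dim,
         " (line 1: header)")
  df <- as.data.frame(dt)
  V <- as.matrix(df[, fcols, drop = FALSE])
  storage.mode(V) <- "double"
  dimnames(V) <- NULL
  sid <- if (nrow(df)) as.character(df$slide_id[1]) else "empty"
  new("EmbeddingMatrix", slideId = sid,
      coords = data.frame(grid_row = as.integer(df$grid_row),
                          grid_col = as.integer(df$grid_col)),
      values = V)
}

#' Serialize encoder parameters to raw bytes
#'
#' Canonical byte representation used by the freeze contract (fine-tuning
#' must leave these bytes unchanged) and for checkpointing.
#'
#' @param encoder an [EncoderState-class].
#' @return raw vector.
#' @export
serializeEncoder <- function(encoder) {
  stopifnot(is(encoder, "EncoderState"))
  serialize(list(params = encoder@params, buffers = encoder@buffers,
                 config = encoder@config),
            connection = NULL, version = 3L)
}

#' Save / load an encoder checkpoint
#'
#' Writes the opaque parameter blob next to a JSON sidecar describing the
#' architecture configuration and a content hash.
#'
#' @param encoder an [EncoderState-class].
#' @param path checkpoint file path (the sidecar gets `.json` appended).
#' @return `saveEncoder` returns `path` invisibly; `loadEncoder` returns
#'   the [EncoderState-class].
#' @export
saveEncoder <- function(encoder, path) {
  raw <- serializeEncoder(encoder)
  writeBin(raw, path)
  sidecar <- list(config = encoder@config,
                  sha1 = .raw_hash(raw))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveEncoder
#' @export
loadEncoder <- function(path) {
  obj <- unserialize(readBin(path, "raw", file.info(path)$size))
  new("EncoderState", params = obj$params, buffers = obj$buffers,
      config = obj$config)
}

# small content hash (sum-based; integrity hint, not cryptographic)
.raw_hash <- function(raw) {
  v <- as.integer(raw)
  sprintf("%08x", sum(v * (seq_along(v) %% 97L + 1L)) %% .Machine$integer.max)
}
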