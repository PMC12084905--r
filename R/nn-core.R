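# Minimal neural-network primitives (forward + analytic backward) used by
# the contrastive encoder and the graph-transformer head. Parameters and
# gradients are flat named lists of numeric arrays; correctness of every
# backward pass is pinned by finite-difference tests.

# ---- parameter-list utilities and Adam -------------------------------

.param_zeros <- function(params) lapply(params, function(p) p * 0)

.param_axpy <- function(a, x, y) { # a*x + y elementwise over lists
  mapply(function(xi, yi) a * xi + yi, x, y, SIMPLIFY = FALSE)
}

.adamInit <- function(params) {
  list(m = .param_zeros(params), v = .param_zeros(params), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- convolution via im2col ------------------------------------------

.im2col_cache <- new.env(parent = emptyenv())

# Linear-index matrix mapping a padded H x W x C image to the im2col
# matrix (one row per output pixel, one column per kernel tap x channel).
.im2col_idx <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  got <- .im2col_cache[[key]]
  if (!is.null(got)) return(got)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  oi <- rep(seq_len(Ho), times = Wo)   # output row, varies fastest
  oj <- rep(seq_len(Wo), each = Ho)
  D <- k * k * C
  idx <- matrix(0L, Ho * Wo, D)
  m <- 0L
  for (ch in seq_len(C)) for (dj in seq_len(k)) for (di in seq_len(k)) {
    m <- m + 1L
    idx[, m] <- (ch - 1L) * Hp * Wp +
      ((oj - 1L) * stride + dj - 1L) * Hp +
      ((oi - 1L) * stride + di)
  }
  res <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
  .im2col_cache[[key]] <- res
  res
}

.pad_img <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out
}

# x: H x W x Cin; W_mat: (k*k*Cin) x Cout; returns Ho x Wo x Cout + cache
.conv2dForward <- function(x, W_mat, b, k, stride = 1L, pad = 1L) {
  d <- dim(x)
  ii <- .im2col_idx(d[1], d[2], d[3], k, stride, pad)
  xp <- .pad_img(x, pad)
  X <- matrix(xp[ii$idx], nrow(ii$idx), ncol(ii$idx))
  Y <- X %*% W_mat
  Y <- sweep(Y, 2, b, "+")
  out <- array(Y, c(ii$Ho, ii$Wo, ncol(W_mat)))
  list(out = out, cache = list(X = X, ii = ii, dimx = d, k = k,
                               stride = stride, pad = pad, W = W_mat))
}

.conv2dBackward <- function(dout, cache) {
  ii <- cache$ii
  Cout <- dim(dout)[3]
  dY <- matrix(dout, nrow(ii$idx), Cout)
  dW <- crossprod(cache$X, dY)
  db <- colSums(dY)
  dX <- dY %*% t(cache$W)              # rows: output pixels, cols: taps
  dpad <- numeric(ii$Hp * ii$Wp * cache$dimx[3])
  for (m in seq_len(ncol(dX))) {
    tgt <- ii$idx[, m]
    dpad[tgt] <- dpad[tgt] + dX[, m]
  }
  dpad <- array(dpad, c(ii$Hp, ii$Wp, cache$dimx[3]))
  p <- cache$pad
  dx <- dpad[p + seq_len(cache$dimx[1]), p + seq_len(cache$dimx[2]), ,
             drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# ---- average pooling (integer factor) --------------------------------

.avgpoolForward <- function(x, f) {
  d <- dim(x)
  Wr <- .area_weights(d[1], d[1] %/% f)
  Wc <- .area_weights(d[2], d[2] %/% f)
  out <- array(0, c(nrow(Wr), nrow(Wc), d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- Wr %*% x[, , ch] %*% t(Wc)
  list(out = out, cache = list(Wr = Wr, Wc = Wc, dimx = d))
}

.avgpoolBackward <- function(dout, cache) {
  d <- cache$dimx
  dx <- array(0, d)
  for (ch in seq_len(d[3]))
    dx[, , ch] <- t(cache$Wr) %*% dout[, , ch] %*% cache$Wc
  dx
}

# ---- dense layers on matrices ----------------------------------------

.linearForward <- function(X, W, b) {
  out <- X %*% W
  out <- sweep(out, 2, b, "+")
  list(out = out, cache = list(X = X, W = W))
}

.linearBackward <- function(dout, cache) {
  list(dX = dout %*% t(cache$W), dW = crossprod(cache$X, dout),
       db = colSums(dout))
}

.reluForward <- function(X) list(out = pmax(X, 0), cache = X > 0)
.reluBackward <- function(dout, cache) dout * cache

# Row-wise layer normalization with learned gain/bias; eps 1e-5.
.layernormForward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  out <- sweep(xhat * g[col(xhat)], 2, b, "+")
  # g[col(xhat)] broadcasts the gain across rows
  list(out = out, cache = list(xhat = xhat, istd = istd, g = g))
}

.layernormBackward <- function(dout, cache) {
  g <- cache$g
  xhat <- cache$xhat
  d <- ncol(xhat)
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- dout * g[col(dout)]
  # standard layernorm backward over each row
  dX <- (dxhat - rowMeans(dxhat) -
           xhat * rowMeans(dxhat * xhat)) * cache$istd
  list(dX = dX, dg = dg, db = db)
}

.softmaxRows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

# ---- multi-head self-attention ---------------------------------------

# X: T x d tokens; weights Wq/Wk/Wv/Wo d x d with biases; n_heads | d.
.mhaForward <- function(X, p, prefix, n_heads) {
  d <- ncol(X)
  dh <- d %/% n_heads
  Q <- sweep(X %*% p[[paste0(prefix, "Wq")]], 2, p[[paste0(prefix, "bq")]], "+")
  K <- sweep(X %*% p[[paste0(prefix, "Wk")]], 2, p[[paste0(prefix, "bk")]], "+")
  V <- sweep(X %*% p[[paste0(prefix, "Wv")]], 2, p[[paste0(prefix, "bv")]], "+")
  O <- matrix(0, nrow(X), d)
  Ps <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
    P <- .softmaxRows(S)
    Ps[[h]] <- P
    O[, cols] <- P %*% V[, cols, drop = FALSE]
  }
  out <- sweep(O %*% p[[paste0(prefix, "Wo")]], 2, p[[paste0(prefix, "bo")]], "+")
  list(out = out,
       cache = list(X = X, Q = Q, K = K, V = V, O = O, Ps = Ps,
                    n_heads = n_heads, dh = dh, prefix = prefix,
                    Wq = p[[paste0(prefix, "Wq")]],
                    Wk = p[[paste0(prefix, "Wk")]],
                    Wv = p[[paste0(prefix, "Wv")]],
                    Wo = p[[paste0(prefix, "Wo")]]))
}

.mhaBackward <- function(dout, cache) {
  X <- cache$X
  dh <- cache$dh
  dWo <- crossprod(cache$O, dout)
  dbo <- colSums(dout)
  dO <- dout %*% t(cache$Wo)
  dQ <- matrix(0, nrow(X), ncol(X))
  dK <- dQ; dV <- dQ
  for (h in seq_len(cache$n_heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    P <- cache$Ps[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dP <- dOh %*% t(cache$V[, cols, drop = FALSE])
    dV[, cols] <- crossprod(P, dOh)
    dS <- P * (dP - rowSums(dP * P))    # softmax backward per row
    dS <- dS / sqrt(dh)
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE]
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE])
  }
  grads <- list()
  pfx <- cache$prefix
  grads[[paste0(pfx, "Wq")]] <- crossprod(X, dQ)
  grads[[paste0(pfx, "bq")]] <- colSums(dQ)
  grads[[paste0(pfx, "Wk")]] <- crossprod(X, dK)
  grads[[paste0(pfx, "bk")]] <- colSums(dK)
  grads[[paste0(pfx, "Wv")]] <- crossprod(X, dV)
  grads[[paste0(pfx, "bv")]] <- colSums(dV)
  grads[[paste0(pfx, "Wo")]] <- dWo
  grads[[paste0(pfx, "bo")]] <- dbo
  dX <- dQ %*% t(cache$Wq) + dK %*% t(cache$Wk) + dV %*% t(cache$Wv)
  list(dX = dX, grads = grads)
}

# ---- initializers -----------------------------------------------------

.init_mat <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}
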