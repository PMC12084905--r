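# Independent brute-force oracles used across the suite. These never call
# into the code paths they check.

# per-cell tissue fraction by direct pixel counting on a logical mask
brute_cell_fractions <- function(mask, patch_side) {
  G_r <- nrow(mask) %/% patch_side
  G_c <- ncol(mask) %/% patch_side
  out <- expand.grid(grid_row = 0:(G_r - 1L), grid_col = 0:(G_c - 1L))
  out$fraction <- mapply(function(r, cc) {
    mean(mask[r * patch_side + seq_len(patch_side),
              cc * patch_side + seq_len(patch_side)])
  }, out$grid_row, out$grid_col)
  out
}

# surviving cells at a threshold, by brute force (>= kept)
brute_surviving_cells <- function(mask, patch_side, min_tissue) {
  f <- brute_cell_fractions(mask, patch_side)
  f[f$fraction >= min_tissue, c("grid_row", "grid_col")]
}

# O(V^2) Chebyshev-distance-1 adjacency
brute_adjacency <- function(coords) {
  n <- nrow(coords)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j &&
        max(abs(coords$grid_row[i] - coords$grid_row[j]),
            abs(coords$grid_col[i] - coords$grid_col[j])) == 1L)
      A[i, j] <- 1
  }
  A
}

# flood-fill (8-connectivity) component count over occupied grid cells
flood_fill_components <- function(coords) {
  key <- paste(coords$grid_row, coords$grid_col)
  todo <- new.env(parent = emptyenv())
  for (k in key) assign(k, TRUE, envir = todo)
  n_comp <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (i in seq_along(key)) {
    if (!exists(key[i], envir = todo)) next
    n_comp <- n_comp + 1L
    queue <- list(c(coords$grid_row[i], coords$grid_col[i]))
    rm(list = key[i], envir = todo)
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        nb <- paste(cur[1] + offs$dr[k], cur[2] + offs$dc[k])
        if (exists(nb, envir = todo)) {
          rm(list = nb, envir = todo)
          queue <- c(queue, list(c(cur[1] + offs$dr[k],
                                   cur[2] + offs$dc[k])))
        }
      }
    }
  }
  n_comp
}

# NT-Xent by explicit double loop over anchors and candidates
brute_ntxent <- function(Z, tau) {
  n2 <- nrow(Z)
  N <- n2 / 2
  total <- 0
  for (i in seq_len(n2)) {
    pos <- if (i <= N) i + N else i - N
    num <- exp(sum(Z[i, ] * Z[pos, ]) / tau)
    den <- 0
    for (k in seq_len(n2)) {
      if (k != i) den <- den + exp(sum(Z[i, ] * Z[k, ]) / tau)
    }
    total <- total - log(num / den)
  }
  total / n2
}

# Mann-Whitney pair-count AUC with half credit for ties
paircount_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  sum(cmp) / (length(pos) * length(neg))
}

# macro-averaged recall (independent balanced-accuracy oracle)
macro_recall_pct <- function(m) {
  rec <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) rec[i] <- m[i, i] / sum(m[i, ])
  100 * mean(rec)
}

# dense normalized-adjacency GCN oracle: relu(D^-1/2 (A+I) D^-1/2 H W)
dense_gcn_oracle <- function(A, H, W, b = NULL) {
  A <- as.matrix(A)
  n <- nrow(A)
  Ahat <- A + diag(n)
  dinv <- diag(1 / sqrt(rowSums(Ahat)), n)
  pre <- dinv %*% Ahat %*% dinv %*% H %*% W
  if (!is.null(b)) pre <- sweep(pre, 2, b, "+")
  pmax(pre, 0)
}

# random normalized embedding batch of N pairs (views loosely correlated)
random_pair_batch <- function(N, d) {
  A <- matrix(stats::rnorm(N * d), N, d)
  B <- A + matrix(stats::rnorm(N * d, sd = 0.5), N, d)
  Z <- rbind(A, B)
  Z / sqrt(rowSums(Z^2))
}

# random sparse patch layout on a g x g grid
random_layout <- function(g = 12, p = 0.3) {
  occ <- which(matrix(stats::runif(g * g) < p, g, g), arr.ind = TRUE)
  if (nrow(occ) == 0) occ <- matrix(c(1, 1), 1, 2)
  data.frame(grid_row = occ[, 1] - 1L, grid_col = occ[, 2] - 1L)
}

# small random TissueGraph with unit-norm features
random_tissue_graph <- function(g = 8, p = 0.4, d = 16, slide_id = "toy") {
  coords <- random_layout(g, p)
  F <- matrix(stats::rnorm(nrow(coords) * d), nrow(coords), d)
  F <- F / sqrt(rowSums(F^2))
  buildTissueGraph(coords, features = F, slide_id = slide_id)
}
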