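# Graph-transformer head: pooling, GCN, transformer contracts, gradients.

small_cfg <- modelConfig(n_classes = 3, in_dim = 12L, gcn_dim = 8L,
                         n_blocks = 2L, n_heads = 2L, mlp_dim = 16L,
                         pool_factor = 1L)

test_that("pool factor 1 leaves the graph unchanged", {
  set.seed(1)
  g <- random_tissue_graph(g = 6, p = 0.5, d = 4)
  expect_identical(maxpoolGraph(g, 1L), g)
  expect_error(maxpoolGraph(g, 0L), "pool_factor")
})

test_that("a full 4x4 grid pools to a full 2x2 grid", {
  coords <- expand.grid(grid_row = 0:3, grid_col = 0:3)
  F <- matrix(seq_len(16 * 2), 16, 2) * 1.0
  g <- buildTissueGraph(coords, features = F)
  pg <- maxpoolGraph(g, 2L)
  expect_equal(nrow(gridCoords(pg)), 4L)
  expect_setequal(paste(gridCoords(pg)$grid_row, gridCoords(pg)$grid_col),
                  c("0 0", "0 1", "1 0", "1 1"))
  # block feature = elementwise max over member nodes (block enumeration)
  for (i in seq_len(4)) {
    br <- gridCoords(pg)$grid_row[i]; bc <- gridCoords(pg)$grid_col[i]
    members <- which(coords$grid_row %/% 2 == br &
                     coords$grid_col %/% 2 == bc)
    expect_equal(nodeFeatures(pg)[i, ],
                 apply(F[members, , drop = FALSE], 2, max))
  }
  # pooled graph satisfies the tissue-graph invariants (validity ran),
  # and a full 2x2 grid has 6 undirected edges
  expect_equal(sum(adjacency(pg)) / 2, 6)
})

test_that("elementwise max pooling combines member features by hand", {
  coords <- data.frame(grid_row = c(0L, 1L), grid_col = c(0L, 0L))
  F <- rbind(c(1, 0, 5), c(0, 2, 4))
  g <- buildTissueGraph(coords, features = F)
  pg <- maxpoolGraph(g, 2L)
  expect_equal(nrow(gridCoords(pg)), 1L)
  expect_equal(nodeFeatures(pg)[1, ], c(1, 2, 5))
})

test_that("gcnBlock matches hand arithmetic and the dense oracle", {
  # single node: Ahat = 1; identity-slice W clamps/truncates the features
  g1 <- buildTissueGraph(data.frame(grid_row = 0L, grid_col = 0L),
                         features = matrix(c(2, -3, 1), 1, 3))
  W <- diag(3)[, 1:2]
  expect_equal(gcnBlock(g1, W), matrix(c(2, 0), 1, 2))
  # two-node path graph, hand-computed Ahat H W
  g2 <- buildTissueGraph(data.frame(grid_row = c(0L, 1L),
                                    grid_col = c(0L, 0L)),
                         features = rbind(c(1, 2), c(3, 4)))
  W2 <- rbind(c(1, 0.5), c(-1, 2))
  # Ahat = [[.5,.5],[.5,.5]] -> Ahat H = [[2,3],[2,3]]
  hand <- pmax(rbind(c(2, 3), c(2, 3)) %*% W2, 0)
  expect_equal(gcnBlock(g2, W2), hand, tolerance = 1e-10)
  # dense oracle on random graphs
  set.seed(21)
  for (rep in 1:10) {
    g <- random_tissue_graph(g = 8, p = 0.5, d = 6)
    Wr <- matrix(rnorm(6 * 5), 6, 5)
    br <- rnorm(5)
    expect_equal(gcnBlock(g, Wr, br),
                 dense_gcn_oracle(adjacency(g), nodeFeatures(g), Wr, br),
                 tolerance = 1e-8)
  }
  expect_error(gcnBlock(g1, matrix(0, 5, 2)), "does not match")
})

test_that("gcn output width follows the configured dimension", {
  set.seed(3)
  g <- random_tissue_graph(g = 6, p = 0.5, d = 12)
  m <- initGraphTransformer(small_cfg, seed = 1)
  out <- gcnBlock(g, m@params$gcn_W, m@params$gcn_b)
  expect_equal(ncol(out), 8L)
})

test_that("the transformer head emits a probability simplex", {
  set.seed(4)
  m <- initGraphTransformer(small_cfg, seed = 5)
  g <- random_tissue_graph(g = 6, p = 0.5, d = 12)
  tok <- gcnBlock(g, m@params$gcn_W, m@params$gcn_b)
  pr <- transformerHead(m, tok, gridCoords(g))
  expect_length(pr, 3L)
  expect_true(all(pr >= 0))
  expect_equal(sum(pr), 1, tolerance = 1e-6)
  # determinism
  expect_identical(pr, transformerHead(m, tok, gridCoords(g)))
  expect_error(transformerHead(m, tok[0, , drop = FALSE],
                               gridCoords(g)[0, ]), "at least one token")
})

test_that("a zeroed final MLP yields uniform class probabilities", {
  cfg2 <- modelConfig(n_classes = 2, in_dim = 12L, gcn_dim = 8L,
                      n_blocks = 2L, n_heads = 2L, mlp_dim = 16L,
                      pool_factor = 1L)
  m <- initGraphTransformer(cfg2, seed = 6)
  m@params$head_W1[] <- 0; m@params$head_b1[] <- 0
  m@params$head_W2[] <- 0; m@params$head_b2[] <- 0
  set.seed(7)
  g <- random_tissue_graph(g = 5, p = 0.5, d = 12)
  expect_equal(predictWsi(m, list(g)), c(0.5, 0.5))
})

test_that("predicting a single component equals the transformer head on it", {
  set.seed(8)
  cfg <- modelConfig(n_classes = 3, in_dim = 12L, gcn_dim = 8L,
                     n_blocks = 2L, n_heads = 2L, mlp_dim = 16L,
                     pool_factor = 2L)
  m <- initGraphTransformer(cfg, seed = 9)
  g <- random_tissue_graph(g = 6, p = 0.6, d = 12)
  comps <- splitComponents(g)
  one <- comps[[1]]
  pooled <- maxpoolGraph(one, 2L)
  tok <- gcnBlock(pooled, m@params$gcn_W, m@params$gcn_b)
  expect_equal(predictWsi(m, list(one)),
               transformerHead(m, tok, gridCoords(pooled)),
               tolerance = 1e-12)
})

test_that("slide prediction is invariant to component order", {
  set.seed(10)
  cfg <- modelConfig(n_classes = 2, in_dim = 12L, gcn_dim = 8L,
                     n_blocks = 2L, n_heads = 2L, mlp_dim = 16L,
                     pool_factor = 2L)
  m <- initGraphTransformer(cfg, seed = 11)
  # three disjoint pieces
  coords <- rbind(expand.grid(grid_row = 0:1, grid_col = 0:1),
                  expand.grid(grid_row = 5:6, grid_col = 5:6),
                  expand.grid(grid_row = 0:1, grid_col = 8:9))
  F <- matrix(rnorm(nrow(coords) * 12), nrow(coords), 12)
  g <- buildTissueGraph(coords, features = F)
  comps <- splitComponents(g)
  base <- predictWsi(m, comps)
  for (rep in 1:5) {
    perm <- sample(length(comps))
    expect_equal(predictWsi(m, comps[perm]), base, tolerance = 1e-6)
  }
  expect_equal(sum(predictWsi(m, c(comps, comps[1]))), 1, tolerance = 1e-6)
  expect_error(predictWsi(m, list()), "no components")
})

test_that("analytic gradients match central differences on a 5-node graph", {
  set.seed(12)
  coords <- data.frame(grid_row = c(0L, 0L, 1L, 1L, 4L),
                       grid_col = c(0L, 1L, 0L, 1L, 4L))
  F <- matrix(rnorm(5 * 12), 5, 12)
  g <- buildTissueGraph(coords, features = F)
  comps <- splitComponents(g)
  m <- initGraphTransformer(small_cfg, seed = 13)
  p <- m@params
  y <- 2L
  fw <- wsigt:::.headForward(p, small_cfg, comps, keep_cache = TRUE)
  ce <- wsigt:::.ceLossGrad(fw$logits, y)
  an <- wsigt:::.headBackward(ce$dlogits, fw$cache, p, small_cfg)
  loss_at <- function(pp) {
    f <- wsigt:::.headForward(pp, small_cfg, comps)
    wsigt:::.ceLossGrad(f$logits, y)$loss
  }
  eps <- 1e-6
  for (nm in names(p)) {
    idx <- sample(length(p[[nm]]), min(3L, length(p[[nm]])))
    for (i in idx) {
      p_hi <- p; p_hi[[nm]][i] <- p_hi[[nm]][i] + eps
      p_lo <- p; p_lo[[nm]][i] <- p_lo[[nm]][i] - eps
      num <- (loss_at(p_hi) - loss_at(p_lo)) / (2 * eps)
      ana <- an[[nm]][i]
      expect_equal(ana, num, tolerance = 1e-4,
                   info = paste("param", nm, "index", i))
    }
  }
})

test_that("model checkpoints round-trip", {
  m <- initGraphTransformer(small_cfg, seed = 14)
  path <- tempfile(fileext = ".ckpt")
  saveModel(m, path)
  back <- loadModel(path)
  expect_identical(back@params, m@params)
  expect_equal(back@config, m@config)
})
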