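# Contrastive encoder: embedding contracts, pretraining behaviour,
# feature persistence.

tiny_cfg <- encoderConfig(channels = c(4L, 6L), input_side = 16L,
                          embedding_dim = 24L, proj_hidden = 12L,
                          proj_dim = 8L)

tiny_corpus <- function(n = 20, side = 16, seed = 5) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    base <- if (i %% 2 == 0) c(0.85, 0.6, 0.7) else c(0.5, 0.3, 0.6)
    img <- array(rep(base, each = side * side), c(side, side, 3))
    if (i %% 2 == 1) {            # blotchy texture on odd patches
      for (b in 1:6) {
        r <- sample(side - 3, 1); cc <- sample(side - 3, 1)
        img[r:(r + 2), cc:(cc + 2), ] <- 0.2
      }
    }
    img + array(rnorm(side * side * 3, 0, 0.01), c(side, side, 3))
  })
}

test_that("embeddings are unit rows, deterministic and batch-independent", {
  enc <- initEncoder(tiny_cfg, seed = 2)
  corpus <- tiny_corpus(6)
  emb <- embedPatches(enc, corpus)
  V <- embeddingValues(emb)
  expect_equal(sqrt(rowSums(V^2)), rep(1, 6), tolerance = 1e-6)
  # duplicated patch -> identical rows
  emb2 <- embedPatches(enc, c(corpus[1], corpus[1]))
  expect_identical(embeddingValues(emb2)[1, ], embeddingValues(emb2)[2, ])
  # batch invariance: a patch embeds the same alone or with others
  solo <- embedPatches(enc, corpus[3])
  expect_identical(embeddingValues(solo)[1, ], V[3, ])
})

test_that("zero steps returns the freshly initialized state", {
  res <- pretrainEncoder(tiny_corpus(4), augmentationPolicy(output_side = 16L),
                         steps = 0L, config = tiny_cfg, seed = 9)
  ref <- initEncoder(tiny_cfg, seed = 9)
  expect_identical(res$encoder@params, ref@params)
  expect_identical(res$encoder@buffers, ref@buffers)
  expect_length(res$history, 0L)
})

test_that("pretraining is bitwise reproducible under a fixed seed", {
  corpus <- tiny_corpus(10)
  pol <- augmentationPolicy(output_side = 16L)
  a <- pretrainEncoder(corpus, pol, steps = 5L, batch_size = 4L,
                       config = tiny_cfg, seed = 33)
  b <- pretrainEncoder(corpus, pol, steps = 5L, batch_size = 4L,
                       config = tiny_cfg, seed = 33)
  expect_identical(serializeEncoder(a$encoder), serializeEncoder(b$encoder))
  expect_identical(a$history, b$history)
})

test_that("contrastive pretraining reduces the loss on a two-texture corpus", {
  corpus <- tiny_corpus(24)
  pol <- augmentationPolicy(crop_scale_range = c(0.5, 1),
                            blur_sigma_range = c(0, 1), output_side = 16L)
  res <- pretrainEncoder(corpus, pol, steps = 120L, batch_size = 6L,
                         lr = 2e-3, config = tiny_cfg, seed = 4)
  expect_lt(mean(tail(res$history, 10)), mean(head(res$history, 10)))
})

test_that("pretrained embeddings separate the two textures", {
  corpus <- tiny_corpus(24)
  pol <- augmentationPolicy(crop_scale_range = c(0.5, 1),
                            blur_sigma_range = c(0, 1), output_side = 16L)
  res <- pretrainEncoder(corpus, pol, steps = 120L, batch_size = 6L,
                         lr = 2e-3, config = tiny_cfg, seed = 4)
  V <- embeddingValues(embedPatches(res$encoder, corpus))
  odd <- seq(1, 24, by = 2)
  S <- V %*% t(V)
  within <- c(S[odd, odd][upper.tri(S[odd, odd])],
              S[-odd, -odd][upper.tri(S[-odd, -odd])])
  between <- S[odd, -odd]
  expect_gt(mean(within), mean(between))
})

test_that("invalid pretraining calls are rejected", {
  pol <- augmentationPolicy(output_side = 16L)
  expect_error(pretrainEncoder(list(), pol, steps = 1L, config = tiny_cfg),
               "empty")
  expect_error(pretrainEncoder(tiny_corpus(4), pol, steps = 1L,
                               batch_size = 1L, config = tiny_cfg),
               "batch_size")
})

test_that("a zero-output backbone is reported with the patch index", {
  enc <- initEncoder(tiny_cfg, seed = 1)
  enc@params$fc_W[] <- 0
  enc@params$fc_b[] <- 0
  expect_error(embedPatches(enc, tiny_corpus(2), slide_id = "z"),
               "zero-norm.*patch 1")
})

test_that("feature matrices round-trip through CSV to 1e-9", {
  enc <- initEncoder(tiny_cfg, seed = 2)
  corpus <- tiny_corpus(5)
  emb <- embedPatches(enc, corpus,
                      coords = data.frame(grid_row = 0:4, grid_col = 4:0),
                      slide_id = "rt")
  path <- tempfile(fileext = ".csv")
  writeFeatures(emb, path)
  back <- readFeatures(path, expected_dim = 24L)
  expect_equal(embeddingValues(back), embeddingValues(emb),
               tolerance = 1e-9)
  expect_equal(gridCoords(back), gridCoords(emb))
  expect_equal(slideId(back), "rt")
})

test_that("an empty matrix writes a header-only file and reads back empty", {
  emb <- new("EmbeddingMatrix", slideId = "none",
             coords = data.frame(grid_row = integer(), grid_col = integer()),
             values = matrix(numeric(), 0, 24))
  path <- tempfile(fileext = ".csv")
  writeFeatures(emb, path)
  expect_length(readLines(path), 1L)
  back <- readFeatures(path, expected_dim = 24L)
  expect_equal(nrow(embeddingValues(back)), 0L)
})

test_that("a hand-written feature fixture parses to its exact numbers", {
  # independently authored CSV: two one-hot unit rows
  d <- 8L
  hdr <- paste(c("slide_id", "grid_row", "grid_col",
                 paste0("f", 0:(d - 1))), collapse = ",")
  row1 <- paste(c("fix", 0, 0, 1, rep(0, d - 1)), collapse = ",")
  row2 <- paste(c("fix", 0, 1, rep(0, d - 1), 1), collapse = ",")
  path <- tempfile(fileext = ".csv")
  writeLines(c(hdr, row1, row2), path)
  back <- readFeatures(path, expected_dim = d)
  expect_equal(embeddingValues(back),
               rbind(c(1, rep(0, d - 1)), c(rep(0, d - 1), 1)))
  expect_error(readFeatures(path, expected_dim = 16L), "feature columns")
})

test_that("encoder checkpoints round-trip bitwise with a JSON sidecar", {
  enc <- initEncoder(tiny_cfg, seed = 8)
  path <- tempfile(fileext = ".ckpt")
  saveEncoder(enc, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- loadEncoder(path)
  expect_identical(serializeEncoder(back), serializeEncoder(enc))
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(sidecar$config$embedding_dim, 24L)
})
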