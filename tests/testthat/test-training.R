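# Task schemes, stratified folds, fine-tuning protocol, ensembling.

test_that("task schemes remap base labels as graded", {
  s1 <- taskScheme(1); s2 <- taskScheme(2); s3 <- taskScheme(3)
  expect_length(s1$classes, 2L)
  expect_length(s2$classes, 3L)
  expect_length(s3$classes, 5L)
  expect_equal(as.character(remapLabels("Ia", s2)), "low-risk")
  expect_equal(as.character(remapLabels("Ib", s2)), "low-risk")
  expect_equal(as.character(remapLabels(c("II", "III"), s2)),
               c("high-risk", "high-risk"))
  expect_equal(as.character(remapLabels("III", s1)), "tumor")
  for (s in list(s1, s2, s3))
    expect_equal(as.character(remapLabels("no-tumor", s)), "no-tumor")
  expect_error(remapLabels("IV", s1), "unknown base label.*IV")
})

test_that("stratified folds distribute classes within one sample", {
  labels <- rep(letters[1:5], each = 10)
  plan <- makeFolds(labels, k = 5, seed = 3)
  expect_equal(sort(unique(plan$fold)), 1:5)
  for (f in 1:5) for (cl in letters[1:5])
    expect_equal(sum(plan$fold == f & labels == cl), 2L)
  # a 3-member class spreads over exactly 3 folds
  labels2 <- c(rep("x", 20), rep("y", 3))
  expect_warning(plan2 <- makeFolds(labels2, k = 5, seed = 4),
                 "smallest class")
  per_fold_y <- table(factor(plan2$fold[labels2 == "y"], levels = 1:5))
  expect_equal(sort(as.integer(per_fold_y)), c(0L, 0L, 1L, 1L, 1L))
  # determinism
  expect_identical(makeFolds(labels, k = 5, seed = 3), plan)
  expect_false(identical(makeFolds(labels, k = 5, seed = 9)$fold,
                         plan$fold))
})

test_that("every class stays within one sample of proportionality", {
  set.seed(5)
  for (rep in 1:10) {
    n_cls <- sample(2:5, 1)
    labels <- sample(seq_len(n_cls), 60, replace = TRUE,
                     prob = runif(n_cls, 0.5, 2))
    k <- sample(3:5, 1)
    plan <- suppressWarnings(makeFolds(labels, k = k, seed = rep))
    for (cl in seq_len(n_cls)) {
      per_fold <- table(factor(plan$fold[labels == cl], levels = 1:k))
      expect_lte(max(per_fold) - min(per_fold), 1L)
    }
  }
})

test_that("early stopping halts after `patience` stagnant epochs", {
  es <- wsigt:::.earlyStop
  expect_false(es(c(0.5, 0.6, 0.7), patience = 3))
  expect_false(es(c(0.7, 0.6, 0.6), patience = 3))
  expect_true(es(c(0.7, 0.6, 0.6, 0.5), patience = 3))
  # strictly increasing trace never triggers the stop
  expect_false(es(seq(0.1, 0.9, by = 0.1), patience = 1))
})

# shared tiny training setup: random separable features on toy layouts
mk_training_data <- function(n_slides, d = 12, seed = 1) {
  set.seed(seed)
  graphs <- list(); y <- integer(n_slides)
  for (i in seq_len(n_slides)) {
    y[i] <- (i %% 2L) + 1L
    coords <- expand.grid(grid_row = 0:2, grid_col = 0:2)
    mu <- if (y[i] == 1L) 0.8 else -0.8
    F <- matrix(rnorm(9 * d, mean = mu, sd = 0.3), 9, d)
    F <- F / sqrt(rowSums(F^2))
    g <- buildTissueGraph(coords, features = F,
                          slide_id = paste0("t", i))
    graphs[[i]] <- splitComponents(g)
  }
  list(graphs = graphs, y = y)
}

tiny_model_cfg <- modelConfig(n_classes = 2, in_dim = 12L, gcn_dim = 8L,
                              n_blocks = 2L, n_heads = 2L, mlp_dim = 16L,
                              pool_factor = 1L)

test_that("fine-tuning learns a separable cohort and freezes the encoder", {
  td <- mk_training_data(24, seed = 6)
  enc <- initEncoder(encoderConfig(channels = c(4L, 6L), input_side = 16L,
                                   embedding_dim = 24L), seed = 1)
  bytes_before <- serializeEncoder(enc)
  m0 <- initGraphTransformer(tiny_model_cfg, seed = 2)
  fit <- finetune(m0, td$graphs[1:16], td$y[1:16],
                  td$graphs[17:24], td$y[17:24],
                  config = trainConfig(lr = 3e-3, max_epochs = 30,
                                       patience = 8, seed = 3),
                  encoder = enc)
  expect_identical(serializeEncoder(fit$encoder), bytes_before)
  # the best checkpoint classifies the validation slides perfectly and
  # the training loss collapses over the run
  expect_equal(max(fit$history$val_acc), 1)
  preds <- vapply(td$graphs[17:24], function(g)
    which.max(predictWsi(fit$model, g)), integer(1))
  expect_equal(preds, td$y[17:24])
  expect_lt(tail(fit$history$train_loss, 1),
            fit$history$train_loss[1] / 10)
  # best checkpoint is the earliest maximum of validation accuracy
  expect_equal(fit$best_epoch,
               which.max(fit$history$val_acc))
  expect_error(finetune(m0, list(), integer(), td$graphs[1:2], td$y[1:2]),
               "nonempty")
})

test_that("fine-tuning is reproducible under a fixed seed", {
  td <- mk_training_data(10, seed = 7)
  m0 <- initGraphTransformer(tiny_model_cfg, seed = 4)
  cfg <- trainConfig(lr = 1e-3, max_epochs = 3, patience = 5, seed = 8)
  a <- finetune(m0, td$graphs[1:6], td$y[1:6], td$graphs[7:10], td$y[7:10],
                config = cfg)
  b <- finetune(m0, td$graphs[1:6], td$y[1:6], td$graphs[7:10], td$y[7:10],
                config = cfg)
  expect_identical(a$model@params, b$model@params)
  expect_identical(a$history, b$history)
})

test_that("cross-validation partitions cleanly and ensembles k members", {
  td <- mk_training_data(40, seed = 9)
  res <- runCV(td$graphs, td$y, n_classes = 2, k = 5,
               model_config = tiny_model_cfg,
               train_config = trainConfig(lr = 3e-3, max_epochs = 3,
                                          patience = 3, seed = 1),
               test_frac = 0.15, seed = 2)
  expect_length(res$members, 5L)
  expect_length(res$reports, 5L)
  # the held-out test set never overlaps any fold's training slides
  dev_idx <- setdiff(seq_along(td$graphs), res$test_idx)
  expect_length(intersect(res$test_idx, dev_idx), 0L)
  # every development slide validates in exactly one fold
  expect_equal(sort(unique(res$fold_plan$fold)), 1:5)
  expect_length(res$fold_plan$fold, length(dev_idx))
  # per-fold validation class counts stay within 1 of proportionality
  for (cl in 1:2) {
    per_fold <- table(factor(res$fold_plan$fold[td$y[dev_idx] == cl],
                             levels = 1:5))
    expect_lte(max(per_fold) - min(per_fold), 1L)
  }
  expect_s4_class(res$aggregate, "EvalReport")
  expect_s4_class(res$ensemble_report, "EvalReport")
})

test_that("ensemble prediction averages softmax vectors with index tie-break", {
  mk_const_model <- function(probs) {
    cfg <- modelConfig(n_classes = length(probs), in_dim = 12L,
                       gcn_dim = 8L, n_blocks = 1L, n_heads = 2L,
                       mlp_dim = 4L, pool_factor = 1L)
    m <- initGraphTransformer(cfg, seed = 1)
    # zero the trunk and write the target logits into the head bias
    for (nm in names(m@params)) m@params[[nm]][] <- 0
    m@params$head_b2 <- log(probs)
    m
  }
  set.seed(10)
  g <- list(random_tissue_graph(g = 4, p = 0.6, d = 12))
  m1 <- mk_const_model(c(0.8, 0.2))
  m2 <- mk_const_model(c(0.6, 0.4))
  expect_equal(ensemblePredict(list(m1, m2), g)$probs, c(0.7, 0.3),
               tolerance = 1e-9)
  expect_equal(ensemblePredict(list(m1, m1), g)$probs, c(0.8, 0.2),
               tolerance = 1e-9)
  tie <- ensemblePredict(list(mk_const_model(c(0.5, 0.5))), g)
  expect_equal(tie$pred, 1L)
  expect_equal(sum(ensemblePredict(list(m1, m2), g)$probs), 1,
               tolerance = 1e-9)
  m3 <- mk_const_model(c(0.2, 0.3, 0.5))
  expect_error(ensemblePredict(list(m1, m3), g), "disagree")
  expect_error(ensemblePredict(list(), g), "at least one member")
})

test_that("label manifests round-trip through CSV", {
  df <- data.frame(slide_id = c("a", "b"), base_label = c("no-tumor", "II"))
  path <- tempfile(fileext = ".csv")
  writeLabels(df, path)
  expect_equal(readLabels(path), df)
})
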