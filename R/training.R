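# Task label schemes, stratified splitting and k-fold cross-validation,
# fine-tuning of the graph-transformer head with a frozen encoder, and
# fold-ensemble inference.

.base_labels <- c("no-tumor", "Ia", "Ib", "II", "III")

#' Task label scheme
#'
#' Maps the five base labels (no-tumor and the four tumor subtypes: Ia
#' nodular, Ib superficial, II medium-aggressive, III high-aggressive)
#' into the class set of a task: task 1 distinguishes no-tumor vs tumor
#' (2 classes), task 2 no-tumor vs low-risk (Ia, Ib) vs high-risk
#' (II, III) per the WHO grading (3 classes), task 3 keeps all five.
#'
#' @param task_id 1, 2 or 3.
#' @return list with `task_id`, `classes` (ordered class names) and `map`
#'   (named character: base label -> class).
#' @export
taskScheme <- function(task_id) {
  if (!task_id %in% 1:3) stop("task_id must be 1, 2 or 3")
  map <- switch(task_id,
    `1` = c("no-tumor" = "no-tumor", Ia = "tumor", Ib = "tumor",
            II = "tumor", III = "tumor"),
    `2` = c("no-tumor" = "no-tumor", Ia = "low-risk", Ib = "low-risk",
            II = "high-risk", III = "high-risk"),
    `3` = c("no-tumor" = "no-tumor", Ia = "Ia", Ib = "Ib",
            II = "II", III = "III"))
  list(task_id = task_id, classes = unique(unname(map)), map = map)
}

#' Remap base labels into a task's classes
#'
#' @param labels character vector of base labels.
#' @param scheme a [taskScheme()].
#' @return factor with the scheme's class levels.
#' @export
remapLabels <- function(labels, scheme) {
  unknown <- setdiff(unique(labels), names(scheme$map))
  if (length(unknown))
    stop("unknown base label(s): ", paste(unknown, collapse = ", "))
  factor(unname(scheme$map[labels]), levels = scheme$classes)
}

#' Stratified k-fold assignment
#'
#' Within each class, samples are shuffled (seeded) and dealt to the k
#' folds round-robin, with the starting fold rotated per class so the
#' remainder samples spread across folds. Per-fold class counts therefore
#' differ from perfect proportionality by at most one sample per class.
#'
#' @param labels vector (factor or character) of task labels.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of class `FoldPlan`: `k`, `fold` (integer per sample),
#'   `seed`.
#' @export
makeFolds <- function(labels, k = 5L, seed = 1L) {
  stopifnot(k >= 2L)
  labels <- as.factor(labels)
  tab <- table(labels)
  if (any(tab == 0L)) stop("every class needs at least one sample")
  if (k > min(tab))
    warning("k = ", k, " exceeds the smallest class size (", min(tab),
            "); some folds will lack that class")
  set.seed(seed)
  fold <- integer(length(labels))
  for (ci in seq_along(levels(labels))) {
    ix <- which(labels == levels(labels)[ci])
    ix <- ix[sample.int(length(ix))]
    fold[ix] <- ((seq_along(ix) - 1L + (ci - 1L)) %% k) + 1L
  }
  structure(list(k = as.integer(k), fold = fold, seed = as.integer(seed)),
            class = "FoldPlan")
}

#' Stratified held-out split
#'
#' Reserves approximately `frac` of the cohort as a fixed held-out set,
#' stratified by class (per-class counts rounded to the nearest sample).
#'
#' @param labels task labels.
#' @param frac held-out fraction (default 0.15).
#' @param seed integer seed.
#' @return logical vector, TRUE for held-out samples.
#' @export
holdoutSplit <- function(labels, frac = 0.15, seed = 1L) {
  labels <- as.factor(labels)
  set.seed(seed)
  held <- logical(length(labels))
  for (lv in levels(labels)) {
    ix <- which(labels == lv)
    n_test <- max(1L, round(frac * length(ix)))
    held[ix[sample.int(length(ix), n_test)]] <- TRUE
  }
  held
}

#' Training configuration for fine-tuning
#'
#' @param lr Adam learning rate (default 1e-4).
#' @param max_epochs epoch cap (default 100).
#' @param patience early-stopping patience in epochs without validation-
#'   accuracy improvement (default 10).
#' @param seed integer seed (initialization and epoch shuffling).
#' @param freeze_encoder keep the contrastive encoder untouched (default
#'   TRUE, the main transfer-learning arm).
#' @param arm "pretrained-finetune" or "from-scratch" (which corpus the
#'   encoder was pretrained on; bookkeeping for the ablation harness).
#' @return config list.
#' @export
trainConfig <- function(lr = 1e-4, max_epochs = 100L, patience = 10L,
                        seed = 1L, freeze_encoder = TRUE,
                        arm = c("pretrained-finetune", "from-scratch")) {
  stopifnot(patience >= 0, max_epochs >= 1, lr > 0)
  list(optimizer = "adam", lr = lr, max_epochs = as.integer(max_epochs),
       patience = as.integer(patience), seed = as.integer(seed),
       freeze_encoder = isTRUE(freeze_encoder), arm = match.arg(arm))
}

# early-stopping decision: stop after epoch e when e - best >= patience;
# best is the earliest epoch attaining the maximum validation accuracy
.earlyStop <- function(val_acc, patience) {
  length(val_acc) - which.max(val_acc) >= patience
}

#' Fine-tune the graph-transformer head
#'
#' Adam training (batch = one slide) of the GCN and transformer
#' parameters on slide-level labels; the contrastive encoder is frozen
#' and never touched. Training halts when validation accuracy has not
#' improved for `patience` epochs or at `max_epochs`; the returned model
#' is the epoch with maximum validation accuracy (earliest on ties).
#'
#' @param model a [GraphTransformer-class] (initial parameters).
#' @param train_graphs,val_graphs lists of slides, each a list of
#'   [TissueGraph-class] components.
#' @param train_y,val_y integer class labels (1-based) per slide.
#' @param config a [trainConfig()].
#' @param encoder optional [EncoderState-class]; returned byte-identical
#'   (the freeze contract) and never consulted during training.
#' @return list: `model` (best checkpoint), `history` (per-epoch
#'   train loss and validation accuracy), `best_epoch`, `encoder`.
#' @export
finetune <- function(model, train_graphs, train_y, val_graphs, val_y,
                     config = trainConfig(), encoder = NULL) {
  stopifnot(is(model, "GraphTransformer"))
  if (length(train_graphs) == 0L || length(val_graphs) == 0L)
    stop("train and validation sets must be nonempty")
  if (!is.null(encoder)) {
    if (!config$freeze_encoder)
      stop("only the frozen-encoder regime is implemented; ",
           "unfreezing would require backpropagating into stored features")
    frozen_bytes <- serializeEncoder(encoder)
  }
  cfg <- model@config
  p <- model@params
  opt <- .adamInit(p)
  set.seed(config$seed)
  train_loss <- numeric(); val_acc <- numeric()
  best_params <- p; best_epoch <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(length(train_graphs))
    losses <- numeric(length(ord))
    for (s in seq_along(ord)) {
      i <- ord[s]
      fw <- .headForward(p, cfg, train_graphs[[i]], keep_cache = TRUE)
      ce <- .ceLossGrad(fw$logits, train_y[i])
      losses[s] <- ce$loss
      grads <- .headBackward(ce$dlogits, fw$cache, p, cfg)
      upd <- .adamStep(p, grads, opt, config$lr)
      p <- upd$params
      opt <- upd$state
    }
    train_loss[epoch] <- mean(losses)
    preds <- vapply(val_graphs, function(g)
      which.max(.headForward(p, cfg, g)$probs), integer(1))
    val_acc[epoch] <- mean(preds == val_y)
    if (epoch == 1L || val_acc[epoch] > max(val_acc[seq_len(epoch - 1L)])) {
      best_params <- p
      best_epoch <- epoch
    }
    if (.earlyStop(val_acc, config$patience)) break
  }
  out_model <- model
  out_model@params <- best_params
  res <- list(model = out_model,
              history = data.frame(epoch = seq_along(train_loss),
                                   train_loss = train_loss,
                                   val_acc = val_acc),
              best_epoch = best_epoch)
  if (!is.null(encoder)) {
    stopifnot(identical(serializeEncoder(encoder), frozen_bytes))
    res$encoder <- encoder
  }
  res
}

#' Stratified k-fold cross-validation with a fixed held-out test set
#'
#' Reconciles the fixed 70/15/15 split with fivefold cross-validation by
#' first reserving the stratified held-out test fraction, then running
#' k-fold CV over the remainder: fold i serves as the validation set for
#' member i (early stopping), the other folds as its training set. Each
#' member is evaluated on the shared held-out test set and the reports
#' are aggregated by the evaluation module.
#'
#' @param graphs list of slides (each a list of [TissueGraph-class]
#'   components).
#' @param labels integer class labels (1-based) per slide.
#' @param n_classes number of task classes.
#' @param k folds (default 5).
#' @param model_config a [modelConfig()] shared by all members.
#' @param train_config a [trainConfig()].
#' @param test_frac held-out fraction (default 0.15).
#' @param seed integer seed for the splits and member initialization.
#' @return list: `members` (k fitted models), `reports` (per-fold
#'   [EvalReport-class] on the held-out set), `aggregate` (fold-mean
#'   report), `fold_plan`, `test_idx`, `ensemble_report` (held-out report
#'   of the softmax-averaged ensemble).
#' @export
runCV <- function(graphs, labels, n_classes, k = 5L,
                  model_config = modelConfig(n_classes),
                  train_config = trainConfig(), test_frac = 0.15,
                  seed = 1L) {
  stopifnot(length(graphs) == length(labels))
  held <- holdoutSplit(labels, frac = test_frac, seed = seed)
  test_idx <- which(held)
  dev_idx <- which(!held)
  plan <- makeFolds(labels[dev_idx], k = k, seed = seed)
  members <- vector("list", k)
  reports <- vector("list", k)
  for (i in seq_len(k)) {
    tr <- dev_idx[plan$fold != i]
    va <- dev_idx[plan$fold == i]
    stopifnot(length(intersect(tr, test_idx)) == 0L)
    model0 <- initGraphTransformer(model_config, seed = seed + i)
    cfg_i <- train_config
    cfg_i$seed <- train_config$seed + i
    fit <- tryCatch(
      finetune(model0, graphs[tr], labels[tr], graphs[va], labels[va],
               config = cfg_i),
      error = function(e) stop("fold ", i, ": ", conditionMessage(e)))
    members[[i]] <- fit$model
    probs <- t(vapply(graphs[test_idx], function(g)
      predictWsi(fit$model, g), numeric(n_classes)))
    preds <- apply(probs, 1, which.max)
    reports[[i]] <- evalReport(labels[test_idx], preds, probs, n_classes)
  }
  ens_probs <- t(vapply(graphs[test_idx], function(g)
    ensemblePredict(members, g)$probs, numeric(n_classes)))
  ens_preds <- apply(ens_probs, 1, which.max)
  list(members = members, reports = reports,
       aggregate = aggregateFolds(reports),
       fold_plan = plan, test_idx = test_idx,
       ensemble_report = evalReport(labels[test_idx], ens_preds, ens_probs,
                                    n_classes))
}

#' Fold-ensemble prediction
#'
#' Arithmetic mean of the member models' softmax vectors; the hard label
#' is the argmax with lowest-index tie-break.
#'
#' @param members nonempty list of [GraphTransformer-class] models
#'   sharing `n_classes`.
#' @param components one slide's list of [TissueGraph-class] components.
#' @return list with `probs` (mean probability vector) and `pred`
#'   (1-based class index).
#' @export
ensemblePredict <- function(members, components) {
  if (length(members) == 0L) stop("ensemble needs at least one member")
  ncls <- vapply(members, function(m) m@config$n_classes, integer(1))
  if (length(unique(ncls)) != 1L)
    stop("ensemble members disagree on n_classes: ",
         paste(unique(ncls), collapse = ", "))
  P <- vapply(members, function(m) predictWsi(m, components),
              numeric(ncls[1]))
  probs <- rowMeans(P)
  list(probs = probs, pred = which.max(probs))
}

#' Write / read a slide label manifest CSV
#'
#' Columns: `slide_id`, `base_label`.
#'
#' @param labels data.frame with `slide_id` and `base_label`.
#' @param path CSV path.
#' @return `writeLabels` returns `path` invisibly; `readLabels` the
#'   data.frame.
#' @export
writeLabels <- function(labels, path) {
  stopifnot(all(c("slide_id", "base_label") %in% names(labels)))
  data.table::fwrite(labels[, c("slide_id", "base_label")], path)
  invisible(path)
}

#' @rdname writeLabels
#' @export
readLabels <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  if (!all(c("slide_id", "base_label") %in% names(df)))
    stop("not a label manifest: ", path)
  df
}
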