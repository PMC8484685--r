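# Optimization loop: class-weighted softmax cross-entropy with auxiliary
# branch losses, Adam, and the validate/checkpoint/early-stop schedule.
# Validation (mean loss over a fixed number of batches) runs every
# `validateEvery` iterations and additionally whenever the training loss
# reaches a new minimum after `minIterLossminValidation`; a checkpoint is
# taken on every new validation minimum; training stops once no validation
# minimum has occurred for `earlyStopPatience` iterations, enforced only
# after `minIterBeforeStop`.

#' TrainSchedule: optimization and stopping constants
#'
#' Defaults are the full-scale settings (1e-4 learning rate, validation of
#' 100 batches every 1000 iterations, loss-minimum validations after
#' 30000 iterations, 10000-iteration patience enforced after 100000
#' iterations; batch size 24 for Panoptes, 64 for baselines). Desk-scale
#' runs use [deskSchedule].
#'
#' @slot batchSize samples per gradient step.
#' @slot learningRate Adam learning rate.
#' @slot validateEvery iterations between scheduled validations.
#' @slot validateBatches batches per validation event.
#' @slot minIterLossminValidation first iteration from which a new training
#'   loss minimum also triggers a validation.
#' @slot earlyStopPatience stop after this many iterations without a new
#'   validation minimum.
#' @slot minIterBeforeStop the stop rule is enforced only from this
#'   iteration on.
#' @slot maxIter hard iteration cap (`Inf` at full scale).
#' @slot seed RNG seed for batch draws, dropout and initialization.
#' @export
setClass("TrainSchedule",
  representation(batchSize = "integer", learningRate = "numeric",
                 validateEvery = "integer", validateBatches = "integer",
                 minIterLossminValidation = "integer",
                 earlyStopPatience = "integer", minIterBeforeStop = "integer",
                 maxIter = "numeric", seed = "integer"))

setValidity("TrainSchedule", function(object) {
  msg <- character()
  cnt <- c(object@batchSize, object@validateEvery, object@validateBatches,
           object@minIterLossminValidation, object@earlyStopPatience,
           object@minIterBeforeStop)
  if (any(cnt <= 0L)) msg <- c(msg, "all counters must be positive")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
  if (object@earlyStopPatience < object@validateEvery)
    msg <- c(msg, "earlyStopPatience must be >= validateEvery")
  if (length(msg)) msg else TRUE
})

#' Construct a TrainSchedule
#' @param batchSize samples per step (24 Panoptes / 64 baselines).
#' @param learningRate Adam learning rate.
#' @param validateEvery,validateBatches validation cadence and size.
#' @param minIterLossminValidation iteration from which training-loss minima
#'   trigger validations.
#' @param earlyStopPatience,minIterBeforeStop stopping rule.
#' @param maxIter hard cap on iterations.
#' @param seed RNG seed.
#' @return a [TrainSchedule-class]
#' @export
trainSchedule <- function(batchSize = 24L, learningRate = 1e-4,
                          validateEvery = 1000L, validateBatches = 100L,
                          minIterLossminValidation = 30000L,
                          earlyStopPatience = 10000L,
                          minIterBeforeStop = 100000L, maxIter = Inf,
                          seed = 1L) {
  new("TrainSchedule", batchSize = as.integer(batchSize),
      learningRate = learningRate, validateEvery = as.integer(validateEvery),
      validateBatches = as.integer(validateBatches),
      minIterLossminValidation = as.integer(minIterLossminValidation),
      earlyStopPatience = as.integer(earlyStopPatience),
      minIterBeforeStop = as.integer(minIterBeforeStop),
      maxIter = maxIter, seed = as.integer(seed))
}

setMethod("show", "TrainSchedule", function(object) {
  cat(sprintf(
    "TrainSchedule: batch %d, lr %g, validate %d batches every %d it, lossmin-val from %d, patience %d (from %d), cap %s, seed %d\n",
    object@batchSize, object@learningRate, object@validateBatches,
    object@validateEvery, object@minIterLossminValidation,
    object@earlyStopPatience, object@minIterBeforeStop,
    if (is.finite(object@maxIter)) format(object@maxIter) else "none",
    object@seed))
  invisible(NULL)
})

#' Desk-scale training schedule
#'
#' Scaled-down constants for CPU runs of width-reduced models: the cadence
#' and stopping structure are preserved while counters shrink to a few
#' hundred iterations, and the learning rate rises to 3e-3 — width-0.1
#' networks carry gradients two orders of magnitude smaller than the
#' full-width models the 1e-4 default was tuned for. Used by the package's
#' synthetic end-to-end studies.
#'
#' @param maxIter iteration cap (default 300)
#' @param seed RNG seed
#' @param batchSize samples per step
#' @return a [TrainSchedule-class]
#' @export
deskSchedule <- function(maxIter = 600L, seed = 1L, batchSize = 24L) {
  trainSchedule(batchSize = batchSize, learningRate = 3e-3,
                validateEvery = 50L, validateBatches = 8L,
                minIterLossminValidation = 150L, earlyStopPatience = 200L,
                minIterBeforeStop = 400L, maxIter = maxIter, seed = seed)
}

#' Training loss: weighted main cross-entropy plus auxiliary terms
#'
#' `L = CE_w(main) + auxWeight * mean_b CE_w(aux_b)` where `CE_w` is the
#' class-weighted softmax cross-entropy (mean over the batch of
#' `w[y_i] * CE_i`). Returns the scalar and the logit gradients.
#'
#' @param logits `[K, n]` main logits
#' @param auxLogits list of `[K, n]` auxiliary logits (may be empty)
#' @param labels integer labels in 1..K
#' @param weights per-class weights ordered by class index (NULL for unit)
#' @param auxWeight auxiliary loss weight
#' @return list: `loss`, `main`, `dlogits`, `daux` (list)
#' @export
trainingLoss <- function(logits, auxLogits, labels, weights = NULL,
                         auxWeight = 0.4) {
  main <- softmaxCE(logits, labels, weights)
  aux <- lapply(auxLogits, softmaxCE, labels = labels, weights = weights)
  nb <- length(aux)
  loss <- main$loss +
    if (nb) auxWeight * mean(vapply(aux, `[[`, numeric(1), "loss")) else 0
  daux <- if (nb) lapply(aux, function(a) a$dlogits * (auxWeight / nb)) else list()
  list(loss = loss, main = main$loss, dlogits = main$dlogits, daux = daux)
}

#' Generic validate/checkpoint/early-stop loop
#'
#' Drives the schedule's state machine against three callbacks, so the
#' policy can be exercised (and tested) independently of any real model:
#' `stepFn(iter)` performs one training iteration and returns its training
#' loss; `validateFn(iter)` returns the mean validation loss;
#' `checkpointFn(iter, valLoss)` snapshots the current model. Validation
#' events happen at iterations divisible by `validateEvery` and whenever
#' the training loss sets a new minimum at or after
#' `minIterLossminValidation`. A checkpoint is taken when the validation
#' loss sets a new minimum. The loop stops when `earlyStopPatience`
#' iterations pass without a new validation minimum (enforced only from
#' `minIterBeforeStop`), or at `maxIter`.
#'
#' @param schedule a [TrainSchedule-class]
#' @param stepFn,validateFn,checkpointFn callbacks (see above)
#' @return list: `log` (data.frame of validation events with columns
#'   iteration, train_loss, val_loss, checkpointed), `stoppedAt`,
#'   `bestIteration`, `bestValLoss`
#' @export
runTrainingLoop <- function(schedule, stepFn, validateFn, checkpointFn) {
  bestTrain <- Inf
  bestVal <- Inf
  bestIter <- NA_integer_
  lastMinIter <- 0L
  log <- list()
  iter <- 0L
  stopped <- NA_integer_
  while (iter < schedule@maxIter) {
    iter <- iter + 1L
    trLoss <- stepFn(iter)
    newTrainMin <- trLoss < bestTrain
    if (newTrainMin) bestTrain <- trLoss
    doVal <- (iter %% schedule@validateEvery == 0L) ||
      (newTrainMin && iter >= schedule@minIterLossminValidation)
    if (doVal) {
      vl <- validateFn(iter)
      ck <- vl < bestVal
      if (ck) {
        bestVal <- vl
        bestIter <- iter
        lastMinIter <- iter
        checkpointFn(iter, vl)
      }
      log[[length(log) + 1L]] <- data.frame(
        iteration = iter, train_loss = trLoss, val_loss = vl,
        checkpointed = ck)
    }
    if (iter >= schedule@minIterBeforeStop &&
        (iter - lastMinIter) >= schedule@earlyStopPatience) {
      stopped <- iter
      break
    }
  }
  list(log = if (length(log)) do.call(rbind, log) else
         data.frame(iteration = integer(), train_loss = numeric(),
                    val_loss = numeric(), checkpointed = logical()),
       stoppedAt = if (is.na(stopped)) iter else stopped,
       bestIteration = bestIter, bestValLoss = bestVal)
}

#' Train a model on a tensor store
#'
#' Runs Adam at the schedule's learning rate over seeded-permutation epochs
#' of the training tensors, with the full validate/checkpoint/early-stop
#' policy of [runTrainingLoop]. Clinical standardization constants are
#' fitted on the training partition before the first step. Single-stream
#' and fully reproducible: two runs with the same seed and data produce
#' identical logs and weights.
#'
#' @param model a freshly built [PanoptesModel-class]
#' @param trainTens,valTens outputs of [recordsToTensors] for the train and
#'   validation partitions
#' @param schedule a [TrainSchedule-class]
#' @param classWeights named weights from [computeClassWeights] (or NULL)
#' @param augment apply a random dihedral (rotation/flip) transform to each
#'   training sample, the same transform across the three co-registered
#'   members so the set stays aligned. Off by default; desk-scale studies
#'   enable it — with few training slides it suppresses tile memorization
#'   in favor of the orientation-invariant tissue features.
#' @return list: `model` (best checkpoint), `finalModel`, `log`,
#'   `stoppedAt`, `bestIteration`, `bestValLoss`
#' @export
trainModel <- function(model, trainTens, valTens, schedule,
                       classWeights = NULL, augment = FALSE) {
  cfg <- model@config
  if (length(valTens$labels) == 0L)
    stop("validation partition is empty; cannot train")
  if (length(trainTens$labels) == 0L)
    stop("training partition is empty; cannot train")
  if (cfg@useClinical)
    model@clinicalStats <- fitClinicalStats(trainTens$age, trainTens$bmi)
  w <- if (is.null(classWeights)) NULL else unname(classWeights[c("0", "1")])
  opt <- adamInit(model@params)
  ntr <- length(trainTens$labels)
  nval <- length(valTens$labels)
  env <- new.env(parent = emptyenv())
  env$model <- model
  env$opt <- opt
  env$perm <- integer(0)
  env$best <- NULL
  clinStats <- if (cfg@useClinical) model@clinicalStats else NULL
  set.seed(childSeed(schedule@seed, "trainloop"))
  nextBatch <- function() {
    if (length(env$perm) < schedule@batchSize)
      env$perm <- c(env$perm, sample.int(ntr))
    idx <- env$perm[seq_len(schedule@batchSize)]
    env$perm <- env$perm[-seq_len(schedule@batchSize)]
    idx
  }
  stepFn <- function(iter) {
    idx <- nextBatch()
    b <- batchFromTensors(trainTens, idx, cfg@inputPx, clinStats)
    if (augment) b <- augmentBatch(b)
    fw <- modelForward(env$model, b, train = TRUE)
    ls <- trainingLoss(fw$logits, fw$aux, b$labels, w, cfg@auxWeight)
    grads <- modelBackward(env$model, fw, ls$dlogits, ls$daux)
    up <- adamStep(env$model@params, grads, env$opt, schedule@learningRate)
    env$model@params <- up$params
    env$opt <- up$state
    # commit the batch-norm running buffers observed in this step
    for (nm in names(fw$cache$bnUpdates))
      env$model@params[[nm]] <- fw$cache$bnUpdates[[nm]]
    ls$loss
  }
  validateFn <- function(iter) {
    losses <- numeric(schedule@validateBatches)
    for (vb in seq_len(schedule@validateBatches)) {
      vidx <- ((vb - 1L) * schedule@batchSize + seq_len(schedule@batchSize) - 1L) %% nval + 1L
      b <- batchFromTensors(valTens, vidx, cfg@inputPx, clinStats)
      fw <- modelForward(env$model, b, train = FALSE)
      losses[vb] <- trainingLoss(fw$logits, fw$aux, b$labels, w,
                                 cfg@auxWeight)$loss
    }
    mean(losses)
  }
  checkpointFn <- function(iter, vl) env$best <- env$model
  res <- runTrainingLoop(schedule, stepFn, validateFn, checkpointFn)
  list(model = if (is.null(env$best)) env$model else env$best,
       finalModel = env$model, log = res$log, stoppedAt = res$stoppedAt,
       bestIteration = res$bestIteration, bestValLoss = res$bestValLoss)
}

# One of the 8 square symmetries applied to [h, w, c] (op in 0..7:
# op %% 4 quarter turns, op >= 4 adds a horizontal flip).
#' @keywords internal
dihedral <- function(img, op) {
  r <- op %% 4L
  if (r == 1L) img <- aperm(img, c(2, 1, 3))[dim(img)[2]:1, , , drop = FALSE]
  else if (r == 2L) img <- img[dim(img)[1]:1, dim(img)[2]:1, , drop = FALSE]
  else if (r == 3L) img <- aperm(img, c(2, 1, 3))[, dim(img)[1]:1, , drop = FALSE]
  if (op >= 4L) img <- img[, dim(img)[2]:1, , drop = FALSE]
  img
}

# Random per-sample dihedral transform, shared across the co-registered
# members of each tile set. Draws from the active RNG stream.
#' @keywords internal
augmentBatch <- function(b) {
  n <- dim(b$x[[1]])[4]
  ops <- sample(0:7, n, replace = TRUE)
  b$x <- lapply(b$x, function(a) {
    for (i in seq_len(n)) if (ops[i] > 0L)
      a[, , , i] <- dihedral(a[, , , i, drop = TRUE], ops[i])
    a
  })
  b
}

#' Score tile sets with a trained model
#'
#' Evaluation-mode forward passes in batches; returns a prediction table
#' with one row per tile set (positive-class probability).
#'
#' @param model a [PanoptesModel-class]
#' @param tens output of [recordsToTensors]
#' @param batchSize evaluation batch size
#' @return data.frame (patient_id, slide_id, tile_set_id, score,
#'   true_label), a prediction table
#' @export
predictTensors <- function(model, tens, batchSize = 64L) {
  cfg <- model@config
  clinStats <- if (cfg@useClinical) model@clinicalStats else NULL
  n <- length(tens$labels)
  scores <- numeric(n)
  for (s in seq(1L, n, by = batchSize)) {
    idx <- s:min(s + batchSize - 1L, n)
    b <- batchFromTensors(tens, idx, cfg@inputPx, clinStats)
    fw <- modelForward(model, b, train = FALSE)
    scores[idx] <- softmaxProbs(fw$logits)[2, ]
  }
  data.frame(patient_id = tens$patient_id, slide_id = tens$slide_id,
             tile_set_id = tens$tile_set_id, score = scores,
             true_label = tens$labels - 1L)
}
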