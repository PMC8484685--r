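# Loss composition and the validate/checkpoint/early-stop state machine.

test_that("the loss matches its closed forms", {
  # uniform logits, balanced weights, 2 classes: main term = ln 2
  lg <- matrix(0, 2, 8)
  ls <- trainingLoss(lg, list(), rep(1:2, 4), NULL, 0.4)
  expect_equal(ls$loss, log(2))
  # auxiliary heads add auxWeight * mean of their cross-entropies
  ls2 <- trainingLoss(lg, list(lg, lg, lg), rep(1:2, 4), NULL, 0.4)
  expect_equal(ls2$loss, log(2) * 1.4)
  # near-perfect logits drive the loss to zero
  big <- rbind(c(50, -50), c(-50, 50))
  ls3 <- trainingLoss(big, list(), c(1L, 2L), NULL, 0.4)
  expect_lt(ls3$loss, 1e-10)
  # doubling the positive-class weight doubles a pure-positive batch's term
  lgp <- matrix(rnorm(6), 2, 3)
  l1 <- trainingLoss(lgp, list(), rep(2L, 3), c(1, 1), 0.4)$main
  l2 <- trainingLoss(lgp, list(), rep(2L, 3), c(1, 2), 0.4)$main
  expect_equal(l2, 2 * l1)
})

test_that("the gradient of the weighted loss is exact", {
  withr::with_seed(9, {
    lg <- matrix(rnorm(10), 2, 5)
    y <- c(1L, 2L, 2L, 1L, 2L)
    w <- c(0.7, 1.6)
    ls <- trainingLoss(lg, list(), y, w, 0.4)
    eps <- 1e-6
    for (k in sample(10, 4)) {
      lp <- lg; lp[k] <- lp[k] + eps
      lm <- lg; lm[k] <- lm[k] - eps
      num <- (trainingLoss(lp, list(), y, w, 0.4)$loss -
              trainingLoss(lm, list(), y, w, 0.4)$loss) / (2 * eps)
      expect_equal(ls$dlogits[k], num, tolerance = 1e-5)
    }
  })
})

test_that("scripted losses reproduce the documented stop/checkpoint trace", {
  vals <- c(5, 4, 3, 3, 3, 3, 3, 3, 3, 3)
  i <- 0
  sched <- trainSchedule(batchSize = 1, validateEvery = 1,
                         earlyStopPatience = 3, minIterBeforeStop = 5,
                         minIterLossminValidation = 100, maxIter = 50)
  res <- runTrainingLoop(sched,
    stepFn = function(iter) 1,          # constant training loss
    validateFn = function(iter) { i <<- i + 1; vals[i] },
    checkpointFn = function(iter, vl) NULL)
  expect_equal(res$stoppedAt, 6L)
  expect_equal(res$bestIteration, 3L)
  expect_equal(res$bestValLoss, 3)
  expect_equal(res$log$checkpointed, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("strictly decreasing validation never stops before the cap", {
  i <- 0
  sched <- trainSchedule(batchSize = 1, validateEvery = 1,
                         earlyStopPatience = 3, minIterBeforeStop = 5,
                         minIterLossminValidation = 100, maxIter = 20)
  res <- runTrainingLoop(sched,
    stepFn = function(iter) 1,
    validateFn = function(iter) { i <<- i + 1; 100 - i },
    checkpointFn = function(iter, vl) NULL)
  expect_equal(res$stoppedAt, 20L)
  expect_true(all(res$log$checkpointed))
  # checkpointed validation losses are strictly decreasing
  ck <- res$log$val_loss[res$log$checkpointed]
  expect_true(all(diff(ck) < 0))
})

test_that("validation fires on the cadence plus post-threshold loss minima", {
  withr::with_seed(31, {
    trainLosses <- runif(60, 1, 2)
    trainLosses[c(17, 35, 36, 50)] <- c(0.9, 0.8, 0.85, 0.7)
    valLosses <- runif(40, 1, 2)
    sched <- trainSchedule(batchSize = 1, validateEvery = 10,
                           minIterLossminValidation = 30,
                           earlyStopPatience = 25, minIterBeforeStop = 55,
                           maxIter = 60)
    i <- 0
    res <- runTrainingLoop(sched,
      stepFn = function(iter) trainLosses[iter],
      validateFn = function(iter) { i <<- i + 1; valLosses[i] },
      checkpointFn = function(iter, vl) NULL)
    oracle <- scheduleOracle(trainLosses, valLosses, 10, 30, 25, 55, 60)
    expect_equal(res$log$iteration, oracle$events[, 1])
    expect_equal(res$log$val_loss, oracle$events[, 2])
    expect_equal(res$log$checkpointed, oracle$events[, 3] == 1)
    expect_equal(res$stoppedAt, oracle$stopped)
    # loss-minimum triggers: iteration 35 and 50 validate off-cadence,
    # iteration 17 (a minimum before the threshold) does not
    expect_true(all(c(35, 50) %in% res$log$iteration))
    expect_false(17 %in% res$log$iteration)
  })
})

test_that("training a real model is reproducible and honors errors", {
  tens <- tinyTensors(n = 16, shift = 0.2)
  val <- tinyTensors(n = 8, shift = 0.2, seed = 2)
  cfg <- architectureConfig("inception_v1", widthMultiplier = 0.1,
                            inputPx = 75L)
  sched <- trainSchedule(batchSize = 4, learningRate = 1e-3,
                         validateEvery = 3, validateBatches = 2,
                         minIterLossminValidation = 100,
                         earlyStopPatience = 6, minIterBeforeStop = 100,
                         maxIter = 6, seed = 5)
  f1 <- trainModel(buildModel(cfg, 1), tens, val, sched, NULL)
  f2 <- trainModel(buildModel(cfg, 1), tens, val, sched, NULL)
  expect_equal(f1$log, f2$log)
  expect_equal(f1$finalModel@params, f2$finalModel@params)
  # the weights actually moved
  expect_false(identical(f1$finalModel@params, buildModel(cfg, 1)@params))
  # empty validation partition is a configuration error
  empty <- tinyTensors(2); empty$labels <- integer(0)
  expect_error(trainModel(buildModel(cfg, 1), tens, empty, sched, NULL),
               "validation")
})

test_that("schedule constructors validate their counters", {
  expect_error(trainSchedule(validateEvery = 0), "positive")
  expect_error(trainSchedule(earlyStopPatience = 5, validateEvery = 10),
               "earlyStopPatience")
  expect_s4_class(deskSchedule(), "TrainSchedule")
})
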