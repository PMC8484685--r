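# Architecture construction contracts: shapes, feature bookkeeping,
# equivariance, width scaling, checkpoints.

smallCfg <- function(family, ...) {
  architectureConfig(family, widthMultiplier = 0.1, inputPx = 75L, ...)
}

randBatch <- function(n, mags = c("10x", "5x", "2.5x"), px = 75L, seed = 1,
                      clin = FALSE) {
  withr::with_seed(seed, {
    x <- lapply(mags, function(m) array(runif(px * px * 3 * n),
                                        c(px, px, 3, n)))
    names(x) <- mags
    list(x = x, clin = if (clin) matrix(rnorm(4 * n), 4, n) else NULL)
  })
}

test_that("panoptes produces main logits, three aux heads, and softmax rows", {
  m <- buildModel(smallCfg("panoptes2"), seed = 1)
  b <- randBatch(5)
  fw <- modelForward(m, b, train = TRUE)
  expect_equal(dim(fw$logits), c(2L, 5L))
  expect_length(fw$aux, 3L)
  expect_true(all(vapply(fw$aux, function(a) all(dim(a) == c(2, 5)),
                         logical(1))))
  pr <- panoptes:::softmaxProbs(fw$logits)
  expect_equal(colSums(pr), rep(1, 5))
})

test_that("outputs are equivariant under batch permutation", {
  m <- buildModel(smallCfg("panoptes1"), seed = 2)
  b <- randBatch(6, seed = 3)
  perm <- c(4, 1, 6, 2, 5, 3)
  bp <- list(x = lapply(b$x, function(a) a[, , , perm, drop = FALSE]))
  f1 <- modelForward(m, b, train = FALSE)
  f2 <- modelForward(m, bp, train = FALSE)
  expect_equal(f2$logits, f1$logits[, perm], tolerance = 1e-10)
  expect_equal(f2$features, f1$features[, perm], tolerance = 1e-10)
})

test_that("feature lengths follow the architecture bookkeeping", {
  for (fam in c("panoptes1", "panoptes2")) {
    cfg <- smallCfg(fam)
    m <- buildModel(cfg, 1)
    plan <- panoptes:::branchPlan(fam)
    c4 <- panoptes:::scaleCh(plan$ch, 0.1)[4]
    f <- forwardFeatures(m, randBatch(2))
    expect_equal(nrow(f), 3L * c4)
  }
  # panoptes3/4: the 1x1 feature-pool conv sets the pooled width
  cfg3 <- smallCfg("panoptes3")
  m3 <- buildModel(cfg3, 1)
  fp <- max(4L, round(1024 * 0.1))
  expect_equal(nrow(forwardFeatures(m3, randBatch(2))), fp)
  # clinical branch appends its 16-unit embedding
  cfgc <- smallCfg("panoptes1", useClinical = TRUE)
  mc <- buildModel(cfgc, 1)
  mc@clinicalStats <- panoptes:::fitClinicalStats(rnorm(10, 64), rnorm(10, 30))
  plan <- panoptes:::branchPlan("panoptes1")
  c4 <- panoptes:::scaleCh(plan$ch, 0.1)[4]
  expect_equal(nrow(forwardFeatures(mc, randBatch(2, clin = TRUE))),
               3L * c4 + 16L)
})

test_that("evaluation mode is deterministic and inputs matter", {
  m <- buildModel(smallCfg("panoptes2"), seed = 4)
  b <- randBatch(3, seed = 5)
  expect_identical(forwardFeatures(m, b), forwardFeatures(m, b))
  zero <- list(x = lapply(b$x, function(a) a * 0))
  expect_false(isTRUE(all.equal(forwardFeatures(m, b),
                                forwardFeatures(m, zero))))
})

test_that("baselines consume exactly the 10x member", {
  m <- buildModel(smallCfg("inception_v3"), seed = 1)
  b <- randBatch(3, seed = 6)
  only10 <- list(x = b$x["10x"])
  f1 <- modelForward(m, b, train = FALSE)
  f2 <- modelForward(m, only10, train = FALSE)
  expect_equal(f1$logits, f2$logits)
  expect_length(f1$aux, 1L)
  # altering the 5x member changes nothing
  b$x[["5x"]] <- b$x[["5x"]] * 0
  expect_equal(modelForward(m, b, train = FALSE)$logits, f1$logits)
})

test_that("parameter counts are monotone in the width multiplier", {
  counts <- vapply(c(0.1, 0.3, 0.6, 1.0), function(w) {
    parameterCount(buildModel(architectureConfig("panoptes4",
      widthMultiplier = w, inputPx = 75L), 1))
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("all nine families build and agree on spatial grids", {
  fams <- c(paste0("panoptes", 1:4), "inception_v1", "inception_v2",
            "inception_v3", "inception_resnet_v1", "inception_resnet_v2")
  for (fam in fams) {
    m <- buildModel(smallCfg(fam), seed = 1)
    fw <- modelForward(m, randBatch(2), train = FALSE)
    expect_equal(ncol(fw$logits), 2L)
  }
})

test_that("clinical embedding standardizes, imputes and stays length 16", {
  m <- buildModel(smallCfg("panoptes1", useClinical = TRUE), 1)
  age <- c(55, 60, 70, NA); bmi <- c(25, NA, 35, 30)
  m@clinicalStats <- panoptes:::fitClinicalStats(age, bmi)
  e <- clinicalEmbedding(m, age, bmi)
  expect_equal(dim(e), c(16L, 4L))
  expect_identical(e, clinicalEmbedding(m, age, bmi))
  # the training-mean point maps through the zero-standardized input
  st <- m@clinicalStats
  e0 <- clinicalEmbedding(m, st$muAge, st$muBmi)
  direct <- panoptes:::clinicalForward(m@params, matrix(c(0, 0, 0, 0), 4, 1))$y
  expect_equal(e0, direct)
  # wiring error when the clinical branch gets no inputs
  expect_error(modelForward(m, randBatch(2, clin = FALSE), train = FALSE),
               "clinical")
})

test_that("checkpoints refuse weights from a different architecture", {
  m <- buildModel(smallCfg("panoptes1"), 1)
  path <- file.path(withr::local_tempdir(), "m.ckpt")
  saveCheckpoint(m, path)
  back <- loadCheckpoint(path)
  expect_equal(back@params, m@params)
  expect_error(loadCheckpoint(path, smallCfg("panoptes2")), "fingerprint")
  expect_silent(loadCheckpoint(path, smallCfg("panoptes1")))
})
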