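# The Panoptes architecture family and single-resolution baselines.
#
# A Panoptes model runs three convolutional branch extractors — one per
# equivalent magnification (10x, 5x, 2.5x) of the same region — truncated
# before any pooling, concatenates their final feature maps on the channel
# axis (equal spatial grids are guaranteed by equal input sizes), optionally
# applies a 1x1 feature-pooling convolution (panoptes3/4), then global
# average pooling, optional concatenation of a clinical embedding (age/BMI),
# dropout, and a final fully connected layer. Each branch carries an
# auxiliary classifier head. Baselines are one branch on the 10x tile only.
# Branches are compact Inception(-ResNet)-style extractors: stem
# convolutions, inception blocks with parallel 1x1/3x3 paths (with a
# residual connection for the ResNet families), a strided reduction, and a
# 1x1 tail.

PANOPTES_FAMILIES <- c("panoptes1", "panoptes2", "panoptes3", "panoptes4")
BASELINE_FAMILIES <- c("inception_v1", "inception_v2", "inception_v3",
                       "inception_resnet_v1", "inception_resnet_v2")

#' ArchitectureConfig: model family and hyperparameters
#'
#' @slot family one of `panoptes1..4` (three-branch multi-resolution) or
#'   `inception_v1/v2/v3`, `inception_resnet_v1/v2` (single-resolution
#'   baselines on the 10x tile).
#' @slot useClinical add the age/BMI branch (embedding concatenated after
#'   pooling).
#' @slot featurePoolChannels channels of the optional 1x1 convolution
#'   between branch concatenation and pooling (panoptes3/4 only; default
#'   1024, scaled by the width multiplier).
#' @slot dropoutKeep dropout keep rate before the final layer (default 0.3).
#' @slot auxWeight weight of the auxiliary-classifier losses (default 0.4).
#' @slot widthMultiplier uniform channel scaling in (0, 1] for desk-scale
#'   runs (default 1).
#' @slot inputPx input tile side (default 299; may be reduced to >= 75 for
#'   CPU-scale testing).
#' @slot nClasses number of output classes (2).
#' @export
setClass("ArchitectureConfig",
  representation(family = "character", useClinical = "logical",
                 featurePoolChannels = "integer", dropoutKeep = "numeric",
                 auxWeight = "numeric", widthMultiplier = "numeric",
                 inputPx = "integer", nClasses = "integer"))

setValidity("ArchitectureConfig", function(object) {
  msg <- character()
  if (!object@family %in% c(PANOPTES_FAMILIES, BASELINE_FAMILIES))
    msg <- c(msg, paste("unknown family:", object@family))
  if (!(object@widthMultiplier > 0 && object@widthMultiplier <= 1))
    msg <- c(msg, "widthMultiplier must be in (0, 1]")
  if (object@inputPx < 75L) msg <- c(msg, "inputPx must be >= 75")
  if (!(object@dropoutKeep > 0 && object@dropoutKeep <= 1))
    msg <- c(msg, "dropoutKeep must be in (0, 1]")
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Construct an ArchitectureConfig
#' @param family architecture family name (see
#'   [ArchitectureConfig-class]).
#' @param useClinical include the clinical (age/BMI) branch.
#' @param featurePoolChannels 1x1 feature-pool channels (panoptes3/4).
#' @param dropoutKeep dropout keep rate.
#' @param auxWeight auxiliary loss weight.
#' @param widthMultiplier channel scaling in (0, 1].
#' @param inputPx input side length in pixels (>= 75).
#' @param nClasses output classes.
#' @return an [ArchitectureConfig-class]
#' @export
architectureConfig <- function(family = "panoptes2", useClinical = FALSE,
                               featurePoolChannels = 1024L,
                               dropoutKeep = 0.3, auxWeight = 0.4,
                               widthMultiplier = 1.0, inputPx = 299L,
                               nClasses = 2L) {
  new("ArchitectureConfig", family = family, useClinical = useClinical,
      featurePoolChannels = as.integer(featurePoolChannels),
      dropoutKeep = dropoutKeep, auxWeight = auxWeight,
      widthMultiplier = widthMultiplier, inputPx = as.integer(inputPx),
      nClasses = as.integer(nClasses))
}

setMethod("show", "ArchitectureConfig", function(object) {
  cat(sprintf("ArchitectureConfig %s%s: width %g, input %d px, dropout keep %g, aux %g\n",
              object@family, if (object@useClinical) " + clinical" else "",
              object@widthMultiplier, object@inputPx, object@dropoutKeep,
              object@auxWeight))
  invisible(NULL)
})

#' @keywords internal
isPanoptes <- function(family) grepl("^panoptes", family)

# Branch topology per family: base channels, number of inception blocks,
# residual connections. Panoptes1/3 branches follow the ResNet-v1 plan,
# panoptes2/4 the ResNet-v2 plan.
#' @keywords internal
branchPlan <- function(family) {
  key <- switch(family,
    panoptes1 = , panoptes3 = "inception_resnet_v1",
    panoptes2 = , panoptes4 = "inception_resnet_v2",
    family)
  switch(key,
    inception_v1 = list(ch = c(32, 64, 96, 128), blocks = 1L, residual = FALSE),
    inception_v2 = list(ch = c(32, 64, 96, 128), blocks = 2L, residual = FALSE),
    inception_v3 = list(ch = c(40, 80, 120, 160), blocks = 2L, residual = FALSE),
    inception_resnet_v1 = list(ch = c(32, 64, 96, 128), blocks = 1L, residual = TRUE),
    inception_resnet_v2 = list(ch = c(40, 80, 120, 160), blocks = 2L, residual = TRUE),
    stop("unknown family: ", key))
}

#' @keywords internal
scaleCh <- function(c, w) pmax(2L, as.integer(round(c * w)))

#' PanoptesModel: a built network
#'
#' @slot config the [ArchitectureConfig-class] it was built from.
#' @slot params named flat list of weight arrays.
#' @slot clinicalStats named list (mean/sd per clinical input) fitted on the
#'   training partition; empty until training.
#' @slot env geometry memoization environment.
#' @export
setClass("PanoptesModel",
  representation(config = "ArchitectureConfig", params = "list",
                 clinicalStats = "list", env = "environment"))

setMethod("show", "PanoptesModel", function(object) {
  cat(sprintf("PanoptesModel %s: %d parameters in %d arrays%s\n",
              object@config@family, parameterCount(object),
              length(object@params),
              if (object@config@useClinical) " (clinical branch fitted)" else ""))
  invisible(NULL)
})

#' Total trainable parameter count of a model
#' @param model a [PanoptesModel-class]
#' @return integer
#' @export
parameterCount <- function(model) {
  sum(vapply(model@params, length, integer(1)))
}

# Convolution weights plus the (non-trainable) running mean/variance
# buffers of the batch normalization that follows every convolution.
#' @keywords internal
convUnit <- function(name, cout, fanIn) {
  P <- list()
  P[[paste0(name, ".W")]] <- heInit(cout, fanIn)
  P[[paste0(name, ".b")]] <- numeric(cout)
  P[[paste0(name, ".rm")]] <- numeric(cout)
  P[[paste0(name, ".rv")]] <- rep(1, cout)
  P
}

#' @keywords internal
initBranchParams <- function(prefix, plan, w) {
  ch <- scaleCh(plan$ch, w)
  hc <- max(2L, ch[3] %/% 2L)
  P <- list()
  P <- c(P, convUnit(paste0(prefix, ".stem1"), ch[1], 9 * 3))
  P <- c(P, convUnit(paste0(prefix, ".stem2"), ch[2], 9 * ch[1]))
  for (j in seq_len(plan$blocks)) {
    bp <- paste0(prefix, ".block", j)
    P <- c(P, convUnit(paste0(bp, ".a"), hc, ch[2]))
    P <- c(P, convUnit(paste0(bp, ".b1"), hc, ch[2]))
    P <- c(P, convUnit(paste0(bp, ".b2"), hc, 9 * hc))
    P <- c(P, convUnit(paste0(bp, ".m"), ch[2], 2 * hc))
  }
  P <- c(P, convUnit(paste0(prefix, ".red"), ch[3], 9 * ch[2]))
  P[[paste0(prefix, ".aux.W")]] <- heInit(2, ch[3])
  P[[paste0(prefix, ".aux.b")]] <- numeric(2)
  P <- c(P, convUnit(paste0(prefix, ".tail"), ch[4], ch[3]))
  P
}

# conv -> batch norm; running-buffer updates are collected in `upd` during
# training and committed to the model by the training loop.
#' @keywords internal
convBnF <- function(x, P, name, k, s, p, genv, train, upd) {
  cv <- convF(x, P[[paste0(name, ".W")]], P[[paste0(name, ".b")]],
              k, s, p, genv)
  bn <- bnF(cv$y, P[[paste0(name, ".rm")]], P[[paste0(name, ".rv")]], train)
  if (train && !is.null(upd)) {
    upd[[paste0(name, ".rm")]] <- bn$newMean
    upd[[paste0(name, ".rv")]] <- bn$newVar
  }
  list(y = bn$y, cache = list(conv = cv$cache, bn = bn$cache, name = name))
}

#' @keywords internal
convBnB <- function(dy, cache, grads) {
  dc <- bnB(dy, cache$bn)
  bb <- convB(dc, cache$conv)
  grads <- accumGrad(grads, paste0(cache$name, ".W"), bb$dW)
  grads <- accumGrad(grads, paste0(cache$name, ".b"), bb$db)
  list(dx = bb$dx, grads = grads)
}

#' Build a model from an architecture configuration
#'
#' Panoptes families get three branch extractors (one per magnification)
#' with an auxiliary head each; baselines get a single branch fed by the
#' 10x tile. Initialization is He-normal, driven by `seed`.
#'
#' @param cfg an [ArchitectureConfig-class]
#' @param seed initialization seed
#' @return a [PanoptesModel-class]
#' @export
buildModel <- function(cfg, seed = 1L) {
  validObject(cfg)
  plan <- branchPlan(cfg@family)
  w <- cfg@widthMultiplier
  ch <- scaleCh(plan$ch, w)
  nb <- if (isPanoptes(cfg@family)) 3L else 1L
  withSeed(childSeed(seed, paste0("init_", cfg@family)), {
    P <- list()
    for (b in seq_len(nb))
      P <- c(P, initBranchParams(paste0("br", b), plan, w))
    featC <- nb * ch[4]
    if (cfg@family %in% c("panoptes3", "panoptes4")) {
      fp <- max(4L, as.integer(round(cfg@featurePoolChannels * w)))
      P <- c(P, convUnit("pool", fp, featC))
      featC <- fp
    }
    featF <- featC
    if (cfg@useClinical) {
      P[["clin1.W"]] <- heInit(16, 4)
      P[["clin1.b"]] <- numeric(16)
      P[["clin2.W"]] <- heInit(16, 16)
      P[["clin2.b"]] <- numeric(16)
      featF <- featF + 16L
    }
    P[["head.W"]] <- heInit(cfg@nClasses, featF)
    P[["head.b"]] <- numeric(cfg@nClasses)
    new("PanoptesModel", config = cfg, params = P,
        clinicalStats = list(), env = new.env(parent = emptyenv()))
  })
}

#' @keywords internal
branchForward <- function(x, P, prefix, plan, genv, train = FALSE,
                          upd = NULL) {
  c1 <- convBnF(x, P, paste0(prefix, ".stem1"), 3L, 2L, 1L, genv, train, upd)
  r1 <- reluF(c1$y)
  c2 <- convBnF(r1$y, P, paste0(prefix, ".stem2"), 3L, 2L, 1L, genv, train, upd)
  r2 <- reluF(c2$y)
  h <- r2$y
  blocks <- list()
  for (j in seq_len(plan$blocks)) {
    bp <- paste0(prefix, ".block", j)
    a <- convBnF(h, P, paste0(bp, ".a"), 1L, 1L, 0L, genv, train, upd)
    ra <- reluF(a$y)
    b1 <- convBnF(h, P, paste0(bp, ".b1"), 1L, 1L, 0L, genv, train, upd)
    rb1 <- reluF(b1$y)
    b2 <- convBnF(rb1$y, P, paste0(bp, ".b2"), 3L, 1L, 1L, genv, train, upd)
    rb2 <- reluF(b2$y)
    hcn <- dim(ra$y)[3]
    cat4 <- array(0, c(dim(ra$y)[1:2], 2L * hcn, dim(ra$y)[4]))
    cat4[, , seq_len(hcn), ] <- ra$y
    cat4[, , hcn + seq_len(hcn), ] <- rb2$y
    m <- convBnF(cat4, P, paste0(bp, ".m"), 1L, 1L, 0L, genv, train, upd)
    pre <- if (plan$residual) m$y + h else m$y
    rm_ <- reluF(pre)
    blocks[[j]] <- list(a = a, ra = ra, b1 = b1, rb1 = rb1, b2 = b2,
                        rb2 = rb2, m = m, rm = rm_, hcn = hcn)
    h <- rm_$y
  }
  red <- convBnF(h, P, paste0(prefix, ".red"), 3L, 2L, 1L, genv, train, upd)
  rr <- reluF(red$y)
  ag <- gapF(rr$y)
  auxl <- denseF(ag$y, P[[paste0(prefix, ".aux.W")]], P[[paste0(prefix, ".aux.b")]])
  tl <- convBnF(rr$y, P, paste0(prefix, ".tail"), 1L, 1L, 0L, genv, train, upd)
  rt <- reluF(tl$y)
  list(y = rt$y, aux = auxl$y,
       cache = list(c1 = c1, r1 = r1, c2 = c2, r2 = r2, blocks = blocks,
                    red = red, rr = rr, ag = ag, auxl = auxl, tl = tl,
                    rt = rt, residual = plan$residual, prefix = prefix))
}

#' @keywords internal
branchBackward <- function(dy, daux, cache, grads) {
  pr <- cache$prefix
  # tail
  dtl <- reluB(dy, cache$rt$cache)
  bb <- convBnB(dtl, cache$tl$cache, grads); grads <- bb$grads
  drr <- bb$dx
  # aux head
  if (!is.null(daux)) {
    db <- denseB(daux, cache$auxl$cache)
    grads <- accumGrad(grads, paste0(pr, ".aux.W"), db$dW)
    grads <- accumGrad(grads, paste0(pr, ".aux.b"), db$db)
    drr <- drr + gapB(db$dx, cache$ag$cache)
  }
  dred <- reluB(drr, cache$rr$cache)
  bb <- convBnB(dred, cache$red$cache, grads); grads <- bb$grads
  dh <- bb$dx
  for (j in rev(seq_along(cache$blocks))) {
    bl <- cache$blocks[[j]]
    dpre <- reluB(dh, bl$rm$cache)
    bb <- convBnB(dpre, bl$m$cache, grads); grads <- bb$grads
    dcat <- bb$dx
    hcn <- bl$hcn
    dra <- dcat[, , seq_len(hcn), , drop = FALSE]
    drb2 <- dcat[, , hcn + seq_len(hcn), , drop = FALSE]
    # path b
    db2 <- reluB(drb2, bl$rb2$cache)
    bb <- convBnB(db2, bl$b2$cache, grads); grads <- bb$grads
    db1 <- reluB(bb$dx, bl$rb1$cache)
    bb <- convBnB(db1, bl$b1$cache, grads); grads <- bb$grads
    dh_in <- bb$dx
    # path a
    da <- reluB(dra, bl$ra$cache)
    bb <- convBnB(da, bl$a$cache, grads); grads <- bb$grads
    dh_in <- dh_in + bb$dx
    if (cache$residual) dh_in <- dh_in + dpre
    dh <- dh_in
  }
  dr2 <- reluB(dh, cache$r2$cache)
  bb <- convBnB(dr2, cache$c2$cache, grads); grads <- bb$grads
  dr1 <- reluB(bb$dx, cache$r1$cache)
  bb <- convBnB(dr1, cache$c1$cache, grads); grads <- bb$grads
  grads
}

#' @keywords internal
clinicalForward <- function(P, clin) {
  d1 <- denseF(clin, P[["clin1.W"]], P[["clin1.b"]])
  rd1 <- reluF(d1$y)
  d2 <- denseF(rd1$y, P[["clin2.W"]], P[["clin2.b"]])
  rd2 <- reluF(d2$y)
  list(y = rd2$y, cache = list(d1 = d1, rd1 = rd1, d2 = d2, rd2 = rd2))
}

#' Full forward pass
#'
#' @param model a [PanoptesModel-class]
#' @param batch list with `x`, a named list of input arrays
#'   `[h, w, 3, n]` keyed `"10x"`, `"5x"`, `"2.5x"` (baselines use only
#'   `"10x"`), and optionally `clin`, a `[4, n]` matrix of standardized
#'   (age, bmi, missing-age, missing-bmi) rows.
#' @param train training mode (dropout active; draws from the RNG).
#' @return list with `logits` (`[nClasses, n]`), `aux` (list of per-branch
#'   auxiliary logits), `features` (post-pooling, post-clinical-concat
#'   feature matrix `[F, n]`) and `cache` for the backward pass.
#' @export
modelForward <- function(model, batch, train = FALSE) {
  cfg <- model@config
  P <- model@params
  plan <- branchPlan(cfg@family)
  mags <- if (isPanoptes(cfg@family)) c("10x", "5x", "2.5x") else "10x"
  upd <- if (train) new.env(parent = emptyenv()) else NULL
  brs <- list()
  for (b in seq_along(mags)) {
    xb <- batch$x[[mags[b]]]
    if (is.null(xb)) stop("batch is missing the ", mags[b], " input")
    xb <- (xb - 0.5) * 2   # Inception-lineage input scaling to [-1, 1]
    brs[[b]] <- branchForward(xb, P, paste0("br", b), plan, model@env,
                              train, upd)
  }
  sp <- lapply(brs, function(r) dim(r$y)[1:2])
  if (length(brs) > 1 && !all(vapply(sp, identical, logical(1), sp[[1]])))
    stop("branch spatial grids differ; inputs must share one size")
  d1 <- dim(brs[[1]]$y)
  cpb <- vapply(brs, function(r) dim(r$y)[3], integer(1))
  conc <- array(0, c(d1[1], d1[2], sum(cpb), d1[4]))
  off <- 0L
  for (b in seq_along(brs)) {
    conc[, , off + seq_len(cpb[b]), ] <- brs[[b]]$y
    off <- off + cpb[b]
  }
  poolc <- NULL
  hmap <- conc
  if (!is.null(P[["pool.W"]])) {
    poolc <- convBnF(conc, P, "pool", 1L, 1L, 0L, model@env, train, upd)
    poolr <- reluF(poolc$y)
    hmap <- poolr$y
  } else poolr <- NULL
  gp <- gapF(hmap)
  feats <- gp$y
  clinc <- NULL
  if (cfg@useClinical) {
    if (is.null(batch$clin))
      stop("model has a clinical branch but the batch carries no clinical inputs")
    clinc <- clinicalForward(P, batch$clin)
    feats <- rbind(feats, clinc$y)
  }
  dp <- dropoutF(feats, cfg@dropoutKeep, train)
  head <- denseF(dp$y, P[["head.W"]], P[["head.b"]])
  list(logits = head$y, aux = lapply(brs, `[[`, "aux"), features = feats,
       cache = list(brs = brs, cpb = cpb, poolc = poolc, poolr = poolr,
                    gp = gp, clinc = clinc, dp = dp, head = head,
                    dimConc = dim(conc), nImgFeat = nrow(gp$y),
                    bnUpdates = if (is.null(upd)) list() else
                      as.list(upd, all.names = TRUE)))
}

#' @keywords internal
modelBackward <- function(model, fw, dlogits, dauxs) {
  P <- model@params
  cfg <- model@config
  grads <- list()
  hb <- denseB(dlogits, fw$cache$head$cache)
  grads <- accumGrad(grads, "head.W", hb$dW)
  grads <- accumGrad(grads, "head.b", hb$db)
  dfeat <- dropoutB(hb$dx, fw$cache$dp$cache)
  nimg <- fw$cache$nImgFeat
  dimg <- dfeat[seq_len(nimg), , drop = FALSE]
  if (cfg@useClinical) {
    dclin <- dfeat[nimg + seq_len(16), , drop = FALSE]
    cl <- fw$cache$clinc$cache
    dd2 <- reluB(dclin, cl$rd2$cache)
    bb <- denseB(dd2, cl$d2$cache)
    grads <- accumGrad(grads, "clin2.W", bb$dW)
    grads <- accumGrad(grads, "clin2.b", bb$db)
    dd1 <- reluB(bb$dx, cl$rd1$cache)
    bb <- denseB(dd1, cl$d1$cache)
    grads <- accumGrad(grads, "clin1.W", bb$dW)
    grads <- accumGrad(grads, "clin1.b", bb$db)
  }
  dhmap <- gapB(dimg, fw$cache$gp$cache)
  if (!is.null(fw$cache$poolc)) {
    dpool <- reluB(dhmap, fw$cache$poolr$cache)
    bb <- convBnB(dpool, fw$cache$poolc$cache, grads)
    grads <- bb$grads
    dconc <- bb$dx
  } else dconc <- dhmap
  off <- 0L
  for (b in seq_along(fw$cache$brs)) {
    nc <- fw$cache$cpb[b]
    dyb <- dconc[, , off + seq_len(nc), , drop = FALSE]
    off <- off + nc
    grads <- branchBackward(dyb, dauxs[[b]], fw$cache$brs[[b]]$cache, grads)
  }
  grads
}

#' Post-pooling feature vectors for a batch
#'
#' Returns the feature map before the final fully connected layer — the
#' pooled branch features, with the clinical embedding appended when the
#' model has a clinical branch. Evaluation mode (deterministic).
#'
#' @inheritParams modelForward
#' @return `[F, n]` numeric matrix
#' @export
forwardFeatures <- function(model, batch) {
  modelForward(model, batch, train = FALSE)$features
}

#' Clinical embedding of age/BMI inputs
#'
#' Standardizes age and BMI with the constants fitted on the training
#' partition (see [trainModel]) and applies the 2-layer perceptron
#' (2 + missingness flags -> 16 -> 16).
#'
#' @param model a trained [PanoptesModel-class] with a clinical branch
#' @param age,bmi numeric vectors (NA allowed; imputed with the training
#'   median and flagged)
#' @return `[16, n]` embedding matrix
#' @export
clinicalEmbedding <- function(model, age, bmi) {
  if (!model@config@useClinical) stop("model has no clinical branch")
  clin <- standardizeClinical(model@clinicalStats, age, bmi)
  clinicalForward(model@params, clin)$y
}

#' @keywords internal
fitClinicalStats <- function(age, bmi) {
  list(medAge = median(age, na.rm = TRUE), medBmi = median(bmi, na.rm = TRUE),
       muAge = mean(age, na.rm = TRUE), sdAge = max(sd(age, na.rm = TRUE), 1e-6),
       muBmi = mean(bmi, na.rm = TRUE), sdBmi = max(sd(bmi, na.rm = TRUE), 1e-6))
}

#' @keywords internal
standardizeClinical <- function(stats, age, bmi) {
  if (!length(stats)) stop("clinical standardization constants not fitted")
  ma <- is.na(age); mb <- is.na(bmi)
  age[ma] <- stats$medAge; bmi[mb] <- stats$medBmi
  rbind((age - stats$muAge) / stats$sdAge,
        (bmi - stats$muBmi) / stats$sdBmi,
        as.numeric(ma), as.numeric(mb))
}

#' Configuration fingerprint of a model or config
#' @param x an [ArchitectureConfig-class] or [PanoptesModel-class]
#' @return md5 hex string
#' @export
configFingerprint <- function(x) {
  cfg <- if (is(x, "PanoptesModel")) x@config else x
  jsonFingerprint(list(family = cfg@family, useClinical = cfg@useClinical,
                       featurePoolChannels = cfg@featurePoolChannels,
                       dropoutKeep = cfg@dropoutKeep, auxWeight = cfg@auxWeight,
                       widthMultiplier = cfg@widthMultiplier,
                       inputPx = cfg@inputPx, nClasses = cfg@nClasses))
}

#' Save / load a model checkpoint
#'
#' The checkpoint couples the weights with the architecture fingerprint;
#' loading refuses weights whose fingerprint does not match the target
#' configuration.
#'
#' @param model a [PanoptesModel-class]
#' @param path checkpoint file
#' @return [saveCheckpoint]: `path` invisibly; [loadCheckpoint]: a
#'   [PanoptesModel-class]
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(fingerprint = configFingerprint(model),
               config = model@config, params = model@params,
               clinicalStats = model@clinicalStats), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @param cfg optional [ArchitectureConfig-class] the weights must match
#' @export
loadCheckpoint <- function(path, cfg = NULL) {
  ck <- readRDS(path)
  if (!is.null(cfg) && !identical(configFingerprint(cfg), ck$fingerprint))
    stop("checkpoint fingerprint ", ck$fingerprint,
         " does not match the requested architecture ", configFingerprint(cfg))
  new("PanoptesModel", config = ck$config, params = ck$params,
      clinicalStats = ck$clinicalStats, env = new.env(parent = emptyenv()))
}
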