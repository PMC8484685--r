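# Shared fixtures, built in code at test time.

to255 <- function(img) round(img * 255)

# Brute-force AUROC over all positive x negative pairs, ties counted 1/2.
pairwiseAuroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Independent average precision: precision at each descending-score
# threshold weighted by the recall increment.
naiveAupr <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prevRec <- 0; ap <- 0; npos <- sum(labels == 1)
  for (t in thr) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / npos
    ap <- ap + (rec - prevRec) * prec
    prevRec <- rec
  }
  ap
}

# Independent simulation of the validate/checkpoint/early-stop policy.
scheduleOracle <- function(trainLosses, valLosses, validateEvery, lossminFrom,
                           patience, minStop, maxIter) {
  bestTrain <- Inf; bestVal <- Inf; lastMin <- 0; events <- list()
  stopped <- maxIter; bestIter <- NA
  vi <- 0
  for (it in seq_len(maxIter)) {
    tl <- trainLosses[it]
    newMin <- tl < bestTrain
    if (newMin) bestTrain <- tl
    if (it %% validateEvery == 0 || (newMin && it >= lossminFrom)) {
      vi <- vi + 1
      vl <- valLosses[vi]
      ck <- vl < bestVal
      if (ck) { bestVal <- vl; lastMin <- it; bestIter <- it }
      events[[length(events) + 1]] <- c(it, vl, ck)
    }
    if (it >= minStop && (it - lastMin) >= patience) { stopped <- it; break }
  }
  list(events = do.call(rbind, events), stopped = stopped,
       bestIter = bestIter)
}

# Tile a written cohort into a record store (75 px records) and return the
# store directory. The learning studies skip stain normalization: synthetic
# slides are rendered in one common basis, so normalization is an identity
# up to estimation noise there (its properties are verified separately).
buildRecordStore <- function(cohortDir, labels, splitSeed, outDir,
                             mode = "mixed", held = NULL, profile = NULL) {
  split <- makeSplit(labels, "tumor_class", mode, seed = splitSeed,
                     heldOutCohort = held)
  part <- stats::setNames(split$partition, split$patient_id)
  wr <- recordStoreWriter(outDir)
  for (i in seq_len(nrow(labels))) {
    sid <- labels$slide_id[i]; pid <- labels$patient_id[i]
    slide <- openSlide(file.path(cohortDir, paste0(sid, ".tiff")))
    tileSlide(slide, tileFilterConfig(), profile = profile,
              patientId = pid, storePx = 75L,
              sink = function(ts) wr$add(ts, labels$tumor_class[i],
                                         labels$age[i], labels$bmi[i],
                                         unname(part[pid])))
  }
  wr$finish("tumor_class", "store")
  outDir
}

# In-memory pyramid with pages derived from a level-0 image by area
# averaging (the generator's construction).
pyramidFrom <- function(img0, baseMag, nLevels = 3L, slideId = "fix") {
  pages <- list(img0)
  for (l in seq_len(nLevels - 1L))
    pages[[l + 1L]] <- areaDownsample(pages[[l]], 2L)
  slidePyramid(pages, slideId = slideId, baseMag = baseMag)
}

# Metadata-only pyramid (no pixels) for pure-geometry operations.
fakePyramid <- function(w, h, baseMag, slideId = "geom") {
  lv <- data.frame(width = w, height = h, downsample = 1)
  new("SlidePyramid", slideId = slideId, levels = lv, mpp = NA_real_,
      baseMag = baseMag, source = "", pages = list(),
      cache = new.env(parent = emptyenv()))
}

# Smooth low-frequency level-0 image (resample-friendly; values in
# mid-range so nothing trips the background filter).
smoothImage <- function(h, w, seed = 1) {
  withr::with_seed(seed, {
    base <- matrix(runif(36, 0.3, 0.7), 6, 6)
    ch <- bilinearResize(base, h, w)
    arr <- array(0, c(h, w, 3))
    for (k in 1:3) arr[, , k] <- pmin(pmax(ch * (0.8 + 0.1 * k), 0), 1)
    quantize8(arr)
  })
}

# Two-dye tile rendered from a known basis with nonnegative random
# concentrations; moderate optical densities (realistic tissue range).
oracleStainTile <- function(n = 120L, S = defaultStainProfile()@stainMatrix,
                            seed = 3, hMean = 0.7, eMean = 0.37) {
  withr::with_seed(seed, {
    C <- cbind(pmin(rexp(n * n, 1 / hMean), 2.2),
               pmin(rexp(n * n, 1 / eMean), 1.2))
    list(tile = odToRgb(array(C %*% S, c(n, n, 3))), C = C, S = S)
  })
}

# Perturbed-but-valid H&E-like basis, ~0.11 rad from the default.
perturbedBasis <- function() {
  S <- rbind(c(0.72, 0.62, 0.31), c(0.12, 0.93, 0.20))
  S / sqrt(rowSums(S^2))
}

# A uniform-valued square tile on the 8-bit grid.
flatTile <- function(px, value255) {
  array(value255 / 255, c(px, px, 3))
}

# Tile with exactly k pure-white pixels, the rest mid-gray.
whiteFractionTile <- function(px, k) {
  t <- flatTile(px, 128)
  if (k > 0) {
    idx <- seq_len(k)
    for (ch in 1:3) {
      pl <- t[, , ch]
      pl[idx] <- 1
      t[, , ch] <- pl
    }
  }
  t
}

# Small label table: n patients, balanced classes, optional extra slides.
labelFixture <- function(n, posFrac = 0.5, slides = 1L, cohortB = 0.2,
                         seed = 1) {
  withr::with_seed(seed, {
    cls <- rep(c(1, 0), c(round(n * posFrac), n - round(n * posFrac)))
    coh <- ifelse(runif(n) < cohortB, "B", "A")
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(patient_id = sprintf("P%03d", i),
                 slide_id = sprintf("P%03d_S%d", i, seq_len(slides)),
                 cohort = coh[i], tumor_class = cls[i],
                 age = round(rnorm(1, 64, 10), 1),
                 bmi = round(rnorm(1, 30, 6), 1))
    }))
  })
}

# Random prediction table.
predFixture <- function(n = 40, seed = 1, signal = 1, patients = NULL) {
  withr::with_seed(seed, {
    if (is.null(patients)) patients <- sprintf("P%02d", seq_len(max(2, n %/% 4)))
    pid <- patients[1 + (seq_len(n) - 1) %% length(patients)]
    lab <- rbinom(n, 1, 0.5)
    if (length(unique(lab)) == 1) lab[1] <- 1 - lab[1]
    sc <- pmin(pmax(0.5 + signal * 0.2 * (lab - 0.5) + rnorm(n, 0, 0.2), 0), 1)
    data.frame(patient_id = pid, slide_id = paste0(pid, "_S1"),
               tile_set_id = sprintf("t%04d", seq_len(n)),
               score = sc, true_label = lab)
  })
}

# Tiny tile-set tensor store synthesized directly (bypasses slides) for
# model/training mechanics tests; class shifts the mean of every channel so
# the problem is trivially separable when `shift` is large.
tinyTensors <- function(n = 16, px = 75L, shift = 0.15, seed = 1) {
  withr::with_seed(seed, {
    lab <- rep(c(1L, 2L), length.out = n)
    mk <- function() {
      m <- vapply(seq_len(n), function(i) {
        v <- runif(px * px * 3, 0.35, 0.65) + (lab[i] - 1L) * shift
        as.raw(round(pmin(pmax(v, 0), 1) * 255))
      }, raw(px * px * 3))
      matrix(m, px * px * 3, n)
    }
    pix <- list(`10x` = mk(), `5x` = mk(), `2.5x` = mk())
    list(pix = pix,
         dims = list(`10x` = c(px, px, 3), `5x` = c(px, px, 3),
                     `2.5x` = c(px, px, 3)),
         labels = lab,
         age = rnorm(n, 64, 10), bmi = rnorm(n, 30, 6),
         patient_id = sprintf("P%02d", rep(seq_len(max(2, n %/% 4)),
                                           length.out = n)),
         slide_id = sprintf("S%02d", seq_len(n)),
         tile_set_id = sprintf("t%03d", seq_len(n)),
         anchor = cbind(rep(0, n), rep(0, n)),
         cell_index = cbind(rep(1L, n), rep(1L, n)))
  })
}

# One real tiled slide shared by several test files (cached per session).
.fixtureEnv <- new.env(parent = emptyenv())
tiledSlideFixture <- function() {
  if (is.null(.fixtureEnv$tiled)) {
    spec <- syntheticSlideSpec(seed = 42, extent10x = 1196,
                               backgroundFraction = 0, contaminants = 0,
                               class = 0, slideId = "fixslide")
    g <- generateSlide(spec)
    res <- tileSlide(g$slide, tileFilterConfig(), profile = NULL,
                     patientId = "Pfix")
    .fixtureEnv$tiled <- list(slide = g$slide, mask = g$mask,
                              sets = res$tileSets, summary = res$summary)
  }
  .fixtureEnv$tiled
}
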