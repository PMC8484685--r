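# Synthetic pyramidal slides with scale-specific class signal.
#
# Tissue is rendered through the same two-dye optical-density model the
# stain module assumes: an eosin-like concentration field (stroma/gland
# texture) and a hematoxylin-like field (diffuse baseline plus Poisson
# nuclear dots), combined with a stain basis and exponentiated to RGB.
# The class signal is planted at a chosen spatial scale:
#   macro — the eosin field's correlation length grows by (1 + effect) for
#     class 1 while its single-pixel marginal distribution is fixed exactly
#     by rank transformation and the micro texture is identical, so 10x
#     tiles are nearly class-indistinguishable while 2.5x tiles differ in
#     their within-tile spatial structure;
#   micro — the nuclear-dot density grows by (1 + effect) for class 1 with
#     identical macro arrangement;
#   none — no class difference.
# Slides carry white margins (all channels > 200) and dark contaminant
# patches (all channels < 50) exercising the background filter, plus a
# ground-truth mask (0 background, 1 tissue, 2 contaminant).

#' Specification of one synthetic slide
#'
#' @param seed RNG seed; the whole slide is a pure function of the spec.
#' @param extent10x slide extent in pixels at 10x equivalent (scalar or
#'   (width, height)); rounded up to a multiple of 4 for the pyramid.
#' @param backgroundFraction target white-margin areal fraction.
#' @param contaminants number of dark contaminant disks.
#' @param class 0 or 1.
#' @param signalScale `"macro"`, `"micro"` or `"none"`.
#' @param effect texture-parameter separation between classes (>= 0): the
#'   macro correlation length or nuclear-dot density of class 1 is
#'   `(1 + effect)` times that of class 0.
#' @param profile [StainProfile-class] whose basis renders the slide.
#' @param slideId slide identifier.
#' @param nLevels pyramid depth (downsample factors 1, 2, 4, ...).
#' @return object of class `syntheticSlideSpec` (a list)
#' @export
syntheticSlideSpec <- function(seed = 1L, extent10x = 1196L,
                               backgroundFraction = 0.1, contaminants = 1L,
                               class = 0L, signalScale = c("macro", "micro", "none"),
                               effect = 1, profile = defaultStainProfile(),
                               slideId = "synthetic", nLevels = 3L) {
  signalScale <- match.arg(signalScale)
  extent10x <- rep(as.integer(extent10x), length.out = 2L)
  extent10x <- as.integer(ceiling(extent10x / 4) * 4)
  stopifnot(all(extent10x >= 1196L %/% 4L * 0 + 4L), effect >= 0,
            backgroundFraction >= 0, backgroundFraction < 0.9)
  structure(list(seed = as.integer(seed), extent10x = extent10x,
                 backgroundFraction = backgroundFraction,
                 contaminants = as.integer(contaminants),
                 class = as.integer(class), signalScale = signalScale,
                 effect = effect, profile = profile, slideId = slideId,
                 nLevels = as.integer(nLevels)),
            class = "syntheticSlideSpec")
}

# Dense 1-D linear-interpolation operator mapping nIn samples to nOut
# (center-aligned), so a field upsample is two small matrix products.
#' @keywords internal
interpMatrix <- function(nOut, nIn) {
  xi <- (seq_len(nOut) - 0.5) * nIn / nOut - 0.5
  xi <- pmin(pmax(xi, 0), nIn - 1)
  x0 <- pmin(floor(xi), nIn - 2)
  wx <- xi - x0
  M <- matrix(0, nOut, nIn)
  M[cbind(seq_len(nOut), x0 + 1)] <- 1 - wx
  M[cbind(seq_len(nOut), x0 + 2)] <- M[cbind(seq_len(nOut), x0 + 2)] + wx
  M
}

# Smooth Gaussian random field with the given correlation length, built by
# bilinear upsampling of a coarse white-noise lattice.
#' @keywords internal
smoothField <- function(h, w, scale) {
  ny <- max(2L, ceiling(h / scale) + 1L)
  nx <- max(2L, ceiling(w / scale) + 1L)
  coarse <- matrix(rnorm(ny * nx), ny, nx)
  interpMatrix(h, ny) %*% coarse %*% t(interpMatrix(w, nx))
}

# Generator texture constants: the conditions of the synthetic study.
# The macro correlation length sits well above the 10x tile field (299 px)
# in units of micro-texture wavelengths, while a 2.5x tile (1196 px at 10x
# equivalent) spans several macro modes, so the class contrast in the
# macro scale is estimable per 2.5x tile; the micro texture amplitude
# dominates within-10x-tile variation, masking the residual macro slope
# there.
.synMacroScale <- 300      # base eosin correlation length, 10x px
.synMicroScale <- 8        # fine eosin texture correlation length, 10x px
.synMacroAmp <- 1.0
.synMicroAmp <- 2.5
.synDotDensity <- 300      # nuclear dots per 299x299 region at 10x
.synDotSd <- 2.2           # dot Gaussian radius, px
.synDiffuseH <- 0.20       # diffuse hematoxylin concentration

#' Generate one synthetic pyramidal slide
#'
#' @param spec a [syntheticSlideSpec]
#' @param path optional TIFF output path; the pyramid is written with
#'   [writeSlide] and the mask to `<path>.mask.tiff` (codes 0/1/2 scaled
#'   by 1/255)
#' @return list: `slide` (an in-memory [SlidePyramid-class]), `mask`
#'   (integer matrix, 0 background / 1 tissue / 2 contaminant), `spec`
#' @export
generateSlide <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "syntheticSlideSpec"))
  w <- spec$extent10x[1]; h <- spec$extent10x[2]
  img <- withSeed(childSeed(spec$seed, paste0("slide_", spec$slideId)), {
    macroScale <- .synMacroScale *
      (1 + if (spec$signalScale == "macro") spec$effect * spec$class else 0)
    dotDensity <- .synDotDensity *
      (1 + if (spec$signalScale == "micro") spec$effect * spec$class else 0)
    eMacro <- smoothField(h, w, macroScale)
    eMicro <- smoothField(h, w, .synMicroScale)
    eRaw <- .synMacroAmp * eMacro + .synMicroAmp * eMicro
    # fix the single-pixel marginal exactly: rank -> Beta(2,2) on [0.35, 1]
    # (quantiles through a fine interpolation grid; qbeta itself is costly
    # at megapixel scale)
    u <- rank(eRaw, ties.method = "first") / (length(eRaw) + 1)
    qgrid <- stats::qbeta(seq(0, 1, length.out = 2048), 2, 2)
    qv <- stats::approx(seq(0, 1, length.out = 2048), qgrid, xout = u,
                        rule = 2)$y
    eConc <- matrix(0.35 + 0.65 * qv, h, w)
    # hematoxylin: diffuse base + Poisson nuclear dots
    nDots <- rpois(1, dotDensity * (w * h) / 299^2)
    hConc <- matrix(.synDiffuseH, h, w)
    if (nDots > 0) {
      dx <- runif(nDots, 1, w); dy <- runif(nDots, 1, h)
      amp <- runif(nDots, 0.7, 1.1)
      r <- 5L
      off <- expand.grid(oy = -r:r, ox = -r:r)
      kw <- exp(-(off$oy^2 + off$ox^2) / (2 * .synDotSd^2))
      pyl <- round(dy); pxl <- round(dx)
      iy <- rep(pyl, each = nrow(off)) + rep(off$oy, nDots)
      ix <- rep(pxl, each = nrow(off)) + rep(off$ox, nDots)
      vv <- rep(amp, each = nrow(off)) * rep(kw, nDots)
      ok <- iy >= 1 & iy <= h & ix >= 1 & ix <= w
      lin <- iy[ok] + (ix[ok] - 1) * h
      acc <- rowsum(vv[ok], lin)
      hConc[as.integer(rownames(acc))] <- hConc[as.integer(rownames(acc))] +
        acc[, 1]
    }
    eConc <- pmax(eConc + matrix(rnorm(h * w, sd = 0.02), h, w), 0)
    S <- spec$profile@stainMatrix
    od <- array(0, c(h, w, 3))
    for (ch in 1:3) od[, , ch] <- hConc * S[1, ch] + eConc * S[2, ch]
    odToRgb(od)
  })
  mask <- matrix(1L, h, w)
  # white margins sized for the target background fraction
  if (spec$backgroundFraction > 0) {
    mfrac <- (1 - sqrt(1 - spec$backgroundFraction)) / 2
    mw <- round(w * mfrac); mh <- round(h * mfrac)
    if (mw > 0) mask[, c(seq_len(mw), (w - mw + 1):w)] <- 0L
    if (mh > 0) mask[c(seq_len(mh), (h - mh + 1):h), ] <- 0L
  }
  # dark contaminant disks inside the tissue area
  if (spec$contaminants > 0) {
    ctr <- withSeed(childSeed(spec$seed, paste0("contam_", spec$slideId)), {
      rad <- max(8, round(min(w, h) / 40))
      cbind(x = runif(spec$contaminants, rad + 1, w - rad),
            y = runif(spec$contaminants, rad + 1, h - rad), r = rad)
    })
    xs <- matrix(rep(seq_len(w), each = h), h, w)
    ys <- matrix(rep(seq_len(h), w), h, w)
    for (i in seq_len(nrow(ctr))) {
      d2 <- (xs - ctr[i, "x"])^2 + (ys - ctr[i, "y"])^2
      mask[d2 <= ctr[i, "r"]^2 & mask == 1L] <- 2L
    }
  }
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[mask == 0L] <- 1.0          # white glass, 255 on the 8-bit scale
    pl[mask == 2L] <- 30 / 255     # dark debris, below the low bound
    img[, , ch] <- pl
  }
  pages <- list(img)
  for (l in seq_len(spec$nLevels - 1L))
    pages[[l + 1L]] <- areaDownsample(pages[[l]], 2L)
  slide <- slidePyramid(pages, slideId = spec$slideId, baseMag = 10)
  if (!is.null(path)) {
    writeSlide(slide, path)
    tiff::writeTIFF(mask / 255, paste0(path, ".mask.tiff"),
                    bits.per.sample = 8L)
  }
  list(slide = slide, mask = mask, spec = spec)
}

#' Generate a synthetic cohort: slides plus a label table
#'
#' Per-patient binary class labels at the requested balance (exact counts),
#' `slidesPerPatient` slides each, age ~ N(64, 10) years and BMI
#' ~ N(30, 6) kg/m^2 (optionally class-shifted to exercise the clinical
#' branch), and cohort membership A/B at the given fraction. Labels follow
#' the standard schema with task column `tumor_class`.
#'
#' @param nPatients number of patients (>= 4)
#' @param slidesPerPatient slides per patient
#' @param classBalance positive-class fraction (exact count
#'   `round(nPatients * classBalance)`)
#' @param signalScale,effect class-signal placement (see
#'   [syntheticSlideSpec])
#' @param seed cohort seed
#' @param extent10x slide extent at 10x equivalent
#' @param backgroundFraction,contaminants slide composition
#' @param ageShift,bmiShift additive shift of age/BMI for class-1 patients
#' @param cohortFrac fraction of patients in cohort A
#' @param dir optional directory: slides are written as pyramidal TIFFs and
#'   `labels.csv` alongside; otherwise slides stay in memory
#' @return list: `labels` (data.frame), `slides` (named list of
#'   [SlidePyramid-class] or file paths), `masks` (named list, in-memory
#'   mode only)
#' @export
generateCohort <- function(nPatients, slidesPerPatient = 1L,
                           classBalance = 0.5, signalScale = "macro",
                           effect = 1, seed = 1L, extent10x = 1196L,
                           backgroundFraction = 0.1, contaminants = 0L,
                           ageShift = 0, bmiShift = 0, cohortFrac = 0.8,
                           dir = NULL) {
  stopifnot(nPatients >= 4L)
  meta <- withSeed(childSeed(seed, "cohortmeta"), {
    nPos <- round(nPatients * classBalance)
    cls <- sample(rep(c(1L, 0L), c(nPos, nPatients - nPos)))
    coh <- ifelse(seq_len(nPatients) <= round(cohortFrac * nPatients), "A", "B")
    coh <- sample(coh)
    age <- round(rnorm(nPatients, 64, 10) + ageShift * cls, 1)
    bmi <- round(rnorm(nPatients, 30, 6) + bmiShift * cls, 1)
    list(cls = cls, coh = coh, age = pmax(age, 25), bmi = pmax(bmi, 15))
  })
  rows <- list(); slides <- list(); masks <- list()
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in seq_len(nPatients)) {
    pid <- sprintf("P%03d", p)
    for (s in seq_len(slidesPerPatient)) {
      sid <- sprintf("%s_S%d", pid, s)
      spec <- syntheticSlideSpec(
        seed = childSeed(seed, paste0("slideseed_", sid)),
        extent10x = extent10x, backgroundFraction = backgroundFraction,
        contaminants = contaminants, class = meta$cls[p],
        signalScale = signalScale, effect = effect, slideId = sid)
      if (is.null(dir)) {
        g <- generateSlide(spec)
        slides[[sid]] <- g$slide
        masks[[sid]] <- g$mask
      } else {
        path <- file.path(dir, paste0(sid, ".tiff"))
        generateSlide(spec, path = path)
        slides[[sid]] <- path
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, slide_id = sid, cohort = meta$coh[p],
        tumor_class = meta$cls[p], age = meta$age[p], bmi = meta$bmi[p])
    }
  }
  labels <- do.call(rbind, rows)
  validateLabelTable(labels)
  if (!is.null(dir)) writeLabelTable(labels, file.path(dir, "labels.csv"))
  list(labels = labels, slides = slides, masks = masks)
}
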