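#' SlidePyramid: a multi-level whole-slide image
#'
#' Represents a pyramidal slide — a stack of progressively downsampled
#' renderings of one scan — addressed in a level-0 (full resolution),
#' 0-based, half-open pixel coordinate frame. The pyramid may be backed by a
#' multi-page TIFF on disk (pages read on demand and cached) or held fully
#' in memory.
#'
#' @slot slideId character scan identifier.
#' @slot levels data.frame with columns `width`, `height`, `downsample`
#'   (factor relative to level 0, strictly increasing from 1).
#' @slot mpp microns per pixel at level 0 (`NA_real_` when unknown).
#' @slot baseMag nominal objective power of level 0 (e.g. 40 or 20).
#' @slot source file path, or `""` for an in-memory pyramid.
#' @slot pages list of `[h, w, 3]` arrays for in-memory pyramids (empty for
#'   file-backed ones).
#' @slot cache environment used to memoize file-backed page reads.
#' @export
setClass("SlidePyramid",
  representation(slideId = "character", levels = "data.frame",
                 mpp = "numeric", baseMag = "numeric",
                 source = "character", pages = "list", cache = "environment"))

setValidity("SlidePyramid", function(object) {
  lv <- object@levels
  msg <- character()
  if (!all(c("width", "height", "downsample") %in% names(lv)))
    msg <- c(msg, "levels must have width/height/downsample columns")
  else {
    if (nrow(lv) < 1L) msg <- c(msg, "at least one level required")
    if (abs(lv$downsample[1] - 1) > 1e-9)
      msg <- c(msg, "level 0 downsample must be 1")
    if (nrow(lv) > 1L && any(diff(lv$downsample) <= 0))
      msg <- c(msg, "downsample factors must be strictly increasing")
    # dimensions consistent with factors within 1 px rounding
    w0 <- lv$width[1]; h0 <- lv$height[1]
    bad <- abs(lv$width - w0 / lv$downsample) > 1 |
           abs(lv$height - h0 / lv$downsample) > 1
    if (any(bad))
      msg <- c(msg, "level dimensions inconsistent with downsample factors")
  }
  if (length(object@baseMag) != 1L || is.na(object@baseMag) ||
      object@baseMag <= 0)
    msg <- c(msg, "baseMag must be a single positive number")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SlidePyramid", function(object) {
  lv <- object@levels
  cat(sprintf("SlidePyramid '%s': %d level(s), %dx%d px at level 0, base %gx%s\n",
              object@slideId, nrow(lv), lv$width[1], lv$height[1],
              object@baseMag,
              if (is.na(object@mpp)) "" else sprintf(", %.3f um/px", object@mpp)))
  for (i in seq_len(nrow(lv)))
    cat(sprintf("  level %d: %5d x %5d  (/%g)\n", i - 1L,
                lv$width[i], lv$height[i], lv$downsample[i]))
  invisible(NULL)
})

#' @describeIn SlidePyramid slide identifier accessor
#' @param x,object a `SlidePyramid`
#' @export
slideId <- function(x) x@slideId

#' @describeIn SlidePyramid level table accessor
#' @export
slideLevels <- function(x) x@levels

#' @describeIn SlidePyramid base magnification accessor
#' @export
baseMagnification <- function(x) x@baseMag

#' TileSet: three co-registered tiles of one region
#'
#' A single sample of the multi-resolution pipeline: square tiles of the
#' same anatomical region at 10x, 5x and 2.5x equivalent magnification.
#' Each higher-power tile covers one fourth of the area of the next lower
#' power tile; all three share the 10x tile's centering cell.
#'
#' @slot slideId,patientId,tileSetId character identifiers.
#' @slot anchor numeric (x, y): level-0 origin of the 10x tile.
#' @slot cellIndex integer (row, col) of the enclosing 2.5x grid cell,
#'   1-based.
#' @slot images named list of `[p, p, 3]` arrays with names
#'   `"10x"`, `"5x"`, `"2.5x"`.
#' @slot footprints 3x4 matrix (rows `10x`,`5x`,`2.5x`; cols x, y, w, h):
#'   level-0 half-open rectangles of the three tiles.
#' @export
setClass("TileSet",
  representation(slideId = "character", patientId = "character",
                 tileSetId = "character", anchor = "numeric",
                 cellIndex = "integer", images = "list",
                 footprints = "matrix"))

setValidity("TileSet", function(object) {
  msg <- character()
  nm <- c("10x", "5x", "2.5x")
  if (!identical(names(object@images), nm))
    msg <- c(msg, "images must be named 10x, 5x, 2.5x in order")
  fp <- object@footprints
  if (!all(dim(fp) == c(3, 4))) {
    msg <- c(msg, "footprints must be 3x4")
  } else {
    a <- unname(fp[, 3] * fp[, 4])
    if (!(isTRUE(all.equal(a[2] / a[1], 4)) &&
          isTRUE(all.equal(a[3] / a[2], 4))))
      msg <- c(msg, "footprint areas must scale 1:4:16")
    contained <- function(i, o)
      fp[i, 1] >= fp[o, 1] && fp[i, 2] >= fp[o, 2] &&
      fp[i, 1] + fp[i, 3] <= fp[o, 1] + fp[o, 3] &&
      fp[i, 2] + fp[i, 4] <= fp[o, 2] + fp[o, 4]
    if (!(contained(1, 2) && contained(2, 3)))
      msg <- c(msg, "10x footprint must lie inside 5x inside 2.5x")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TileSet", function(object) {
  p <- dim(object@images[[1]])[1]
  cat(sprintf("TileSet %s (slide %s, patient %s): %dpx tiles, 10x anchor (%g, %g), cell (%d, %d)\n",
              object@tileSetId, object@slideId, object@patientId, p,
              object@anchor[1], object@anchor[2],
              object@cellIndex[1], object@cellIndex[2]))
  invisible(NULL)
})

#' @describeIn TileSet tile image accessor
#' @param x a `TileSet`
#' @param mag one of `"10x"`, `"5x"`, `"2.5x"`
#' @export
tileImage <- function(x, mag = "10x") x@images[[mag]]

#' @describeIn TileSet level-0 footprint rectangles (3x4 matrix)
#' @export
tileFootprints <- function(x) x@footprints

#' TileFilterConfig: background/contaminant filtering parameters
#'
#' A pixel is background or contaminant when all three channels fall below
#' `lowRgb` (dark debris) or all three rise above `highRgb` (white glass).
#' A tile is discarded when strictly more than `maxBackgroundFraction` of
#' its pixels are background — 40% exactly still passes. Bounds are on the
#' 0..255 scale.
#'
#' @slot tilePx tile side length in pixels (default 299).
#' @slot maxBackgroundFraction default 0.40.
#' @slot lowRgb default 50.
#' @slot highRgb default 200.
#' @export
setClass("TileFilterConfig",
  representation(tilePx = "integer", maxBackgroundFraction = "numeric",
                 lowRgb = "numeric", highRgb = "numeric"))

setValidity("TileFilterConfig", function(object) {
  msg <- character()
  if (object@tilePx < 1L) msg <- c(msg, "tilePx must be positive")
  if (!(object@maxBackgroundFraction > 0 && object@maxBackgroundFraction < 1))
    msg <- c(msg, "maxBackgroundFraction must be in (0, 1)")
  if (!(object@lowRgb >= 0 && object@lowRgb < object@highRgb &&
        object@highRgb <= 255))
    msg <- c(msg, "need 0 <= lowRgb < highRgb <= 255")
  if (length(msg)) msg else TRUE
})

#' Construct a TileFilterConfig
#' @param tilePx tile side length (pixels)
#' @param maxBackgroundFraction retained tiles have background fraction
#'   `<=` this value
#' @param lowRgb,highRgb contaminant/background channel bounds (0..255)
#' @return a [TileFilterConfig-class] object
#' @export
tileFilterConfig <- function(tilePx = 299L, maxBackgroundFraction = 0.40,
                             lowRgb = 50, highRgb = 200) {
  new("TileFilterConfig", tilePx = as.integer(tilePx),
      maxBackgroundFraction = maxBackgroundFraction,
      lowRgb = lowRgb, highRgb = highRgb)
}

setMethod("show", "TileFilterConfig", function(object) {
  cat(sprintf("TileFilterConfig: %d px tiles, discard > %.0f%% background, bounds [%g, %g]\n",
              object@tilePx, 100 * object@maxBackgroundFraction,
              object@lowRgb, object@highRgb))
  invisible(NULL)
})

#' StainProfile: reference H&E stain basis
#'
#' Holds the 2x3 optical-density color basis (row 1 hematoxylin-like, row 2
#' eosin-like; rows unit-norm, nonnegative) and the reference 99th-percentile
#' stain concentrations used to rescale tiles during normalization.
#'
#' @slot stainMatrix 2x3 unit-row matrix of H and E OD vectors (RGB order).
#' @slot maxConcentrations length-2 positive vector of reference
#'   99th-percentile concentrations.
#' @slot odThreshold pixels with max-channel OD below this are treated as
#'   unstained background (default 0.15).
#' @slot sparsityWeight L1 penalty on concentrations during stain estimation
#'   (default 0.10).
#' @export
setClass("StainProfile",
  representation(stainMatrix = "matrix", maxConcentrations = "numeric",
                 odThreshold = "numeric", sparsityWeight = "numeric"))

setValidity("StainProfile", function(object) {
  msg <- character()
  S <- object@stainMatrix
  if (!all(dim(S) == c(2, 3))) msg <- c(msg, "stainMatrix must be 2x3")
  else {
    if (any(S < -1e-9)) msg <- c(msg, "stain vectors must be nonnegative")
    if (any(abs(sqrt(rowSums(S^2)) - 1) > 1e-6))
      msg <- c(msg, "stain vector rows must have unit norm")
  }
  if (length(object@maxConcentrations) != 2L ||
      any(object@maxConcentrations <= 0))
    msg <- c(msg, "maxConcentrations must be 2 positive values")
  if (length(msg)) msg else TRUE
})

setMethod("show", "StainProfile", function(object) {
  cat("StainProfile (rows: hematoxylin, eosin; columns R,G,B):\n")
  print(round(object@stainMatrix, 4))
  cat(sprintf("  max concentrations: %.3f, %.3f; OD threshold %.2f; L1 %.2f\n",
              object@maxConcentrations[1], object@maxConcentrations[2],
              object@odThreshold, object@sparsityWeight))
  invisible(NULL)
})

#' Heatmap: whole-slide prediction score grid
#'
#' Per-cell positive-class prediction scores reassembled on the 10x anchor
#' grid of a slide. Each cell spans 299 px (or the configured tile size) at
#' 10x equivalent magnification; cells with no surviving tile set are `NA`.
#'
#' @slot scores numeric matrix `[rows, cols]`, values in `[0,1]` or `NA`.
#' @slot slideId character.
#' @slot cellPx cell side at 10x equivalent (pixels).
#' @slot level0CellPx cell side at level 0 (pixels).
#' @slot slideDim level-0 (width, height) of the source slide.
#' @export
setClass("Heatmap",
  representation(scores = "matrix", slideId = "character",
                 cellPx = "integer", level0CellPx = "numeric",
                 slideDim = "numeric"))

setValidity("Heatmap", function(object) {
  s <- object@scores
  if (any(!is.na(s) & (s < 0 | s > 1))) "scores must be in [0,1] or NA"
  else TRUE
})

setMethod("show", "Heatmap", function(object) {
  cat(sprintf("Heatmap for slide %s: %d x %d cells (%d px at 10x), %d scored\n",
              object@slideId, nrow(object@scores), ncol(object@scores),
              object@cellPx, sum(!is.na(object@scores))))
  invisible(NULL)
})
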