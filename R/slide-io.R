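# Pyramidal slide reading. File-backed slides are multi-page TIFFs whose
# pages are progressively downsampled renderings of page 1; scan metadata
# (microns per pixel, base magnification, slide id) travels in a JSON
# sidecar `<path>.json` because baseline TIFF tags cannot carry it.

#' Construct an in-memory slide pyramid
#'
#' @param pages list of `[h, w, 3]` arrays ordered from the finest level;
#'   each subsequent page must be a downsampled rendering of page 1.
#' @param slideId slide identifier.
#' @param baseMag nominal objective power of level 0 (e.g. 40 or 20).
#' @param mpp optional microns per pixel at level 0. When given, the base
#'   magnification may be omitted and is inferred (0.25 um/px is called 40x,
#'   0.5 um/px 20x, by nearest match).
#' @return a [SlidePyramid-class]
#' @export
slidePyramid <- function(pages, slideId = "slide", baseMag = NULL, mpp = NA_real_) {
  stopifnot(length(pages) >= 1L)
  dims <- vapply(pages, function(p) dim(p)[1:2], numeric(2))
  lv <- data.frame(width = dims[2, ], height = dims[1, ],
                   downsample = dims[2, 1] / dims[2, ])
  if (is.null(baseMag)) baseMag <- magFromMpp(mpp)
  new("SlidePyramid", slideId = slideId, levels = lv,
      mpp = as.numeric(mpp), baseMag = as.numeric(baseMag),
      source = "", pages = pages, cache = new.env(parent = emptyenv()))
}

#' @keywords internal
magFromMpp <- function(mpp) {
  if (is.na(mpp))
    stop("base magnification unknown: supply baseMag or an mpp sidecar value")
  # nearest of the two conventional calibrations
  if (abs(mpp - 0.25) <= abs(mpp - 0.5)) 40 else 20
}

#' Open a pyramidal TIFF slide
#'
#' Reads page geometry only; pixel data are loaded per level on demand and
#' cached. Metadata are taken from the `<path>.json` sidecar when present
#' (fields `slide_id`, `mpp`, `base_magnification`); arguments override the
#' sidecar. A single-page file is accepted — coarser magnifications are then
#' produced by resampling level 0.
#'
#' @param path path to a pyramidal (multi-page) TIFF.
#' @param baseMag base magnification override; required when neither the
#'   sidecar nor `mpp` determines it.
#' @param mpp microns-per-pixel override.
#' @return a [SlidePyramid-class]
#' @export
openSlide <- function(path, baseMag = NULL, mpp = NULL) {
  if (!file.exists(path)) stop("no such slide file: ", path)
  info <- tryCatch(tiff::readTIFF(path, all = TRUE, payload = FALSE),
                   error = function(e)
                     stop("not a readable TIFF slide: ", path, " (", conditionMessage(e), ")"))
  info <- as.data.frame(info)
  if (nrow(info) < 1L || any(info$width <= 0))
    stop("not a readable pyramidal slide: ", path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  if (is.null(mpp)) mpp <- if (!is.null(meta$mpp)) as.numeric(meta$mpp) else NA_real_
  if (is.null(baseMag)) {
    baseMag <- if (!is.null(meta$base_magnification))
      as.numeric(meta$base_magnification) else magFromMpp(mpp)
  }
  sid <- if (!is.null(meta$slide_id)) as.character(meta$slide_id)
         else sub("\\.tiff?$", "", basename(path))
  # order pages by size; they must form a pyramid
  o <- order(info$width, decreasing = TRUE)
  info <- info[o, , drop = FALSE]
  lv <- data.frame(width = info$width, height = info$length,
                   downsample = info$width[1] / info$width)
  obj <- new("SlidePyramid", slideId = sid, levels = lv,
             mpp = as.numeric(mpp), baseMag = as.numeric(baseMag),
             source = path, pages = list(),
             cache = new.env(parent = emptyenv()))
  attr(obj, "pageOrder") <- o  # map level -> TIFF page index
  obj
}

#' Fetch one pyramid level as an array (cached for file-backed slides)
#' @keywords internal
slidePage <- function(slide, level) {
  if (length(slide@pages)) return(slide@pages[[level]])
  key <- paste0("p", level)
  if (!is.null(slide@cache[[key]])) return(slide@cache[[key]])
  ord <- attr(slide, "pageOrder")
  page_idx <- if (is.null(ord)) level else ord[level]
  img <- tiff::readTIFF(slide@source, all = page_idx)[[1]]
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3]
  slide@cache[[key]] <- img
  img
}

#' Read a square region at an equivalent magnification
#'
#' The requested footprint at level 0 is `sizePx * baseMag / targetMag`
#' pixels on each side, anchored at `(x, y)` (0-based, level-0 frame,
#' half-open). The nearest pyramid level at least as fine as the requested
#' magnification is read; the residual factor is applied by area averaging
#' when integral and aligned, else by bilinear interpolation.
#'
#' @param slide a [SlidePyramid-class]
#' @param x,y level-0 origin of the region (0-based pixels).
#' @param sizePx output side length in pixels.
#' @param targetMag requested equivalent power (must not exceed the slide's
#'   base magnification).
#' @return `[sizePx, sizePx, 3]` array in `[0,1]`
#' @export
readRegion <- function(slide, x, y, sizePx, targetMag) {
  stopifnot(is(slide, "SlidePyramid"))
  if (targetMag > slide@baseMag + 1e-9)
    stop(sprintf("target magnification %g exceeds base %g", targetMag, slide@baseMag))
  f <- slide@baseMag / targetMag
  L <- sizePx * f
  if (abs(L - round(L)) > 1e-6)
    stop(sprintf("footprint %g px is not integral for size %d at %gx", L, sizePx, targetMag))
  L <- round(L)
  lv <- slide@levels
  if (x < 0 || y < 0 || x + L > lv$width[1] || y + L > lv$height[1])
    stop(sprintf("region [%g, %g) x [%g, %g) out of level-0 bounds %d x %d",
                 x, x + L, y, y + L, lv$width[1], lv$height[1]))
  # nearest level at least as fine as the request
  lvl <- max(which(lv$downsample <= f + 1e-9))
  d <- lv$downsample[lvl]
  page <- slidePage(slide, lvl)
  r <- f / d
  aligned <- d == round(d) && x %% d == 0 && y %% d == 0 && L %% d == 0
  if (aligned) {
    xl <- x / d; yl <- y / d; Ll <- L / d
    crop <- page[(yl + 1):(yl + Ll), (xl + 1):(xl + Ll), , drop = FALSE]
    if (abs(r - 1) < 1e-9) return(crop)
    if (abs(r - round(r)) < 1e-9 && Ll %% round(r) == 0)
      return(areaDownsample(crop, round(r)))
    return(bilinearResize(crop, sizePx, sizePx))
  }
  # covering crop at the chosen level, then bilinear to the output grid
  x0 <- floor(x / d); y0 <- floor(y / d)
  x1 <- ceiling((x + L) / d); y1 <- ceiling((y + L) / d)
  crop <- page[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  bilinearResize(crop, sizePx, sizePx)
}

#' Write an in-memory pyramid to a multi-page TIFF with a JSON sidecar
#'
#' @param slide a [SlidePyramid-class] holding its pages in memory.
#' @param path output TIFF path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly
#' @export
writeSlide <- function(slide, path) {
  stopifnot(length(slide@pages) >= 1L)
  tiff::writeTIFF(lapply(slide@pages, clamp01), path, bits.per.sample = 8L)
  meta <- list(slide_id = slide@slideId,
               base_magnification = slide@baseMag)
  if (!is.na(slide@mpp)) meta$mpp <- slide@mpp
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
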