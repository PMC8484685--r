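# Grid planning and matched tile-set extraction. A slide is partitioned
# into non-overlapping 299 px cells at 2.5x equivalent magnification; every
# cell holds a 4x4 lattice of 10x tiles and a 2x2 lattice of 5x tiles, so a
# fully usable cell yields 16 matched (10x, 5x, 2.5x) tile sets.

#' Plan the 2.5x tiling grid of a slide
#'
#' Non-overlapping `tilePx` cells at 2.5x equivalent magnification, row
#' major, partial edge cells dropped (padding would fabricate tissue). A
#' slide smaller than one cell yields an empty plan.
#'
#' @param slide a [SlidePyramid-class]
#' @param cfg a [TileFilterConfig-class]
#' @return data.frame with columns `row`, `col` (1-based), `x`, `y`,
#'   `sizeL0` (level-0 half-open cell rectangle)
#' @export
planGrid <- function(slide, cfg = tileFilterConfig()) {
  lv <- slide@levels
  cellL0 <- cfg@tilePx * slide@baseMag / 2.5
  if (abs(cellL0 - round(cellL0)) > 1e-6)
    stop("cell footprint is not integral at this base magnification")
  cellL0 <- round(cellL0)
  ncol_ <- floor(lv$width[1] / cellL0)
  nrow_ <- floor(lv$height[1] / cellL0)
  if (ncol_ < 1L || nrow_ < 1L)
    return(data.frame(row = integer(), col = integer(),
                      x = numeric(), y = numeric(), sizeL0 = numeric()))
  g <- expand.grid(col = seq_len(ncol_), row = seq_len(nrow_))
  data.frame(row = g$row, col = g$col,
             x = (g$col - 1) * cellL0, y = (g$row - 1) * cellL0,
             sizeL0 = cellL0)
}

#' Background/contaminant filter decision for one tile
#'
#' A pixel counts as background or contaminant iff all three channels are
#' strictly below `lowRgb` (dark debris) or strictly above `highRgb` (white
#' glass), on the 0..255 scale. The tile is discarded only when strictly
#' more than `maxBackgroundFraction` of pixels are background, so a tile at
#' exactly the threshold passes. The decision depends on pixel values only.
#'
#' @param tile `[p, p, 3]` RGB array in `[0,1]`
#' @param cfg a [TileFilterConfig-class]
#' @return list with `pass` (logical) and `backgroundFraction`
#' @export
passesFilter <- function(tile, cfg = tileFilterConfig()) {
  v <- to255(tile)
  lo <- v[, , 1] < cfg@lowRgb & v[, , 2] < cfg@lowRgb & v[, , 3] < cfg@lowRgb
  hi <- v[, , 1] > cfg@highRgb & v[, , 2] > cfg@highRgb & v[, , 3] > cfg@highRgb
  frac <- mean(lo | hi)
  list(pass = frac <= cfg@maxBackgroundFraction, backgroundFraction = frac)
}

#' Enumerate the surviving tile sets of one grid cell
#'
#' Candidate anchors are the 4x4 lattice of 10x tiles inside the cell; each
#' pairs with its enclosing 5x tile (one of the cell's 2x2) and the cell's
#' single 2.5x tile. A candidate is kept only when all three member tiles
#' pass [passesFilter] — every branch of a multi-resolution model then sees
#' informative pixels. Filtering is evaluated on raw (pre-normalization)
#' pixels.
#'
#' @param slide a [SlidePyramid-class]
#' @param cell one row of [planGrid]'s output
#' @param cfg a [TileFilterConfig-class]
#' @param patientId patient identifier stamped on emitted sets
#' @return list of [TileSet-class] (possibly empty)
#' @export
enumerateTileSets <- function(slide, cell, cfg = tileFilterConfig(),
                              patientId = NA_character_) {
  p <- cfg@tilePx
  s10 <- cell$sizeL0 / 4
  s5 <- cell$sizeL0 / 2
  img25 <- readRegion(slide, cell$x, cell$y, p, 2.5)
  f25 <- passesFilter(img25, cfg)
  img5 <- vector("list", 4L)   # row-major 2x2
  f5 <- rep(NA, 4L)
  out <- list()
  for (ai in 0:3) for (aj in 0:3) {
    x10 <- cell$x + aj * s10
    y10 <- cell$y + ai * s10
    if (!f25$pass) next
    q <- floor(ai / 2) * 2 + floor(aj / 2) + 1   # enclosing 5x quadrant
    if (is.null(img5[[q]])) {
      x5 <- cell$x + floor(aj / 2) * s5
      y5 <- cell$y + floor(ai / 2) * s5
      img5[[q]] <- readRegion(slide, x5, y5, p, 5)
      f5[q] <- passesFilter(img5[[q]], cfg)$pass
    }
    if (!f5[q]) next
    img10 <- readRegion(slide, x10, y10, p, 10)
    if (!passesFilter(img10, cfg)$pass) next
    x5 <- cell$x + floor(aj / 2) * s5
    y5 <- cell$y + floor(ai / 2) * s5
    fp <- rbind(`10x` = c(x10, y10, s10, s10),
                `5x` = c(x5, y5, s5, s5),
                `2.5x` = c(cell$x, cell$y, cell$sizeL0, cell$sizeL0))
    colnames(fp) <- c("x", "y", "w", "h")
    ts <- new("TileSet",
              slideId = slide@slideId, patientId = as.character(patientId),
              tileSetId = sprintf("%s_r%dc%d_a%d", slide@slideId,
                                  cell$row, cell$col, ai * 4 + aj),
              anchor = c(x10, y10),
              cellIndex = c(as.integer(cell$row), as.integer(cell$col)),
              images = list(`10x` = img10, `5x` = img5[[q]], `2.5x` = img25),
              footprints = fp)
    out[[length(out) + 1L]] <- ts
  }
  out
}

#' Tile a whole slide into filtered, normalized tile sets
#'
#' Runs [planGrid] and [enumerateTileSets] over the slide, stain-normalizes
#' every kept tile set against `profile` (unless `profile` is `NULL`), and
#' either returns the sets or streams them into `sink`. Counts are
#' conserved: `kept + discarded == candidates`.
#'
#' @param slide a [SlidePyramid-class]
#' @param cfg a [TileFilterConfig-class]
#' @param profile [StainProfile-class] normalization target, or `NULL` to
#'   skip normalization
#' @param sink optional function called with each finished [TileSet-class]
#' @param patientId patient identifier stamped on emitted sets
#' @param stainMode `"tile"` (default) estimates stains per tile, so
#'   normalization cannot leave slide-level intensity offsets behind;
#'   `"slide"` fits one basis per slide on a thumbnail (faster at full tile
#'   size)
#' @param storePx when given, member images are bilinearly reduced to this
#'   side length before normalization and sinking (storage/throughput
#'   control; the background filter always sees full-resolution pixels).
#'   Emitted pixels are quantized to 8-bit depth either way.
#' @return list: `summary` (cells, candidates, kept, discarded,
#'   unnormalized) and, when `sink` is `NULL`, `tileSets`
#' @export
tileSlide <- function(slide, cfg = tileFilterConfig(), profile = NULL,
                      sink = NULL, patientId = NA_character_,
                      stainMode = c("tile", "slide"), storePx = NULL) {
  stainMode <- match.arg(stainMode)
  grid <- planGrid(slide, cfg)
  slideStains <- NULL
  if (!is.null(profile) && stainMode == "slide" && nrow(grid) > 0) {
    thumb <- slideThumbnail(slide, 512L)
    slideStains <- tryCatch(estimateStains(thumb, profile),
                            unstainableTile = function(e) NULL)
  }
  kept <- 0L; candidates <- 0L; unnormalized <- 0L
  sets <- if (is.null(sink)) list() else NULL
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    candidates <- candidates + 16L
    for (ts in enumerateTileSets(slide, cell, cfg, patientId)) {
      if (!is.null(storePx) && storePx != cfg@tilePx)
        ts@images <- lapply(ts@images, resizeBox, px = storePx)
      if (!is.null(profile)) {
        st <- if (stainMode == "slide") slideStains else NULL
        norm_ok <- TRUE
        imgs <- lapply(ts@images, function(im) {
          tryCatch(normalizeTile(im, profile, stains = st),
                   unstainableTile = function(e) { norm_ok <<- FALSE; im })
        })
        if (!norm_ok) unnormalized <- unnormalized + 1L
        ts@images <- imgs
      }
      ts@images <- lapply(ts@images, quantize8)
      kept <- kept + 1L
      if (is.null(sink)) sets[[kept]] <- ts else sink(ts)
    }
  }
  res <- list(summary = list(slideId = slide@slideId, cells = nrow(grid),
                             candidates = candidates, kept = kept,
                             discarded = candidates - kept,
                             unnormalized = unnormalized))
  if (is.null(sink)) res$tileSets <- sets
  res
}

#' Whole-slide thumbnail from the coarsest pyramid level
#' @keywords internal
slideThumbnail <- function(slide, maxSide = 512L) {
  lv <- slide@levels
  n <- nrow(lv)
  page <- slidePage(slide, n)
  d <- dim(page)
  if (max(d[1:2]) > maxSide) {
    sc <- maxSide / max(d[1:2])
    page <- bilinearResize(page, max(1L, round(d[1] * sc)),
                           max(1L, round(d[2] * sc)))
  }
  quantize8(page)
}
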