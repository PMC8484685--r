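# Feature-space and slide-space visualization: tSNE embedding of
# penultimate feature vectors colored by prediction score, and whole-slide
# heatmaps reassembled from tile-set predictions on the 10x anchor grid.

# ---- exact tSNE (O(n^2); adequate for the <= few thousand points used) ----

#' @keywords internal
tsnePerplexityP <- function(D2, perplexity) {
  n <- nrow(D2)
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; bmin <- -Inf; bmax <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp < 1e-12) { H <- 0; p[] <- 0 }
      else {
        p <- p / sp
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { bmin <- beta; beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2 }
      else { bmax <- beta; beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' @keywords internal
tsneRun <- function(X, perplexity = 30, nIter = 1000, seed = 1L) {
  n <- nrow(X)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  D2 <- as.matrix(dist(X))^2
  P <- tsnePerplexityP(D2, perplexity)
  withSeed(childSeed(seed, "tsne"), {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    gain <- matrix(1, n, 2)
    inc <- matrix(0, n, 2)
    ex <- 12
    for (it in seq_len(nIter)) {
      Pex <- if (it <= 100) P * ex else P
      num <- 1 / (1 + as.matrix(dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pex - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      mom <- if (it < 250) 0.5 else 0.8
      gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
      gain[gain < 0.01] <- 0.01
      inc <- mom * inc - 200 * gain * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

#' Embed penultimate features in two dimensions
#'
#' Randomly subsamples up to `sampleN` rows without replacement (clamped to
#' availability with a warning), projects to `initDims` principal
#' components, and runs tSNE to two dimensions. Deterministic per seed.
#'
#' @param features numeric matrix, one row per tile set
#' @param scores positive prediction score per row
#' @param ids optional row identifiers
#' @param sampleN subsample size (default 20000)
#' @param initDims principal components kept before tSNE (default 100)
#' @param perplexity,nIter tSNE parameters (recorded in the result)
#' @param seed RNG seed for sampling and embedding
#' @return list (`coords` n x 2, `scores`, `ids`, `sampleIdx`, `seed`,
#'   `perplexity`, `nIter`, `initDims`)
#' @export
embedFeatures <- function(features, scores, ids = NULL, sampleN = 20000L,
                          initDims = 100L, perplexity = 30, nIter = 1000L,
                          seed = 1L) {
  features <- as.matrix(features)
  if (nrow(features) != length(scores))
    stop("features and scores are not row-aligned")
  if (nrow(features) < 10L) stop("need at least 10 rows to embed")
  if (is.null(ids)) ids <- as.character(seq_len(nrow(features)))
  n <- nrow(features)
  if (n > sampleN) {
    idx <- withSeed(childSeed(seed, "embedsample"), sample.int(n, sampleN))
  } else {
    if (n < sampleN)
      warning("only ", n, " rows available; embedding all of them")
    idx <- seq_len(n)
  }
  X <- features[idx, , drop = FALSE]
  keep <- apply(X, 2, sd) > 0
  X <- scale(X[, keep, drop = FALSE])
  k <- min(initDims, ncol(X), nrow(X) - 1L)
  pc <- prcomp(X, center = FALSE, scale. = FALSE, rank. = k)
  Y <- tsneRun(pc$x, perplexity = perplexity, nIter = nIter, seed = seed)
  list(coords = Y, scores = scores[idx], ids = ids[idx], sampleIdx = idx,
       seed = seed, perplexity = perplexity, nIter = nIter,
       initDims = k)
}

#' Render an embedding as a scatter plot
#'
#' Points colored by prediction score on a fixed 0-1 diverging scale;
#' thumbnail mode places at most one tile thumbnail per cell of a
#' `gridN` x `gridN` collision grid.
#'
#' @param result output of [embedFeatures]
#' @param outPath PNG output path
#' @param tiles optional list of tile images aligned with `result$ids`
#'   (activates thumbnail mode)
#' @param gridN collision-grid resolution for thumbnail mode
#' @param pointCex scatter point size
#' @return `outPath` invisibly; the file's metadata records the point count
#' @export
renderEmbedding <- function(result, outPath, tiles = NULL, gridN = 20L,
                            pointCex = 0.7) {
  co <- result$coords
  cols <- scoreColors(result$scores)
  grDevices::png(outPath, width = 1200, height = 1000, res = 150)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 3, 6))
  if (is.null(tiles)) {
    plot(co[, 1], co[, 2], col = cols, pch = 16, cex = pointCex,
         xlab = "tSNE 1", ylab = "tSNE 2",
         main = sprintf("%d tile sets", nrow(co)))
  } else {
    plot(co[, 1], co[, 2], type = "n", xlab = "tSNE 1", ylab = "tSNE 2",
         main = sprintf("%d tile sets (thumbnails)", nrow(co)))
    rx <- range(co[, 1]); ry <- range(co[, 2])
    gx <- pmin(gridN, 1L + floor((co[, 1] - rx[1]) / diff(rx) * gridN))
    gy <- pmin(gridN, 1L + floor((co[, 2] - ry[1]) / diff(ry) * gridN))
    cell <- gx + gridN * gy
    first <- !duplicated(cell)
    w <- diff(rx) / gridN / 2; h <- diff(ry) / gridN / 2
    for (i in which(first)) {
      img <- tiles[[i]]
      graphics::rasterImage(grDevices::as.raster(clamp01(img)),
                            co[i, 1] - w, co[i, 2] - h,
                            co[i, 1] + w, co[i, 2] + h)
    }
  }
  scoreLegend()
  invisible(outPath)
}

#' @keywords internal
scorePalette <- function(n = 256) {
  grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(n)
}

#' @keywords internal
scoreColors <- function(scores) {
  pal <- scorePalette()
  pal[pmin(256L, 1L + floor(pmax(0, pmin(1, scores)) * 255))]
}

#' @keywords internal
scoreLegend <- function() {
  usr <- graphics::par("usr")
  xr <- usr[2] - usr[1]
  x0 <- usr[2] + 0.02 * xr
  pal <- scorePalette(64)
  yy <- seq(usr[3], usr[4], length.out = 65)
  graphics::par(xpd = TRUE)
  graphics::rect(x0, yy[-65], x0 + 0.03 * xr, yy[-1], col = pal, border = NA)
  graphics::text(x0 + 0.04 * xr, c(usr[3], (usr[3] + usr[4]) / 2, usr[4]),
                 c("0", "0.5", "1"), adj = 0, cex = 0.8)
  graphics::par(xpd = FALSE)
}

# ---- whole-slide heatmaps ----

#' Reassemble tile-set predictions into a slide heatmap
#'
#' Each predicted tile set writes its score into the grid cell of its 10x
#' anchor; the grid has `floor(extent10x / cellPx)` cells per axis, where
#' `extent10x` is the slide's extent at 10x equivalent magnification. Cells
#' with no surviving tile set stay `NA`.
#'
#' @param preds prediction table rows for one slide, carrying an `anchor_x`
#'   and `anchor_y` column (level-0 pixels of the 10x tile origin)
#' @param slide the [SlidePyramid-class] the predictions came from
#' @param cellPx heatmap cell side at 10x equivalent (default 299)
#' @return a [Heatmap-class]
#' @export
assembleHeatmap <- function(preds, slide, cellPx = 299L) {
  stopifnot(all(c("anchor_x", "anchor_y", "score") %in% names(preds)))
  sc10 <- 10 / slide@baseMag                 # level0 px -> 10x px
  w10 <- floor(slide@levels$width[1] * sc10)
  h10 <- floor(slide@levels$height[1] * sc10)
  nc <- floor(w10 / cellPx); nr <- floor(h10 / cellPx)
  grid <- matrix(NA_real_, nr, nc)
  if (nrow(preds)) {
    ax <- preds$anchor_x * sc10; ay <- preds$anchor_y * sc10
    if (any(ax < 0 | ay < 0 | ax >= w10 | ay >= h10))
      stop("anchor outside slide bounds: corrupt prediction table")
    ci <- 1L + floor(ax / cellPx); ri <- 1L + floor(ay / cellPx)
    if (any(ci > nc | ri > nr))
      stop("anchor outside the heatmap grid: corrupt prediction table")
    for (i in seq_len(nrow(preds))) grid[ri[i], ci[i]] <- preds$score[i]
  }
  new("Heatmap", scores = grid, slideId = slide@slideId,
      cellPx = as.integer(cellPx), level0CellPx = cellPx / sc10,
      slideDim = c(slide@levels$width[1], slide@levels$height[1]))
}

#' Flatten a heatmap back to (row, col, score) records
#' @param heatmap a [Heatmap-class]
#' @return data.frame (row, col, score) of non-missing cells
#' @export
disassembleHeatmap <- function(heatmap) {
  idx <- which(!is.na(heatmap@scores), arr.ind = TRUE)
  data.frame(row = idx[, 1], col = idx[, 2],
             score = heatmap@scores[idx])
}

#' Render a heatmap over a slide thumbnail
#'
#' The colormapped score grid (diverging scale, midpoint 0.5) is blended at
#' opacity `alpha` over the slide thumbnail; missing cells stay fully
#' transparent.
#'
#' @param heatmap a [Heatmap-class]
#' @param slide the matching [SlidePyramid-class]
#' @param outPath PNG path
#' @param alpha overlay opacity in [0,1]
#' @return `outPath` invisibly
#' @export
renderOverlay <- function(heatmap, slide, outPath, alpha = 0.5) {
  thumb <- slideThumbnail(slide, 800L)
  d <- dim(thumb)
  grDevices::png(outPath, width = d[2], height = d[1])
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  plot(0, 0, type = "n", xlim = c(0, heatmap@slideDim[1]),
       ylim = c(heatmap@slideDim[2], 0), xaxs = "i", yaxs = "i",
       axes = FALSE, xlab = "", ylab = "")
  graphics::rasterImage(grDevices::as.raster(clamp01(thumb)),
                        0, heatmap@slideDim[2], heatmap@slideDim[1], 0)
  cp <- heatmap@level0CellPx
  sc <- heatmap@scores
  pal <- scorePalette()
  for (r in seq_len(nrow(sc))) for (cc in seq_len(ncol(sc))) {
    if (is.na(sc[r, cc])) next
    col <- grDevices::adjustcolor(pal[1L + floor(sc[r, cc] * 255)],
                                  alpha.f = alpha)
    graphics::rect((cc - 1) * cp, r * cp, cc * cp, (r - 1) * cp,
                   col = col, border = NA)
  }
  invisible(outPath)
}

#' Serialize a heatmap to CSV (scores) + JSON (geometry)
#' @param heatmap a [Heatmap-class]
#' @param basePath path prefix; writes `<basePath>.csv` and
#'   `<basePath>.json`
#' @return paths, invisibly
#' @export
writeHeatmap <- function(heatmap, basePath) {
  write.csv(heatmap@scores, paste0(basePath, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(slide_id = heatmap@slideId,
                            cell_px = heatmap@cellPx,
                            level0_cell_px = heatmap@level0CellPx,
                            slide_dim = heatmap@slideDim),
                       paste0(basePath, ".json"), auto_unbox = TRUE)
  invisible(c(paste0(basePath, ".csv"), paste0(basePath, ".json")))
}
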