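#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats rnorm runif rpois rbinom quantile median sd prcomp
#'   wilcox.test t.test dist setNames aggregate rbeta
#' @importFrom utils head tail read.csv write.csv modifyList
NULL

# Images are numeric arrays [rows, cols, 3] with values in [0, 1], the
# convention of tiff::readTIFF. Helpers below convert to/from 8-bit scale.

#' Clamp a numeric array into [0, 1]
#' @param x numeric array
#' @return array of the same shape
#' @keywords internal
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Convert a [0,1] image to integer 8-bit scale (0..255)
#' @param img numeric array in [0,1]
#' @return integer-valued array on the 0..255 scale
#' @keywords internal
to255 <- function(img) round(img * 255)

#' Quantize an image to the 8-bit grid while staying on the [0,1] scale
#' @param img numeric array in [0,1]
#' @return numeric array in [0,1] on the 256-level grid
#' @keywords internal
quantize8 <- function(img) round(clamp01(img) * 255) / 255

#' Area-average (box filter) downsample by an integer factor
#'
#' Each output pixel is the mean of an f x f input block. Used for pyramid
#' construction and integer-factor magnification reads; it is antialiased
#' and independent of evaluation order.
#'
#' @param img numeric array `[h, w]` or `[h, w, c]`; `h`, `w` divisible by `f`
#' @param f integer downsample factor (>= 1)
#' @return downsampled array
#' @export
areaDownsample <- function(img, f) {
  f <- as.integer(f)
  stopifnot(f >= 1L)
  if (f == 1L) return(img)
  d <- dim(img)
  if (length(d) == 2L) d <- c(d, 1L)
  h <- d[1]; w <- d[2]; nc <- d[3]
  stopifnot(h %% f == 0L, w %% f == 0L)
  oh <- h %/% f; ow <- w %/% f
  x <- array(img, c(h, w, nc))
  # fold rows then columns: [f, oh, w, nc] -> mean over dim 1, likewise cols
  x <- array(x, c(f, oh, w * nc))
  x <- colMeans(x)                       # [oh, w*nc]
  x <- array(x, c(oh, w, nc))
  x <- aperm(x, c(2, 1, 3))              # [w, oh, nc]
  x <- array(x, c(f, ow, oh * nc))
  x <- colMeans(x)                       # [ow, oh*nc]
  x <- aperm(array(x, c(ow, oh, nc)), c(2, 1, 3))
  if (length(dim(img)) == 2L) x <- x[, , 1] else x
}

#' Bilinear resize to a target size
#'
#' Separable linear interpolation on pixel centers. Used when a requested
#' magnification does not correspond to an integer downsample of an
#' available pyramid level, and for shrinking tiles to a model's input size.
#'
#' @param img numeric array `[h, w]` or `[h, w, c]`
#' @param oh,ow output height and width in pixels
#' @return resized array
#' @export
bilinearResize <- function(img, oh, ow) {
  d <- dim(img)
  two_d <- length(d) == 2L
  if (two_d) { img <- array(img, c(d, 1L)); d <- dim(img) }
  h <- d[1]; w <- d[2]; nc <- d[3]
  if (oh == h && ow == w) return(if (two_d) img[, , 1] else img)
  # map output pixel centers to input coordinates (align centers)
  yi <- (seq_len(oh) - 0.5) * h / oh - 0.5
  xi <- (seq_len(ow) - 0.5) * w / ow - 0.5
  yi <- pmin(pmax(yi, 0), h - 1)
  xi <- pmin(pmax(xi, 0), w - 1)
  y0 <- pmin(floor(yi), h - 2); y1 <- y0 + 1; wy <- yi - y0
  x0 <- pmin(floor(xi), w - 2); x1 <- x0 + 1; wx <- xi - x0
  if (h == 1L) { y0 <- y1 <- rep(0, oh); wy <- rep(0, oh) }
  if (w == 1L) { x0 <- x1 <- rep(0, ow); wx <- rep(0, ow) }
  out <- array(0, c(oh, ow, nc))
  for (ch in seq_len(nc)) {
    m <- img[, , ch]
    a <- m[cbind(rep(y0 + 1, ow), rep(x0 + 1, each = oh))]
    b <- m[cbind(rep(y0 + 1, ow), rep(x1 + 1, each = oh))]
    cc <- m[cbind(rep(y1 + 1, ow), rep(x0 + 1, each = oh))]
    dd <- m[cbind(rep(y1 + 1, ow), rep(x1 + 1, each = oh))]
    WX <- rep(wx, each = oh); WY <- rep(wy, ow)
    v <- (1 - WY) * ((1 - WX) * a + WX * b) + WY * ((1 - WX) * cc + WX * dd)
    out[, , ch] <- v
  }
  if (two_d) out[, , 1] else out
}

#' Antialiased (box-prefiltered) resize to a square target
#'
#' For shrink factors of 2 or more, the image is first mapped bilinearly to
#' the nearest integer multiple of the target and then box-averaged down —
#' averaging, rather than point-sampling, high-frequency texture. Smaller
#' factors fall back to plain bilinear interpolation. Used when tiles are
#' reduced to a model input or storage size.
#'
#' @param img numeric array `[h, w]` or `[h, w, c]`
#' @param px output side length
#' @return resized array
#' @export
resizeBox <- function(img, px) {
  d <- dim(img)
  k <- min(d[1], d[2]) %/% px
  if (k >= 2L) areaDownsample(bilinearResize(img, px * k, px * k), k)
  else bilinearResize(img, px, px)
}

#' md5 digest of an R object via its canonical JSON form
#' @param x a jsonlite-serializable object
#' @return hex md5 string
#' @keywords internal
jsonFingerprint <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  unname(tools::md5sum(tf))
}

#' md5 of a file
#' @keywords internal
fileMd5 <- function(path) unname(tools::md5sum(path))

#' Append one line-delimited JSON log record
#' @keywords internal
logJson <- function(path, stage, level, message, fingerprint = NULL, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage, level = level, message = message),
           if (!is.null(fingerprint)) list(fingerprint = fingerprint),
           list(...))
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(line)
}

#' Derive a reproducible child seed from a base seed and a tag
#' @keywords internal
childSeed <- function(seed, tag) {
  h <- jsonFingerprint(list(seed = seed, tag = tag))
  # fold the first 7 hex digits into a positive 32-bit integer
  as.integer(strtoi(substr(h, 1, 7), base = 16L) %% 2147483640L) + 1L
}

#' Run an expression with a temporarily-set RNG seed
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}
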