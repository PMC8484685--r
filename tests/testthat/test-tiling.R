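# Grid planning, the background/contaminant filter, and tile-set geometry.

test_that("grid planning floors to whole 2.5x cells", {
  cfg <- tileFilterConfig()
  # 10x extent 2392 -> 2.5x extent 598 -> 2x2 cells of 299
  g <- planGrid(fakePyramid(2392, 2392, baseMag = 10), cfg)
  expect_equal(nrow(g), 4L)
  expect_equal(max(g$row), 2L)
  expect_equal(max(g$col), 2L)
  expect_equal(g$sizeL0[1], 1196)
  # 897x598 at 2.5x -> 3x2 = 6 cells
  g2 <- planGrid(fakePyramid(897 * 4, 598 * 4, baseMag = 10), cfg)
  expect_equal(nrow(g2), 6L)
  expect_equal(max(g2$col), 3L)
  expect_equal(max(g2$row), 2L)
  # below one cell: empty plan, not an error
  g3 <- planGrid(fakePyramid(1000, 1000, baseMag = 10), cfg)
  expect_equal(nrow(g3), 0L)
  # cells are non-overlapping, row-major
  expect_equal(g$x, c(0, 1196, 0, 1196))
  expect_equal(g$y, c(0, 0, 1196, 1196))
})

test_that("filter counts background pixels by strict channel bounds", {
  cfg <- tileFilterConfig(tilePx = 100L)
  expect_true(passesFilter(flatTile(100, 128), cfg)$pass)
  expect_equal(passesFilter(flatTile(100, 128), cfg)$backgroundFraction, 0)
  # dark debris: all channels strictly below 50
  expect_equal(passesFilter(flatTile(100, 49), cfg)$backgroundFraction, 1)
  expect_equal(passesFilter(flatTile(100, 50), cfg)$backgroundFraction, 0)
  # white glass: all channels strictly above 200
  expect_equal(passesFilter(flatTile(100, 201), cfg)$backgroundFraction, 1)
  expect_equal(passesFilter(flatTile(100, 200), cfg)$backgroundFraction, 0)
  # a pixel with one mid channel is not background
  t <- flatTile(100, 255); t[, , 2] <- 128 / 255
  expect_equal(passesFilter(t, cfg)$backgroundFraction, 0)
})

test_that("exactly 40% background passes, strictly more is discarded", {
  cfg <- tileFilterConfig(tilePx = 100L)
  at <- passesFilter(whiteFractionTile(100, 4000), cfg)
  expect_true(at$pass)
  expect_equal(at$backgroundFraction, 0.4)
  above <- passesFilter(whiteFractionTile(100, 4100), cfg)  # 41%
  expect_false(above$pass)
  expect_false(passesFilter(whiteFractionTile(100, 4001), cfg)$pass)
})

test_that("a fully usable cell yields 16 sets with exact 1:4:16 geometry", {
  fx <- tiledSlideFixture()
  expect_equal(fx$summary$cells, 1L)
  expect_equal(length(fx$sets), 16L)
  cell <- c(0, 0, 1196)
  anchors <- t(vapply(fx$sets, function(ts) ts@anchor, numeric(2)))
  expect_equal(nrow(unique(anchors)), 16L)
  # anchors tile the cell footprint exactly
  expect_setequal(anchors[, 1], rep(c(0, 299, 598, 897), each = 4))
  for (ts in fx$sets) {
    fp <- tileFootprints(ts)
    areas <- unname(fp[, "w"] * fp[, "h"])
    expect_equal(areas / areas[1], c(1, 4, 16))
    # brute-force containment: 10x inside 5x inside 2.5x
    for (pair in list(c(1, 2), c(2, 3))) {
      inner <- fp[pair[1], ]; outer <- fp[pair[2], ]
      expect_gte(inner["x"], outer["x"])
      expect_gte(inner["y"], outer["y"])
      expect_lte(inner["x"] + inner["w"], outer["x"] + outer["w"])
      expect_lte(inner["y"] + inner["h"], outer["y"] + outer["h"])
    }
    # the 5x parent is the quadrant containing the 10x anchor
    expect_equal(unname(fp["5x", c("x", "y")]),
                 floor(ts@anchor / 598) * 598)
  }
})

test_that("background and partial cells filter as the pixel oracle dictates", {
  # all-white slide: no sets
  white <- pyramidFrom(array(1, c(1196, 1196, 3)), baseMag = 10)
  cfg <- tileFilterConfig()
  res <- tileSlide(white, cfg)
  expect_equal(res$summary$kept, 0L)
  expect_equal(res$summary$candidates, 16L)
  expect_equal(res$summary$discarded, 16L)
  # one fully-white 10x tile (25% of its 5x parent, 6.25% of the cell):
  # exactly that one candidate is lost
  img <- smoothImage(1196, 1196, seed = 9)
  img[1:299, 1:299, ] <- 1
  one <- pyramidFrom(img, baseMag = 10)
  sets <- tileSlide(one, cfg)$tileSets
  expect_equal(length(sets), 15L)
  expect_false(any(vapply(sets, function(ts)
    all(ts@anchor == c(0, 0)), logical(1))))
})

test_that("tiling summary conserves counts and output is deterministic", {
  fx <- tiledSlideFixture()
  s <- fx$summary
  expect_equal(s$kept + s$discarded, s$candidates)
  res2 <- tileSlide(fx$slide, tileFilterConfig(), profile = NULL,
                    patientId = "Pfix")
  expect_identical(lapply(res2$tileSets, function(t) t@images),
                   lapply(fx$sets, function(t) t@images))
})

test_that("stored tile sets can be shrunk at emission", {
  fx <- tiledSlideFixture()
  res <- tileSlide(fx$slide, tileFilterConfig(), profile = NULL,
                   patientId = "P", storePx = 75L)
  expect_equal(dim(res$tileSets[[1]]@images[["2.5x"]]), c(75, 75, 3))
  expect_equal(length(res$tileSets), 16L)
})
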