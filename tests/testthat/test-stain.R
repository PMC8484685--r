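# Beer-Lambert transforms and Vahadane-style stain estimation /
# normalization.

test_that("optical density transforms match their closed forms", {
  white <- flatTile(4, 255)
  expect_equal(max(abs(rgbToOd(white))), 0)
  black <- flatTile(4, 0)
  expect_equal(unique(as.vector(rgbToOd(black))), log(256))
  # monotone decreasing in intensity
  vals <- seq(0, 255, by = 5)
  ods <- vapply(vals, function(v) rgbToOd(flatTile(1, v))[1], numeric(1))
  expect_true(all(diff(ods) < 0))
  # od -> rgb -> od round trip within 8-bit quantization
  tile <- oracleStainTile(40)$tile
  od <- rgbToOd(tile)
  od2 <- rgbToOd(odToRgb(od))
  expect_lt(max(abs(od - od2)), rgbToOd(flatTile(1, 254))[1] -
              rgbToOd(flatTile(1, 255))[1] + 1e-9)
})

test_that("stain vectors are recovered within 0.05 rad of generator truth", {
  St <- perturbedBasis()
  fix <- oracleStainTile(120, S = St, seed = 5, hMean = 0.5, eMean = 0.7)
  est <- estimateStains(fix$tile)
  ang <- function(a, b) acos(pmin(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2))))
  # rows are ordered hematoxylin (blue-absorbing) first, matching truth
  expect_lt(ang(est$stainMatrix[1, ], St[1, ]), 0.05)
  expect_lt(ang(est$stainMatrix[2, ], St[2, ]), 0.05)
  # invariants: nonnegative unit-norm rows
  expect_true(all(est$stainMatrix >= 0))
  expect_equal(unname(sqrt(rowSums(est$stainMatrix^2))), c(1, 1))
})

test_that("estimation is deterministic and reconstructs within tolerance", {
  fix <- oracleStainTile(100, seed = 8)
  e1 <- estimateStains(fix$tile)
  e2 <- estimateStains(fix$tile)
  expect_identical(e1, e2)
  od <- matrix(rgbToOd(fix$tile), ncol = 3)
  C <- matrix(e1$concentrations, ncol = 2)
  relerr <- norm(od - C %*% e1$stainMatrix, "F") / norm(od, "F")
  expect_lt(relerr, 0.15)
  expect_true(all(C >= 0))
})

test_that("white and single-dye tiles behave as degenerate cases", {
  expect_error(estimateStains(flatTile(60, 250)), class = "unstainableTile")
  # single stain: the second vector's mean concentration is ~0
  S <- defaultStainProfile()@stainMatrix
  one <- withr::with_seed(4, odToRgb(array(
    cbind(pmin(rexp(3600, 2), 2), rep(0, 3600)) %*% S, c(60, 60, 3))))
  est <- estimateStains(one)
  C <- matrix(est$concentrations, ncol = 2)
  expect_lt(mean(C[, 2]), 0.05 * mean(C[, 1]))
})

test_that("normalization is idempotent on reference-rendered tiles", {
  P0 <- defaultStainProfile()
  fix <- oracleStainTile(120, seed = 3)
  od <- matrix(rgbToOd(fix$tile), ncol = 3)
  tissue <- pmax(od[, 1], od[, 2], od[, 3]) > P0@odThreshold
  p99 <- apply(fix$C[tissue, ], 2, quantile, 0.99)
  P <- new("StainProfile", stainMatrix = fix$S,
           maxConcentrations = unname(p99), odThreshold = P0@odThreshold,
           sparsityWeight = P0@sparsityWeight)
  nt <- normalizeTile(fix$tile, P)
  expect_equal(dim(nt), dim(fix$tile))
  expect_lte(max(abs(to255(nt) - to255(fix$tile))), 2)
})

test_that("normalization cancels a global stain-intensity scaling", {
  P0 <- defaultStainProfile()
  fix <- oracleStainTile(120, seed = 3)
  od <- matrix(rgbToOd(fix$tile), ncol = 3)
  tissue <- pmax(od[, 1], od[, 2], od[, 3]) > P0@odThreshold
  p99 <- apply(fix$C[tissue, ], 2, quantile, 0.99)
  P <- new("StainProfile", stainMatrix = fix$S,
           maxConcentrations = unname(p99), odThreshold = P0@odThreshold,
           sparsityWeight = P0@sparsityWeight)
  a <- normalizeTile(fix$tile, P)
  scaled <- odToRgb(array((fix$C * 0.75) %*% fix$S, c(120, 120, 3)))
  b <- normalizeTile(scaled, P)
  expect_lte(max(abs(to255(a) - to255(b))), 2)
})

test_that("background pixels stay near-white through normalization", {
  fix <- oracleStainTile(60, seed = 7)
  half <- array(1, c(60, 60, 3))
  half[1:30, , ] <- fix$tile[1:30, , ]
  nt <- normalizeTile(half)
  expect_gte(min(to255(nt[31:60, , ])), 250)
})

test_that("a profile survives a JSON round trip", {
  fix <- oracleStainTile(100, S = perturbedBasis(), seed = 9)
  p <- fitStainProfile(fix$tile)
  path <- file.path(withr::local_tempdir(), "profile.json")
  writeStainProfile(p, path)
  q <- readStainProfile(path)
  expect_equal(q@stainMatrix, p@stainMatrix, tolerance = 1e-12)
  expect_equal(q@maxConcentrations, p@maxConcentrations, tolerance = 1e-12)
  expect_equal(q@odThreshold, p@odThreshold)
})
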