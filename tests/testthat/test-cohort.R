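# Label handling, splits, class weights, and the record store.

test_that("label tables are validated against the schema", {
  lab <- labelFixture(10)
  expect_invisible(validateLabelTable(lab))
  bad <- rbind(lab, lab[1, ])
  expect_error(validateLabelTable(bad), "duplicate")
  lab2 <- labelFixture(4, slides = 2)
  lab2$tumor_class[2] <- 1 - lab2$tumor_class[2]
  expect_error(validateLabelTable(lab2), "differs across slides")
})

test_that("mixed split is 8:1:1 by patient and keeps patients whole", {
  lab <- labelFixture(100, slides = 1)
  sp <- makeSplit(lab, "tumor_class", "mixed", seed = 3)
  expect_equal(as.vector(table(sp$partition)[c("train", "validation", "test")]),
               c(80L, 10L, 10L))
  # stratification within one patient of exact
  m <- merge(lab, sp, by = "patient_id")
  for (p in c("train", "validation", "test")) {
    frac <- mean(m$tumor_class[m$partition == p])
    expect_lt(abs(frac - 0.5), 0.11)
  }
  # a patient with several slides lands in exactly one partition
  lab3 <- labelFixture(20, slides = 3)
  sp3 <- makeSplit(lab3, "tumor_class", "mixed", seed = 1)
  m3 <- merge(lab3, sp3, by = "patient_id")
  perPatient <- tapply(m3$partition, m3$patient_id,
                       function(v) length(unique(v)))
  expect_true(all(perPatient == 1L))
})

test_that("cohort-independent split holds out the whole cohort at 9:1", {
  lab <- labelFixture(100, cohortB = 0)
  lab$cohort[c(1:5, 96:100)] <- "B"
  # B patients span both classes so every partition can satisfy presence
  expect_true(length(unique(lab$tumor_class[lab$cohort == "B"])) == 2L)
  sp <- makeSplit(lab, "tumor_class", "cohort_independent", seed = 2,
                  heldOutCohort = "B")
  m <- merge(lab, sp, by = "patient_id")
  expect_true(all(m$partition[m$cohort == "B"] == "test"))
  expect_equal(sum(sp$partition == "test"), 10L)
  expect_equal(sum(sp$partition == "train"), 81L)
  expect_equal(sum(sp$partition == "validation"), 9L)
})

test_that("splits never leak patients and are seed-deterministic", {
  lab <- labelFixture(30)
  for (s in 1:5) {
    sp <- makeSplit(lab, "tumor_class", "mixed", seed = s)
    parts <- split(sp$patient_id, sp$partition)
    expect_equal(length(Reduce(intersect, parts)), 0L)
    m <- merge(lab, sp, by = "patient_id")
    for (p in names(parts)) {
      v <- m$tumor_class[m$partition == p]
      expect_true(any(v == 1) && any(v == 0))
    }
  }
  expect_identical(makeSplit(lab, "tumor_class", "mixed", seed = 4),
                   makeSplit(lab, "tumor_class", "mixed", seed = 4))
})

test_that("impossible stratification raises an infeasibility error", {
  lab <- labelFixture(10, posFrac = 0.1)   # a single positive patient
  expect_error(makeSplit(lab, "tumor_class", "mixed", seed = 1),
               "class presence|at least one")
})

test_that("class weights equalize weighted composition", {
  lab <- labelFixture(20)
  sp <- makeSplit(lab, "tumor_class", "mixed", seed = 1)
  w <- computeClassWeights(lab, "tumor_class", sp)
  expect_equal(unname(w), c(1, 1), tolerance = 0.26)  # near-balanced split
  # 75/25 composition via tile counts
  tr <- merge(lab, sp, by = "patient_id")
  tr <- tr[tr$partition == "train", ]
  n1 <- sum(tr$tumor_class == 1); n0 <- sum(tr$tumor_class == 0)
  counts <- data.frame(slide_id = tr$slide_id,
                       n = ifelse(tr$tumor_class == 0, 3 * n1, n0))
  w2 <- computeClassWeights(lab, "tumor_class", sp, counts)
  expect_equal(unname(w2), c(2 / 3, 2), tolerance = 1e-9)
  # invariant to the total count at fixed composition
  counts$n <- counts$n * 5
  expect_equal(computeClassWeights(lab, "tumor_class", sp, counts), w2)
})

test_that("records round-trip tile sets losslessly with honest manifests", {
  fx <- tiledSlideFixture()
  sets <- fx$sets[1:6]
  sets <- lapply(sets, function(ts) { ts@patientId <- "P001"; ts })
  lab <- labelFixture(4)
  sp <- data.frame(patient_id = sprintf("P%03d", 1:4),
                   partition = c("train", "validation", "test", "train"))
  dirp <- withr::local_tempdir()
  mf <- writeRecords(sets, lab, "tumor_class", sp, dirp)
  expect_equal(mf$partitions$train$n, 6L)
  expect_equal(mf$partitions$validation$n, 0L)
  recs <- readRecords(dirp, "train")
  expect_equal(length(recs), 6L)
  back <- panoptes:::recordToTileSet(recs[[1]])
  orig <- sets[[1]]
  expect_equal(back@images, orig@images)  # emitted pixels are 8-bit already
  expect_equal(back@anchor, orig@anchor)
  expect_equal(back@tileSetId, orig@tileSetId)
  expect_equal(recs[[1]]$label, lab$tumor_class[lab$patient_id == "P001"][1])
  # seeded shuffle is reproducible
  o1 <- vapply(readRecords(dirp, "train", shuffleSeed = 9), `[[`,
               character(1), "tile_set_id")
  o2 <- vapply(readRecords(dirp, "train", shuffleSeed = 9), `[[`,
               character(1), "tile_set_id")
  expect_identical(o1, o2)
  expect_false(identical(o1, vapply(recs, `[[`, character(1), "tile_set_id")))
  # corruption is caught and named
  shard <- list.files(dirp, pattern = "train.*shard", full.names = TRUE)[1]
  raw <- readBin(shard, "raw", file.size(shard))
  raw[100] <- as.raw(bitwXor(as.integer(raw[100]), 255L))
  writeBin(raw, shard)
  expect_error(readRecords(dirp, "train"), "checksum mismatch.*train")
})

test_that("tile sets of unlabeled patients are excluded and counted", {
  fx <- tiledSlideFixture()
  sets <- lapply(fx$sets[1:4], function(ts) { ts@patientId <- "P009"; ts })
  lab <- labelFixture(4)        # P009 absent
  sp <- data.frame(patient_id = sprintf("P%03d", 1:4),
                   partition = c("train", "validation", "test", "train"))
  dirp <- withr::local_tempdir()
  mf <- writeRecords(sets, lab, "tumor_class", sp, dirp)
  expect_equal(mf$excluded_tile_sets, 4L)
  expect_equal(mf$partitions$train$n, 0L)
})

test_that("tensor packing and batch assembly preserve pixels and labels", {
  tens <- tinyTensors(n = 8, px = 75)
  b <- batchFromTensors(tens, c(2, 5), inputPx = 75)
  expect_equal(dim(b$x[["10x"]]), c(75, 75, 3, 2))
  expect_equal(b$labels, tens$labels[c(2, 5)])
  decoded <- array(as.integer(tens$pix[["10x"]][, 2]) / 255, c(75, 75, 3))
  expect_equal(b$x[["10x"]][, , , 1], decoded)
  # shrink on assembly
  b2 <- batchFromTensors(tens, 1:2, inputPx = 75L)
  expect_equal(dim(b2$x[["5x"]])[1:2], c(75, 75))
})
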