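# The synthetic-slide generator: determinism, composition, and the
# scale-specificity of the planted class signal.

test_that("margin-free specs give all-tissue masks; fractions track targets", {
  g <- generateSlide(syntheticSlideSpec(seed = 1, extent10x = 400,
                                        backgroundFraction = 0,
                                        contaminants = 0, slideId = "full"))
  expect_true(all(g$mask == 1L))
  # background areal fraction within 2% of target across seeds
  for (s in 1:5) {
    g2 <- generateSlide(syntheticSlideSpec(seed = s, extent10x = 600,
                                           backgroundFraction = 0.25,
                                           contaminants = 0))
    expect_lt(abs(mean(g2$mask == 0L) - 0.25), 0.02)
  }
})

test_that("slides are pure functions of their spec, including on disk", {
  spec <- syntheticSlideSpec(seed = 9, extent10x = 400,
                             backgroundFraction = 0.15, contaminants = 2,
                             slideId = "det")
  dirp <- withr::local_tempdir()
  generateSlide(spec, path = file.path(dirp, "a.tiff"))
  generateSlide(spec, path = file.path(dirp, "b.tiff"))
  expect_identical(unname(tools::md5sum(file.path(dirp, "a.tiff"))),
                   unname(tools::md5sum(file.path(dirp, "b.tiff"))))
  g1 <- generateSlide(spec); g2 <- generateSlide(spec)
  expect_identical(g1$slide@pages, g2$slide@pages)
})

test_that("contaminants are dark, margins are white, tissue is neither", {
  g <- generateSlide(syntheticSlideSpec(seed = 3, extent10x = 600,
                                        backgroundFraction = 0.2,
                                        contaminants = 2, slideId = "c"))
  img <- to255(g$slide@pages[[1]])
  bg <- g$mask == 0L
  expect_true(all(img[, , 1][bg] > 200 & img[, , 2][bg] > 200 &
                    img[, , 3][bg] > 200))
  cont <- g$mask == 2L
  expect_gt(sum(cont), 0)
  expect_true(all(img[, , 1][cont] < 50 & img[, , 2][cont] < 50 &
                    img[, , 3][cont] < 50))
  tis <- g$mask == 1L
  below <- img[, , 1][tis] < 50 & img[, , 2][tis] < 50 & img[, , 3][tis] < 50
  above <- img[, , 1][tis] > 200 & img[, , 2][tis] > 200 & img[, , 3][tis] > 200
  expect_lt(mean(below | above), 0.01)
})

test_that("cohorts honor balance, label constancy, and clinical ranges", {
  co <- generateCohort(20, slidesPerPatient = 2, classBalance = 0.5,
                       signalScale = "none", seed = 4, extent10x = 400)
  lab <- co$labels
  perPat <- lab[!duplicated(lab$patient_id), ]
  expect_equal(sum(perPat$tumor_class), 10)
  expect_equal(nrow(lab), 40L)
  cons <- tapply(lab$tumor_class, lab$patient_id,
                 function(v) length(unique(v)))
  expect_true(all(cons == 1L))
  expect_true(all(lab$age > 20 & lab$age < 110))
  expect_true(all(lab$bmi > 12 & lab$bmi < 60))
  expect_length(co$slides, 40L)
})

test_that("macro signal separates 2.5x statistics but not 10x statistics", {
  perClass <- 8
  stat10 <- list(); stat25 <- list()
  for (cl in 0:1) {
    s10 <- c(); s25 <- c()
    for (i in seq_len(perClass)) {
      g <- generateSlide(syntheticSlideSpec(
        seed = 100 * cl + i, extent10x = 1196, backgroundFraction = 0,
        contaminants = 0, class = cl, signalScale = "macro", effect = 2,
        slideId = sprintf("m%d_%d", cl, i)))
      # 16 10x tiles: plain per-tile mean and sd of the green channel
      for (ai in 0:3) for (aj in 0:3) {
        t10 <- readRegion(g$slide, aj * 299, ai * 299, 299, 10)[, , 2]
        s10 <- rbind(s10, c(mean(t10), sd(t10)))
      }
      # the slide's 2.5x tile: macro-band roughness (mean absolute step of
      # the block-averaged view), the statistic a low-power reader sees
      t25 <- resizeBox(readRegion(g$slide, 0, 0, 299, 2.5), 75)[, , 2]
      sm <- areaDownsample(t25[1:72, 1:72], 12)
      s25 <- c(s25, mean(abs(diff(sm))) + mean(abs(diff(t(sm)))))
    }
    stat10[[cl + 1]] <- s10; stat25[[cl + 1]] <- s25
  }
  # 10x: per-tile means are class-indistinguishable (the rank transform
  # fixes the pixel marginal exactly), and the within-tile sd differs by at
  # most a small standardized effect — the residual macro slope inside a
  # 299 px field. A p-value threshold here would merely measure the sample
  # size, so the claim is on the effect scale.
  cohenD <- function(a, b) {
    (mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
  }
  expect_gt(t.test(stat10[[1]][, 1], stat10[[2]][, 1])$p.value, 0.01)
  expect_lt(abs(cohenD(stat10[[1]][, 2], stat10[[2]][, 2])), 0.5)
  # 2.5x: the macro-band statistic separates the classes with a huge effect
  expect_lt(t.test(stat25[[1]], stat25[[2]])$p.value, 0.01)
  expect_gt(abs(cohenD(stat25[[1]], stat25[[2]])), 1.5)
  expect_gt(mean(stat25[[1]]), mean(stat25[[2]]))  # finer texture varies more
})

test_that("micro signal shifts nuclear-dot density at 10x", {
  dotStat <- function(cl) {
    g <- generateSlide(syntheticSlideSpec(
      seed = 7, extent10x = 400, backgroundFraction = 0, contaminants = 0,
      class = cl, signalScale = "micro", effect = 2, slideId = "mic"))
    # hematoxylin-heavy pixels (dark blue dots) per unit area
    img <- g$slide@pages[[1]]
    mean(img[, , 3] < 0.55 & img[, , 2] < 0.55)
  }
  expect_gt(dotStat(1), 1.5 * dotStat(0))
})
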