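# Metrics and hypothesis-testing procedures against independent oracles
# (pairwiseAuroc / naiveAupr from the test helpers).

test_that("per-patient scores are tile means, invariant to sharding", {
  p <- data.frame(patient_id = c("A", "A", "A", "B"),
                  slide_id = "s", tile_set_id = paste0("t", 1:4),
                  score = c(0.2, 0.4, 0.9, 0.5), true_label = c(1, 1, 1, 0))
  ps <- patientScores(p)
  expect_equal(ps$score[ps$patient_id == "A"], 0.5)
  expect_equal(ps$score[ps$patient_id == "B"], 0.5)
  # row order / sharding cannot matter
  expect_equal(patientScores(p[c(3, 1, 4, 2), ])$score, ps$score)
})

test_that("classification at the cutoff is strictly greater-than", {
  expect_equal(classifyScore(c(0.6, 0.5, 0.0, 1.0)), c(1L, 0L, 0L, 1L))
})

test_that("AUROC equals exhaustive pairwise comparison, including ties", {
  expect_equal(auroc(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1)), 1)
  withr::with_seed(7, {
    for (rep in 1:25) {
      n <- sample(10:200, 1)
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      s <- round(runif(n), sample(c(1, 2, 3), 1))  # rounding makes ties
      expect_equal(auroc(s, y), pairwiseAuroc(s, y))
    }
    # near 0.5 when labels are independent of scores
    y <- rbinom(4000, 1, 0.5); s <- runif(4000)
    expect_lt(abs(auroc(s, y) - 0.5), 0.03)
  })
  expect_warning(expect_true(is.na(auroc(c(0.1, 0.2), c(1, 1)))),
                 "one class")
})

test_that("AUROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(3, {
    for (rep in 1:5) {
      y <- rbinom(60, 1, 0.4); if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      s <- round(runif(60), 2)
      ref <- as.numeric(suppressMessages(pROC::auc(y, s,
        direction = "<", quiet = TRUE)))
      expect_equal(auroc(s, y), ref)
    }
  })
})

test_that("AUPR equals the stepwise average-precision oracle", {
  withr::with_seed(11, {
    for (rep in 1:15) {
      n <- sample(10:120, 1)
      y <- rbinom(n, 1, 0.4)
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      s <- round(runif(n), 2)
      expect_equal(aupr(s, y), naiveAupr(s, y))
    }
  })
})

test_that("threshold metrics reconcile with the confusion matrix", {
  p <- predFixture(120, seed = 5)
  th <- thresholdMetrics(p$score, p$true_label)
  expect_equal(th$tp + th$fn, th$n_pos)
  expect_equal(th$tn + th$fp, th$n_neg)
  expect_equal(th$accuracy, (th$tp + th$tn) / nrow(p))
  expect_equal(th$sensitivity, th$tp / (th$tp + th$fn))
  expect_equal(th$specificity, th$tn / (th$tn + th$fp))
})

test_that("bootstrap CIs are seeded, contain the point, and can degenerate", {
  p <- predFixture(60, seed = 2)
  ci1 <- bootstrapCi(p, "auroc", "per_tile", nBoot = 200, seed = 4)
  ci2 <- bootstrapCi(p, "auroc", "per_tile", nBoot = 200, seed = 4)
  expect_identical(ci1, ci2)
  # property harness: the interval brackets the point estimate
  withr::with_seed(13, {
    for (rep in 1:20) {
      q <- predFixture(40, seed = 100 + rep, signal = runif(1, 0, 2))
      ci <- bootstrapCi(q, sample(c("auroc", "accuracy"), 1), "per_tile",
                        nBoot = 120, seed = rep)
      expect_lte(ci["lower"], ci["point"] + 1e-9)
      expect_gte(ci["upper"], ci["point"] - 1e-9)
    }
  })
  # a perfectly separated table resamples to the same metric every time
  sep <- data.frame(patient_id = paste0("P", 1:10), slide_id = "s",
                    tile_set_id = paste0("t", 1:10),
                    score = c(rep(0.9, 5), rep(0.1, 5)),
                    true_label = rep(c(1, 0), each = 5))
  ci <- bootstrapCi(sep, "auroc", "per_tile", nBoot = 100, seed = 1)
  expect_equal(unname(ci), c(1, 1, 1))
})

test_that("the rank-sum test matches exact enumeration when separable", {
  sep <- data.frame(patient_id = paste0("P", 1:10), slide_id = "s",
                    tile_set_id = paste0("t", 1:10),
                    score = c(6:10, 1:5) / 10,
                    true_label = rep(c(1, 0), each = 5))
  expect_equal(wilcoxonTiles(sep), 1 / choose(10, 5))
  # identical distributions: p near 0.5 for large n
  withr::with_seed(2, {
    big <- predFixture(600, signal = 0)
    p <- wilcoxonTiles(big)
    expect_gt(p, 0.1); expect_lte(p, 1)
  })
})

test_that("architecture comparison resamples 50 AUROCs per model", {
  a <- predFixture(80, seed = 1, signal = 2)
  cmp <- compareArchitectures(a, a, "per_tile", seed = 7)
  expect_length(cmp$aurocA, 50L)
  expect_length(cmp$aurocB, 50L)
  expect_gt(cmp$p_value, 0.05)  # no effect against itself
  # power: perfect model vs random model
  b <- a
  withr::with_seed(8, b$score <- runif(80))
  sepA <- a; sepA$score <- ifelse(a$true_label == 1, 0.9, 0.1)
  cmp2 <- compareArchitectures(sepA, b, "per_tile", seed = 7)
  expect_lt(cmp2$p_value, 0.01)
})

test_that("metrics reports carry CIs and undefined metrics stay missing", {
  p <- predFixture(80, seed = 9, signal = 1.5)
  rep_ <- metricsReport(p, "per_patient", nBoot = 100, seed = 1)
  expect_true(rep_$auroc$ci_lower <= rep_$auroc$point + 1e-9)
  expect_true(rep_$auroc$ci_upper >= rep_$auroc$point - 1e-9)
  expect_true(all(vapply(c("auroc", "aupr", "accuracy"), function(m)
    rep_[[m]]$point >= 0 && rep_[[m]]$point <= 1, logical(1))))
})
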