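# Per-tile and per-patient evaluation. A prediction table has one row per
# tile set (a multi-resolution set counts as a single tile): patient_id,
# slide_id, tile_set_id, score (positive-class probability), true_label.
# Per-patient scores are the arithmetic mean of the patient's tile-set
# scores; metrics are then computed treating each patient as one sample.

#' Validate a prediction table
#' @param preds data.frame with columns patient_id, slide_id, tile_set_id,
#'   score, true_label
#' @return the table, invisibly
#' @export
validatePredictionTable <- function(preds) {
  need <- c("patient_id", "slide_id", "tile_set_id", "score", "true_label")
  miss <- setdiff(need, names(preds))
  if (length(miss)) stop("prediction table lacks: ", paste(miss, collapse = ", "))
  if (any(preds$score < 0 | preds$score > 1)) stop("scores must be in [0,1]")
  if (anyDuplicated(preds$tile_set_id)) stop("duplicate tile_set_id rows")
  if (!all(preds$true_label %in% c(0, 1))) stop("true_label must be 0/1")
  invisible(preds)
}

#' Per-patient score table
#'
#' One row per patient; the score is the arithmetic mean of the predicted
#' probabilities of all tile sets belonging to that patient (invariant to
#' row order and to how tiles were sharded).
#'
#' @param preds a prediction table
#' @return data.frame (patient_id, score, true_label, n_tiles)
#' @export
patientScores <- function(preds) {
  validatePredictionTable(preds)
  sc <- tapply(preds$score, preds$patient_id, mean)
  lb <- tapply(preds$true_label, preds$patient_id, function(v) v[1])
  nt <- tapply(preds$score, preds$patient_id, length)
  data.frame(patient_id = names(sc), score = as.numeric(sc),
             true_label = as.numeric(lb), n_tiles = as.integer(nt),
             row.names = NULL)
}

#' Hard classification at a cutoff
#'
#' Positive iff the score is strictly greater than the cutoff, so a score
#' of exactly 0.5 is called negative.
#'
#' @param score numeric in [0,1]
#' @param cutoff decision threshold (default 0.5)
#' @return integer 0/1 vector
#' @export
classifyScore <- function(score, cutoff = 0.5) as.integer(score > cutoff)

#' Area under the ROC curve
#'
#' Mann-Whitney probability that a positive outranks a negative, ties
#' counted one half — identical to exhaustive pairwise comparison.
#'
#' @param scores numeric scores
#' @param labels 0/1 labels
#' @return AUROC in [0,1], or `NA` with a warning when only one class is
#'   present
#' @export
auroc <- function(scores, labels) {
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    warning("AUROC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: the sum over descending-score thresholds of
#' the recall increment times the precision at that threshold (tied scores
#' grouped into one step).
#'
#' @inheritParams auroc
#' @return AUPR in [0,1], or `NA` when no positives/negatives
#' @export
aupr <- function(scores, labels) {
  npos <- sum(labels == 1)
  if (npos == 0 || sum(labels == 0) == 0) {
    warning("AUPR undefined: only one class present")
    return(NA_real_)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); n <- seq_along(y)
  last <- !duplicated(grp, fromLast = TRUE)  # end of each tied block
  tp <- tp[last]; n <- n[last]
  prec <- tp / n
  rec <- tp / npos
  drec <- diff(c(0, rec))
  sum(drec * prec)
}

#' Confusion-matrix metrics at a cutoff
#'
#' @inheritParams auroc
#' @param cutoff decision threshold (strict `>`)
#' @return named list: accuracy, sensitivity, specificity, precision,
#'   recall, f1, tp, fp, tn, fn, n_pos, n_neg
#' @export
thresholdMetrics <- function(scores, labels, cutoff = 0.5) {
  pred <- classifyScore(scores, cutoff)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = rec, specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       precision = prec, recall = rec,
       f1 = if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
         2 * prec * rec / (prec + rec) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn,
       n_pos = sum(labels == 1), n_neg = sum(labels == 0))
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Resamples rows (tile sets at per-tile level, patients at per-patient
#' level) with replacement `nBoot` times; resamples containing one class
#' only are redrawn. Returns the 2.5/97.5 percentile interval.
#'
#' @param preds a prediction table
#' @param metric `"auroc"`, `"aupr"` or `"accuracy"`
#' @param level `"per_tile"` or `"per_patient"`
#' @param nBoot bootstrap resamples (default 1000)
#' @param seed RNG seed
#' @return named numeric c(lower, point, upper)
#' @export
bootstrapCi <- function(preds, metric = c("auroc", "aupr", "accuracy"),
                        level = c("per_patient", "per_tile"), nBoot = 1000L,
                        seed = 1L) {
  metric <- match.arg(metric)
  level <- match.arg(level)
  tab <- if (level == "per_patient") patientScores(preds) else preds
  mfun <- switch(metric,
                 auroc = function(s, y) auroc(s, y),
                 aupr = function(s, y) aupr(s, y),
                 accuracy = function(s, y) thresholdMetrics(s, y)$accuracy)
  point <- mfun(tab$score, tab$true_label)
  n <- nrow(tab)
  vals <- withSeed(childSeed(seed, paste0("boot_", metric, "_", level)), {
    v <- numeric(nBoot)
    for (b in seq_len(nBoot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(tab$true_label[idx])) == 2L) break
      }
      v[b] <- suppressWarnings(mfun(tab$score[idx], tab$true_label[idx]))
    }
    v
  })
  q <- quantile(vals, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  c(lower = q[1], point = point, upper = q[2])
}

#' Full metrics report at one level
#'
#' AUROC, AUPR and accuracy with 95% bootstrap CIs plus threshold metrics
#' at the 0.5 cutoff.
#'
#' @inheritParams bootstrapCi
#' @return list (level, auroc/aupr/accuracy with ci, threshold metrics,
#'   n_pos, n_neg)
#' @export
metricsReport <- function(preds, level = c("per_patient", "per_tile"),
                          nBoot = 1000L, seed = 1L) {
  level <- match.arg(level)
  tab <- if (level == "per_patient") patientScores(preds) else preds
  th <- thresholdMetrics(tab$score, tab$true_label)
  rep_ <- list(level = level, n_pos = th$n_pos, n_neg = th$n_neg)
  for (m in c("auroc", "aupr", "accuracy")) {
    ci <- bootstrapCi(preds, m, level, nBoot, seed)
    rep_[[m]] <- list(point = unname(ci["point"]), ci_lower = unname(ci["lower"]),
                      ci_upper = unname(ci["upper"]))
  }
  rep_[c("accuracy_05", "sensitivity", "specificity", "precision",
         "recall", "f1")] <-
    th[c("accuracy", "sensitivity", "specificity", "precision", "recall", "f1")]
  rep_
}

#' One-sided rank-sum test between positive and negative tiles
#'
#' Tests whether positively labeled tile scores are stochastically greater
#' than negative ones (unpaired Mann-Whitney / Wilcoxon rank-sum). Exact
#' enumeration for small tie-free samples (total n <= 20), normal
#' approximation with tie and continuity correction otherwise.
#'
#' @param preds a prediction table
#' @return one-sided p-value
#' @export
wilcoxonTiles <- function(preds) {
  validatePredictionTable(preds)
  pos <- preds$score[preds$true_label == 1]
  neg <- preds$score[preds$true_label == 0]
  if (!length(pos) || !length(neg))
    stop("both classes must be present")
  hasTies <- anyDuplicated(c(pos, neg)) > 0
  ex <- (length(pos) + length(neg) <= 20L) && !hasTies
  wt <- suppressWarnings(
    wilcox.test(pos, neg, alternative = "greater", exact = ex,
                correct = TRUE))
  unname(wt$p.value)
}

#' Resampled AUROC comparison of two models
#'
#' The two prediction tables must cover the same task and test split. Each
#' is resampled 50 times at an 80% sampling rate without replacement (over
#' patients or tile sets, per `level`), the AUROC is computed per resample
#' (single-class resamples are redrawn), and a one-sided unpaired t-test of
#' "A > B" is performed on the two AUROC sets.
#'
#' @param predsA,predsB prediction tables for the two models
#' @param level `"per_patient"` or `"per_tile"`
#' @param nResample resamples per model (default 50)
#' @param rate sampling rate (default 0.8)
#' @param seed RNG seed
#' @return list: `p_value`, `aurocA`, `aurocB` (numeric vectors of length
#'   `nResample`)
#' @export
compareArchitectures <- function(predsA, predsB,
                                 level = c("per_patient", "per_tile"),
                                 nResample = 50L, rate = 0.8, seed = 1L) {
  level <- match.arg(level)
  sampleAuroc <- function(preds, tag) {
    tab <- if (level == "per_patient") patientScores(preds) else preds
    n <- nrow(tab)
    k <- max(2L, round(rate * n))
    withSeed(childSeed(seed, paste0("cmp_", tag, "_", level)), {
      v <- numeric(nResample)
      for (b in seq_len(nResample)) {
        repeat {
          idx <- sample.int(n, k)
          if (length(unique(tab$true_label[idx])) == 2L) break
        }
        v[b] <- auroc(tab$score[idx], tab$true_label[idx])
      }
      v
    })
  }
  a <- sampleAuroc(predsA, "A")
  b <- sampleAuroc(predsB, "B")
  p <- if (sd(a) < 1e-12 && sd(b) < 1e-12) {
    if (mean(a) > mean(b)) 0 else if (mean(a) < mean(b)) 1 else 0.5
  } else t.test(a, b, alternative = "greater")$p.value
  list(p_value = unname(p), aurocA = a, aurocB = b)
}
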