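# Declarative end-to-end runs: simulate (or ingest) -> tile -> split ->
# train -> evaluate -> visualize, with one JSON-serializable configuration
# whose md5 digest is the run fingerprint stamped into every artifact.
# Stages are idempotent: a stage whose manifest already carries the current
# fingerprint is skipped on re-run.

#' Build a run configuration
#'
#' Nested stage configurations with desk-scale defaults. The configuration
#' serializes to one JSON document; its digest ([runFingerprint]) is the run
#' fingerprint.
#'
#' @param outputRoot artifact directory
#' @param seed global seed (all stage seeds derive from it)
#' @param cohort named list passed to [generateCohort] (set `dir = NULL`
#'   fields aside; the pipeline fills `dir` and `seed`); or
#'   `list(labels = <csv>, slides = <dir>)` to ingest existing slides
#' @param filter named list for [tileFilterConfig]
#' @param normalize logical: stain-normalize tiles
#' @param storePx stored tile side (NULL keeps the filter size)
#' @param task task column
#' @param splitMode `"mixed"` or `"cohort_independent"`
#' @param heldOutCohort held-out cohort for cohort mode
#' @param arch named list for [architectureConfig]
#' @param schedule named list overriding [deskSchedule] fields
#' @param augment dihedral training augmentation (see [trainModel])
#' @param nBoot bootstrap resamples for the metrics report
#' @param visualize render the embedding and a heatmap
#' @return object of class `runConfig`
#' @export
runConfig <- function(outputRoot, seed = 1L,
                      cohort = list(nPatients = 20L, slidesPerPatient = 1L,
                                    signalScale = "macro", effect = 3,
                                    extent10x = 1196L),
                      filter = list(), normalize = TRUE, storePx = 75L,
                      task = "tumor_class", splitMode = "mixed",
                      heldOutCohort = NULL,
                      arch = list(family = "panoptes2",
                                  widthMultiplier = 0.1, inputPx = 75L),
                      schedule = list(maxIter = 300L), augment = TRUE,
                      nBoot = 200L, visualize = TRUE) {
  structure(list(outputRoot = outputRoot, seed = as.integer(seed),
                 cohort = cohort, filter = filter, normalize = normalize,
                 storePx = storePx, task = task, splitMode = splitMode,
                 heldOutCohort = heldOutCohort, arch = arch,
                 schedule = schedule, augment = augment, nBoot = nBoot,
                 visualize = visualize),
            class = "runConfig")
}

#' Fingerprint of a run configuration
#'
#' md5 of the canonical JSON form of every stage configuration (the output
#' root is excluded so a run is relocatable).
#'
#' @param config a [runConfig]
#' @return hex string
#' @export
runFingerprint <- function(config) {
  jsonFingerprint(config[setdiff(names(config), "outputRoot")])
}

#' @keywords internal
stageDone <- function(dir, fp) {
  mf <- file.path(dir, "stage.json")
  if (!file.exists(mf)) return(FALSE)
  j <- tryCatch(jsonlite::read_json(mf), error = function(e) NULL)
  identical(j$fingerprint, fp) && isTRUE(j$done)
}

#' @keywords internal
markStage <- function(dir, fp, extra = list()) {
  jsonlite::write_json(c(list(fingerprint = fp, done = TRUE), extra),
                       file.path(dir, "stage.json"), auto_unbox = TRUE,
                       digits = NA)
}

#' Execute a configured pipeline run
#'
#' Runs simulate/ingest, tile (+ record store with per-patient split),
#' train, evaluate, and visualize. Every artifact directory carries the run
#' fingerprint; stages already finished under the same fingerprint are
#' skipped. A stage failure halts with the stage name and the fingerprint.
#'
#' @param config a [runConfig]
#' @return named list of stage outputs (`labels`, `manifest`, `train`,
#'   `metrics`, `figures`)
#' @export
runPipeline <- function(config) {
  fp <- runFingerprint(config)
  root <- config$outputRoot
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(root, "log.ndjson")
  out <- list(fingerprint = fp)
  stage <- function(name, dir, fun) {
    d <- file.path(root, dir)
    dir.create(d, showWarnings = FALSE)
    if (stageDone(d, fp)) {
      logJson(logPath, name, "info", "skipped (up to date)", fp)
      return(d)
    }
    logJson(logPath, name, "info", "start", fp)
    tryCatch(fun(d), error = function(e)
      stop("stage ", name, " failed [config ", fp, "]: ",
           conditionMessage(e)))
    markStage(d, fp)
    logJson(logPath, name, "info", "done", fp)
    d
  }

  # --- simulate / ingest ---
  simDir <- stage("simulate", "simulate", function(d) {
    if (!is.null(config$cohort$labels)) return(invisible())  # ingest mode
    args <- config$cohort
    args$seed <- childSeed(config$seed, "cohort")
    args$dir <- d
    do.call(generateCohort, args)
  })
  if (!is.null(config$cohort$labels)) {
    labels <- readLabelTable(config$cohort$labels)
    slideDir <- config$cohort$slides
  } else {
    labels <- readLabelTable(file.path(simDir, "labels.csv"))
    slideDir <- simDir
  }
  out$labels <- labels

  # --- tile + split + records ---
  recDir <- file.path(root, "records")
  stage("tile", "records", function(d) {
    cfg <- do.call(tileFilterConfig, config$filter)
    profile <- if (isTRUE(config$normalize)) defaultStainProfile() else NULL
    split <- makeSplit(labels, config$task, config$splitMode,
                       seed = childSeed(config$seed, "split"),
                       heldOutCohort = config$heldOutCohort)
    part <- setNames(split$partition, split$patient_id)
    lab <- patientLabels(labels, config$task)
    plab <- setNames(lab[[config$task]], lab$patient_id)
    firstRow <- labels[!duplicated(labels$patient_id), ]
    agev <- setNames(firstRow$age, firstRow$patient_id)
    bmiv <- setNames(firstRow$bmi, firstRow$patient_id)
    wr <- recordStoreWriter(d)
    excluded <- 0L
    summaries <- list()
    for (i in seq_len(nrow(labels))) {
      sid <- labels$slide_id[i]; pid <- labels$patient_id[i]
      sl <- file.path(slideDir, paste0(sid, ".tiff"))
      slide <- openSlide(sl)
      res <- tileSlide(slide, cfg, profile = profile,
                       patientId = pid, storePx = config$storePx,
                       sink = function(ts) {
                         if (is.na(plab[pid]) || is.na(part[pid]))
                           excluded <<- excluded + 1L
                         else wr$add(ts, unname(plab[pid]), unname(agev[pid]),
                                     unname(bmiv[pid]), unname(part[pid]))
                       })
      summaries[[sid]] <- res$summary
      logJson(logPath, "tile", "info",
              sprintf("slide %s: %d/%d tile sets kept", sid,
                      res$summary$kept, res$summary$candidates), fp)
    }
    wr$finish(task = config$task, fingerprint = fp, excluded = excluded)
    jsonlite::write_json(list(split = split, summaries = summaries),
                         file.path(d, "tiling.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  })
  manifest <- jsonlite::read_json(file.path(recDir, "manifest.json"))
  out$manifest <- manifest

  # --- train ---
  trainDir <- file.path(root, "train")
  stage("train", "train", function(d) {
    arch <- do.call(architectureConfig, config$arch)
    model <- buildModel(arch, seed = childSeed(config$seed, "init"))
    schedArgs <- modifyList(list(seed = childSeed(config$seed, "sched")),
                            config$schedule)
    sched <- do.call(deskSchedule, schedArgs[intersect(names(schedArgs),
                       c("maxIter", "seed", "batchSize"))])
    trTens <- recordsToTensors(readRecords(recDir, "train"))
    vaTens <- recordsToTensors(readRecords(recDir, "validation"))
    cw <- c("0" = manifest$partitions$train$n /
              (2 * manifest$partitions$train$n_neg),
            "1" = manifest$partitions$train$n /
              (2 * manifest$partitions$train$n_pos))
    fit <- trainModel(model, trTens, vaTens, sched, cw,
                      augment = isTRUE(config$augment))
    saveCheckpoint(fit$model, file.path(d, "best.ckpt"))
    write.csv(fit$log, file.path(d, "training_log.csv"), row.names = FALSE)
  })

  # --- evaluate ---
  evalDir <- file.path(root, "evaluate")
  testTensEnv <- new.env(parent = emptyenv())
  stage("evaluate", "evaluate", function(d) {
    model <- loadCheckpoint(file.path(trainDir, "best.ckpt"))
    teTens <- recordsToTensors(readRecords(recDir, "test"))
    testTensEnv$tens <- teTens
    preds <- predictTensors(model, teTens)
    preds$anchor_x <- teTens$anchor[, 1]
    preds$anchor_y <- teTens$anchor[, 2]
    write.csv(preds, file.path(d, "predictions.csv"), row.names = FALSE)
    metrics <- list(
      per_tile = metricsReport(preds, "per_tile", nBoot = config$nBoot,
                               seed = childSeed(config$seed, "ci_tile")),
      per_patient = metricsReport(preds, "per_patient", nBoot = config$nBoot,
                                  seed = childSeed(config$seed, "ci_pat")),
      wilcoxon_p = wilcoxonTiles(preds),
      fingerprint = fp)
    jsonlite::write_json(metrics, file.path(d, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  out$metrics <- jsonlite::read_json(file.path(evalDir, "metrics.json"))

  # --- visualize ---
  if (isTRUE(config$visualize)) {
    stage("visualize", "figures", function(d) {
      model <- loadCheckpoint(file.path(trainDir, "best.ckpt"))
      teTens <- testTensEnv$tens %||%
        recordsToTensors(readRecords(recDir, "test"))
      preds <- read.csv(file.path(evalDir, "predictions.csv"),
                        stringsAsFactors = FALSE)
      n <- length(teTens$labels)
      feats <- matrix(0, n, 0)
      bs <- 64L
      for (s in seq(1L, n, by = bs)) {
        idx <- s:min(s + bs - 1L, n)
        b <- batchFromTensors(teTens, idx, model@config@inputPx,
                              if (model@config@useClinical)
                                model@clinicalStats else NULL)
        fb <- t(forwardFeatures(model, b))
        if (ncol(feats) == 0) feats <- matrix(0, n, ncol(fb))
        feats[idx, ] <- fb
      }
      emb <- embedFeatures(feats, preds$score, ids = preds$tile_set_id,
                           sampleN = min(n, 1000L), initDims = 50L,
                           nIter = 300L,
                           seed = childSeed(config$seed, "tsne"))
      renderEmbedding(emb, file.path(d, "embedding.png"))
      sid <- preds$slide_id[1]
      slide <- openSlide(file.path(slideDir, paste0(sid, ".tiff")))
      hm <- assembleHeatmap(preds[preds$slide_id == sid, ], slide)
      writeHeatmap(hm, file.path(d, paste0(sid, "_heatmap")))
      renderOverlay(hm, slide, file.path(d, paste0(sid, "_overlay.png")))
    })
    out$figures <- file.path(root, "figures")
  }
  out
}
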