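# Label handling, per-patient splits, class weights, and the sharded
# record store that decouples tiling from training. Labels live in a plain
# data.frame with columns patient_id, slide_id, cohort, age, bmi plus one
# 0/1 column per task. Records are length-prefixed serialized tile sets in
# shards with an md5-checksummed JSON manifest; pixels are stored at 8-bit
# depth (the acquisition depth), so a write/read round trip is lossless.

#' Validate a label table
#'
#' Checks the schema (patient_id, slide_id, cohort, age, bmi, task
#' columns), uniqueness of (patient_id, slide_id), and that a task's label
#' is constant across the slides of one patient.
#'
#' @param labels data.frame
#' @param task optional task column to check specifically
#' @return the table, invisibly (errors describe the first violation)
#' @export
validateLabelTable <- function(labels, task = NULL) {
  need <- c("patient_id", "slide_id", "cohort")
  miss <- setdiff(need, names(labels))
  if (length(miss)) stop("label table lacks columns: ", paste(miss, collapse = ", "))
  key <- paste(labels$patient_id, labels$slide_id)
  if (anyDuplicated(key))
    stop("duplicate (patient_id, slide_id): ", key[duplicated(key)][1])
  tasks <- if (is.null(task)) taskColumns(labels) else task
  for (tk in tasks) {
    if (!tk %in% names(labels)) stop("no such task column: ", tk)
    v <- labels[[tk]]
    if (!all(v %in% c(0, 1, NA)))
      stop("task ", tk, " must be 0/1/NA")
    bad <- tapply(v, labels$patient_id, function(z) length(unique(z[!is.na(z)])) > 1)
    if (any(bad, na.rm = TRUE))
      stop("task ", tk, " differs across slides of patient ",
           names(bad)[which(bad)[1]])
  }
  invisible(labels)
}

#' @keywords internal
taskColumns <- function(labels) {
  setdiff(names(labels), c("patient_id", "slide_id", "cohort", "age", "bmi"))
}

#' Read / write a label table CSV
#' @param path CSV file with the documented header
#' @return data.frame
#' @export
readLabelTable <- function(path) {
  labels <- read.csv(path, stringsAsFactors = FALSE)
  validateLabelTable(labels)
  labels
}

#' @rdname readLabelTable
#' @param labels a valid label table
#' @export
writeLabelTable <- function(labels, path) {
  validateLabelTable(labels)
  write.csv(labels, path, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
patientLabels <- function(labels, task) {
  agg <- labels[!is.na(labels[[task]]), c("patient_id", "cohort", task)]
  agg <- agg[!duplicated(agg$patient_id), ]
  rownames(agg) <- NULL
  agg
}

# Allocate class-c patients to train/val/test with val and test getting
# round(n/10) each (floored at 1 when the class has >= 3 patients).
#' @keywords internal
allocCounts <- function(n, fracVal = 0.1, fracTest = 0.1) {
  nv <- round(n * fracVal); nt <- round(n * fracTest)
  if (n >= 3) { nv <- max(nv, 1L); nt <- max(nt, 1L) }
  while (n - nv - nt < 1L && (nv > 0L || nt > 0L)) {
    if (nv >= nt) nv <- nv - 1L else nt <- nt - 1L
  }
  c(train = n - nv - nt, validation = nv, test = nt)
}

#' Split patients into train/validation/test
#'
#' Mixed mode draws a per-patient 8:1:1 split stratified by the task label
#' (class proportions within one patient of exact stratification); cohort
#' independent mode holds out every patient of `heldOutCohort` as the test
#' set and splits the remaining cohort 9:1 into train and validation. The
#' draw is re-attempted (bounded retries) until every partition holds at
#' least one positively and one negatively labeled slide; a task that
#' cannot satisfy this (e.g. a single positive patient) raises an
#' infeasibility error. Deterministic given `seed`; all slides of a patient
#' share its partition by construction.
#'
#' @param labels label table (see [validateLabelTable])
#' @param task task column name
#' @param mode `"mixed"` or `"cohort_independent"`
#' @param seed integer split seed
#' @param heldOutCohort cohort id held out as test (cohort mode)
#' @param maxRetries bounded re-draws for the class-presence check
#' @return data.frame (patient_id, partition) with attributes `mode`,
#'   `seed`, `task`
#' @export
makeSplit <- function(labels, task, mode = c("mixed", "cohort_independent"),
                      seed = 1L, heldOutCohort = NULL, maxRetries = 50L) {
  mode <- match.arg(mode)
  validateLabelTable(labels, task)
  pl <- patientLabels(labels, task)
  if (length(unique(pl[[task]])) < 2L)
    stop("task ", task, " needs at least one positive and one negative patient")
  for (attempt in seq_len(maxRetries)) {
    asg <- withSeed(childSeed(seed, paste0("split", attempt)), {
      if (mode == "mixed") {
        parts <- character(nrow(pl))
        for (cl in c(0, 1)) {
          idx <- which(pl[[task]] == cl)
          idx <- idx[sample.int(length(idx))]
          cnt <- allocCounts(length(idx), 0.1, 0.1)
          parts[idx] <- rep(c("train", "validation", "test"), cnt)
        }
        parts
      } else {
        if (is.null(heldOutCohort))
          stop("cohort_independent mode needs heldOutCohort")
        parts <- character(nrow(pl))
        held <- pl$cohort == heldOutCohort
        if (!any(held)) stop("no patients in held-out cohort ", heldOutCohort)
        parts[held] <- "test"
        idx <- which(!held)
        idx <- idx[sample.int(length(idx))]
        nv <- max(1L, round(length(idx) * 0.1))
        parts[idx] <- rep(c("validation", "train"), c(nv, length(idx) - nv))
        parts
      }
    })
    sp <- data.frame(patient_id = pl$patient_id, partition = asg)
    ok <- TRUE
    merged <- merge(labels[!is.na(labels[[task]]),
                           c("patient_id", "slide_id", task)], sp,
                    by = "patient_id")
    for (p in c("train", "validation", "test")) {
      v <- merged[[task]][merged$partition == p]
      if (!(any(v == 1) && any(v == 0))) { ok <- FALSE; break }
    }
    if (ok) {
      stopifnot(length(intersect(sp$patient_id[sp$partition == "train"],
                                 sp$patient_id[sp$partition == "test"])) == 0)
      attr(sp, "mode") <- mode
      attr(sp, "seed") <- seed
      attr(sp, "task") <- task
      return(sp)
    }
  }
  stop("could not satisfy class presence in every partition for task ", task,
       " after ", maxRetries, " draws (too few patients per class?)")
}

#' Training-composition class weights
#'
#' `weight_c = N_train / (2 * N_train_c)` over training tile sets, so
#' weighted class frequencies are equal and a balanced composition gives
#' unit weights. Counts default to one per slide; pass per-slide tile-set
#' counts for the tile-level composition.
#'
#' @param labels label table
#' @param task task column
#' @param split output of [makeSplit]
#' @param tileCounts optional data.frame (slide_id, n) of tile-set counts
#' @return named numeric weights `c("0" = w0, "1" = w1)`
#' @export
computeClassWeights <- function(labels, task, split, tileCounts = NULL) {
  tr <- merge(labels[!is.na(labels[[task]]), ], split, by = "patient_id")
  tr <- tr[tr$partition == "train", ]
  n <- if (is.null(tileCounts)) rep(1, nrow(tr))
       else tileCounts$n[match(tr$slide_id, tileCounts$slide_id)]
  n[is.na(n)] <- 0
  n1 <- sum(n[tr[[task]] == 1]); n0 <- sum(n[tr[[task]] == 0])
  if (n0 <= 0 || n1 <= 0)
    stop("empty class in training partition for task ", task)
  N <- n0 + n1
  c("0" = N / (2 * n0), "1" = N / (2 * n1))
}

# ---- record store ----

#' @keywords internal
tileSetToRecord <- function(ts, label, age = NA_real_, bmi = NA_real_) {
  imgs <- lapply(ts@images, function(im) {
    d <- dim(im)
    list(dim = d, bytes = as.raw(as.integer(to255(im))))
  })
  list(tile_set_id = ts@tileSetId, slide_id = ts@slideId,
       patient_id = ts@patientId, anchor = ts@anchor,
       cell_index = ts@cellIndex, footprints = ts@footprints,
       images = imgs, label = label, age = age, bmi = bmi)
}

#' @keywords internal
recordToTileSet <- function(rec) {
  imgs <- lapply(rec$images, function(im)
    array(as.integer(im$bytes) / 255, im$dim))
  names(imgs) <- c("10x", "5x", "2.5x")
  new("TileSet", slideId = rec$slide_id, patientId = rec$patient_id,
      tileSetId = rec$tile_set_id, anchor = rec$anchor,
      cellIndex = rec$cell_index, images = imgs,
      footprints = rec$footprints)
}

#' Write tile sets into a sharded, checksummed record store
#'
#' One shard group per partition. Each record carries the tile set's pixels
#' (8-bit), identifiers, anchor geometry, label and clinical fields. The
#' manifest lists per-shard md5 checksums and record counts per class, the
#' configuration fingerprint, and patients excluded because the task label
#' was missing.
#'
#' @param tileSets list of [TileSet-class]
#' @param labels label table
#' @param task task column used for the stored label
#' @param split output of [makeSplit]
#' @param outDir output directory (created)
#' @param shardSize records per shard
#' @param fingerprint configuration fingerprint string stamped into the
#'   manifest
#' @return manifest (list), invisibly; written to `outDir/manifest.json`
#' @export
writeRecords <- function(tileSets, labels, task, split, outDir,
                         shardSize = 128L, fingerprint = "") {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  part <- setNames(split$partition, split$patient_id)
  lab <- patientLabels(labels, task)
  plab <- setNames(lab[[task]], lab$patient_id)
  clin <- labels[!duplicated(labels$patient_id), ]
  age <- setNames(if ("age" %in% names(clin)) clin$age else NA_real_, clin$patient_id)
  bmi <- setNames(if ("bmi" %in% names(clin)) clin$bmi else NA_real_, clin$patient_id)
  groups <- list(train = list(), validation = list(), test = list())
  excluded <- 0L
  for (ts in tileSets) {
    pid <- ts@patientId
    if (is.na(plab[pid]) || is.null(part[pid]) || is.na(part[pid])) {
      excluded <- excluded + 1L
      next
    }
    groups[[part[[pid]]]][[length(groups[[part[[pid]]]]) + 1L]] <-
      tileSetToRecord(ts, unname(plab[pid]), unname(age[pid]), unname(bmi[pid]))
  }
  manifest <- list(task = task, fingerprint = fingerprint,
                   excluded_tile_sets = excluded, partitions = list())
  for (p in names(groups)) {
    recs <- groups[[p]]
    shards <- list()
    if (length(recs)) {
      starts <- seq(1L, length(recs), by = shardSize)
      for (si in seq_along(starts)) {
        sl <- recs[starts[si]:min(starts[si] + shardSize - 1L, length(recs))]
        fn <- sprintf("%s-%03d.shard", p, si)
        writeShard(sl, file.path(outDir, fn))
        shards[[si]] <- list(file = fn, n = length(sl),
                             md5 = fileMd5(file.path(outDir, fn)))
      }
    }
    labs <- vapply(recs, `[[`, numeric(1), "label")
    manifest$partitions[[p]] <- list(
      shards = shards, n = length(recs),
      n_pos = sum(labs == 1), n_neg = sum(labs == 0))
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @keywords internal
writeShard <- function(records, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (r in records) {
    raw <- serialize(r, NULL, xdr = FALSE)
    writeBin(length(raw), con, size = 4L, endian = "little")
    writeBin(raw, con)
  }
  invisible(path)
}

#' @keywords internal
readShard <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  out <- list()
  repeat {
    len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!length(len)) break
    out[[length(out) + 1L]] <- unserialize(readBin(con, "raw", len))
  }
  out
}

#' Incremental record-store writer
#'
#' Closure-based writer used to stream tile sets into a store slide by
#' slide without holding a cohort in memory. `add(ts, label, age, bmi,
#' partition)` buffers one record; `finish(task, fingerprint, excluded)`
#' flushes buffers and writes the manifest (same layout as
#' [writeRecords]).
#'
#' @param outDir store directory (created)
#' @param shardSize records per shard
#' @return list of functions `add`, `finish`
#' @export
recordStoreWriter <- function(outDir, shardSize = 128L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  st$buf <- list(train = list(), validation = list(), test = list())
  st$shards <- list(train = list(), validation = list(), test = list())
  st$counts <- list(train = c(0L, 0L), validation = c(0L, 0L),
                    test = c(0L, 0L))  # (neg, pos)
  flush <- function(p) {
    if (!length(st$buf[[p]])) return(invisible())
    si <- length(st$shards[[p]]) + 1L
    fn <- sprintf("%s-%03d.shard", p, si)
    writeShard(st$buf[[p]], file.path(outDir, fn))
    st$shards[[p]][[si]] <- list(file = fn, n = length(st$buf[[p]]),
                                 md5 = fileMd5(file.path(outDir, fn)))
    st$buf[[p]] <- list()
  }
  add <- function(ts, label, age, bmi, partition) {
    rec <- tileSetToRecord(ts, label, age, bmi)
    st$buf[[partition]][[length(st$buf[[partition]]) + 1L]] <- rec
    st$counts[[partition]][label + 1L] <- st$counts[[partition]][label + 1L] + 1L
    if (length(st$buf[[partition]]) >= shardSize) flush(partition)
    invisible()
  }
  finish <- function(task = "", fingerprint = "", excluded = 0L) {
    manifest <- list(task = task, fingerprint = fingerprint,
                     excluded_tile_sets = excluded, partitions = list())
    for (p in names(st$buf)) {
      flush(p)
      cnt <- st$counts[[p]]
      manifest$partitions[[p]] <- list(shards = st$shards[[p]],
                                       n = sum(cnt), n_pos = cnt[2],
                                       n_neg = cnt[1])
    }
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
  }
  list(add = add, finish = finish)
}

#' Stream records of one partition back from a store
#'
#' Shard checksums are verified before reading; a mismatch halts naming the
#' shard. With `shuffleSeed`, record order is a seeded permutation —
#' reproducible across calls.
#'
#' @param dir record-store directory holding `manifest.json`
#' @param partition `"train"`, `"validation"` or `"test"`
#' @param shuffleSeed optional permutation seed
#' @param verify verify shard md5 checksums (default TRUE)
#' @return list of records (see [writeRecords])
#' @export
readRecords <- function(dir, partition, shuffleSeed = NULL, verify = TRUE) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  pm <- manifest$partitions[[partition]]
  if (is.null(pm)) stop("no partition ", partition, " in manifest")
  recs <- list()
  for (sh in pm$shards) {
    path <- file.path(dir, sh$file)
    if (verify && !identical(fileMd5(path), sh$md5))
      stop("shard checksum mismatch: ", sh$file)
    recs <- c(recs, readShard(path))
  }
  if (length(recs) != pm$n)
    stop("manifest count ", pm$n, " != streamed count ", length(recs),
         " for partition ", partition)
  if (!is.null(shuffleSeed) && length(recs) > 1L)
    recs <- withSeed(childSeed(shuffleSeed, paste0("shuffle_", partition)),
                     recs[sample.int(length(recs))])
  recs
}

#' Pack records into training tensors
#'
#' Pixels stay raw (8-bit) until batch assembly to keep memory flat; labels
#' are recoded to 1/2 for the engine.
#'
#' @param records list of records from [readRecords]
#' @return list with `pix` (per-magnification raw matrices), `dims`,
#'   `labels` (1 = negative, 2 = positive), `age`, `bmi`, `patient_id`,
#'   `slide_id`, `tile_set_id`, `anchor`, `cell_index`
#' @export
recordsToTensors <- function(records) {
  stopifnot(length(records) > 0L)
  mags <- c("10x", "5x", "2.5x")
  dims <- lapply(records[[1]]$images, `[[`, "dim")
  pix <- lapply(seq_along(mags), function(m) {
    nb <- prod(dims[[m]])
    mat <- vapply(records, function(r) r$images[[m]]$bytes, raw(nb))
    matrix(mat, nb, length(records))
  })
  names(pix) <- mags
  list(pix = pix, dims = dims,
       labels = vapply(records, function(r) as.integer(r$label) + 1L, integer(1)),
       age = vapply(records, function(r) as.numeric(r$age), numeric(1)),
       bmi = vapply(records, function(r) as.numeric(r$bmi), numeric(1)),
       patient_id = vapply(records, `[[`, character(1), "patient_id"),
       slide_id = vapply(records, `[[`, character(1), "slide_id"),
       tile_set_id = vapply(records, `[[`, character(1), "tile_set_id"),
       anchor = t(vapply(records, `[[`, numeric(2), "anchor")),
       cell_index = t(vapply(records, `[[`, integer(2), "cell_index")))
}

#' Assemble a model batch from tensors
#'
#' Decodes the selected records to `[p, p, 3, n]` numeric arrays (bilinear
#' reduction to `inputPx` when the stored size differs) and standardizes
#' clinical inputs when `clinStats` is given.
#'
#' @param tens output of [recordsToTensors]
#' @param idx record indices
#' @param inputPx model input side length
#' @param clinStats clinical standardization constants (or NULL)
#' @return list (`x`, `clin`, `labels`) consumable by [modelForward]
#' @export
batchFromTensors <- function(tens, idx, inputPx = NULL, clinStats = NULL) {
  x <- lapply(names(tens$pix), function(m) {
    d <- tens$dims[[m]]
    arr <- array(as.integer(tens$pix[[m]][, idx, drop = FALSE]) / 255,
                 c(d, length(idx)))
    if (!is.null(inputPx) && inputPx != d[1]) {
      out <- array(0, c(inputPx, inputPx, 3, length(idx)))
      for (i in seq_along(idx))
        out[, , , i] <- resizeBox(arr[, , , i], inputPx)
      out
    } else arr
  })
  names(x) <- names(tens$pix)
  clin <- if (!is.null(clinStats))
    standardizeClinical(clinStats, tens$age[idx], tens$bmi[idx]) else NULL
  list(x = x, clin = clin, labels = tens$labels[idx])
}
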