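# Indirect POLE classification: the POLE subtype carries no strong direct
# image signal, so its score is composed from the *negative* prediction
# scores of the other molecular subtype models (CNV-H, CNV-L, MSI-high):
# a patient predicted negative by all member models is scored as likely
# POLE.

#' Compose a POLE score from member-model scores
#'
#' `pole = agg_m (1 - score_m)` over member tasks, with `agg` the
#' arithmetic mean (default) or product. Monotone decreasing in every
#' member score; all members 0 gives 1, all members 1 gives 0.
#'
#' @param memberScores data.frame with a `patient_id` (or `tile_set_id`)
#'   column and one numeric score column per member model, or a plain
#'   numeric matrix/data.frame of member columns
#' @param aggregation `"mean"` or `"product"`
#' @return numeric POLE scores in [0,1], aligned with the rows
#' @export
poleScore <- function(memberScores, aggregation = c("mean", "product")) {
  aggregation <- match.arg(aggregation)
  m <- memberScores[, !(names(memberScores) %in%
                          c("patient_id", "slide_id", "tile_set_id", "true_label")),
                    drop = FALSE]
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("need at least 2 member models")
  if (any(is.na(m))) stop("missing member scores; drop incomplete rows first")
  if (any(m < 0 | m > 1)) stop("member scores must be in [0,1]")
  comp <- 1 - m
  if (aggregation == "mean") rowMeans(comp) else apply(comp, 1, prod)
}

#' Compose POLE prediction tables from member prediction tables
#'
#' Joins the member tables by patient (or by tile set when all members
#' share a tiling, `level = "per_tile"`), applies [poleScore], and returns
#' a prediction table evaluable with the standard metrics. Patients (or
#' tile sets) missing from any member are dropped with a warning.
#'
#' @param memberPreds named list of prediction tables, one per member task
#' @param poleLabels data.frame (patient_id, true_label) with the POLE
#'   ground truth
#' @param aggregation `"mean"` or `"product"`
#' @param level compose at `"per_patient"` (member scores averaged per
#'   patient first) or `"per_tile"` (joined by tile_set_id)
#' @return a prediction table (tile_set_id is synthetic at patient level)
#' @export
composePole <- function(memberPreds, poleLabels,
                        aggregation = c("mean", "product"),
                        level = c("per_patient", "per_tile")) {
  aggregation <- match.arg(aggregation)
  level <- match.arg(level)
  stopifnot(length(memberPreds) >= 2L)
  key <- if (level == "per_patient") "patient_id" else "tile_set_id"
  tabs <- lapply(seq_along(memberPreds), function(i) {
    nm <- names(memberPreds)[i]
    p <- memberPreds[[i]]
    t0 <- if (level == "per_patient") patientScores(p)
          else p[, c("tile_set_id", "patient_id", "score")]
    out <- t0[, c(key, "score")]
    names(out)[2] <- nm
    # patient ids travel with the first member only; members are joined on
    # the shared tiling's tile_set_id
    if (level == "per_tile" && i == 1L) out$patient_id <- t0$patient_id
    out
  })
  joined <- Reduce(function(a, b) merge(a, b, by = key), tabs)
  nAll <- max(vapply(tabs, nrow, integer(1)))
  if (nrow(joined) < nAll)
    warning(nAll - nrow(joined), " rows dropped: missing member scores")
  sc <- poleScore(joined[, names(memberPreds), drop = FALSE], aggregation)
  pid <- joined$patient_id %||% joined[[key]]
  data.frame(patient_id = pid,
             slide_id = pid,
             tile_set_id = if (level == "per_tile") joined$tile_set_id
                           else paste0(joined[[key]], "_pole"),
             score = sc,
             true_label = poleLabels$true_label[
               match(pid, poleLabels$patient_id)])
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
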