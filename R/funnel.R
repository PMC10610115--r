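#' @include AllClasses.R
NULL

#' Construct a funnel stage
#'
#' @param name Stage label (e.g. "HTVS", "SP", "XP").
#' @param scoreColumn Score column the stage filters on.
#' @param threshold Retention threshold (kcal/mol); rows with score at or
#'   below the threshold survive (more negative = better). The comparison
#'   is inclusive for every stage.
#' @param maxRetained Optional cap: keep at most this many best-scoring
#'   rows, ties broken by id.
#' @param posesPerLigand Metadata: poses generated per ligand upstream.
#' @return A \linkS4class{FunnelStage}.
#' @export
funnelStage <- function(name, scoreColumn, threshold,
                        maxRetained = NA_integer_, posesPerLigand = 1L) {
  methods::new("FunnelStage", name = name, scoreColumn = scoreColumn,
               threshold = threshold, maxRetained = as.integer(maxRetained),
               posesPerLigand = as.integer(posesPerLigand))
}

.checkScoreTable <- function(t) {
  if (!"id" %in% names(t)) stop("score table must have an 'id' column")
  if (anyDuplicated(t$id)) stop("duplicate ids in score table")
  invisible(t)
}

#' Collapse multiple poses per ligand to the best score
#'
#' When a ligand has several poses (duplicate ids), the most negative
#' value per numeric score column is kept, giving one row per ligand.
#'
#' @param t data.frame with an `id` column and numeric score columns.
#' @return data.frame with unique ids.
#' @export
collapseBestPose <- function(t) {
  if (!anyDuplicated(t$id)) return(t)
  num <- names(t)[vapply(t, is.numeric, logical(1))]
  agg <- stats::aggregate(t[num], by = list(id = t$id),
                          FUN = function(v) if (all(is.na(v))) NA_real_
                                            else min(v, na.rm = TRUE))
  agg[match(unique(t$id), agg$id), , drop = FALSE]
}

#' Apply one funnel stage to a score table
#'
#' Rows with score <= threshold are retained (inclusive comparison); rows
#' with a missing score are dropped and counted. With `maxRetained` set,
#' the best (most negative) scores survive, ties broken by id.
#'
#' @param t data.frame keyed by `id` with numeric score columns.
#' @param s A \linkS4class{FunnelStage}.
#' @return Filtered data.frame with attributes `inputCount`, `outputCount`
#'   and `missingDropped`.
#' @export
applyStage <- function(t, s) {
  stopifnot(is(s, "FunnelStage"))
  .checkScoreTable(t)
  if (!s@scoreColumn %in% names(t))
    stop("unknown score column: ", s@scoreColumn)
  nIn <- nrow(t)
  sc <- t[[s@scoreColumn]]
  missing <- is.na(sc)
  keep <- !missing & sc <= s@threshold
  out <- t[keep, , drop = FALSE]
  if (!is.na(s@maxRetained) && nrow(out) > s@maxRetained) {
    ord <- order(out[[s@scoreColumn]], out$id)
    out <- out[ord[seq_len(s@maxRetained)], , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "inputCount") <- nIn
  attr(out, "outputCount") <- nrow(out)
  attr(out, "missingDropped") <- sum(missing)
  out
}

#' Run a staged screening funnel
#'
#' Applies the stages in order, recording input/output counts and
#' surviving ids per stage. Survivor counts are non-increasing by
#' construction.
#'
#' @param t data.frame keyed by `id`.
#' @param stages List of \linkS4class{FunnelStage}.
#' @param collapsePoses Collapse duplicate-id pose rows to the best score
#'   per column before filtering (default TRUE).
#' @return A \linkS4class{FunnelReport}.
#' @export
runFunnel <- function(t, stages, collapsePoses = TRUE) {
  if (!length(stages)) stop("need at least one stage")
  if (collapsePoses && anyDuplicated(t$id)) t <- collapseBestPose(t)
  .checkScoreTable(t)
  counts <- list(); survivors <- list()
  cur <- t
  for (s in stages) {
    cur <- applyStage(cur, s)
    counts[[s@name]] <- data.frame(
      stage = s@name, input = attr(cur, "inputCount"),
      output = attr(cur, "outputCount"),
      missingDropped = attr(cur, "missingDropped"))
    survivors[[s@name]] <- cur$id
  }
  methods::new("FunnelReport",
               counts = do.call(rbind, c(counts, list(make.row.names = FALSE))),
               survivors = survivors, finalTable = cur,
               provenance = lapply(stages, function(s) list(
                 name = s@name, column = s@scoreColumn,
                 threshold = s@threshold, maxRetained = s@maxRetained,
                 posesPerLigand = s@posesPerLigand)))
}

#' Assemble a consensus score table from per-method tables
#'
#' Joins id-keyed tables (inner join by default; outer join keeps rows
#' with missing values flagged as NA). Column order follows the order of
#' the supplied tables.
#'
#' @param tables Named list of data.frames, each keyed by `id`.
#' @param joinOn Key column, default "id".
#' @param outer Use an outer join (default FALSE = inner).
#' @return Consensus data.frame.
#' @export
assembleConsensus <- function(tables, joinOn = "id", outer = FALSE) {
  stopifnot(length(tables) >= 1)
  for (t in tables) {
    if (!joinOn %in% names(t)) stop("every table needs a '", joinOn, "' column")
    if (anyDuplicated(t[[joinOn]])) stop("duplicate ids within a source table")
  }
  out <- tables[[1]]
  for (t in tables[-1])
    out <- merge(out, t, by = joinOn, all = outer, sort = FALSE)
  out[order(match(out[[joinOn]], tables[[1]][[joinOn]])), , drop = FALSE]
}

#' Rank candidates by a weighted composite of z-scored columns
#'
#' A transparent, reproducible surrogate for expert hit triage: each
#' weighted column is z-scored (population SD), oriented so that larger
#' composite = better, and combined as a weighted sum. Default
#' orientation: docking/MM-GBSA/external scores are better when more
#' negative (orientation -1), predicted pIC50 when larger (+1).
#'
#' @param t Consensus data.frame keyed by `id`.
#' @param weights Named numeric vector of column weights; default equal
#'   weights on score_xp, mmgbsa_dg, external_score, pic50_pred.
#' @param orientation Named vector of +1/-1 per weighted column; columns
#'   not named default to -1 (score-like) except pIC50-like columns.
#' @return data.frame (id, composite, rank) ordered best-first;
#'   deterministic with ties broken by id.
#' @export
rankCandidates <- function(t, weights = NULL, orientation = NULL) {
  .checkScoreTable(t)
  if (is.null(weights)) {
    cand <- intersect(c("score_xp", "mmgbsa_dg", "external_score",
                        "pic50_pred"), names(t))
    if (!length(cand)) stop("no rankable columns found")
    weights <- stats::setNames(rep(1, length(cand)), cand)
  }
  missingCols <- setdiff(names(weights), names(t))
  if (length(missingCols)) stop("missing columns: ",
                                paste(missingCols, collapse = ", "))
  composite <- numeric(nrow(t))
  for (cn in names(weights)) {
    v <- t[[cn]]
    if (all(is.na(v))) stop("column all-missing: ", cn)
    orient <- if (!is.null(orientation) && cn %in% names(orientation))
      orientation[[cn]] else if (grepl("pic50|pIC50", cn)) 1 else -1
    mu <- mean(v, na.rm = TRUE)
    sd0 <- sqrt(mean((v - mu)^2, na.rm = TRUE))
    if (sd0 < .Machine$double.eps^0.5) sd0 <- 1
    z <- (v - mu) / sd0
    z[is.na(z)] <- 0
    composite <- composite + weights[[cn]] * orient * z
  }
  out <- data.frame(id = t$id, composite = composite)
  out <- out[order(-out$composite, out$id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write a funnel report as JSON
#' @param report A \linkS4class{FunnelReport}.
#' @param path Output file.
#' @export
writeFunnelReport <- function(report, path) {
  stopifnot(is(report, "FunnelReport"))
  jsonlite::write_json(list(counts = report@counts,
                            survivors = report@survivors,
                            provenance = report@provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
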