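#' @include gat.R mol-graph.R
NULL

#' Seeded 8:1:1 train/validation/test split
#'
#' Ids are shuffled with the given seed; validation and test sizes are
#' floor(n * ratio_i / sum(ratio)) each and the remainder goes to train
#' (so n = 1072 gives 858/107/107 at the default 8:1:1 ratio).
#'
#' @param ids Character vector of unique ids (>= 10).
#' @param ratio Numeric length-3 ratio, default c(8, 1, 1).
#' @param seed Integer seed; identical seeds give identical assignments.
#' @return A \linkS4class{SplitAssignment}.
#' @export
splitDataset <- function(ids, ratio = c(8, 1, 1), seed = 1L) {
  ids <- as.character(ids)
  n <- length(ids)
  if (n < 10) stop("need at least 10 ids to split")
  if (anyDuplicated(ids)) stop("ids must be unique")
  frac <- ratio / sum(ratio)
  nVal <- floor(n * frac[2]); nTest <- floor(n * frac[3])
  hadSeed <- exists(".Random.seed", envir = globalenv())
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  shuffled <- sample(ids, n)
  if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
  methods::new("SplitAssignment",
               trainIds = shuffled[seq_len(n - nVal - nTest)],
               valIds = shuffled[seq(n - nVal - nTest + 1, n - nTest)],
               testIds = shuffled[seq(n - nTest + 1, n)])
}

#' Coefficient of determination
#'
#' R-squared = 1 - SS_res / SS_tot. Requires positive label variance.
#'
#' @param y Observed values.
#' @param yhat Predicted values (same length, >= 2).
#' @return Numeric scalar (<= 1; can be negative for bad fits).
#' @examples
#' rSquared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
rSquared <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2)
    stop("y and yhat must have equal length >= 2")
  ssTot <- sum((y - mean(y))^2)
  if (ssTot <= 0) stop("zero variance in y: R-squared undefined")
  1 - sum((y - yhat)^2) / ssTot
}

# Inject global scalars into graphs given a scalar table (id-keyed).
.injectAll <- function(graphs, scalarTab, scaler) {
  idCol <- scalarTab$id
  cols <- names(scaler@center)
  lapply(graphs, function(g) {
    row <- match(g@molId, idCol)
    if (is.na(row)) stop("no scalar row for molecule ", g@molId)
    sc <- unlist(scalarTab[row, cols])
    injectGlobalFeatures(g, sc, scaler)
  })
}

#' Train the GAT + MLP pIC50 regressor
#'
#' Splits the molecules 8:1:1 with the training seed, optionally fits the
#' global-scalar z-scaler on the training split only and injects the
#' scaled scalars into every node, then minimizes mean-squared error with
#' Adam. Early stopping monitors validation MSE; the best-epoch weights
#' are restored before the final per-split R-squared report. All RNG
#' streams (split, initialization, batch order, dropout) derive from the
#' training seed, so identical calls give identical reports on CPU.
#'
#' @param graphs List of \linkS4class{MolGraph}.
#' @param labels Named numeric vector of pIC50 labels (names = mol ids) or
#'   unnamed vector in graph order.
#' @param mcfg A \linkS4class{ModelConfig}.
#' @param tcfg A \linkS4class{TrainConfig}. `earlyStopPatience = 0` disables
#'   early stopping.
#' @param scalars Optional data.frame of global scalars (column `id` plus
#'   numeric columns, canonically external_score, tpsa, mw, rot_bonds).
#'   When supplied, scaling and injection happen inside the training
#'   routine so no test-split information leaks into the scaler.
#' @param verbose Print progress every 20 epochs.
#' @return List with elements `model` (\linkS4class{GNNModel}) and
#'   `report` (\linkS4class{FitReport}).
#' @export
trainModel <- function(graphs, labels, mcfg = methods::new("ModelConfig"),
                       tcfg = methods::new("TrainConfig"), scalars = NULL,
                       verbose = FALSE) {
  stopifnot(length(graphs) >= 10)
  ids <- vapply(graphs, function(g) g@molId, character(1))
  if (!is.null(names(labels))) labels <- labels[ids]
  if (anyNA(labels) || !all(is.finite(labels)))
    stop("labels must be finite for every graph")
  names(labels) <- ids

  split <- splitDataset(ids, tcfg@splitRatio, tcfg@seed)
  if (stats::var(labels[split@trainIds]) <= 0)
    stop("zero label variance in training split: R-squared undefined")

  scaler <- NULL; scalarNames <- character(0)
  if (!is.null(scalars)) {
    cols <- setdiff(names(scalars), "id")
    trainRows <- scalars[match(split@trainIds, scalars$id), cols, drop = FALSE]
    scaler <- fitScaler(trainRows)
    scalarNames <- names(scaler@center)
    graphs <- .injectAll(graphs, scalars, scaler)
  }

  set.seed(tcfg@seed + 1L)
  inputDim <- ncol(graphs[[1]]@nodeFeatures)
  w <- .initWeights(mcfg, inputDim)
  adam <- .adamInit(w)

  pack <- .packGraphs(graphs)
  gTrain <- which(ids %in% split@trainIds)
  packVal <- .packSubset(pack, which(ids %in% split@valIds))
  yVal <- labels[packVal$ids]

  bestVal <- Inf; bestW <- w; bestEpoch <- 0L; sinceBest <- 0L
  lossCurve <- numeric(tcfg@epochs)
  useDrop <- mcfg@dropout > 0
  for (epoch in seq_len(tcfg@epochs)) {
    ord <- sample(gTrain)
    batches <- split(ord, ceiling(seq_along(ord) / tcfg@batchSize))
    epochLoss <- 0; nSeen <- 0
    for (b in batches) {
      pb <- .packSubset(pack, b)
      dropMask <- NULL
      if (useDrop) {
        dropMask <- lapply(seq_len(mcfg@nGatLayers), function(l) {
          keep <- matrix(stats::rbinom(sum(pb$nNodes) * mcfg@hiddenDim, 1,
                                       1 - mcfg@dropout),
                         sum(pb$nNodes), mcfg@hiddenDim)
          keep / (1 - mcfg@dropout)
        })
      }
      fw <- .gnnForward(w, pb, mcfg, keepCache = TRUE, dropMask = dropMask)
      yb <- labels[pb$ids]
      grads <- .gnnBackward(w, pb, mcfg, fw, yb, dropMask = dropMask)
      upd <- .adamStep(w, grads, adam, tcfg@learningRate)
      w <- upd$w; adam <- upd$state
      epochLoss <- epochLoss + sum((fw$yhat - yb)^2); nSeen <- nSeen + length(b)
    }
    lossCurve[epoch] <- epochLoss / nSeen
    valPred <- .gnnForward(w, packVal, mcfg)$yhat
    valMse <- mean((valPred - yVal)^2)
    if (valMse < bestVal - 1e-9) {
      bestVal <- valMse; bestW <- w; bestEpoch <- epoch; sinceBest <- 0L
    } else sinceBest <- sinceBest + 1L
    if (verbose && epoch %% 20 == 0)
      message(sprintf("epoch %d train MSE %.4f val MSE %.4f", epoch,
                      lossCurve[epoch], valMse))
    if (tcfg@earlyStopPatience > 0L && sinceBest >= tcfg@earlyStopPatience)
      break
  }
  if (tcfg@earlyStopPatience == 0L) { bestW <- w; bestEpoch <- epoch }
  lossCurve <- lossCurve[seq_len(epoch)]

  model <- methods::new("GNNModel", weights = bestW, config = mcfg,
                        scaler = scaler, scalarNames = scalarNames,
                        inputDim = as.integer(inputDim), split = split)
  # R-squared is undefined for degenerate splits (< 2 ids or zero label
  # variance); report NA there rather than failing the whole run
  r2For <- function(whichIds) {
    ps <- .packSubset(pack, which(ids %in% whichIds))
    tryCatch(rSquared(labels[ps$ids], .gnnForward(bestW, ps, mcfg)$yhat),
             error = function(e) NA_real_)
  }
  report <- methods::new("FitReport",
                         r2Train = r2For(split@trainIds),
                         r2Val = r2For(split@valIds),
                         r2Test = r2For(split@testIds),
                         lossCurve = lossCurve, bestEpoch = bestEpoch)
  list(model = model, report = report)
}

#' Predict pIC50 for a set of molecule graphs
#'
#' Deterministic given the model; one finite value per graph. When the
#' model was trained with injected global scalars, the same scalar table
#' must be supplied and is transformed with the scaler stored in the
#' model (fitted on its training split).
#'
#' @param model A \linkS4class{GNNModel}.
#' @param graphs List of \linkS4class{MolGraph}.
#' @param scalars Optional scalar data.frame (see [trainModel()]).
#' @return Numeric vector of predictions, named by molecule id.
#' @export
predictActivity <- function(model, graphs, scalars = NULL) {
  stopifnot(is(model, "GNNModel"))
  if (!length(graphs)) return(numeric(0))
  if (!is.null(model@scaler)) {
    if (is.null(scalars))
      stop("model expects global scalars: supply `scalars`")
    graphs <- .injectAll(graphs, scalars, model@scaler)
  }
  dims <- vapply(graphs, function(g) ncol(g@nodeFeatures), integer(1))
  if (any(dims != model@inputDim))
    stop("feature dimension mismatch: model expects ", model@inputDim)
  pack <- .packGraphs(graphs)
  out <- .gnnForward(model@weights, pack, model@config)$yhat
  stats::setNames(out, pack$ids)
}

#' Seeded random hyperparameter search
#'
#' Samples `budget` configurations from the supplied space (a named list
#' of candidate vectors over ModelConfig fields and optionally
#' `learningRate`), trains each with the given data and training config,
#' and returns the configuration with the best validation R-squared plus
#' the full trial log. Identical seeds give identical trial sequences.
#'
#' @param space Named list, e.g. list(nGatLayers = 1:3, hiddenDim = c(32, 64)).
#' @param budget Number of trials (>= 1).
#' @param seed Integer seed.
#' @param graphs,labels,scalars,tcfg Data and training settings passed to
#'   [trainModel()].
#' @return List with `best` (ModelConfig), `bestLearningRate`, and
#'   `trials` (data.frame log).
#' @export
hyperparameterSearch <- function(space, budget, seed, graphs, labels,
                                 scalars = NULL,
                                 tcfg = methods::new("TrainConfig")) {
  if (budget < 1) stop("budget must be >= 1")
  if (!length(space)) stop("empty search space")
  set.seed(seed)
  draws <- lapply(seq_len(budget), function(i)
    lapply(space, function(v) v[[sample.int(length(v), 1)]]))
  trials <- vector("list", budget)
  best <- NULL; bestLr <- tcfg@learningRate; bestVal <- -Inf
  for (i in seq_len(budget)) {
    d <- draws[[i]]
    mcfg <- methods::new("ModelConfig")
    for (nm in intersect(names(d), methods::slotNames("ModelConfig")))
      methods::slot(mcfg, nm) <- switch(nm,
        dropout = as.numeric(d[[nm]]), readout = as.character(d[[nm]]),
        as.integer(d[[nm]]))
    methods::validObject(mcfg)
    tcfgI <- tcfg
    if (!is.null(d$learningRate)) tcfgI@learningRate <- as.numeric(d$learningRate)
    fit <- trainModel(graphs, labels, mcfg, tcfgI, scalars = scalars)
    trials[[i]] <- data.frame(trial = i,
                              as.data.frame(d, stringsAsFactors = FALSE),
                              r2Val = fit$report@r2Val)
    if (fit$report@r2Val > bestVal) {
      bestVal <- fit$report@r2Val; best <- mcfg; bestLr <- tcfgI@learningRate
    }
  }
  list(best = best, bestLearningRate = bestLr, bestR2Val = bestVal,
       trials = do.call(rbind, trials))
}

#' Save / load a trained model
#'
#' The model artifact is a directory holding `config.json` (architecture,
#' scalar names, scaler parameters, split manifest) and `weights.rds`.
#' Loading a saved model predicts identically to the original.
#'
#' @param model A \linkS4class{GNNModel}.
#' @param dir Artifact directory (created if needed).
#' @return `saveModel` invisibly returns `dir`; `loadModel` returns the
#'   \linkS4class{GNNModel}.
#' @export
saveModel <- function(model, dir) {
  stopifnot(is(model, "GNNModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(
    format_version = 1L,
    nGatLayers = model@config@nGatLayers,
    attentionHeads = model@config@attentionHeads,
    hiddenDim = model@config@hiddenDim,
    mlpDims = model@config@mlpDims,
    dropout = model@config@dropout,
    readout = model@config@readout,
    inputDim = model@inputDim,
    scalarNames = model@scalarNames,
    scalerCenter = if (!is.null(model@scaler)) as.list(model@scaler@center),
    scalerScale = if (!is.null(model@scaler)) as.list(model@scaler@scale),
    split = if (!is.null(model@split)) list(
      train = model@split@trainIds, val = model@split@valIds,
      test = model@split@testIds))
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(model@weights, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  cfgPath <- file.path(dir, "config.json")
  wPath <- file.path(dir, "weights.rds")
  if (!file.exists(cfgPath) || !file.exists(wPath))
    stop("not a model directory: ", dir)
  cfg <- tryCatch(jsonlite::read_json(cfgPath, simplifyVector = TRUE),
                  error = function(e) stop("corrupt model config: ",
                                           conditionMessage(e)))
  if (is.null(cfg$format_version) || cfg$format_version != 1L)
    stop("unsupported model format version")
  weights <- tryCatch(readRDS(wPath),
                      error = function(e) stop("corrupt model weights: ",
                                               conditionMessage(e)))
  mcfg <- methods::new("ModelConfig",
                       nGatLayers = as.integer(cfg$nGatLayers),
                       attentionHeads = as.integer(cfg$attentionHeads),
                       hiddenDim = as.integer(cfg$hiddenDim),
                       mlpDims = as.integer(cfg$mlpDims),
                       dropout = as.numeric(cfg$dropout),
                       readout = cfg$readout)
  scaler <- NULL
  if (length(cfg$scalerCenter))
    scaler <- methods::new("FeatureScaler",
                           center = unlist(cfg$scalerCenter),
                           scale = unlist(cfg$scalerScale))
  split <- NULL
  if (length(cfg$split))
    split <- methods::new("SplitAssignment",
                          trainIds = as.character(cfg$split$train),
                          valIds = as.character(cfg$split$val),
                          testIds = as.character(cfg$split$test))
  methods::new("GNNModel", weights = weights, config = mcfg, scaler = scaler,
               scalarNames = as.character(cfg$scalarNames %||% character(0)),
               inputDim = as.integer(cfg$inputDim), split = split)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
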