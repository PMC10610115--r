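#' @import methods
NULL

#' MoleculeRecord: a single small molecule
#'
#' Holds one molecule as an explicit heavy-atom connection table together
#' with its canonical SMILES serialization, an optional 3D conformer and a
#' free-form property map. Atom-level perception (aromaticity, ring
#' membership, implicit hydrogen counts) is computed at parse time and
#' stored in the `atoms` table so descriptor and graph code never re-derive
#' it.
#'
#' @slot id Character scalar, unique within a library.
#' @slot smiles Canonical SMILES serialization of the heavy-atom structure.
#' @slot atoms data.frame with one row per heavy atom: `element`, `charge`,
#'   `aromatic`, `inRing`, `in3Ring`, `nH` (implicit hydrogen count),
#'   `degree` (heavy-atom degree).
#' @slot bonds data.frame with one row per bond: `a1`, `a2` (atom indices),
#'   `order` (1/2/3, kekulized), `inRing`, `aromatic`.
#' @slot conformer Numeric matrix (n_atoms x 3, Angstrom) or NULL.
#' @slot props Named list of numeric properties.
#' @export
setClass("MoleculeRecord",
  representation(id = "character", smiles = "character",
                 atoms = "data.frame", bonds = "data.frame",
                 conformer = "ANY", props = "list"),
  prototype(conformer = NULL, props = list()))

setValidity("MoleculeRecord", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a non-empty character scalar")
  if (nrow(object@atoms) < 1L)
    msg <- c(msg, "structure must have at least one heavy atom")
  if (nrow(object@bonds) > 0 &&
      (max(object@bonds$a1, object@bonds$a2) > nrow(object@atoms)))
    msg <- c(msg, "bond indices out of range")
  if (!is.null(object@conformer) &&
      (!is.matrix(object@conformer) ||
       nrow(object@conformer) != nrow(object@atoms)))
    msg <- c(msg, "conformer must be an n_atoms x 3 matrix")
  if (length(msg)) msg else TRUE
})

#' MoleculeLibrary: an ordered collection of MoleculeRecord objects
#'
#' @slot records List of \linkS4class{MoleculeRecord}; ids must be unique.
#' @slot skipped Character vector of input entries that failed to parse.
#' @export
setClass("MoleculeLibrary",
  representation(records = "list", skipped = "character"),
  prototype(records = list(), skipped = character(0)))

setValidity("MoleculeLibrary", function(object) {
  ok <- vapply(object@records, is, logical(1), class2 = "MoleculeRecord")
  if (!all(ok)) return("all records must be MoleculeRecord objects")
  ids <- vapply(object@records, function(r) r@id, character(1))
  if (anyDuplicated(ids)) return("molecule ids must be unique")
  TRUE
})

#' DescriptorSet: physicochemical descriptors for one molecule
#'
#' Field conventions (documented in detail in `computeDescriptors`):
#' average-mass molecular weight, heavy-atom count, hydrogen-bond donor and
#' acceptor counts, rotatable-bond count (amide C-N excluded) and Ertl
#' fragment-contribution TPSA including sulfur/phosphorus terms.
#'
#' @export
setClass("DescriptorSet",
  representation(mw = "numeric", heavyAtoms = "integer", hbd = "integer",
                 hba = "integer", rotBonds = "integer", tpsa = "numeric",
                 logp = "numeric"),
  prototype(logp = NA_real_))

setValidity("DescriptorSet", function(object) {
  msg <- character(0)
  if (object@mw <= 0) msg <- c(msg, "mw must be positive")
  if (object@tpsa < 0) msg <- c(msg, "tpsa must be non-negative")
  if (any(c(object@heavyAtoms, object@hbd, object@hba, object@rotBonds) < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' MolGraph: attributed heavy-atom graph of a molecule
#'
#' @slot nodeFeatures Numeric matrix, n_atoms x d.
#' @slot edges Integer matrix, n_bonds x 2, undirected heavy-atom bond pairs.
#' @slot edgeFeatures Numeric matrix, n_bonds x e (bond-order one-hot,
#'   conjugation flag, ring flag).
#' @slot molId Character scalar.
#' @slot featureNames Character vector naming node-feature columns.
#' @export
setClass("MolGraph",
  representation(nodeFeatures = "matrix", edges = "matrix",
                 edgeFeatures = "matrix", molId = "character",
                 featureNames = "character"))

setValidity("MolGraph", function(object) {
  msg <- character(0)
  if (!all(is.finite(object@nodeFeatures)))
    msg <- c(msg, "node features must be finite")
  if (nrow(object@edges) > 0 && max(object@edges) > nrow(object@nodeFeatures))
    msg <- c(msg, "edge indices out of range")
  if (nrow(object@edges) != nrow(object@edgeFeatures))
    msg <- c(msg, "edges and edgeFeatures must have equal row counts")
  if (length(msg)) msg else TRUE
})

#' FeatureScaler: z-score parameters for global scalar features
#'
#' Fitted on the training split only; columns with zero variance get a
#' standard deviation of 1 so their transformed values are exactly 0.
#'
#' @slot center Named numeric vector of per-column means.
#' @slot scale Named numeric vector of per-column population standard
#'   deviations (degenerate columns coerced to 1).
#' @export
setClass("FeatureScaler",
  representation(center = "numeric", scale = "numeric"))

setValidity("FeatureScaler", function(object) {
  if (!identical(names(object@center), names(object@scale)))
    return("center and scale must share names")
  if (any(object@scale <= 0)) return("scale entries must be positive")
  TRUE
})

#' ModelConfig: architecture of the GAT + MLP regressor
#'
#' `hiddenDim` is the total per-layer width; it is split evenly across
#' attention heads (so it must be divisible by `attentionHeads`).
#'
#' @export
setClass("ModelConfig",
  representation(nGatLayers = "integer", attentionHeads = "integer",
                 hiddenDim = "integer", mlpDims = "integer",
                 dropout = "numeric", readout = "character"),
  prototype(nGatLayers = 3L, attentionHeads = 4L, hiddenDim = 64L,
            mlpDims = c(64L, 32L), dropout = 0, readout = "mean"))

setValidity("ModelConfig", function(object) {
  msg <- character(0)
  if (object@nGatLayers < 1L) msg <- c(msg, "need >= 1 GAT layer")
  if (object@attentionHeads < 1L) msg <- c(msg, "need >= 1 attention head")
  if (object@hiddenDim < 1L || any(object@mlpDims < 1L))
    msg <- c(msg, "all dims must be positive")
  if (object@hiddenDim %% object@attentionHeads != 0L)
    msg <- c(msg, "hiddenDim must be divisible by attentionHeads")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0,1)")
  if (!object@readout %in% c("mean", "sum", "max"))
    msg <- c(msg, "readout must be mean, sum or max")
  if (length(msg)) msg else TRUE
})

#' TrainConfig: training-run settings for the GAT regressor
#'
#' The split ratio is 8:1:1 (train:validation:test) applied as fractions of
#' the library size; all random streams (split, parameter init, batch
#' order) derive from `seed`.
#'
#' @export
setClass("TrainConfig",
  representation(splitRatio = "numeric", seed = "integer", epochs = "integer",
                 learningRate = "numeric", batchSize = "integer",
                 earlyStopPatience = "integer"),
  prototype(splitRatio = c(8, 1, 1), seed = 1L, epochs = 200L,
            learningRate = 3e-3, batchSize = 128L, earlyStopPatience = 30L))

setValidity("TrainConfig", function(object) {
  msg <- character(0)
  if (length(object@splitRatio) != 3L || any(object@splitRatio <= 0))
    msg <- c(msg, "splitRatio must be three positive numbers")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' SplitAssignment: disjoint train/validation/test id sets
#' @export
setClass("SplitAssignment",
  representation(trainIds = "character", valIds = "character",
                 testIds = "character"))

setValidity("SplitAssignment", function(object) {
  all_ids <- c(object@trainIds, object@valIds, object@testIds)
  if (anyDuplicated(all_ids)) return("split sets must be pairwise disjoint")
  TRUE
})

#' FitReport: per-split R-squared and training diagnostics
#' @export
setClass("FitReport",
  representation(r2Train = "numeric", r2Val = "numeric", r2Test = "numeric",
                 lossCurve = "numeric", bestEpoch = "integer"))

#' GNNModel: a trained GAT + MLP pIC50 regressor
#'
#' @slot weights List of layer parameter matrices.
#' @slot config \linkS4class{ModelConfig} used at training time.
#' @slot scaler \linkS4class{FeatureScaler} for injected global scalars
#'   (fitted on the training split), or NULL when graphs arrive
#'   pre-injected.
#' @slot scalarNames Names of injected global scalar columns.
#' @slot inputDim Expected node-feature dimension.
#' @slot split \linkS4class{SplitAssignment} used at training time.
#' @export
setClass("GNNModel",
  representation(weights = "list", config = "ModelConfig", scaler = "ANY",
                 scalarNames = "character", inputDim = "integer",
                 split = "ANY"),
  prototype(scaler = NULL, split = NULL))

#' FunnelStage: one filtering stage of a docking-score funnel
#'
#' Rows with score at or below `threshold` (more negative = better) are
#' retained; when `maxRetained` is set, at most that many best-scoring rows
#' survive, ties broken by id.
#'
#' @export
setClass("FunnelStage",
  representation(name = "character", scoreColumn = "character",
                 threshold = "numeric", maxRetained = "integer",
                 posesPerLigand = "integer"),
  prototype(maxRetained = NA_integer_, posesPerLigand = 1L))

setValidity("FunnelStage", function(object) {
  if (!is.na(object@maxRetained) && object@maxRetained < 1L)
    return("maxRetained must be >= 1 when set")
  TRUE
})

#' FunnelReport: per-stage survivor bookkeeping for a funnel run
#' @slot counts data.frame with columns stage, input, output, missingDropped.
#' @slot survivors Named list of surviving id vectors per stage.
#' @slot finalTable data.frame of surviving rows after the last stage.
#' @slot provenance List of stage configurations.
#' @export
setClass("FunnelReport",
  representation(counts = "data.frame", survivors = "list",
                 finalTable = "data.frame", provenance = "list"))

setValidity("FunnelReport", function(object) {
  out <- object@counts$output
  if (length(out) > 1 && any(diff(out) > 0))
    return("survivor counts must be non-increasing across stages")
  TRUE
})

#' TrajectorySet: replicate trajectories of a protein-ligand complex
#'
#' @slot topology data.frame with one row per atom: `name`, `element`,
#'   `segment` ("protein" or "ligand"), `isHydrogen`, `isDonor`,
#'   `isAcceptor`, `hParent` (heavy-atom index for hydrogens, NA
#'   otherwise), `isFit` (atom participates in the superposition mask).
#' @slot replicates List of numeric arrays (n_frames x n_atoms x 3, Angstrom).
#' @slot times List of numeric vectors (ns), one per replicate.
#' @slot reference Numeric matrix (n_atoms x 3), the starting pose.
#' @export
setClass("TrajectorySet",
  representation(topology = "data.frame", replicates = "list",
                 times = "list", reference = "matrix"))

setValidity("TrajectorySet", function(object) {
  n <- nrow(object@topology)
  msg <- character(0)
  if (nrow(object@reference) != n)
    msg <- c(msg, "reference must cover all topology atoms")
  for (i in seq_along(object@replicates)) {
    a <- object@replicates[[i]]
    if (length(dim(a)) != 3L || dim(a)[2] != n || dim(a)[3] != 3L)
      msg <- c(msg, sprintf("replicate %d has wrong dimensions", i))
    else if (dim(a)[1] < 1L)
      msg <- c(msg, sprintf("replicate %d has no frames", i))
    else if (!all(is.finite(a)))
      msg <- c(msg, sprintf("replicate %d has non-finite coordinates", i))
  }
  if (length(object@times) != length(object@replicates))
    msg <- c(msg, "times must match replicates")
  if (length(msg)) msg else TRUE
})

#' HBondCriteria: geometric hydrogen-bond definition
#'
#' Defaults: donor-acceptor heavy-atom distance <= 3.5 Angstrom and
#' donor-H-acceptor angle >= 120 degrees, both boundaries inclusive.
#'
#' @export
setClass("HBondCriteria",
  representation(distCutoff = "numeric", angleCutoff = "numeric"),
  prototype(distCutoff = 3.5, angleCutoff = 120))

setValidity("HBondCriteria", function(object) {
  msg <- character(0)
  if (object@distCutoff <= 0) msg <- c(msg, "distCutoff must be positive")
  if (object@angleCutoff <= 0 || object@angleCutoff > 180)
    msg <- c(msg, "angleCutoff must be in (0, 180]")
  if (length(msg)) msg else TRUE
})

#' PoseStabilityResult: stability scores for one candidate pose
#'
#' `poseScore` is the mean ligand heavy-atom RMSD from the starting pose
#' across all frames and replicates (Angstrom; lower = more stable).
#' `persScore` is the fraction of initial protein-ligand hydrogen bonds
#' still present over the final simulation window, in [0, 1].
#'
#' @export
setClass("PoseStabilityResult",
  representation(poseScore = "numeric", persScore = "numeric",
                 rmsdSeries = "list", initialHBonds = "data.frame"))

setValidity("PoseStabilityResult", function(object) {
  msg <- character(0)
  if (object@poseScore < 0) msg <- c(msg, "poseScore must be >= 0")
  if (!is.na(object@persScore) &&
      (object@persScore < 0 || object@persScore > 1))
    msg <- c(msg, "persScore must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' FourPLParams: four-parameter logistic dose-response parameters
#'
#' Parameterized as response = bottom + (top - bottom) /
#' (1 + 10^((logIC50 - x) * hillSlope)) with x = log10(concentration).
#'
#' @export
setClass("FourPLParams",
  representation(bottom = "numeric", top = "numeric", logIC50 = "numeric",
                 hillSlope = "numeric"))

setValidity("FourPLParams", function(object) {
  msg <- character(0)
  if (!is.finite(object@hillSlope) || object@hillSlope == 0)
    msg <- c(msg, "hillSlope must be finite and nonzero")
  if (length(msg)) msg else TRUE
})

#' DoseResponseCurve: dose-response observations
#'
#' @slot x Numeric vector of log10 concentrations (log10 nM by convention).
#' @slot y Numeric vector of responses (percent inhibition).
#' @slot replicate Integer vector of replicate labels (same length as x).
#' @export
setClass("DoseResponseCurve",
  representation(x = "numeric", y = "numeric", replicate = "integer"))

setValidity("DoseResponseCurve", function(object) {
  if (length(object@x) != length(object@y) ||
      length(object@x) != length(object@replicate))
    return("x, y and replicate must have equal lengths")
  TRUE
})
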