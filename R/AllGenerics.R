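#' @include AllClasses.R
NULL

#' Mean ligand RMSD from the starting pose across replicates
#' @param ts A \linkS4class{TrajectorySet} (or PoseStabilityResult accessor).
#' @param ... Further arguments for methods.
#' @return Numeric scalar (Angstrom).
#' @export
setGeneric("poseScore", function(ts, ...) standardGeneric("poseScore"))

#' Hydrogen-bond persistence over the final simulation window
#' @param ts A \linkS4class{TrajectorySet} (or PoseStabilityResult accessor).
#' @param ... Further arguments for methods.
#' @return Numeric scalar in [0, 1].
#' @export
setGeneric("persScore", function(ts, ...) standardGeneric("persScore"))

#' Molecule ids of a library or split
#' @param x Object with molecule identifiers.
#' @export
setGeneric("molIds", function(x) standardGeneric("molIds"))

#' Number of molecules / records
#' @param x Object with records.
#' @export
setGeneric("nMolecules", function(x) standardGeneric("nMolecules"))

#' @describeIn MoleculeLibrary ids of all records
#' @param x A MoleculeLibrary.
#' @export
setMethod("molIds", "MoleculeLibrary", function(x)
  vapply(x@records, function(r) r@id, character(1)))

#' @describeIn MoleculeLibrary number of records
#' @export
setMethod("nMolecules", "MoleculeLibrary", function(x) length(x@records))

#' @describeIn MoleculeLibrary extract a single MoleculeRecord
#' @param i Index.
#' @param j,drop Unused.
#' @export
setMethod("[[", "MoleculeLibrary", function(x, i, j, ...) x@records[[i]])

setMethod("show", "MoleculeRecord", function(object) {
  cat("MoleculeRecord", object@id, "\n  SMILES:", object@smiles,
      "\n  heavy atoms:", nrow(object@atoms),
      " bonds:", nrow(object@bonds),
      if (!is.null(object@conformer)) " (3D conformer)" else "", "\n")
})

setMethod("show", "MoleculeLibrary", function(object) {
  cat("MoleculeLibrary with", length(object@records), "molecules")
  if (length(object@skipped))
    cat(" (", length(object@skipped), "input entries skipped)", sep = "")
  cat("\n")
})

setMethod("show", "DescriptorSet", function(object) {
  cat(sprintf(
    "DescriptorSet: MW %.1f | heavy %d | HBD %d | HBA %d | rot %d | TPSA %.1f\n",
    object@mw, object@heavyAtoms, object@hbd, object@hba, object@rotBonds,
    object@tpsa))
})

setMethod("show", "MolGraph", function(object) {
  cat("MolGraph", object@molId, ":", nrow(object@nodeFeatures), "nodes,",
      nrow(object@edges), "edges,", ncol(object@nodeFeatures),
      "node features\n")
})

setMethod("show", "FunnelReport", function(object) {
  cat("FunnelReport:\n")
  print(object@counts, row.names = FALSE)
})

setMethod("show", "FitReport", function(object) {
  cat(sprintf("FitReport: R2 train %.4f | val %.4f | test %.4f (best epoch %d)\n",
              object@r2Train, object@r2Val, object@r2Test, object@bestEpoch))
})

setMethod("show", "GNNModel", function(object) {
  cat("GNNModel:", object@config@nGatLayers, "GAT layers,",
      object@config@attentionHeads, "heads, hidden", object@config@hiddenDim,
      "| input dim", object@inputDim, "\n")
})

setMethod("show", "PoseStabilityResult", function(object) {
  cat(sprintf("PoseStabilityResult: PoseScore %.3f A | PersScore %s | %d replicates\n",
              object@poseScore,
              ifelse(is.na(object@persScore), "NA",
                     sprintf("%.3f", object@persScore)),
              length(object@rmsdSeries)))
})

setMethod("show", "FourPLParams", function(object) {
  cat(sprintf("FourPLParams: bottom %.3g top %.3g logIC50 %.4f hill %.3g (IC50 %.4g)\n",
              object@bottom, object@top, object@logIC50, object@hillSlope,
              10^object@logIC50))
})
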