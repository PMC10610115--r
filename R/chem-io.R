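#' @include chem-parse.R
NULL

#' Parse a single SMILES string into a MoleculeRecord
#'
#' @param smiles SMILES string.
#' @param id Molecule identifier.
#' @return A \linkS4class{MoleculeRecord}.
#' @examples
#' moleculeFromSmiles("c1ccccc1", "benzene")
#' @export
moleculeFromSmiles <- function(smiles, id = "mol1") {
  .parseSmiles(smiles, id)
}

#' Read a molecule library from SMILES list, SDF or CSV
#'
#' Supported formats: `"smiles"` (one molecule per line, whitespace-
#' separated optional id), `"sdf"` (MDL V2000; a 3D conformer is attached
#' when non-zero z coordinates are present) and `"csv"` (requires a
#' `smiles` column, optional `id` column). Unparsable entries are skipped
#' with a message; their count is available via the `skipped` slot.
#'
#' @param path Input file.
#' @param format One of "smiles", "sdf", "csv"; default guessed from the
#'   file extension.
#' @return A \linkS4class{MoleculeLibrary}.
#' @export
readStructures <- function(path, format = c("auto", "smiles", "sdf", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = "sdf", csv = "csv",
                     smi = "smiles", smiles = "smiles", "smiles")
  }
  records <- list(); skipped <- character(0)

  if (format == "sdf") {
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
    ok <- tryCatch(ChemmineR::validSDF(sdfset), error = function(e)
      rep(TRUE, length(sdfset)))
    for (i in seq_along(sdfset)) {
      id <- tryCatch(ChemmineR::sdfid(sdfset[[i]]), error = function(e) "")
      if (is.null(id) || !nzchar(id)) id <- paste0("mol", i)
      if (!ok[i]) { skipped <- c(skipped, id); next }
      rec <- tryCatch(.sdfToRecord(sdfset[[i]], id, keepConformer = TRUE),
                      error = function(e) NULL)
      if (is.null(rec)) skipped <- c(skipped, id)
      else records[[length(records) + 1L]] <- rec
    }
  } else {
    if (format == "smiles") {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      parts <- strsplit(trimws(lines), "[[:space:]]+")
      smi <- vapply(parts, `[`, character(1), 1)
      ids <- vapply(seq_along(parts), function(i)
        if (length(parts[[i]]) >= 2) parts[[i]][2] else paste0("mol", i),
        character(1))
    } else {
      tab <- utils::read.csv(path, stringsAsFactors = FALSE)
      if (!"smiles" %in% names(tab))
        stop("CSV must contain a 'smiles' column")
      smi <- tab$smiles
      ids <- if ("id" %in% names(tab)) as.character(tab$id)
             else paste0("mol", seq_along(smi))
    }
    for (i in seq_along(smi)) {
      rec <- tryCatch(.parseSmiles(smi[i], ids[i]), error = function(e) NULL)
      if (is.null(rec)) skipped <- c(skipped, smi[i])
      else records[[length(records) + 1L]] <- rec
    }
  }
  if (length(skipped))
    message(length(skipped), " unparsable entr",
            ifelse(length(skipped) == 1, "y", "ies"), " skipped")
  if (!length(records)) stop("no parsable records in ", path)
  methods::new("MoleculeLibrary", records = records, skipped = skipped)
}

#' Standardize a molecule: strip salts, normalize hydrogens, canonicalize
#'
#' Keeps the largest organic covalent fragment (most heavy atoms; ties by
#' larger molecular weight, then input order), folds explicit hydrogens
#' into implicit counts, and re-serializes the result to canonical SMILES.
#' A structure with no carbon-containing fragment is rejected as
#' non-drug-like.
#'
#' @param m A \linkS4class{MoleculeRecord}.
#' @return A standardized \linkS4class{MoleculeRecord}.
#' @examples
#' m <- moleculeFromSmiles("CC(=O)[O-].[Na+]", "acetate")
#' standardizeMolecule(m)
#' @export
standardizeMolecule <- function(m) {
  stopifnot(is(m, "MoleculeRecord"))
  frag <- .fragments(m)
  nFrag <- max(frag)
  if (nFrag > 1L) {
    hasC <- vapply(seq_len(nFrag), function(f)
      any(m@atoms$element[frag == f] == "C"), logical(1))
    if (!any(hasC)) stop("no organic (carbon-containing) fragment in ", m@id)
    heavy <- tabulate(frag, nFrag)
    mws <- vapply(seq_len(nFrag), function(f)
      sum(.atomicMass[m@atoms$element[frag == f]], na.rm = TRUE), numeric(1))
    score <- heavy + mws * 1e-6 - (!hasC) * 1e6
    best <- which.max(score)  # which.max takes the first on exact ties
    m <- .subsetRecord(m, which(frag == best))
  } else if (!any(m@atoms$element == "C")) {
    stop("no organic (carbon-containing) fragment in ", m@id)
  }
  .reperceive(m)
}

#' Serialize a MoleculeRecord to SMILES
#'
#' @param m A \linkS4class{MoleculeRecord}.
#' @return Canonical SMILES string.
#' @export
serializeSmiles <- function(m) {
  stopifnot(is(m, "MoleculeRecord"))
  if (!is.na(m@smiles)) return(m@smiles)
  .reperceive(m)@smiles
}

#' Write a descriptor table as CSV
#'
#' @param tab data.frame from [descriptorTable()].
#' @param path Output CSV path.
#' @param digits Decimal places for mw/tpsa at report time (default 1).
#' @return Invisibly, the rounded table.
#' @export
writeDescriptorCSV <- function(tab, path, digits = 1) {
  out <- tab
  out$mw <- round(out$mw, digits)
  out$tpsa <- round(out$tpsa, digits)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
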