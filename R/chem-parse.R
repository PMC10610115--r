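#' @include AllClasses.R
NULL

# Internal perception and parsing layer. SMILES/SDF reading, ring
# perception and canonicalization go through ChemmineR/ChemmineOB
# (OpenBabel); everything downstream works on the plain atom/bond tables
# stored in MoleculeRecord, so descriptor and graph code is independent of
# the parser's object model.

.requireOB <- function() {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("ChemmineOB is required for SMILES parsing/canonicalization")
}

# The connection-table model is constitution-only (no E/Z or tetrahedral
# stereo), so serialized SMILES are normalized to stereo-free form; this
# keeps parse -> standardize -> serialize round trips exact.
.stripStereo <- function(smi) {
  smi <- gsub("[/\\\\]", "", smi)
  gsub("@", "", smi, fixed = TRUE)
}

# MDL charge codes: 1..7 map to +3,+2,+1,doublet,-1,-2,-3
.mdlCharge <- function(code) {
  ifelse(code == 0L, 0L, ifelse(code == 4L, 0L, 4L - as.integer(code)))
}

.defaultValence <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                     F = 1, Cl = 1, Br = 1, I = 1, B = 3, H = 1)

# Average atomic masses (IUPAC 2021 abridged), g/mol
.atomicMass <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, Na = 22.990, Mg = 24.305, Si = 28.085,
                 P = 30.974, S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078,
                 Fe = 55.845, Zn = 65.38, Br = 79.904, I = 126.904,
                 Li = 6.94, Al = 26.982)

# Build a MoleculeRecord from a ChemmineR SDF object. Explicit hydrogens
# are folded into heavy-atom implicit-H counts; aromaticity and ring flags
# come from ChemmineR ring perception on the kekulized connection table.
.sdfToRecord <- function(sdf, id, keepConformer = FALSE) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  n <- length(elem)
  chg <- if ("C6" %in% colnames(ab)) .mdlCharge(ab[, "C6"]) else rep(0L, n)
  coords <- cbind(ab[, 1], ab[, 2],
                  if (ncol(ab) >= 3 && "C3" %in% colnames(ab)) ab[, "C3"] else 0)
  if (is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }

  # ring perception in original index space (H atoms are never ring members)
  aromatic <- logical(n); inRing <- logical(n); in3Ring <- logical(n)
  ringKeys <- character(0); aromKeys <- character(0)
  if (nrow(bonds) >= 3) {
    rr <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, upper = 20, type = "all",
                                        arom = TRUE)),
      error = function(e) list(RINGS = list(), AROMATIC = logical(0)))
    for (k in seq_along(rr$RINGS)) {
      idx <- as.integer(sub("^.*_", "", rr$RINGS[[k]]))
      inRing[idx] <- TRUE
      if (length(idx) == 3) in3Ring[idx] <- TRUE
      pairs <- cbind(idx, c(idx[-1], idx[1]))
      keys <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
      ringKeys <- c(ringKeys, keys)
      if (isTRUE(rr$AROMATIC[[k]])) {
        aromatic[idx] <- TRUE
        aromKeys <- c(aromKeys, keys)
      }
    }
  }

  # fold explicit hydrogens into heavy-atom H counts
  isH <- elem == "H"
  explicitH <- integer(n)
  if (any(isH)) {
    for (k in seq_len(nrow(bonds))) {
      a <- bonds$a1[k]; b <- bonds$a2[k]
      if (isH[a] && !isH[b]) explicitH[b] <- explicitH[b] + 1L
      if (isH[b] && !isH[a]) explicitH[a] <- explicitH[a] + 1L
    }
    keep <- which(!isH)
    remap <- integer(n); remap[keep] <- seq_along(keep)
    dropB <- isH[bonds$a1] | isH[bonds$a2]
    bonds <- bonds[!dropB, , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    elem <- elem[keep]; chg <- chg[keep]; coords <- coords[keep, , drop = FALSE]
    explicitH <- explicitH[keep]
    aromatic <- aromatic[keep]; inRing <- inRing[keep]; in3Ring <- in3Ring[keep]
    # ring bond keys were built in original indices; rebuild in new indices
    reKey <- function(keys) {
      vapply(strsplit(keys, " "), function(p) {
        i <- remap[as.integer(p[1])]; j <- remap[as.integer(p[2])]
        paste(min(i, j), max(i, j))
      }, character(1))
    }
    ringKeys <- reKey(ringKeys); aromKeys <- reKey(aromKeys)
    n <- length(elem)
  }
  if (n == 0L) stop("structure has no heavy atoms")
  rownames(bonds) <- NULL
  bkey <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
  bonds$inRing <- bkey %in% ringKeys
  bonds$aromatic <- bkey %in% aromKeys

  # implicit hydrogens from standard valences (charge-adjusted)
  bosum <- numeric(n); degree <- integer(n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      bosum[bonds$a1[k]] <- bosum[bonds$a1[k]] + bonds$order[k]
      bosum[bonds$a2[k]] <- bosum[bonds$a2[k]] + bonds$order[k]
      degree[bonds$a1[k]] <- degree[bonds$a1[k]] + 1L
      degree[bonds$a2[k]] <- degree[bonds$a2[k]] + 1L
    }
  }
  dv <- unname(.defaultValence[elem]); dv[is.na(dv)] <- 0
  adj <- dv + ifelse(elem %in% c("N", "P", "O", "S"), chg, -abs(chg))
  nH <- pmax(0L, as.integer(round(adj - bosum))) + explicitH

  atoms <- data.frame(element = elem, charge = as.integer(chg),
                      aromatic = aromatic, inRing = inRing,
                      in3Ring = in3Ring, nH = as.integer(nH),
                      degree = degree, stringsAsFactors = FALSE)
  conformer <- NULL
  if (keepConformer && any(abs(coords[, 3]) > 1e-6)) {
    conformer <- unname(as.matrix(coords))
    storage.mode(conformer) <- "double"
  }
  smi <- tryCatch(.canonicalFromSDF(sdf), error = function(e) NA_character_)
  methods::new("MoleculeRecord", id = id, smiles = smi, atoms = atoms,
               bonds = bonds, conformer = conformer, props = list())
}

.canonicalFromSDF <- function(sdf) {
  .requireOB()
  smi <- suppressWarnings(ChemmineR::sdf2smiles(
    methods::as(list(sdf), "SDFset")))
  as.character(ChemmineR::smile(smi))[1]
}

# Parse an MDL V2000 text block directly. Only used for the zero-bond
# case (single atoms, bare ions), which ChemmineR's block reader does not
# represent; everything else goes through ChemmineR.
.parseV2000Zero <- function(lines, id) {
  counts <- lines[4]
  nA <- as.integer(substr(counts, 1, 3))
  if (is.na(nA) || nA < 1) stop("structure has no heavy atoms")
  elem <- character(nA); coords <- matrix(0, nA, 3)
  for (i in seq_len(nA)) {
    al <- lines[4 + i]
    coords[i, ] <- as.numeric(c(substr(al, 1, 10), substr(al, 11, 20),
                                substr(al, 21, 30)))
    elem[i] <- trimws(substr(al, 32, 34))
  }
  chg <- integer(nA)
  for (cl in grep("^M  CHG", lines, value = TRUE)) {
    fields <- as.integer(strsplit(trimws(sub("^M  CHG", "", cl)),
                                  "[[:space:]]+")[[1]])
    npairs <- fields[1]
    for (p in seq_len(npairs))
      chg[fields[2 * p]] <- fields[2 * p + 1]
  }
  keep <- elem != "H"
  explicitH <- sum(!keep)
  elem <- elem[keep]; chg <- chg[keep]
  nA <- length(elem)
  if (nA == 0L) stop("structure has no heavy atoms")
  dv <- unname(.defaultValence[elem]); dv[is.na(dv)] <- 0
  adj <- dv + ifelse(elem %in% c("N", "P", "O", "S"), chg, -abs(chg))
  nH <- pmax(0L, as.integer(round(adj)))
  atoms <- data.frame(element = elem, charge = as.integer(chg),
                      aromatic = FALSE, inRing = FALSE, in3Ring = FALSE,
                      nH = nH, degree = 0L, stringsAsFactors = FALSE)
  methods::new("MoleculeRecord", id = id, smiles = NA_character_,
               atoms = atoms,
               bonds = data.frame(a1 = integer(0), a2 = integer(0),
                                  order = integer(0), inRing = logical(0),
                                  aromatic = logical(0)),
               conformer = NULL, props = list())
}

# Parse SDF text (one molecule) into a MoleculeRecord with canonical
# SMILES attached.
.parseSDFText <- function(text, id, keepConformer = FALSE) {
  .requireOB()
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  nBonds <- as.integer(substr(lines[4], 4, 6))
  if (is.na(nBonds)) stop("malformed SDF counts line")
  if (nBonds == 0L) {
    rec <- .parseV2000Zero(lines, id)
  } else {
    tf <- tempfile(fileext = ".sdf")
    on.exit(unlink(tf))
    writeLines(text, tf)
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
    rec <- .sdfToRecord(sdfset[[1]], id = id, keepConformer = keepConformer)
  }
  if (is.na(rec@smiles)) {
    can <- tryCatch(suppressWarnings(
      ChemmineOB::convertFormat("SDF", "CAN", text)), error = function(e) "")
    can <- strsplit(trimws(can), "[[:space:]]+")[[1]][1]
    if (!is.na(can) && nzchar(can)) rec@smiles <- .stripStereo(can)
  }
  rec
}

# Parse one SMILES string; returns MoleculeRecord or signals an error.
.parseSmiles <- function(smiles, id) {
  .requireOB()
  smiles <- trimws(smiles)
  if (!nzchar(smiles)) stop("empty SMILES")
  text <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, " ", id, "\n")))
  if (!grepl("V2000", text)) stop("unparsable SMILES: ", smiles)
  can <- tryCatch(suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n"))),
    error = function(e) "")
  can <- strsplit(trimws(can), "[[:space:]]+")[[1]][1]
  if (is.na(can) || !nzchar(can)) stop("unparsable SMILES: ", smiles)
  rec <- .parseSDFText(text, id, keepConformer = FALSE)
  rec@smiles <- .stripStereo(can)
  rec
}

# Minimal V2000 writer used to re-serialize a (possibly subsetted)
# connection table so OpenBabel can canonicalize it.
.recordToSDFText <- function(m) {
  n <- nrow(m@atoms); nb <- nrow(m@bonds)
  coords <- if (!is.null(m@conformer)) m@conformer else
    cbind(seq_len(n) * 0.1, 0, 0)
  lines <- c(m@id, "  ScreenFunnel", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              coords[i, 1], coords[i, 2], coords[i, 3],
                              m@atoms$element[i]))
  }
  for (k in seq_len(nb)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", m@bonds$a1[k],
                              m@bonds$a2[k], m@bonds$order[k]))
  }
  chgIdx <- which(m@atoms$charge != 0L)
  for (i in chgIdx) {
    lines <- c(lines, sprintf("M  CHG  1%4d%4d", i, m@atoms$charge[i]))
  }
  c(lines, "M  END", "$$$$")
}

# Re-serialize a record through OpenBabel to get its canonical SMILES and
# a freshly perceived record (used after fragment subsetting).
.reperceive <- function(m) {
  text <- paste(.recordToSDFText(m), collapse = "\n")
  rec <- .parseSDFText(text, id = m@id, keepConformer = !is.null(m@conformer))
  rec@props <- m@props
  rec
}

# Connected components of the heavy-atom graph (fragment labels).
.fragments <- function(m) {
  n <- nrow(m@atoms)
  comp <- seq_len(n)
  if (nrow(m@bonds)) {
    repeat {
      changed <- FALSE
      for (k in seq_len(nrow(m@bonds))) {
        a <- m@bonds$a1[k]; b <- m@bonds$a2[k]
        lo <- min(comp[a], comp[b])
        if (comp[a] != lo || comp[b] != lo) {
          members <- comp %in% c(comp[a], comp[b])
          comp[members] <- lo
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  match(comp, unique(comp))
}

# Subset a record to one fragment (atom index subset).
.subsetRecord <- function(m, keep) {
  remap <- integer(nrow(m@atoms)); remap[keep] <- seq_along(keep)
  bonds <- m@bonds[m@bonds$a1 %in% keep & m@bonds$a2 %in% keep, , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  rownames(bonds) <- NULL
  methods::new("MoleculeRecord", id = m@id, smiles = NA_character_,
               atoms = m@atoms[keep, , drop = FALSE],
               bonds = bonds,
               conformer = if (!is.null(m@conformer))
                 m@conformer[keep, , drop = FALSE] else NULL,
               props = m@props)
}
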