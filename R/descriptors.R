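#' @include chem-parse.R
NULL

# Ertl fragment-contribution TPSA. Classification per polar atom by
# element, aromaticity, charge, attached-H count and bond-order pattern
# (ring bonds of aromatic systems count as aromatic; the kekulized orders
# of non-aromatic bonds as written). Sulfur and phosphorus contributions
# are included by default: drug-like heteroaromatics (thiazoles,
# thiophenes) need the aromatic-S term to match published polar surface
# areas.
.tpsaAtomContribution <- function(e, aromatic, q, h, nAr, s1, s2, s3,
                                  in3ring, totalDegree) {
  key <- NA_real_
  if (e == "N") {
    if (!aromatic) {
      if (q == 0) {
        if (h == 0 && s1 == 3 && s2 == 0 && s3 == 0)
          key <- if (in3ring) 3.01 else 3.24
        else if (h == 0 && s1 == 1 && s2 == 1) key <- 12.36
        else if (h == 0 && s3 == 1 && s1 == 0 && s2 == 0) key <- 23.79
        else if (h == 0 && s1 == 1 && s2 == 2) key <- 11.68
        else if (h == 0 && s2 == 1 && s3 == 1) key <- 13.60
        else if (h == 1 && s1 == 2) key <- if (in3ring) 21.94 else 12.03
        else if (h == 1 && s2 == 1 && s1 == 0) key <- 23.85
        else if (h == 2 && s1 == 1) key <- 26.02
      } else if (q == 1) {
        if (h == 0 && s1 == 4) key <- 0.00
        else if (h == 0 && s1 == 2 && s2 == 1) key <- 3.01
        else if (h == 0 && s1 == 1 && s3 == 1) key <- 4.36
        else if (h == 1 && s1 == 3) key <- 4.44
        else if (h == 1 && s1 == 1 && s2 == 1) key <- 13.97
        else if (h == 2 && s1 == 2) key <- 16.61
        else if (h == 2 && s2 == 1) key <- 25.59
        else if (h == 3 && s1 == 1) key <- 27.64
      }
    } else {
      if (q == 0) {
        if (h == 0 && nAr == 2 && s1 == 0 && s2 == 0) key <- 12.89
        else if (h == 0 && nAr == 3) key <- 4.41
        else if (h == 0 && nAr == 2 && s1 == 1) key <- 4.93
        else if (h == 0 && nAr == 2 && s2 == 1) key <- 8.39
        else if (h == 1 && nAr == 2) key <- 15.79
      } else if (q == 1) {
        if (h == 0 && nAr == 3) key <- 4.10
        else if (h == 0 && nAr == 2 && s1 == 1) key <- 3.88
        else if (h == 1 && nAr == 2) key <- 14.14
      }
    }
    if (is.na(key)) key <- max(0, 30.5 - totalDegree * 8.2 + h * 1.5)
  } else if (e == "O") {
    if (!aromatic) {
      if (q == 0) {
        if (h == 0 && s1 == 2) key <- if (in3ring) 12.53 else 9.23
        else if (h == 0 && s2 == 1) key <- 17.07
        else if (h == 1 && s1 == 1) key <- 20.23
      } else if (q == -1 && s1 == 1) key <- 23.06
    } else if (h == 0 && nAr == 2) key <- 13.14
    if (is.na(key)) key <- max(0, 28.5 - totalDegree * 8.6 + h * 1.5)
  } else if (e == "S") {
    if (!aromatic) {
      if (q == 0) {
        if (h == 0 && s1 == 2 && s2 == 0) key <- 25.30
        else if (h == 0 && s2 == 1 && s1 == 0) key <- 32.09
        else if (h == 0 && s1 == 2 && s2 == 1) key <- 19.21
        else if (h == 0 && s1 == 2 && s2 == 2) key <- 8.38
        else if (h == 1 && s1 == 1) key <- 38.80
      }
    } else {
      if (h == 0 && nAr == 2 && s2 == 0) key <- 28.24
      else if (h == 0 && nAr == 2 && s2 == 1) key <- 21.70
    }
    if (is.na(key)) key <- 0
  } else if (e == "P") {
    if (h == 0 && s1 == 3 && s2 == 0) key <- 13.59
    else if (h == 0 && s1 == 1 && s2 == 1) key <- 34.14
    else if (h == 0 && s1 == 3 && s2 == 1) key <- 9.81
    else if (h == 1 && s1 == 2 && s2 == 1) key <- 23.47
    if (is.na(key)) key <- 0
  }
  key
}

# Per-atom bond environment: aromatic bond count and non-aromatic
# single/double/triple counts.
.bondEnv <- function(m, i) {
  bi <- m@bonds[m@bonds$a1 == i | m@bonds$a2 == i, , drop = FALSE]
  list(bonds = bi,
       neighbors = ifelse(bi$a1 == i, bi$a2, bi$a1),
       nAr = sum(bi$aromatic),
       s1 = sum(!bi$aromatic & bi$order == 1),
       s2 = sum(!bi$aromatic & bi$order == 2),
       s3 = sum(!bi$aromatic & bi$order == 3))
}

.tpsa <- function(m, includeSP = TRUE) {
  total <- 0
  polar <- if (includeSP) c("N", "O", "S", "P") else c("N", "O")
  for (i in seq_len(nrow(m@atoms))) {
    e <- m@atoms$element[i]
    if (!e %in% polar) next
    env <- .bondEnv(m, i)
    total <- total + .tpsaAtomContribution(
      e, m@atoms$aromatic[i], m@atoms$charge[i], m@atoms$nH[i],
      env$nAr, env$s1, env$s2, env$s3, m@atoms$in3Ring[i],
      m@atoms$degree[i] + m@atoms$nH[i])
  }
  total
}

.molecularWeight <- function(m) {
  mass <- .atomicMass[m@atoms$element]
  if (anyNA(mass))
    warning("unknown element(s): ",
            paste(unique(m@atoms$element[is.na(mass)]), collapse = ", "))
  sum(mass, na.rm = TRUE) + sum(m@atoms$nH) * .atomicMass[["H"]]
}

.hbdCount <- function(m) {
  sum(m@atoms$element %in% c("N", "O") & m@atoms$nH >= 1L)
}

# Acceptor convention (reverse-engineered for parity with published
# physicochemical tables of drug-like molecules): every oxygen counts;
# pyridine-type aromatic nitrogen (two ring bonds, no H) counts; aliphatic
# nitrogen counts unless it is an amide/thioamide N, a nitro-type N or
# positively charged; aromatic sulfur and unoxidized divalent sulfide
# sulfur count. Amide N exclusion is the load-bearing rule.
.hbaCount <- function(m, countSulfur = TRUE) {
  hba <- 0L
  for (i in seq_len(nrow(m@atoms))) {
    e <- m@atoms$element[i]
    if (!e %in% c("N", "O", "S")) next
    env <- .bondEnv(m, i)
    if (e == "O") {
      hba <- hba + 1L
    } else if (e == "N") {
      if (m@atoms$aromatic[i]) {
        if (m@atoms$nH[i] == 0L && m@atoms$degree[i] == 2L) hba <- hba + 1L
      } else if (m@atoms$charge[i] <= 0L) {
        nbr <- env$neighbors
        nitro <- any(env$bonds$order == 2 & m@atoms$element[nbr] == "O")
        amide <- FALSE
        for (cc in nbr[m@atoms$element[nbr] == "C"]) {
          ec <- .bondEnv(m, cc)
          if (any(ec$bonds$order == 2 &
                  m@atoms$element[ec$neighbors] %in% c("O", "S")))
            amide <- TRUE
        }
        if (!nitro && !amide) hba <- hba + 1L
      }
    } else if (countSulfur) {
      if (m@atoms$aromatic[i]) hba <- hba + 1L
      else if (m@atoms$degree[i] == 2L && m@atoms$nH[i] == 0L &&
               all(env$bonds$order == 1)) hba <- hba + 1L
    }
  }
  hba
}

# Rotatable bonds: non-ring single bonds between two non-terminal heavy
# atoms, excluding amide C-N bonds.
.rotatableBonds <- function(m) {
  rot <- 0L
  for (k in seq_len(nrow(m@bonds))) {
    b <- m@bonds[k, ]
    if (b$order != 1L || b$inRing || b$aromatic) next
    if (m@atoms$degree[b$a1] < 2L || m@atoms$degree[b$a2] < 2L) next
    amide <- FALSE
    for (pr in list(c(b$a1, b$a2), c(b$a2, b$a1))) {
      cc <- pr[1]; nn <- pr[2]
      if (m@atoms$element[cc] == "C" && m@atoms$element[nn] == "N") {
        ec <- .bondEnv(m, cc)
        if (any(ec$bonds$order == 2 & m@atoms$element[ec$neighbors] == "O"))
          amide <- TRUE
      }
    }
    if (!amide) rot <- rot + 1L
  }
  rot
}

#' Compute the physicochemical descriptor set of a molecule
#'
#' Computes average-mass molecular weight, heavy-atom count, hydrogen-bond
#' donor count (N-H/O-H groups, each group once), hydrogen-bond acceptor
#' count, rotatable-bond count (non-ring single bonds between non-terminal
#' heavy atoms, amide C-N excluded) and topological polar surface area by
#' Ertl fragment contributions.
#'
#' Two conventions are pinned deliberately and exposed as switches:
#' \itemize{
#'   \item \code{tpsaSP}: TPSA includes sulfur and phosphorus fragment
#'     contributions (many toolkits omit them by default). Thiazole- and
#'     thiophene-containing drug-like molecules only reach their published
#'     polar surface areas with the aromatic-S term included.
#'   \item \code{hbaSulfur}: aromatic and unoxidized divalent sulfur count
#'     as acceptors; amide nitrogen never does.
#' }
#' Internal values are kept at full precision; round only at report time.
#'
#' @param m A \linkS4class{MoleculeRecord} (standardized).
#' @param tpsaSP Include S/P TPSA contributions (default TRUE).
#' @param hbaSulfur Count aromatic/divalent S as acceptor (default TRUE).
#' @return A \linkS4class{DescriptorSet}.
#' @examples
#' m <- moleculeFromSmiles("CCO", "ethanol")
#' computeDescriptors(m)
#' @export
computeDescriptors <- function(m, tpsaSP = TRUE, hbaSulfur = TRUE) {
  stopifnot(is(m, "MoleculeRecord"))
  methods::new("DescriptorSet",
               mw = .molecularWeight(m),
               heavyAtoms = nrow(m@atoms),
               hbd = .hbdCount(m),
               hba = .hbaCount(m, countSulfur = hbaSulfur),
               rotBonds = .rotatableBonds(m),
               tpsa = .tpsa(m, includeSP = tpsaSP),
               logp = NA_real_)
}

#' Descriptor table for a molecule library
#'
#' One row per record in library order. Column order is fixed: id, mw,
#' heavy_atoms, hbd, hba, rot_bonds, tpsa. Molecules whose descriptor
#' computation fails are kept as rows with NA values and flagged in the
#' `failed` column.
#'
#' @param lib A \linkS4class{MoleculeLibrary} or list of MoleculeRecord.
#' @param ... Passed to [computeDescriptors()].
#' @return A data.frame, writable as CSV.
#' @export
descriptorTable <- function(lib, ...) {
  records <- if (is(lib, "MoleculeLibrary")) lib@records else lib
  if (length(records) < 1) stop("library is empty")
  rows <- lapply(records, function(r) {
    d <- tryCatch(computeDescriptors(r, ...), error = function(e) NULL)
    if (is.null(d)) {
      data.frame(id = r@id, mw = NA_real_, heavy_atoms = NA_integer_,
                 hbd = NA_integer_, hba = NA_integer_,
                 rot_bonds = NA_integer_, tpsa = NA_real_, failed = TRUE)
    } else {
      data.frame(id = r@id, mw = d@mw, heavy_atoms = d@heavyAtoms,
                 hbd = d@hbd, hba = d@hba, rot_bonds = d@rotBonds,
                 tpsa = d@tpsa, failed = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
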