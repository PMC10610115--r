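#' @include AllClasses.R AllGenerics.R
NULL

#' Optimal least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation that minimize the RMSD of
#' the masked atoms between `mobile` and `ref`, and applies it to all
#' atoms of `mobile`.
#'
#' @param ref Reference coordinates, n x 3 matrix.
#' @param mobile Mobile coordinates, n x 3 matrix.
#' @param fitMask Integer or logical index of atoms used for the fit
#'   (>= 3 non-collinear atoms); default all atoms.
#' @return List with `rotation` (3x3, det +1), `translation` (length 3),
#'   `fitted` (all mobile atoms transformed) and `rmsd` (on the mask).
#' @export
kabschSuperpose <- function(ref, mobile, fitMask = NULL) {
  ref <- as.matrix(ref); mobile <- as.matrix(mobile)
  if (!all(dim(ref) == dim(mobile)))
    stop("ref and mobile must have identical dimensions")
  if (is.null(fitMask)) fitMask <- seq_len(nrow(ref))
  Pr <- ref[fitMask, , drop = FALSE]
  Pm <- mobile[fitMask, , drop = FALSE]
  if (nrow(Pr) < 3) stop("need at least 3 mask atoms")
  cr <- colMeans(Pr); cm <- colMeans(Pm)
  A <- sweep(Pm, 2, cm); B <- sweep(Pr, 2, cr)
  sv <- svd(crossprod(A, A))
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate (collinear) fit mask")
  C <- crossprod(A, B)
  s <- svd(C)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- sweep(sweep(mobile, 2, cm) %*% R, 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((fitted[fitMask, , drop = FALSE] - Pr)^2)))
  list(rotation = R, translation = as.vector(cr - cm %*% R), fitted = fitted,
       rmsd = rmsd)
}

# Default superposition mask: protein C-alpha atoms within `radius`
# Angstrom of any ligand heavy atom in the reference pose; falls back to
# all protein heavy atoms when no C-alpha is close enough or none exist.
.fitMask <- function(ts, radius = 8) {
  topo <- ts@topology
  if ("isFit" %in% names(topo) && any(topo$isFit)) return(which(topo$isFit))
  prot <- which(topo$segment == "protein" & !topo$isHydrogen)
  lig <- .ligandHeavy(ts)
  ca <- prot[topo$name[prot] == "CA"]
  if (length(ca) >= 3 && length(lig)) {
    refL <- ts@reference[lig, , drop = FALSE]
    near <- vapply(ca, function(i) {
      min(sqrt(rowSums(sweep(refL, 2, ts@reference[i, ])^2))) <= radius
    }, logical(1))
    if (sum(near) >= 3) return(ca[near])
  }
  prot
}

.ligandHeavy <- function(ts) {
  which(ts@topology$segment == "ligand" & !ts@topology$isHydrogen)
}

#' Ligand RMSD time series for one replicate
#'
#' Each frame is superposed on the binding-site mask (protein C-alpha
#' within 8 Angstrom of the ligand in the reference pose, or all protein
#' atoms) via [kabschSuperpose()]; the ligand heavy-atom RMSD against the
#' starting pose is then computed without re-fitting the ligand.
#'
#' @param ts A \linkS4class{TrajectorySet}.
#' @param replicate Replicate index.
#' @return data.frame with columns `time` (ns) and `rmsd` (Angstrom).
#' @export
ligandRmsdSeries <- function(ts, replicate = 1L) {
  stopifnot(is(ts, "TrajectorySet"))
  lig <- .ligandHeavy(ts)
  if (!length(lig)) stop("empty ligand heavy-atom mask")
  mask <- .fitMask(ts)
  arr <- ts@replicates[[replicate]]
  nF <- dim(arr)[1]
  refLig <- ts@reference[lig, , drop = FALSE]
  rmsd <- vapply(seq_len(nF), function(f) {
    frame <- arr[f, , ]
    fit <- kabschSuperpose(ts@reference, frame, mask)
    sqrt(mean(rowSums((fit$fitted[lig, , drop = FALSE] - refLig)^2)))
  }, numeric(1))
  data.frame(time = ts@times[[replicate]], rmsd = rmsd)
}

#' @describeIn poseScore Mean ligand heavy-atom RMSD from the starting
#'   pose over all frames of all replicates (Angstrom).
#' @export
setMethod("poseScore", "TrajectorySet", function(ts, ...) {
  if (!length(ts@replicates)) stop("no replicates")
  series <- lapply(seq_along(ts@replicates), function(r)
    ligandRmsdSeries(ts, r)$rmsd)
  mean(unlist(series))
})

#' @describeIn poseScore Stored PoseScore of a result object.
#' @export
setMethod("poseScore", "PoseStabilityResult", function(ts, ...) ts@poseScore)

#' Detect hydrogen bonds in one frame
#'
#' A donor-H...acceptor triple is a hydrogen bond when the donor-acceptor
#' heavy-atom distance is at most the distance cutoff AND the
#' donor-H-acceptor angle is at least the angle cutoff; both boundaries
#' are inclusive.
#'
#' @param coords n x 3 coordinate matrix for one frame.
#' @param topology Topology data.frame (see \linkS4class{TrajectorySet}).
#' @param criteria A \linkS4class{HBondCriteria}.
#' @param crossOnly Only protein-ligand (intermolecular) bonds (default
#'   TRUE).
#' @return data.frame with columns donor, h, acceptor (atom indices).
#' @export
detectHBonds <- function(coords, topology,
                         criteria = methods::new("HBondCriteria"),
                         crossOnly = TRUE) {
  donors <- which(topology$isDonor)
  acceptors <- which(topology$isAcceptor)
  hyd <- which(topology$isHydrogen & !is.na(topology$hParent))
  if (length(donors) && !length(hyd))
    stop("donors without attached hydrogens in topology")
  res <- list()
  for (d in donors) {
    hs <- hyd[topology$hParent[hyd] == d]
    if (!length(hs)) stop("donor atom ", d, " has no attached hydrogen")
    for (a in acceptors) {
      if (a == d) next
      if (crossOnly && topology$segment[a] == topology$segment[d]) next
      dda <- sqrt(sum((coords[d, ] - coords[a, ])^2))
      if (dda > criteria@distCutoff + 1e-12) next
      for (hh in hs) {
        v1 <- coords[d, ] - coords[hh, ]
        v2 <- coords[a, ] - coords[hh, ]
        cosang <- sum(v1 * v2) /
          (sqrt(sum(v1^2)) * sqrt(sum(v2^2)) + 1e-300)
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        if (ang >= criteria@angleCutoff - 1e-9) {
          res[[length(res) + 1L]] <- c(donor = d, h = hh, acceptor = a)
          break
        }
      }
    }
  }
  if (!length(res))
    return(data.frame(donor = integer(0), h = integer(0),
                      acceptor = integer(0)))
  as.data.frame(do.call(rbind, res))
}

#' @describeIn persScore Fraction of initial protein-ligand hydrogen
#'   bonds present over the final window, pooled over (bond, frame) pairs
#'   across replicates. `finalWindow` is in ns (default 2).
#' @param criteria A \linkS4class{HBondCriteria}.
#' @param finalWindow Final analysis window in ns.
#' @export
setMethod("persScore", "TrajectorySet", function(ts,
    criteria = methods::new("HBondCriteria"), finalWindow = 2, ...) {
  initial <- detectHBonds(ts@reference, ts@topology, criteria)
  if (!nrow(initial))
    stop("no initial protein-ligand hydrogen bonds: PersScore undefined")
  key <- function(df) paste(df$donor, df$acceptor)
  initKeys <- key(initial)
  present <- 0L; total <- 0L
  for (r in seq_along(ts@replicates)) {
    tt <- ts@times[[r]]
    if (finalWindow > max(tt) + 1e-9)
      stop("final window longer than trajectory")
    # the "final W ns" are the frames with time in (t_end - W, t_end]
    inWin <- which(tt > max(tt) - finalWindow + 1e-9)
    arr <- ts@replicates[[r]]
    for (f in inWin) {
      bonds <- detectHBonds(arr[f, , ], ts@topology, criteria)
      present <- present + sum(initKeys %in% key(bonds))
      total <- total + length(initKeys)
    }
  }
  present / total
})

#' @describeIn persScore Stored PersScore of a result object.
#' @export
setMethod("persScore", "PoseStabilityResult", function(ts, ...) ts@persScore)

#' Full pose-stability analysis of a trajectory set
#'
#' @param ts A \linkS4class{TrajectorySet}.
#' @param criteria A \linkS4class{HBondCriteria}.
#' @param finalWindow Final window (ns) for PersScore.
#' @return A \linkS4class{PoseStabilityResult}.
#' @export
poseStability <- function(ts, criteria = methods::new("HBondCriteria"),
                          finalWindow = 2) {
  series <- lapply(seq_along(ts@replicates), function(r)
    ligandRmsdSeries(ts, r))
  ps <- mean(unlist(lapply(series, `[[`, "rmsd")))
  initial <- detectHBonds(ts@reference, ts@topology, criteria)
  pers <- if (nrow(initial))
    persScore(ts, criteria = criteria, finalWindow = finalWindow)
  else NA_real_
  methods::new("PoseStabilityResult", poseScore = ps, persScore = pers,
               rmsdSeries = series, initialHBonds = initial)
}

#' Select the most stable initial pose among candidates
#'
#' Candidates are ranked by ascending PoseScore, ties broken by
#' descending PersScore, then label; the best label is returned with the
#' full ranking attached.
#'
#' @param candidates Named list of \linkS4class{PoseStabilityResult}.
#' @return Best label (character) with attribute `ranking` (data.frame).
#' @export
selectStablePose <- function(candidates) {
  if (!length(candidates)) stop("empty candidate list")
  labels <- names(candidates)
  if (is.null(labels)) labels <- paste0("pose", seq_along(candidates))
  df <- data.frame(
    label = labels,
    poseScore = vapply(candidates, function(x) x@poseScore, numeric(1)),
    persScore = vapply(candidates, function(x)
      ifelse(is.na(x@persScore), -Inf, x@persScore), numeric(1)))
  df <- df[order(df$poseScore, -df$persScore, df$label), , drop = FALSE]
  rownames(df) <- NULL
  best <- df$label[1]
  attr(best, "ranking") <- df
  best
}

#' Build a TrajectorySet from PDB files
#'
#' Reads a topology/reference PDB and one multi-model PDB per replicate
#' with the bio3d reader. Atom roles are taken from a sidecar data.frame
#' (or inferred: chain "L" or residue name "LIG" marks the ligand;
#' N/O atoms are marked donor when they have a bonded hydrogen within
#' 1.2 Angstrom in the reference, and acceptor otherwise).
#'
#' @param refPdb Reference (starting pose) PDB path.
#' @param trajPdbs Character vector of multi-model PDB paths (replicates).
#' @param dtNs Time step between frames in ns.
#' @param roles Optional topology data.frame overriding inference.
#' @return A \linkS4class{TrajectorySet}.
#' @export
trajectoryFromPDB <- function(refPdb, trajPdbs, dtNs = 0.1, roles = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("bio3d is required to read PDB trajectories")
  ref <- bio3d::read.pdb(refPdb)
  xyzRef <- matrix(ref$xyz[1, ], ncol = 3, byrow = TRUE)
  atom <- ref$atom
  n <- nrow(atom)
  if (is.null(roles)) {
    isLig <- atom$chain %in% "L" | atom$resid %in% c("LIG", "UNL", "UNK")
    isH <- atom$elety %in% "H" | substr(trimws(atom$elety), 1, 1) == "H" &
      !grepl("^HG|^HE$|^HF", trimws(atom$elety))
    elem <- ifelse(is.na(atom$elesy) | atom$elesy == "",
                   substr(trimws(atom$elety), 1, 1), trimws(atom$elesy))
    isH <- elem == "H"
    hParent <- rep(NA_integer_, n)
    heavy <- which(!isH)
    for (i in which(isH)) {
      d <- sqrt(rowSums(sweep(xyzRef[heavy, , drop = FALSE], 2,
                              xyzRef[i, ])^2))
      j <- heavy[which.min(d)]
      if (min(d) <= 1.3) hParent[i] <- j
    }
    isDonor <- !isH & elem %in% c("N", "O") &
      seq_len(n) %in% stats::na.omit(hParent)
    isAcceptor <- !isH & elem %in% c("N", "O")
    roles <- data.frame(name = trimws(atom$elety), element = elem,
                        segment = ifelse(isLig, "ligand", "protein"),
                        isHydrogen = isH, isDonor = isDonor,
                        isAcceptor = isAcceptor, hParent = hParent)
  }
  reps <- list(); times <- list()
  for (p in trajPdbs) {
    td <- bio3d::read.pdb(p, multi = TRUE)
    nf <- nrow(td$xyz)
    arr <- array(0, c(nf, n, 3))
    for (f in seq_len(nf))
      arr[f, , ] <- matrix(td$xyz[f, ], ncol = 3, byrow = TRUE)
    reps[[length(reps) + 1L]] <- arr
    times[[length(times) + 1L]] <- (seq_len(nf) - 1) * dtNs
  }
  methods::new("TrajectorySet", topology = roles, replicates = reps,
               times = times, reference = xyzRef)
}
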