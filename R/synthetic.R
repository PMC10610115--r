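#' @include chem-io.R descriptors.R assay.R utils.R
NULL

# Fragment grammar for guaranteed-valid drug-like SMILES assembly. Outer
# ring systems use ring-closure digit 1, inner ones digit 2, so any
# combination nests without digit collisions; the empty decoration is
# realized by deleting the branch from the template.
.ring1Templates <- c(
  benzene_para = "c1ccc(%s)cc1",
  benzene_meta = "c1cccc(%s)c1",
  pyridine     = "c1ccnc(%s)c1",
  thiophene    = "c1cc(%s)sc1",
  furan        = "c1cc(%s)oc1",
  thiazole     = "c1csc(%s)n1",
  cyclohexane  = "C1CCC(%s)CC1")

.ring2Templates <- c(
  benzene_para = "c2ccc(%s)cc2",
  benzene_meta = "c2cccc(%s)c2",
  pyridine     = "c2ccnc(%s)c2",
  thiophene    = "c2cc(%s)sc2",
  furan        = "c2cc(%s)oc2",
  thiazole     = "c2csc(%s)n2",
  cyclohexane  = "C2CCC(%s)CC2")

.linkers <- c("", "C", "CC", "CCC", "O", "CO", "OC", "C(=O)N", "C=C")
.decoPrefix <- c("", "C", "CC", "CCC", "CC(C)", "N", "O", "F", "Cl", "CO")
.decoInner <- c("", "C", "CC", "N", "O", "F", "Cl", "OC")

.fillSlot <- function(template, content) {
  if (nzchar(content)) sprintf(template, content)
  else gsub("(%s)", "", template, fixed = TRUE)
}

.assembleSmiles <- function(deco1, ring1, linker, ring2, deco2) {
  inner <- .fillSlot(.ring2Templates[[ring2]], deco2)
  paste0(deco1, .fillSlot(.ring1Templates[[ring1]], paste0(linker, inner)))
}

#' Generate a synthetic drug-like molecule library
#'
#' Molecules are assembled from a fragment grammar (two ring systems, a
#' linker, and terminal decorations) so every generated SMILES is valid
#' by construction. Output is seeded and reproducible; molecules are
#' distinct by canonical structure.
#'
#' @param n Number of molecules (>= 1).
#' @param seed Integer seed.
#' @param idPrefix Prefix for molecule ids (default "mol").
#' @return A \linkS4class{MoleculeLibrary} of `n` records.
#' @export
genMoleculeLibrary <- function(n, seed = 1L, idPrefix = "mol") {
  stopifnot(n >= 1)
  .withSeed(seed, {
    seen <- character(0)
    records <- vector("list", n)
    got <- 0L; tries <- 0L
    while (got < n) {
      tries <- tries + 1L
      if (tries > 200L * n)
        stop("fragment grammar exhausted before reaching n molecules")
      smi <- .assembleSmiles(
        sample(.decoPrefix, 1), sample(names(.ring1Templates), 1),
        sample(.linkers, 1), sample(names(.ring2Templates), 1),
        sample(.decoInner, 1))
      rec <- tryCatch(.parseSmiles(smi, sprintf("%s%04d", idPrefix, got + 1L)),
                      error = function(e) NULL)
      if (is.null(rec) || is.na(rec@smiles) || rec@smiles %in% seen) next
      seen <- c(seen, rec@smiles)
      got <- got + 1L
      records[[got]] <- rec
    }
    methods::new("MoleculeLibrary", records = records, skipped = character(0))
  })
}

#' Plant a descriptor-linear activity signal on a library
#'
#' pIC50 labels are generated as intercept + beta . z(descriptors) +
#' N(0, sigma^2), where z() is the population z-score over the library.
#' The ground-truth coefficients and the descriptor matrix are attached
#' as attributes for recovery tests.
#'
#' @param lib A \linkS4class{MoleculeLibrary}.
#' @param coefficients Named numeric vector over descriptor columns
#'   (default c(tpsa = 0.8, mw = 0.5, rot_bonds = 0.3)).
#' @param intercept Mean pIC50 level (default 6).
#' @param sigma Gaussian noise SD (default 0.2).
#' @param seed Integer seed.
#' @return data.frame with columns id, pic50; attributes `beta`,
#'   `intercept`, `descriptors` (z-scored matrix) and `signal`.
#' @export
plantActivityLabels <- function(lib,
                                coefficients = c(tpsa = 0.8, mw = 0.5,
                                                 rot_bonds = 0.3),
                                intercept = 6, sigma = 0.2, seed = 1L) {
  desc <- descriptorTable(lib)
  if (any(desc$failed)) stop("descriptor computation failed for some molecules")
  cols <- names(coefficients)
  z <- .zscorePop(desc[cols])
  signal <- as.vector(as.matrix(z) %*% coefficients)
  noise <- .withSeed(seed, stats::rnorm(nrow(desc), 0, sigma))
  out <- data.frame(id = desc$id, pic50 = intercept + signal + noise)
  attr(out, "beta") <- coefficients
  attr(out, "intercept") <- intercept
  attr(out, "descriptors") <- z
  attr(out, "signal") <- signal
  out
}

#' Generate a synthetic score table
#'
#' Columns are drawn from declared marginals ("normal" or "uniform");
#' optional rank correlation between columns is induced with a Gaussian
#' copula (latent Pearson correlation 2*sin(pi*rho/6), which yields the
#' requested Spearman rho).
#'
#' @param n Number of molecules.
#' @param columns Named list of marginal specs, e.g.
#'   list(score_xp = list(dist = "normal", mean = -8, sd = 1)).
#' @param seed Integer seed.
#' @param spearman Optional target Spearman correlation (scalar, applied
#'   between all column pairs).
#' @param ids Optional id vector (default mol0001...).
#' @return data.frame keyed by `id`.
#' @export
genScoreTable <- function(n, columns, seed = 1L, spearman = NULL,
                          ids = NULL) {
  k <- length(columns)
  stopifnot(k >= 1)
  if (is.null(ids)) ids <- sprintf("mol%04d", seq_len(n))
  .withSeed(seed, {
    if (!is.null(spearman) && k >= 2) {
      r <- 2 * sin(pi * spearman / 6)
      Sigma <- matrix(r, k, k); diag(Sigma) <- 1
      L <- chol(Sigma)
      Z <- matrix(stats::rnorm(n * k), n, k) %*% L
    } else {
      Z <- matrix(stats::rnorm(n * k), n, k)
    }
    U <- stats::pnorm(Z)
    out <- data.frame(id = ids)
    for (j in seq_len(k)) {
      sp <- columns[[j]]
      out[[names(columns)[j]]] <- switch(
        sp$dist %||% "normal",
        normal = stats::qnorm(U[, j], sp$mean %||% 0, sp$sd %||% 1),
        uniform = stats::qunif(U[, j], sp$min %||% 0, sp$max %||% 1),
        stop("unsupported distribution: ", sp$dist))
    }
    out
  })
}

#' Generate a synthetic replicate trajectory set
#'
#' Builds a protein-ligand complex topology (protein slab with C-alpha
#' markers, ligand cluster, `nHBonds` protein-donor/ligand-acceptor
#' pairs) and replicate coordinate series under one of two motion models:
#' "stable" (isotropic Gaussian jitter of SD `jitterSigma` Angstrom) or
#' "drifting" (ligand random walk with step `driftStep` Angstrom plus
#' jitter). Hydrogen-bond geometries are placed inside/outside the
#' detection criteria frame-by-frame following a deterministic occupancy
#' schedule over the final window, so persistence targets are exact: with
#' occupancy o and nWin window frames, the bond is present in round(o *
#' nWin) frames. Frame timestamps are dt, 2*dt, ..., nFrames*dt ns.
#'
#' @param nProtein,nLigand Heavy-atom counts.
#' @param nFrames Frames per replicate.
#' @param nReplicates Number of replicates (default 10).
#' @param dtNs Time step (ns), default 0.1.
#' @param motion "stable" or "drifting".
#' @param jitterSigma Isotropic jitter SD (Angstrom), default 0.3.
#' @param driftStep Random-walk step (Angstrom), default 0.2.
#' @param nHBonds Number of protein-ligand hydrogen bonds (default 2).
#' @param occupancy Scheduled final-window occupancy per bond (recycled),
#'   default 1.
#' @param finalWindow Final window (ns) the schedule refers to, default 2.
#' @param seed Integer seed.
#' @return A \linkS4class{TrajectorySet}.
#' @export
genTrajectorySet <- function(nProtein = 40, nLigand = 10, nFrames = 100,
                             nReplicates = 10, dtNs = 0.1,
                             motion = c("stable", "drifting"),
                             jitterSigma = 0.3, driftStep = 0.2,
                             nHBonds = 2, occupancy = 1, finalWindow = 2,
                             seed = 1L) {
  motion <- match.arg(motion)
  stopifnot(nFrames >= 2, nProtein >= 6, nLigand >= nHBonds + 1)
  occupancy <- rep(occupancy, length.out = max(nHBonds, 1))
  if (any(occupancy < 0 | occupancy > 1)) stop("occupancies must be in [0,1]")

  # protein slab: 3 Angstrom grid, alternate atoms are C-alpha markers
  side <- ceiling(sqrt(nProtein / 2))
  gridPts <- expand.grid(x = seq_len(side), y = seq_len(side), z = 1:2)
  protXYZ <- as.matrix(gridPts[seq_len(nProtein), ]) * 3
  protName <- rep(c("CA", "N"), length.out = nProtein)
  # ligand cluster 5 Angstrom above the slab centre
  centre <- colMeans(protXYZ) + c(0, 0, 5)

  .withSeed(seed, {
    ligXYZ <- sweep(matrix(stats::rnorm(nLigand * 3, 0, 1.5), nLigand, 3),
                    2, centre, "+")
    # hydrogen-bond scaffolding: donor = protein N near interface with an
    # attached H pointing at a ligand acceptor O placed 2.8 Angstrom away
    donorIdx <- which(protName == "N")[seq_len(nHBonds)]
    hXYZ <- matrix(0, nHBonds, 3)
    for (b in seq_len(nHBonds)) {
      protXYZ[donorIdx[b], ] <- centre + c(3 * b, 0, -2)
      hXYZ[b, ] <- protXYZ[donorIdx[b], ] + c(0, 0, 1)       # H 1 A above
      ligXYZ[b, ] <- protXYZ[donorIdx[b], ] + c(0, 0, 2.8)   # acceptor 2.8 A
    }
    nAtoms <- nProtein + nHBonds + nLigand
    topo <- data.frame(
      name = c(protName, rep("H", nHBonds), rep("LIG", nLigand)),
      element = c(rep(c("C", "N"), length.out = nProtein),
                  rep("H", nHBonds),
                  c(rep("O", nHBonds), rep("C", nLigand - nHBonds))),
      segment = c(rep("protein", nProtein + nHBonds), rep("ligand", nLigand)),
      isHydrogen = c(rep(FALSE, nProtein), rep(TRUE, nHBonds),
                     rep(FALSE, nLigand)),
      isDonor = c(seq_len(nProtein) %in% donorIdx, rep(FALSE, nHBonds),
                  rep(FALSE, nLigand)),
      isAcceptor = c(rep(FALSE, nProtein + nHBonds),
                     seq_len(nLigand) <= nHBonds),
      hParent = c(rep(NA_integer_, nProtein), donorIdx,
                  rep(NA_integer_, nLigand)))
    reference <- rbind(protXYZ, hXYZ, ligXYZ)
    ligRows <- nProtein + nHBonds + seq_len(nLigand)
    accRows <- nProtein + nHBonds + seq_len(nHBonds)
    absentOffset <- c(0, 0, 6)  # acceptor displaced far outside criteria

    times <- dtNs * seq_len(nFrames)
    inWin <- which(times > max(times) - finalWindow + 1e-9)
    presentFrames <- lapply(seq_len(nHBonds), function(b) {
      k <- round(occupancy[b] * length(inWin))
      c(setdiff(seq_len(nFrames), inWin), inWin[seq_len(k)])
    })

    # a frozen stable complex (jitterSigma 0) stays exactly at the
    # reference, protein included, so PoseScore is exactly 0
    protJitter <- if (motion == "stable" && jitterSigma == 0) 0 else 0.05
    replicates <- vector("list", nReplicates)
    for (r in seq_len(nReplicates)) {
      arr <- array(0, c(nFrames, nAtoms, 3))
      drift <- c(0, 0, 0)
      for (f in seq_len(nFrames)) {
        frame <- reference
        if (protJitter > 0)
          frame[seq_len(nProtein), ] <- frame[seq_len(nProtein), ] +
            matrix(stats::rnorm(nProtein * 3, 0, protJitter), nProtein, 3)
        if (motion == "drifting") {
          dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
          drift <- drift + driftStep * dir
          frame[ligRows, ] <- sweep(frame[ligRows, , drop = FALSE], 2,
                                    drift, "+")
        } else if (jitterSigma > 0) {
          frame[ligRows, ] <- frame[ligRows, ] +
            matrix(stats::rnorm(nLigand * 3, 0, jitterSigma), nLigand, 3)
        }
        # hydrogen-bond geometry is scheduled, not stochastic
        for (b in seq_len(nHBonds)) {
          frame[donorIdx[b], ] <- reference[donorIdx[b], ]
          frame[nProtein + b, ] <- reference[nProtein + b, ]
          frame[accRows[b], ] <- if (f %in% presentFrames[[b]])
            reference[accRows[b], ] else reference[accRows[b], ] + absentOffset
        }
        arr[f, , ] <- frame
      }
      replicates[[r]] <- arr
    }
    methods::new("TrajectorySet", topology = topo, replicates = replicates,
                 times = rep(list(times), nReplicates),
                 reference = reference)
  })
}

#' Generate a noisy four-parameter logistic dose-response curve
#'
#' Default doses follow a 10-fold dilution series from 0.1 nM to
#' 10,000 nM (six doses).
#'
#' @param params A \linkS4class{FourPLParams} (log10 nM scale).
#' @param dosesNM Concentrations in nM.
#' @param sigma Gaussian noise SD on the response.
#' @param replicates Replicates per dose (default 1).
#' @param seed Integer seed.
#' @return A \linkS4class{DoseResponseCurve}.
#' @export
genDoseResponse <- function(params,
                            dosesNM = c(0.1, 1, 10, 100, 1000, 10000),
                            sigma = 0, replicates = 1, seed = 1L) {
  stopifnot(is(params, "FourPLParams"))
  x <- rep(log10(dosesNM), each = replicates)
  repl <- rep(seq_len(replicates), times = length(dosesNM))
  y0 <- fourPLResponse(x, params)
  y <- .withSeed(seed, y0 + stats::rnorm(length(x), 0, sigma))
  methods::new("DoseResponseCurve", x = x, y = y, replicate = as.integer(repl))
}
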