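# Shared fixtures, built in code and memoised per test session.

cpd6Smiles <- "CCc1nc(-c2cccc(C)c2)c(-c2ccnc(NC(=O)c3ccccc3)c2)s1"

.fixtureEnv <- new.env(parent = emptyenv())

memoFixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureEnv))
    assign(name, force(expr), envir = .fixtureEnv)
  get(name, envir = .fixtureEnv)
}

cpd6Record <- function() memoFixture("cpd6", {
  standardizeMolecule(moleculeFromSmiles(cpd6Smiles, "cpd6"))
})

# small molecule library + planted labels used by several gnn tests
smallLibrary <- function() memoFixture("smallLib", genMoleculeLibrary(40, seed = 101))

smallActivity <- function() memoFixture("smallAct",
  plantActivityLabels(smallLibrary(), sigma = 0.1, seed = 102))

smallGraphs <- function() memoFixture("smallGraphs",
  lapply(smallLibrary()@records, buildGraph))

# hand-written two-molecule SDF: ethanol (2D, z = 0) and a propane with
# genuine 3D coordinates
twoMolSDFText <- function() {
  c("ethanol", "  test", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.2000    1.2000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  1  0  0  0  0",
    "M  END", "$$$$",
    "propane3d", "  test", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.1000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.4000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.1000    1.3000    0.9000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  1  0  0  0  0",
    "M  END", "$$$$")
}

# Brute-force funnel oracle: plain sort-and-filter, independent of the
# package's implementation details.
oracleStage <- function(df, column, threshold, cap = NA) {
  keep <- df[!is.na(df[[column]]) & df[[column]] <= threshold, , drop = FALSE]
  if (!is.na(cap) && nrow(keep) > cap) {
    keep <- keep[order(keep[[column]], keep$id), , drop = FALSE]
    keep <- keep[seq_len(cap), , drop = FALSE]
  }
  sort(keep$id)
}

# Independent superposition oracle: Horn's quaternion method.
hornSuperpose <- function(ref, mobile) {
  cr <- colMeans(ref); cm <- colMeans(mobile)
  A <- sweep(mobile, 2, cm); B <- sweep(ref, 2, cr)
  M <- crossprod(A, B)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  N <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,     -Sxx-Syy+Szz), 4, 4)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  fitted <- sweep(A %*% t(R), 2, cr, "+")
  sqrt(mean(rowSums((fitted - ref)^2)))
}
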