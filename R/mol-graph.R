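#' @include AllClasses.R
NULL

.elementChannels <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P")
.hybChannels <- c("sp", "sp2", "sp3", "other")

.baseFeatureNames <- function() {
  c(paste0("elem_", c(.elementChannels, "other")),
    paste0("deg_", 1:6),
    "formal_charge", "aromatic", "in_ring", "implicit_h",
    paste0("hyb_", .hybChannels))
}

#' Convert a molecule into an attributed graph
#'
#' One node per heavy atom. Base node features: element one-hot
#' (C,N,O,S,F,Cl,Br,I,P,other), heavy-atom degree one-hot (1..6), formal
#' charge, aromaticity flag, ring flag, implicit hydrogen count and
#' hybridization one-hot (sp/sp2/sp3/other, derived from bond orders).
#' Edge features: bond-order one-hot (single/double/triple/aromatic) plus
#' conjugation and ring flags. Hydrogens are implicit.
#'
#' @param m A standardized \linkS4class{MoleculeRecord}.
#' @return A \linkS4class{MolGraph}.
#' @examples
#' buildGraph(moleculeFromSmiles("CC", "ethane"))
#' @export
buildGraph <- function(m) {
  stopifnot(is(m, "MoleculeRecord"))
  n <- nrow(m@atoms)
  if (n < 1) stop("molecule has no heavy atoms")
  fn <- .baseFeatureNames()
  X <- matrix(0, n, length(fn), dimnames = list(NULL, fn))
  ei <- match(m@atoms$element, .elementChannels)
  for (i in seq_len(n)) {
    X[i, if (is.na(ei[i])) "elem_other" else paste0("elem_", m@atoms$element[i])] <- 1
    X[i, paste0("deg_", max(1L, min(6L, m@atoms$degree[i])))] <- 1
  }
  X[, "formal_charge"] <- m@atoms$charge
  X[, "aromatic"] <- as.numeric(m@atoms$aromatic)
  X[, "in_ring"] <- as.numeric(m@atoms$inRing)
  X[, "implicit_h"] <- m@atoms$nH
  # hybridization from bond pattern
  nDouble <- integer(n); nTriple <- integer(n)
  for (k in seq_len(nrow(m@bonds))) {
    b <- m@bonds[k, ]
    if (b$order == 2L) {
      nDouble[b$a1] <- nDouble[b$a1] + 1L; nDouble[b$a2] <- nDouble[b$a2] + 1L
    } else if (b$order == 3L) {
      nTriple[b$a1] <- nTriple[b$a1] + 1L; nTriple[b$a2] <- nTriple[b$a2] + 1L
    }
  }
  hyb <- ifelse(nTriple > 0 | nDouble >= 2, "sp",
          ifelse(nDouble == 1 | m@atoms$aromatic, "sp2",
            ifelse(m@atoms$element %in% c("C", "N", "O", "S", "P"),
                   "sp3", "other")))
  for (i in seq_len(n)) X[i, paste0("hyb_", hyb[i])] <- 1

  nb <- nrow(m@bonds)
  E <- matrix(0, nb, 6,
              dimnames = list(NULL, c("bond_single", "bond_double",
                                      "bond_triple", "bond_aromatic",
                                      "conjugated", "in_ring")))
  edges <- matrix(0L, nb, 2)
  multAdj <- nDouble + nTriple + as.integer(m@atoms$aromatic)
  for (k in seq_len(nb)) {
    b <- m@bonds[k, ]
    edges[k, ] <- c(b$a1, b$a2)
    type <- if (b$aromatic) "bond_aromatic" else
      c("bond_single", "bond_double", "bond_triple")[min(b$order, 3L)]
    E[k, type] <- 1
    conj <- b$aromatic || (b$order >= 2L) ||
      (multAdj[b$a1] > 0 && multAdj[b$a2] > 0)
    E[k, "conjugated"] <- as.numeric(conj)
    E[k, "in_ring"] <- as.numeric(b$inRing)
  }
  methods::new("MolGraph", nodeFeatures = X, edges = edges, edgeFeatures = E,
               molId = m@id, featureNames = fn)
}

#' Fit a z-score scaler on global scalar columns
#'
#' Per-column mean and population (divide-by-n) standard deviation,
#' intended to be fitted on the training split only. Columns with zero
#' variance get a scale of 1, so their transformed values are exactly 0.
#'
#' @param values data.frame or matrix of numeric columns (>= 2 rows).
#' @return A \linkS4class{FeatureScaler}.
#' @examples
#' fitScaler(data.frame(score = c(0, 10)))
#' @export
fitScaler <- function(values) {
  values <- as.data.frame(values)
  if (nrow(values) < 2) stop("need at least 2 rows to fit a scaler")
  num <- vapply(values, is.numeric, logical(1))
  values <- values[, num, drop = FALSE]
  if (!ncol(values)) stop("no numeric columns")
  ctr <- vapply(values, mean, numeric(1))
  n <- nrow(values)
  sc <- vapply(values, function(v) sqrt(sum((v - mean(v))^2) / n), numeric(1))
  sc[sc < .Machine$double.eps^0.5] <- 1
  methods::new("FeatureScaler", center = ctr, scale = sc)
}

#' Apply a fitted scaler to a named vector or table of scalars
#'
#' @param scaler A \linkS4class{FeatureScaler}.
#' @param x Named numeric vector, or data.frame with the scaled columns.
#' @return Object of the same shape with z-scored values.
#' @export
scaleTransform <- function(scaler, x) {
  stopifnot(is(scaler, "FeatureScaler"))
  nms <- names(scaler@center)
  if (is.data.frame(x)) {
    missing <- setdiff(nms, names(x))
    if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
    for (cn in nms) x[[cn]] <- (x[[cn]] - scaler@center[[cn]]) / scaler@scale[[cn]]
    return(x)
  }
  missing <- setdiff(nms, names(x))
  if (length(missing)) stop("missing scalars: ", paste(missing, collapse = ", "))
  (x[nms] - scaler@center) / scaler@scale
}

#' Broadcast z-scored global scalars into every node of a graph
#'
#' Each node feature vector is extended by the z-scored scalars (identical
#' value on every node); base features and edges are untouched.
#'
#' @param g A \linkS4class{MolGraph}.
#' @param scalars Named numeric vector covering the scaler's columns
#'   (default names: external_score, tpsa, mw, rot_bonds).
#' @param scaler A fitted \linkS4class{FeatureScaler}.
#' @return A \linkS4class{MolGraph} with d + k node-feature columns.
#' @export
injectGlobalFeatures <- function(g, scalars, scaler) {
  stopifnot(is(g, "MolGraph"))
  if (anyNA(scalars)) stop("NaN/NA scalar for molecule ", g@molId)
  z <- scaleTransform(scaler, scalars)
  n <- nrow(g@nodeFeatures)
  extra <- matrix(rep(z, each = n), nrow = n,
                  dimnames = list(NULL, paste0("global_", names(scaler@center))))
  methods::new("MolGraph",
               nodeFeatures = cbind(g@nodeFeatures, extra),
               edges = g@edges, edgeFeatures = g@edgeFeatures,
               molId = g@molId,
               featureNames = c(g@featureNames, colnames(extra)))
}

#' Serialize a MolGraph to JSON (and back)
#'
#' @param g A \linkS4class{MolGraph}.
#' @param path Output file.
#' @return `graphToJson` invisibly returns the path; `graphFromJson`
#'   returns a \linkS4class{MolGraph}.
#' @export
graphToJson <- function(g, path) {
  stopifnot(is(g, "MolGraph"))
  obj <- list(mol_id = g@molId,
              feature_names = g@featureNames,
              node_features = unname(apply(g@nodeFeatures, 1, as.numeric,
                                           simplify = FALSE)),
              edges = unname(apply(g@edges, 1, as.integer, simplify = FALSE)),
              edge_feature_names = colnames(g@edgeFeatures),
              edge_features = unname(apply(g@edgeFeatures, 1, as.numeric,
                                           simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname graphToJson
#' @export
graphFromJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  asMat <- function(x, ncolDefault, integer = FALSE) {
    m <- if (is.list(x)) do.call(rbind, x) else
      if (is.null(dim(x))) matrix(x, nrow = as.integer(length(x) > 0)) else x
    if (is.null(m) || !length(m)) m <- matrix(0, 0, ncolDefault)
    storage.mode(m) <- if (integer) "integer" else "double"
    m
  }
  X <- asMat(obj$node_features, length(obj$feature_names))
  colnames(X) <- obj$feature_names
  edges <- asMat(obj$edges, 2, integer = TRUE)
  E <- asMat(obj$edge_features, length(obj$edge_feature_names))
  colnames(E) <- obj$edge_feature_names
  methods::new("MolGraph", nodeFeatures = X, edges = edges, edgeFeatures = E,
               molId = obj$mol_id, featureNames = obj$feature_names)
}
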