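#' @include AllClasses.R
NULL

# Internal neural-network machinery for the GAT + MLP regressor.
# Everything runs on packed graph batches: node features of all graphs in
# a batch are stacked row-wise, edges are re-indexed into the stacked
# space (both directions plus self-loops), and attention softmax is
# computed per destination node with rowsum() group reductions. All math
# is plain BLAS; no external deep-learning runtime is involved.

.lrelu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
.lreluGrad <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)
.elu <- function(x) ifelse(x > 0, x, expm1(x))
.eluGradFromOut <- function(out) ifelse(out > 0, 1, out + 1)
.relu <- function(x) pmax(x, 0)

# Stack a list of MolGraph into one packed structure.
.packGraphs <- function(graphs) {
  nG <- length(graphs)
  nNodes <- vapply(graphs, function(g) nrow(g@nodeFeatures), integer(1))
  offsets <- c(0L, cumsum(nNodes))[seq_len(nG)]
  X <- do.call(rbind, lapply(graphs, function(g) g@nodeFeatures))
  src <- vector("list", nG); dst <- vector("list", nG)
  for (g in seq_len(nG)) {
    e <- graphs[[g]]@edges
    off <- offsets[g]
    loops <- seq_len(nNodes[g]) + off
    if (nrow(e)) {
      s <- c(e[, 1] + off, e[, 2] + off, loops)
      d <- c(e[, 2] + off, e[, 1] + off, loops)
    } else {
      s <- loops; d <- loops
    }
    src[[g]] <- s; dst[[g]] <- d
  }
  nEdges <- vapply(src, length, integer(1))
  list(X = X,
       src = unlist(src), dst = unlist(dst),
       graphOfNode = rep(seq_len(nG), nNodes),
       graphOfEdge = rep(seq_len(nG), nEdges),
       nNodes = nNodes, offsets = offsets,
       ids = vapply(graphs, function(g) g@molId, character(1)))
}

# Subset a packed structure to a batch of graph indices (order preserved).
.packSubset <- function(pack, gIdx) {
  if (length(gIdx) == length(pack$nNodes) &&
      all(gIdx == seq_along(pack$nNodes))) {
    return(c(pack, list(localGraph = seq_along(gIdx))))
  }
  nodeKeep <- pack$graphOfNode %in% gIdx
  edgeKeep <- pack$graphOfEdge %in% gIdx
  nNodes <- pack$nNodes[gIdx]
  newOff <- c(0L, cumsum(nNodes))[seq_along(gIdx)]
  # shift per graph: new index = old index - oldOffset + newOffset
  delta <- integer(length(pack$nNodes))
  delta[gIdx] <- newOff - pack$offsets[gIdx]
  list(X = pack$X[nodeKeep, , drop = FALSE],
       src = pack$src[edgeKeep] + delta[pack$graphOfEdge[edgeKeep]],
       dst = pack$dst[edgeKeep] + delta[pack$graphOfEdge[edgeKeep]],
       graphOfNode = match(pack$graphOfNode[nodeKeep], gIdx),
       nNodes = nNodes, offsets = newOff,
       ids = pack$ids[gIdx])
}

.glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

# Initialize all weights; call with the RNG already seeded.
.initWeights <- function(mcfg, inputDim) {
  L <- mcfg@nGatLayers; Hh <- mcfg@attentionHeads
  dh <- mcfg@hiddenDim %/% Hh
  w <- list()
  din <- inputDim
  for (l in seq_len(L)) {
    for (h in seq_len(Hh)) {
      w[[sprintf("L%dH%d_W", l, h)]] <- .glorot(din, dh)
      w[[sprintf("L%dH%d_aS", l, h)]] <- .glorot(dh, 1)[, 1]
      w[[sprintf("L%dH%d_aD", l, h)]] <- .glorot(dh, 1)[, 1]
    }
    din <- mcfg@hiddenDim
  }
  dims <- c(mcfg@hiddenDim, mcfg@mlpDims, 1L)
  for (j in seq_len(length(dims) - 1L)) {
    w[[sprintf("M%d_W", j)]] <- .glorot(dims[j], dims[j + 1])
    w[[sprintf("M%d_b", j)]] <- numeric(dims[j + 1])
  }
  w
}

# Group sum over 1..N (every node has a self-loop so all groups occur).
.groupSum <- function(v, idx) {
  if (is.matrix(v)) {
    out <- rowsum(v, idx)
    out[order(as.numeric(rownames(out))), , drop = FALSE]
  } else {
    out <- rowsum(v, idx)
    as.vector(out[order(as.numeric(rownames(out))), 1])
  }
}

# Forward pass. Returns predictions and (optionally) caches for backprop.
.gnnForward <- function(w, pack, mcfg, keepCache = FALSE, dropMask = NULL) {
  L <- mcfg@nGatLayers; Hh <- mcfg@attentionHeads
  src <- pack$src; dst <- pack$dst
  H <- pack$X
  cache <- if (keepCache) list(layers = vector("list", L)) else NULL
  for (l in seq_len(L)) {
    heads <- vector("list", Hh)
    hc <- if (keepCache) vector("list", Hh) else NULL
    for (h in seq_len(Hh)) {
      W <- w[[sprintf("L%dH%d_W", l, h)]]
      aS <- w[[sprintf("L%dH%d_aS", l, h)]]
      aD <- w[[sprintf("L%dH%d_aD", l, h)]]
      Z <- H %*% W
      preS <- as.vector(Z %*% aS); preD <- as.vector(Z %*% aD)
      eRaw <- preS[src] + preD[dst]
      e <- .lrelu(eRaw)
      ex <- exp(e - max(e))
      denom <- .groupSum(ex, dst)
      alpha <- ex / denom[dst]
      agg <- .groupSum(alpha * Z[src, , drop = FALSE], dst)
      out <- .elu(agg)
      heads[[h]] <- out
      if (keepCache)
        hc[[h]] <- list(Z = Z, eRaw = eRaw, alpha = alpha, out = out)
    }
    Hnext <- do.call(cbind, heads)
    if (!is.null(dropMask) && l <= length(dropMask) && !is.null(dropMask[[l]]))
      Hnext <- Hnext * dropMask[[l]]
    if (keepCache) cache$layers[[l]] <- list(Hin = H, heads = hc)
    H <- Hnext
  }
  # readout
  nG <- length(pack$nNodes)
  if (mcfg@readout == "mean") {
    R <- .groupSum(H, pack$graphOfNode) / pack$nNodes
  } else if (mcfg@readout == "sum") {
    R <- .groupSum(H, pack$graphOfNode)
  } else {
    R <- matrix(-Inf, nG, ncol(H))
    argmax <- matrix(0L, nG, ncol(H))
    for (g in seq_len(nG)) {
      rows <- which(pack$graphOfNode == g)
      sub <- H[rows, , drop = FALSE]
      am <- apply(sub, 2, which.max)
      R[g, ] <- sub[cbind(am, seq_len(ncol(sub)))]
      argmax[g, ] <- rows[am]
    }
    if (keepCache) cache$argmax <- argmax
  }
  if (keepCache) cache$Hfinal <- H
  # MLP
  nM <- sum(grepl("^M\\d+_W$", names(w)))
  A <- R
  acts <- if (keepCache) list(A) else NULL
  for (j in seq_len(nM)) {
    S <- sweep(A %*% w[[sprintf("M%d_W", j)]], 2,
               w[[sprintf("M%d_b", j)]], "+")
    A <- if (j < nM) .relu(S) else S
    if (keepCache) acts[[j + 1]] <- A
  }
  if (keepCache) { cache$acts <- acts; cache$R <- R }
  list(yhat = as.vector(A), cache = cache)
}

# Backward pass: returns gradients for all weights (MSE loss).
.gnnBackward <- function(w, pack, mcfg, fw, y, dropMask = NULL) {
  L <- mcfg@nGatLayers; Hh <- mcfg@attentionHeads
  dh <- mcfg@hiddenDim %/% Hh
  src <- pack$src; dst <- pack$dst
  cache <- fw$cache
  nG <- length(pack$nNodes)
  grads <- list()

  dyhat <- matrix(2 * (fw$yhat - y) / nG, ncol = 1)
  nM <- sum(grepl("^M\\d+_W$", names(w)))
  dA <- dyhat
  for (j in rev(seq_len(nM))) {
    Ain <- cache$acts[[j]]
    if (j < nM) {
      Aout <- cache$acts[[j + 1]]
      dA <- dA * (Aout > 0)
    }
    grads[[sprintf("M%d_W", j)]] <- crossprod(Ain, dA)
    grads[[sprintf("M%d_b", j)]] <- colSums(dA)
    dA <- dA %*% t(w[[sprintf("M%d_W", j)]])
  }
  dR <- dA

  if (mcfg@readout == "mean") {
    dH <- dR[pack$graphOfNode, , drop = FALSE] / pack$nNodes[pack$graphOfNode]
  } else if (mcfg@readout == "sum") {
    dH <- dR[pack$graphOfNode, , drop = FALSE]
  } else {
    dH <- matrix(0, nrow(cache$Hfinal), ncol(cache$Hfinal))
    for (g in seq_len(nG))
      dH[cbind(cache$argmax[g, ], seq_len(ncol(dH)))] <-
        dH[cbind(cache$argmax[g, ], seq_len(ncol(dH)))] + dR[g, ]
  }

  for (l in rev(seq_len(L))) {
    lc <- cache$layers[[l]]
    if (!is.null(dropMask) && l <= length(dropMask) &&
        !is.null(dropMask[[l]]))
      dH <- dH * dropMask[[l]]
    Hin <- lc$Hin
    dHin <- matrix(0, nrow(Hin), ncol(Hin))
    for (h in seq_len(Hh)) {
      hcc <- lc$heads[[h]]
      cols <- ((h - 1) * dh + 1):(h * dh)
      dOut <- dH[, cols, drop = FALSE]
      dAgg <- dOut * .eluGradFromOut(hcc$out)
      Z <- hcc$Z; alpha <- hcc$alpha
      dAggDst <- dAgg[dst, , drop = FALSE]
      Zsrc <- Z[src, , drop = FALSE]
      dalpha <- rowSums(dAggDst * Zsrc)
      dZ <- .groupSum(alpha * dAggDst, src)
      tmp <- .groupSum(alpha * dalpha, dst)
      de <- alpha * (dalpha - tmp[dst])
      de <- de * .lreluGrad(hcc$eRaw)
      dPreS <- .groupSum(de, src)
      dPreD <- .groupSum(de, dst)
      aS <- w[[sprintf("L%dH%d_aS", l, h)]]
      aD <- w[[sprintf("L%dH%d_aD", l, h)]]
      grads[[sprintf("L%dH%d_aS", l, h)]] <- as.vector(crossprod(Z, dPreS))
      grads[[sprintf("L%dH%d_aD", l, h)]] <- as.vector(crossprod(Z, dPreD))
      dZ <- dZ + outer(dPreS, aS) + outer(dPreD, aD)
      W <- w[[sprintf("L%dH%d_W", l, h)]]
      grads[[sprintf("L%dH%d_W", l, h)]] <- crossprod(Hin, dZ)
      dHin <- dHin + dZ %*% t(W)
    }
    dH <- dHin
  }
  grads
}

.adamInit <- function(w) {
  list(m = lapply(w, function(x) x * 0), v = lapply(w, function(x) x * 0),
       t = 0L)
}

.adamStep <- function(w, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(w)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, state = state)
}
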