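# Hand-written backward passes. Gradients mirror the nested weight list so
# the optimizer can walk both structures in parallel.

# rowsum that scatters into a fixed number of groups (missing groups -> 0).
scatterRowsum <- function(values, groups, n) {
  rs <- rowsum(values, groups)
  out <- matrix(0, n, ncol(values))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

egclBackward <- function(dHout, cc, wl) {
  D <- cc$D
  n <- cc$n
  k <- cc$k
  dh <- dHout                                  # residual identity path
  dU <- dHout
  dA2 <- dU %*% t(wl$hW2)
  g <- list(hW2 = crossprod(cc$A2, dU), hb2 = colSums(dU))
  dZ2 <- dA2 * (cc$S2 * (1 + cc$Z2 * (1 - cc$S2)))
  g$hW1 <- crossprod(cc$Xh, dZ2)
  g$hb1 <- colSums(dZ2)
  dXh <- dZ2 %*% t(wl$hW1)
  dh <- dh + dXh[, seq_len(D), drop = FALSE]
  dAgg <- dXh[, D + seq_len(D), drop = FALSE]
  dM <- dAgg[cc$iE, , drop = FALSE]
  dA1 <- dM %*% t(wl$eW2)
  g$eW2 <- crossprod(cc$A1, dM)
  g$eb2 <- colSums(dM)
  dZ1 <- dA1 * (cc$S1 * (1 + cc$Z1 * (1 - cc$S1)))
  g$eW1 <- crossprod(cc$Xe, dZ1)
  g$eb1 <- colSums(dZ1)
  dXe <- dZ1 %*% t(wl$eW1)
  dhi <- dXe[seq_len(n), seq_len(D), drop = FALSE]
  if (k > 1L) for (s in 2:k)
    dhi <- dhi + dXe[(s - 1L) * n + seq_len(n), seq_len(D), drop = FALSE]
  dh <- dh + dhi
  dh <- dh + scatterRowsum(dXe[, D + seq_len(D), drop = FALSE], cc$jE, cc$n)
  g <- g[c("eW1", "eb1", "eW2", "eb2", "hW1", "hb1", "hW2", "hb2")]
  list(dh = dh, grads = g)
}

trunkBackward <- function(dh, tr, model) {
  w <- model@weights
  nL <- model@config@nLayers
  layerGrads <- vector("list", nL)
  for (l in rev(seq_len(nL))) {
    r <- egclBackward(dh, tr$caches[[l]], w$layers[[l]])
    dh <- r$dh
    layerGrads[[l]] <- r$grads
  }
  list(proj = list(W = crossprod(tr$X, dh), b = colSums(dh)),
       layers = layerGrads)
}

# Backward through the residue head given dL/dz at the final pre-sigmoid
# logits (length-N vector).
residueBackward <- function(dz, fw, model) {
  w <- model@weights
  dZ2 <- matrix(dz, ncol = 1)
  g <- list(decoder = list())
  g$decoder$W2 <- crossprod(fw$decA1, dZ2)
  g$decoder$b2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(w$decoder$W2)
  dZ1 <- dA1 * siluGrad(fw$decZ1)
  g$decoder$W1 <- crossprod(fw$trunk$h, dZ1)
  g$decoder$b1 <- colSums(dZ1)
  dh <- dZ1 %*% t(w$decoder$W1)
  tg <- trunkBackward(dh, fw$trunk, model)
  list(proj = tg$proj, layers = tg$layers,
       decoder = g$decoder[c("W1", "b1", "W2", "b2")])
}

conv2dBackward <- function(dY, cc, Wmat) {
  dYm <- matrix(dY, cc$Ho * cc$Wo, ncol(Wmat))
  gW <- crossprod(cc$P, dYm)
  gb <- colSums(dYm)
  dP <- dYm %*% t(Wmat)
  k2 <- ncol(cc$IDX)
  dA <- array(0, c(cc$H, cc$W, cc$Cin))
  idxv <- as.vector(cc$IDX) + 1L   # 1 = padding bucket
  for (ch in seq_len(cc$Cin)) {
    vals <- as.vector(dP[, (ch - 1L) * k2 + seq_len(k2)])
    acc <- numeric(cc$H * cc$W + 1L)
    rs <- rowsum(vals, idxv)
    acc[as.integer(rownames(rs))] <- rs
    dA[, , ch] <- acc[-1L]
  }
  list(dA = dA, W = gW, b = gb)
}

adaptivePoolBackward <- function(dP, L) {
  targetLen <- nrow(dP)
  dH <- matrix(0, L, ncol(dP))
  for (t in seq_len(targetLen)) {
    rows <- (floor((t - 1) * L / targetLen) + 1):ceiling(t * L / targetLen)
    dH[rows, ] <- dH[rows, , drop = FALSE] +
      matrix(dP[t, ] / length(rows), length(rows), ncol(dP), byrow = TRUE)
  }
  dH
}

# Backward through the protein head given scalar dL/dz at the final logit.
proteinBackward <- function(dz, fw, model) {
  cfg <- model@config
  w <- model@weights
  g <- list()
  dZ3 <- matrix(dz, 1, 1)
  g$dense3 <- list(W = crossprod(fw$B2, dZ3), b = colSums(dZ3))
  dB2 <- dZ3 %*% t(w$dense3$W)
  dZ2 <- dB2 * siluGrad(fw$Z2)
  g$dense2 <- list(W = crossprod(fw$B1, dZ2), b = colSums(dZ2))
  dB1 <- dZ2 %*% t(w$dense2$W)
  dZ1 <- dB1 * siluGrad(fw$Z1)
  g$dense1 <- list(W = crossprod(fw$flat, dZ1), b = colSums(dZ1))
  dFlat <- dZ1 %*% t(w$dense1$W)
  dA2 <- array(as.vector(dFlat), dim(fw$A2))
  dY2 <- dA2 * siluGrad(fw$Y2)
  cb2 <- conv2dBackward(dY2, fw$conv2, w$conv2$W)
  g$conv2 <- list(W = cb2$W, b = cb2$b)
  dA1 <- cb2$dA * siluGrad(fw$Y1)
  cb1 <- conv2dBackward(dA1, fw$conv1, w$conv1$W)
  g$conv1 <- list(W = cb1$W, b = cb1$b)
  dP <- matrix(as.vector(cb1$dA), cfg@poolLen, cfg@embedDim)
  dh <- adaptivePoolBackward(dP, nrow(fw$trunk$h))
  tg <- trunkBackward(dh, fw$trunk, model)
  list(proj = tg$proj, layers = tg$layers, conv1 = g$conv1, conv2 = g$conv2,
       dense1 = g$dense1, dense2 = g$dense2, dense3 = g$dense3)
}
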