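# Residue-graph construction: k-nearest-neighbour topology, local frames,
# and rigid-motion-invariant edge features.

#' Edge feature configuration
#'
#' @param nRbf number of radial basis functions (default 16).
#' @param dMin,dMax range of the RBF centers in Angstrom (default 0-20).
#' @param includeDirection include the local-frame unit direction (3 values).
#' @param includeOrientation include the relative-orientation quaternion
#'   (4 values, scalar first, sign fixed by a nonnegative scalar part).
#' @return a list with class `edgeFeatureConfig`. With both geometric
#'   blocks enabled the edge feature width is `nRbf + 3 + 4`.
#' @export
edgeFeatureConfig <- function(nRbf = 16L, dMin = 0, dMax = 20,
                              includeDirection = TRUE,
                              includeOrientation = TRUE) {
  stopifnot(nRbf >= 1L, dMax > dMin)
  structure(list(nRbf = as.integer(nRbf), dMin = dMin, dMax = dMax,
                 includeDirection = includeDirection,
                 includeOrientation = includeOrientation),
            class = "edgeFeatureConfig")
}

#' Directed k-nearest-neighbour graph
#'
#' Row i of the result holds the indices of the min(k, N-1) nearest other
#' nodes by Euclidean distance, in ascending distance order, ties broken by
#' the lower index. The graph is directed: j being a neighbour of i does
#' not imply the converse.
#'
#' @param coords numeric N x 3 matrix.
#' @param k requested neighbourhood size.
#' @return integer N x min(k, N-1) matrix.
#' @export
buildKnnGraph <- function(coords, k) {
  n <- nrow(coords)
  if (n < 2L) stop("degenerate graph: need at least 2 nodes")
  stopifnot(k >= 1L)
  kk <- min(k, n - 1L)
  d <- crossDist(coords, coords)
  diag(d) <- Inf
  nb <- matrix(0L, n, kk)
  idx <- seq_len(n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], idx)   # secondary key: lower index wins ties
    nb[i, ] <- ord[seq_len(kk)]
  }
  nb
}

#' Local orthonormal frames from a residue trace
#'
#' Frame i is built by Gram-Schmidt on the sequence-adjacent difference
#' vectors (coords[i+1] - coords[i], coords[i-1] - coords[i]), the third
#' axis being their cross product; terminal residues copy the frame of
#' their unique sequence neighbour. Every frame is orthonormal with
#' determinant +1, and rotating the coordinates by R maps each frame to
#' R times the frame.
#'
#' @param coords numeric N x 3 matrix, N >= 3.
#' @return numeric N x 3 x 3 array; `frames[i, , ]` has the axes as columns.
#' @export
localFrames <- function(coords) {
  n <- nrow(coords)
  if (n < 3L) stop("need at least 3 residues to build local frames")
  frames <- array(0, c(n, 3, 3))
  for (i in 2:(n - 1)) {
    u1 <- normalize3(coords[i + 1, ] - coords[i, ], "frame (coincident residues)")
    v <- coords[i - 1, ] - coords[i, ]
    v <- v - sum(v * u1) * u1
    u2 <- normalize3(v, "frame (collinear residues)")
    frames[i, , ] <- cbind(u1, u2, cross3(u1, u2))
  }
  frames[1, , ] <- frames[2, , ]
  frames[n, , ] <- frames[n - 1, , ]
  frames
}

#' Radial basis encoding of a distance
#'
#' Component j is `exp(-((d - c_j) / sigma)^2)` with centers evenly spaced
#' on `[dMin, dMax]` and `sigma` equal to the center spacing.
#'
#' @param d numeric vector of distances (Angstrom, >= 0).
#' @param nRbf number of bases.
#' @param dMin,dMax center range.
#' @return numeric matrix `length(d)` x `nRbf`.
#' @export
rbfEncode <- function(d, nRbf = 16L, dMin = 0, dMax = 20) {
  stopifnot(nRbf >= 1L, dMax > dMin, all(d >= 0))
  centers <- seq(dMin, dMax, length.out = nRbf)
  sigma <- if (nRbf > 1L) centers[2] - centers[1] else dMax - dMin
  exp(-((outer(d, centers, "-")) / sigma)^2)
}

# Vectorized rotation-matrix -> unit quaternion (scalar first, w >= 0).
# Rows of r9 are the 9 entries R11,R21,R31,R12,...,R33 (column major).
rotationToQuaternion <- function(r9) {
  R11 <- r9[, 1]; R21 <- r9[, 2]; R31 <- r9[, 3]
  R12 <- r9[, 4]; R22 <- r9[, 5]; R32 <- r9[, 6]
  R13 <- r9[, 7]; R23 <- r9[, 8]; R33 <- r9[, 9]
  m <- length(R11)
  q <- matrix(0, m, 4)
  t0 <- 1 + R11 + R22 + R33
  t1 <- 1 + R11 - R22 - R33
  t2 <- 1 - R11 + R22 - R33
  t3 <- 1 - R11 - R22 + R33
  branch <- max.col(cbind(t0, t1, t2, t3), ties.method = "first")
  b <- branch == 1L
  if (any(b)) {
    s <- 2 * sqrt(t0[b])
    q[b, ] <- cbind(s / 4, (R32[b] - R23[b]) / s, (R13[b] - R31[b]) / s,
                    (R21[b] - R12[b]) / s)
  }
  b <- branch == 2L
  if (any(b)) {
    s <- 2 * sqrt(t1[b])
    q[b, ] <- cbind((R32[b] - R23[b]) / s, s / 4, (R12[b] + R21[b]) / s,
                    (R13[b] + R31[b]) / s)
  }
  b <- branch == 3L
  if (any(b)) {
    s <- 2 * sqrt(t2[b])
    q[b, ] <- cbind((R13[b] - R31[b]) / s, (R12[b] + R21[b]) / s, s / 4,
                    (R23[b] + R32[b]) / s)
  }
  b <- branch == 4L
  if (any(b)) {
    s <- 2 * sqrt(t3[b])
    q[b, ] <- cbind((R21[b] - R12[b]) / s, (R13[b] + R31[b]) / s,
                    (R23[b] + R32[b]) / s, s / 4)
  }
  q <- q / sqrt(rowSums(q^2))
  neg <- q[, 1] < 0
  q[neg, ] <- -q[neg, , drop = FALSE]
  q
}

#' Invariant edge features
#'
#' For each directed edge (i, j) the feature vector concatenates the radial
#' basis encoding of the distance, the unit direction to j expressed in the
#' local frame of i (3 values), and the quaternion of the relative rotation
#' `t(frame_i) %*% frame_j` (4 values, scalar first, nonnegative scalar
#' part). All components are invariant under any global rotation and
#' translation of the coordinates.
#'
#' @param coords numeric N x 3 matrix.
#' @param frames N x 3 x 3 array from [localFrames()].
#' @param neighbors integer N x k matrix from [buildKnnGraph()].
#' @param config an [edgeFeatureConfig()].
#' @return numeric N x k x E array.
#' @export
edgeFeatures <- function(coords, frames, neighbors,
                         config = edgeFeatureConfig()) {
  n <- nrow(coords)
  k <- ncol(neighbors)
  iE <- rep(seq_len(n), each = k)
  jE <- as.vector(t(neighbors))
  delta <- coords[jE, , drop = FALSE] - coords[iE, , drop = FALSE]
  dist <- sqrt(rowSums(delta^2))
  if (any(dist < 1e-8)) stop("degenerate edge: coincident node coordinates")
  blocks <- list(rbfEncode(dist, config$nRbf, config$dMin, config$dMax))
  if (config$includeDirection) {
    unit <- delta / dist
    dirLocal <- sapply(1:3, function(a)
      rowSums(frames[iE, , a, drop = FALSE][, , 1] * unit))
    blocks <- c(blocks, list(dirLocal))
  }
  if (config$includeOrientation) {
    r9 <- matrix(0, length(iE), 9)
    col <- 0L
    for (b in 1:3) for (a in 1:3) {
      col <- col + 1L
      r9[, col] <- rowSums(frames[iE, , a, drop = FALSE][, , 1] *
                           frames[jE, , b, drop = FALSE][, , 1])
    }
    blocks <- c(blocks, list(rotationToQuaternion(r9)))
  }
  flat <- do.call(cbind, blocks)
  ef <- array(0, c(n, k, ncol(flat)))
  for (e in seq_len(ncol(flat)))
    ef[, , e] <- matrix(flat[, e], n, k, byrow = TRUE)
  ef
}

#' Build the full residue graph for a structure
#'
#' Combines the C-beta trace, the per-residue embeddings, and the invariant
#' edge features into a [ResidueGraph-class], computing neighbour lists and
#' edge tensors for every requested k (the residue head needs k = 16; the
#' protein head the staged 10/20/40/60 schedule).
#'
#' @param structure a [ProteinStructure-class].
#' @param nodeFeats numeric N x D embedding matrix (e.g. from
#'   [stubEmbedder()] or any embedder satisfying the contract).
#' @param ks integer vector of neighbourhood sizes to precompute.
#' @param config an [edgeFeatureConfig()].
#' @return a [ResidueGraph-class].
#' @export
buildResidueGraph <- function(structure, nodeFeats, ks = 16L,
                              config = edgeFeatureConfig()) {
  coords <- cbCoords(structure)
  stopifnot(nrow(nodeFeats) == nrow(coords))
  frames <- localFrames(coords)
  ks <- sort(unique(as.integer(ks)))
  neighbors <- edgeFeats <- list()
  for (k in ks) {
    nb <- buildKnnGraph(coords, k)
    neighbors[[as.character(k)]] <- nb
    edgeFeats[[as.character(k)]] <- edgeFeatures(coords, frames, nb, config)
  }
  new("ResidueGraph", coords = coords, nodeFeats = nodeFeats,
      neighbors = neighbors, edgeFeats = edgeFeats, frames = frames)
}

#' Deterministic stub embedder
#'
#' A stand-in for a protein language model satisfying the embedder
#' contract: a deterministic matrix of unit-variance pseudo-random values
#' keyed by (residue letter, position, seed), one 1280-value row per
#' residue. When `signalLabels` is given, channel 1 of labeled residues is
#' shifted by `signalStrength`, planting a learnable signal correlated with
#' the binding labels.
#'
#' @param sequence one-letter amino-acid string.
#' @param seed integer seed.
#' @param signalLabels optional 0/1 vector of length `nchar(sequence)`.
#' @param signalStrength shift applied to channel 1 of labeled residues.
#' @param dim embedding width (default 1280).
#' @return numeric matrix `nchar(sequence)` x `dim`.
#' @export
stubEmbedder <- function(sequence, seed = 1L, signalLabels = NULL,
                         signalStrength = 0, dim = 1280L) {
  letters1 <- strsplit(sequence, "")[[1]]
  n <- length(letters1)
  if (!is.null(signalLabels)) stopifnot(length(signalLabels) == n)
  out <- matrix(0, n, dim)
  for (i in seq_len(n)) {
    key <- seedKey(seed, i, utf8ToInt(letters1[i]))
    out[i, ] <- withSeed(key, stats::rnorm(dim))
  }
  if (!is.null(signalLabels))
    out[, 1] <- out[, 1] + signalStrength * as.numeric(signalLabels)
  out
}

#' Embedder factory for the workflow functions
#'
#' Returns a function `f(sequence) -> matrix` closing over the stub
#' embedder settings; any function with the same signature (e.g. an
#' adapter around a real language model) can be used in its place.
#'
#' @inheritParams stubEmbedder
#' @export
makeStubEmbedder <- function(seed = 1L, dim = 1280L) {
  force(seed); force(dim)
  function(sequence) stubEmbedder(sequence, seed = seed, dim = dim)
}
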