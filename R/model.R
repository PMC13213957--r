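# Model configurations, weight construction, and forward passes for the
# residue-level (binding-site) and protein-level (binder) heads.
#
# The trunk shared by both heads: a linear projection of the 1280-dim input
# embeddings to the trunk width, then residual graph-convolution layers.
# Each layer computes messages m_ij = MLP_e([h_i, h_j, e_ij]) over the k
# neighbours, aggregates a_i = sum_j m_ij, and updates
# h_i' = h_i + MLP_h([h_i, a_i]). Node coordinates are never modified; all
# geometric information enters through the invariant edge features, which
# makes every output invariant under rigid motion of the structure.

#' Residue-head model configuration
#'
#' Defaults describe the full-size binding-site predictor: 12 residual
#' graph-convolution layers at width 128 over fixed 16-nearest-neighbour
#' graphs, followed by a two-layer dense decoder ending in a per-residue
#' sigmoid. The hidden widths (edge MLP 161, node MLP 136, decoder 129) are
#' calibrated so the model has exactly 1,600,387 trainable parameters.
#'
#' @param nLayers,embedDim,inputDim trunk depth/width and embedder width.
#' @param k neighbourhood size used by every layer.
#' @param edgeHidden,nodeHidden,decoderHidden hidden MLP widths.
#' @param nRbf,dMin,dMax radial-basis edge encoding.
#' @param initSigma weight-initialization standard deviation.
#' @return a [ModelConfig-class] with `head = "residue"`.
#' @export
residueModelConfig <- function(nLayers = 12L, embedDim = 128L,
                               inputDim = 1280L, k = 16L,
                               edgeHidden = 161L, nodeHidden = 136L,
                               decoderHidden = 129L, nRbf = 16L,
                               dMin = 0, dMax = 20, initSigma = 0.02) {
  new("ModelConfig", head = "residue", nLayers = as.integer(nLayers),
      embedDim = as.integer(embedDim), inputDim = as.integer(inputDim),
      kSchedule = rep(as.integer(k), nLayers),
      edgeHidden = as.integer(edgeHidden), nodeHidden = as.integer(nodeHidden),
      decoderHidden = as.integer(decoderHidden), poolLen = 1L,
      convChannels = integer(0), convKernel = 3L, convStride = 2L,
      denseWidths = integer(0), nRbf = as.integer(nRbf),
      dMin = dMin, dMax = dMax, initSigma = as.numeric(initSigma))
}

#' Protein-head model configuration
#'
#' Defaults describe the full-size binder classifier: the same 12-layer
#' width-128 trunk but with a staged neighbourhood schedule (layers 1-3 use
#' 10 neighbours, 4-6 use 20, 7-9 use 40, 10-12 use 60), then adaptive
#' pooling of the residue dimension to length 150, two 3x3 stride-2
#' convolution layers over the resulting 150 x 128 single-channel map, and
#' three dense layers to one sigmoid. Conv channels (8, 8) and dense widths
#' (22, 24) are calibrated so the model has exactly 1,798,895 trainable
#' parameters.
#'
#' @inheritParams residueModelConfig
#' @param kSchedule per-layer neighbourhood sizes (length `nLayers`).
#' @param poolLen pooled sequence length.
#' @param convChannels channel counts of the two convolution layers.
#' @param convKernel,convStride square kernel size and stride (padding 1).
#' @param denseWidths the two hidden dense widths.
#' @return a [ModelConfig-class] with `head = "protein"`.
#' @export
proteinModelConfig <- function(nLayers = 12L, embedDim = 128L,
                               inputDim = 1280L,
                               kSchedule = rep(c(10L, 20L, 40L, 60L),
                                               each = nLayers / 4),
                               edgeHidden = 161L, nodeHidden = 136L,
                               poolLen = 150L, convChannels = c(8L, 8L),
                               convKernel = 3L, convStride = 2L,
                               denseWidths = c(22L, 24L), nRbf = 16L,
                               dMin = 0, dMax = 20, initSigma = 0.02) {
  new("ModelConfig", head = "protein", nLayers = as.integer(nLayers),
      embedDim = as.integer(embedDim), inputDim = as.integer(inputDim),
      kSchedule = as.integer(kSchedule),
      edgeHidden = as.integer(edgeHidden), nodeHidden = as.integer(nodeHidden),
      decoderHidden = 1L, poolLen = as.integer(poolLen),
      convChannels = as.integer(convChannels),
      convKernel = as.integer(convKernel), convStride = as.integer(convStride),
      denseWidths = as.integer(denseWidths), nRbf = as.integer(nRbf),
      dMin = dMin, dMax = dMax, initSigma = as.numeric(initSigma))
}

edgeFeatureWidth <- function(config) config@nRbf + 3L + 4L

convOutDim <- function(x, kernel, stride, pad = 1L) {
  as.integer(floor((x + 2L * pad - kernel) / stride) + 1L)
}

# Flattened width of the protein head's conv output.
flattenWidth <- function(config) {
  h <- convOutDim(config@poolLen, config@convKernel, config@convStride)
  w <- convOutDim(config@embedDim, config@convKernel, config@convStride)
  h2 <- convOutDim(h, config@convKernel, config@convStride)
  w2 <- convOutDim(w, config@convKernel, config@convStride)
  h2 * w2 * config@convChannels[2]
}

# Zero-filled weight template in a fixed traversal order.
weightTemplate <- function(config) {
  D <- config@embedDim
  E <- edgeFeatureWidth(config)
  w <- list(proj = list(W = matrix(0, config@inputDim, D), b = numeric(D)))
  w$layers <- lapply(seq_len(config@nLayers), function(l) list(
    eW1 = matrix(0, 2 * D + E, config@edgeHidden),
    eb1 = numeric(config@edgeHidden),
    eW2 = matrix(0, config@edgeHidden, D), eb2 = numeric(D),
    hW1 = matrix(0, 2 * D, config@nodeHidden),
    hb1 = numeric(config@nodeHidden),
    hW2 = matrix(0, config@nodeHidden, D), hb2 = numeric(D)))
  if (config@head == "residue") {
    hd <- config@decoderHidden
    w$decoder <- list(W1 = matrix(0, D, hd), b1 = numeric(hd),
                      W2 = matrix(0, hd, 1), b2 = numeric(1))
  } else {
    k2 <- config@convKernel^2
    c1 <- config@convChannels[1]; c2 <- config@convChannels[2]
    d1 <- config@denseWidths[1]; d2 <- config@denseWidths[2]
    fw <- flattenWidth(config)
    w$conv1 <- list(W = matrix(0, k2, c1), b = numeric(c1))
    w$conv2 <- list(W = matrix(0, k2 * c1, c2), b = numeric(c2))
    w$dense1 <- list(W = matrix(0, fw, d1), b = numeric(d1))
    w$dense2 <- list(W = matrix(0, d1, d2), b = numeric(d2))
    w$dense3 <- list(W = matrix(0, d2, 1), b = numeric(1))
  }
  w
}

# Apply f elementwise over parallel nested weight lists.
mapWeights <- function(f, ...) {
  ws <- list(...)
  rec <- function(...) {
    xs <- list(...)
    if (is.list(xs[[1]])) {
      out <- xs[[1]]
      for (nm in seq_along(out))
        out[[nm]] <- do.call(rec, lapply(xs, `[[`, nm))
      out
    } else do.call(f, xs)
  }
  do.call(rec, ws)
}

#' Construct a model
#'
#' Builds the weight tensors for a configuration. With a seed, weights are
#' initialized i.i.d. Normal(0, `initSigma`) (reproducibly); without one the
#' tensors are zero and [initWeights()] must be called before use.
#'
#' @param config a [ModelConfig-class].
#' @param seed optional integer seed for initialization.
#' @return a [CarbNetModel-class].
#' @export
buildModel <- function(config, seed = NULL) {
  model <- new("CarbNetModel", config = config, weights = weightTemplate(config))
  if (!is.null(seed)) model <- initWeights(model, seed)
  model
}

#' Initialize weights ~ Normal(0, sigma)
#'
#' Every trainable scalar is drawn i.i.d. from Normal(0, `sigma`)
#' (defaulting to the configuration's `initSigma` of 0.02), reproducibly
#' for a fixed seed. With `sigma = NA` each weight matrix instead uses the
#' fan-in-scaled deviation `1/sqrt(fan_in)` with zero biases — the
#' standard choice when a small-width configuration would otherwise
#' attenuate its forward signal (the full-size default 0.02 is already
#' near unit gain at its large fan-ins).
#'
#' @param model a [CarbNetModel-class].
#' @param seed integer seed.
#' @param sigma standard deviation, or `NA` for fan-in scaling; default
#'   from the config.
#' @return the initialized model.
#' @export
initWeights <- function(model, seed, sigma = model@config@initSigma) {
  stopifnot(is.na(sigma) || sigma > 0)
  model@weights <- withSeed(seedKey(seed), mapWeights(function(x) {
    if (is.na(sigma)) {
      if (is.matrix(x))
        matrix(stats::rnorm(length(x), 0, 1 / sqrt(nrow(x))),
               nrow(x), ncol(x))
      else numeric(length(x))
    } else {
      v <- stats::rnorm(length(x), 0, sigma)
      if (is.matrix(x)) matrix(v, nrow(x), ncol(x)) else v
    }
  }, model@weights))
  model
}

#' Count trainable parameters
#'
#' @param model a [CarbNetModel-class].
#' @return integer: the exact number of trainable scalars. The count
#'   depends only on the configuration, never on input size.
#' @export
countParameters <- function(model) {
  total <- 0L
  rec <- function(x) {
    if (is.list(x)) lapply(x, rec) else total <<- total + length(x)
    invisible(NULL)
  }
  rec(model@weights)
  total
}

addBias <- function(X, b) X + matrix(b, nrow(X), length(b), byrow = TRUE)

#' One residual graph-convolution layer
#'
#' Computes messages over the k neighbours with the edge MLP, sums them per
#' node, and applies the residual node update. Exposed for testing; the
#' heads drive it internally.
#'
#' @param h numeric N x D node representation.
#' @param neighbors integer N x k neighbour matrix.
#' @param edgeFeats numeric N x k x E edge tensor.
#' @param layerWeights one element of the model's `layers` weight list.
#' @param cache return intermediate activations for backpropagation.
#' @return updated N x D matrix (or a list with `out` and `cache`).
#' @export
egclForward <- function(h, neighbors, edgeFeats, layerWeights, cache = FALSE) {
  wl <- layerWeights
  n <- nrow(h); k <- ncol(neighbors); D <- ncol(h)
  iE <- rep(seq_len(n), k)
  jE <- as.vector(neighbors)
  efFlat <- matrix(edgeFeats, n * k, dim(edgeFeats)[3])
  Xe <- cbind(h[iE, , drop = FALSE], h[jE, , drop = FALSE], efFlat)
  Z1 <- addBias(Xe %*% wl$eW1, wl$eb1)
  S1 <- sigmoid(Z1)
  A1 <- Z1 * S1
  M <- addBias(A1 %*% wl$eW2, wl$eb2)
  # edge rows are i-contiguous per neighbour slot: aggregate by slice adds
  agg <- M[seq_len(n), , drop = FALSE]
  if (k > 1L) for (s in 2:k)
    agg <- agg + M[(s - 1L) * n + seq_len(n), , drop = FALSE]
  Xh <- cbind(h, agg)
  Z2 <- addBias(Xh %*% wl$hW1, wl$hb1)
  S2 <- sigmoid(Z2)
  A2 <- Z2 * S2
  U <- addBias(A2 %*% wl$hW2, wl$hb2)
  out <- h + U
  if (!all(is.finite(out)))
    stop("non-finite activations in graph-convolution layer")
  if (!cache) return(out)
  list(out = out, cache = list(iE = iE, jE = jE, Xe = Xe, Z1 = Z1, S1 = S1,
                               A1 = A1, Xh = Xh, Z2 = Z2, S2 = S2, A2 = A2,
                               n = n, k = k, D = D))
}

# Trunk forward over the layer-wise k schedule.
trunkForward <- function(model, graph, cache = FALSE) {
  cfg <- model@config
  w <- model@weights
  X <- graph@nodeFeats
  if (ncol(X) != cfg@inputDim)
    stop("node features have width ", ncol(X), ", config expects ",
         cfg@inputDim)
  if (nrow(X) < 2L) stop("degenerate graph: fewer than 2 residues")
  h <- addBias(X %*% w$proj$W, w$proj$b)
  caches <- if (cache) vector("list", cfg@nLayers) else NULL
  h0 <- h
  for (l in seq_len(cfg@nLayers)) {
    kname <- as.character(cfg@kSchedule[l])
    nb <- graph@neighbors[[kname]]
    ef <- graph@edgeFeats[[kname]]
    if (is.null(nb) || is.null(ef))
      stop("configuration error: graph lacks the k = ", kname,
           " neighbor list required by layer ", l)
    if (cache) {
      r <- egclForward(h, nb, ef, w$layers[[l]], cache = TRUE)
      h <- r$out
      caches[[l]] <- r$cache
    } else h <- egclForward(h, nb, ef, w$layers[[l]])
  }
  list(h = h, h0 = h0, X = X, caches = caches)
}

#' Per-residue binding probabilities
#'
#' Runs the trunk and the two-layer dense decoder; outputs are strictly in
#' (0, 1) and invariant under rigid motion of the input structure.
#'
#' @param model a residue-head [CarbNetModel-class].
#' @param graph a [ResidueGraph-class] built with the model's k.
#' @return numeric vector of length N.
#' @export
predictResidues <- function(model, graph) {
  stopifnot(model@config@head == "residue")
  residueForwardCore(model, graph, cache = FALSE)$p
}

residueForwardCore <- function(model, graph, cache = FALSE) {
  w <- model@weights
  tr <- trunkForward(model, graph, cache = cache)
  Z1 <- addBias(tr$h %*% w$decoder$W1, w$decoder$b1)
  A1 <- silu(Z1)
  Z2 <- addBias(A1 %*% w$decoder$W2, w$decoder$b2)
  p <- as.vector(sigmoid(Z2))
  list(p = p, trunk = tr, decZ1 = Z1, decA1 = A1)
}

#' Adaptive average pooling along the sequence
#'
#' Output row t (1-based) is the mean of input rows
#' `floor((t-1) L / T) .. ceil(t L / T) - 1` (0-based), the standard
#' adaptive pooling windows; the map is the exact identity when L equals T.
#'
#' @param feats numeric L x D matrix.
#' @param targetLen pooled length T.
#' @return numeric T x D matrix.
#' @export
adaptivePool <- function(feats, targetLen) {
  L <- nrow(feats)
  stopifnot(L >= 1L, targetLen >= 1L)
  out <- matrix(0, targetLen, ncol(feats))
  for (t in seq_len(targetLen)) {
    rows <- (floor((t - 1) * L / targetLen) + 1):ceiling(t * L / targetLen)
    out[t, ] <- colMeans(feats[rows, , drop = FALSE])
  }
  out
}

poolWindows <- function(L, targetLen) {
  lapply(seq_len(targetLen), function(t)
    (floor((t - 1) * L / targetLen) + 1):ceiling(t * L / targetLen))
}

# im2col-style 2D convolution with 'same'-style padding 1.
conv2dForward <- function(A, Wmat, b, kernel, stride, cache = FALSE) {
  H <- dim(A)[1]; W <- dim(A)[2]; Cin <- dim(A)[3]
  pad <- 1L
  Ho <- convOutDim(H, kernel, stride, pad)
  Wo <- convOutDim(W, kernel, stride, pad)
  oh <- rep(seq_len(Ho), Wo)
  ow <- rep(seq_len(Wo), each = Ho)
  k2 <- kernel^2
  IDX <- matrix(0L, Ho * Wo, k2)
  col <- 0L
  for (kw in seq_len(kernel)) for (kh in seq_len(kernel)) {
    col <- col + 1L
    ih <- (oh - 1L) * stride - pad + kh
    iw <- (ow - 1L) * stride - pad + kw
    ok <- ih >= 1L & ih <= H & iw >= 1L & iw <= W
    IDX[ok, col] <- ih[ok] + (iw[ok] - 1L) * H
  }
  P <- matrix(0, Ho * Wo, k2 * Cin)
  for (cc in seq_len(Cin)) {
    av <- c(0, as.vector(A[, , cc]))
    P[, (cc - 1L) * k2 + seq_len(k2)] <- matrix(av[IDX + 1L], Ho * Wo, k2)
  }
  Y <- addBias(P %*% Wmat, b)
  out <- array(Y, c(Ho, Wo, ncol(Wmat)))
  if (!cache) return(out)
  list(out = out, P = P, IDX = IDX, H = H, W = W, Cin = Cin, Ho = Ho, Wo = Wo)
}

#' Protein-level binder probability
#'
#' Runs the staged-neighbourhood trunk, pools the residue dimension to the
#' fixed length, and applies the two convolution and three dense layers to
#' a single sigmoid output. The output is strictly in (0, 1), absorbs any
#' input length, and is invariant under rigid motion.
#'
#' @param model a protein-head [CarbNetModel-class].
#' @param graph a [ResidueGraph-class] built with all scheduled k values.
#' @return scalar probability.
#' @export
predictProtein <- function(model, graph) {
  stopifnot(model@config@head == "protein")
  proteinForwardCore(model, graph, cache = FALSE)$p
}

proteinForwardCore <- function(model, graph, cache = FALSE) {
  cfg <- model@config
  w <- model@weights
  tr <- trunkForward(model, graph, cache = cache)
  P <- adaptivePool(tr$h, cfg@poolLen)
  A0 <- array(P, c(cfg@poolLen, cfg@embedDim, 1L))
  c1 <- conv2dForward(A0, w$conv1$W, w$conv1$b, cfg@convKernel,
                      cfg@convStride, cache = cache)
  Y1 <- if (cache) c1$out else c1
  A1 <- silu(Y1)
  c2 <- conv2dForward(A1, w$conv2$W, w$conv2$b, cfg@convKernel,
                      cfg@convStride, cache = cache)
  Y2 <- if (cache) c2$out else c2
  A2 <- silu(Y2)
  flat <- matrix(as.vector(A2), 1)
  Z1 <- addBias(flat %*% w$dense1$W, w$dense1$b)
  B1 <- silu(Z1)
  Z2 <- addBias(B1 %*% w$dense2$W, w$dense2$b)
  B2 <- silu(Z2)
  Z3 <- addBias(B2 %*% w$dense3$W, w$dense3$b)
  p <- as.vector(sigmoid(Z3))
  list(p = p, trunk = tr, P = P, conv1 = c1, Y1 = Y1, A1 = A1,
       conv2 = c2, Y2 = Y2, A2 = A2, flat = flat, Z1 = Z1, B1 = B1,
       Z2 = Z2, B2 = B2)
}

#' Transplant trunk weights between models
#'
#' Copies the trunk (input projection and all graph-convolution layers)
#' from a source model into a target model — the initialization step that
#' carries pretraining into the protein head. Shapes must match exactly;
#' mismatches raise an error listing the offending tensors.
#'
#' @param target,source [CarbNetModel-class] objects with identical trunk
#'   geometry.
#' @return the target model with trunk weights replaced.
#' @export
transplantTrunk <- function(target, source) {
  bad <- character(0)
  checkEq <- function(a, b, nm) {
    if (!identical(dim(a), dim(b)) || length(a) != length(b))
      bad <<- c(bad, nm)
  }
  checkEq(target@weights$proj$W, source@weights$proj$W, "proj$W")
  checkEq(target@weights$proj$b, source@weights$proj$b, "proj$b")
  if (length(target@weights$layers) != length(source@weights$layers)) {
    bad <- c(bad, "layers (depth mismatch)")
  } else {
    for (l in seq_along(target@weights$layers))
      for (nm in names(target@weights$layers[[l]]))
        checkEq(target@weights$layers[[l]][[nm]],
                source@weights$layers[[l]][[nm]],
                sprintf("layers[[%d]]$%s", l, nm))
  }
  if (length(bad) > 0)
    stop("trunk shape mismatch for tensors: ", paste(bad, collapse = ", "))
  target@weights$proj <- source@weights$proj
  target@weights$layers <- source@weights$layers
  target
}
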