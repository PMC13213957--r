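# Shared fixtures, built in code. Heavier objects are cached per session.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, force(expr), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

# A small all-binder labeled protein (deterministic).
toyBinder <- function(index = 1L, seed = 3L) {
  generateToyProtein(syntheticSpec(nProteins = 1, seed = seed), index,
                     binder = TRUE)
}

toyNonbinder <- function(index = 1L, seed = 3L) {
  generateToyProtein(syntheticSpec(nProteins = 1, seed = seed), index,
                     binder = FALSE)
}

# Tiny model configs used throughout the training and model tests.
tinyResidueConfig <- function(inputDim = 1280L)
  residueModelConfig(nLayers = 2L, embedDim = 16L, inputDim = inputDim,
                     k = 8L, edgeHidden = 32L, nodeHidden = 32L,
                     decoderHidden = 16L, nRbf = 8L)

tinyProteinConfig <- function(inputDim = 1280L)
  proteinModelConfig(nLayers = 2L, embedDim = 16L, inputDim = inputDim,
                     kSchedule = c(6L, 8L), edgeHidden = 32L,
                     nodeHidden = 32L, poolLen = 12L,
                     convChannels = c(3L, 4L), denseWidths = c(12L, 8L),
                     nRbf = 8L)

# Graph + planted-signal embeddings for a labeled protein.
toyExample <- function(lp, ks, embSeed = 1L, signal = 3) {
  s <- labeledStructure(lp)
  emb <- stubEmbedder(proteinSequence(s), seed = embSeed,
                      signalLabels = residueLabels(lp),
                      signalStrength = signal)
  list(graph = buildResidueGraph(s, emb, ks = ks,
                                 config = edgeFeatureConfig(nRbf = 8)),
       labels = residueLabels(lp), label = proteinLabel(lp))
}

# A random rigid motion (rotation matrix + translation), seeded.
randomRigidMotion <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0.2, 3)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  list(R = R, t = rnorm(3, 0, 10))
}

applyRigidMotion <- function(structure, motion) {
  structure@ca <- structure@ca %*% t(motion$R) +
    matrix(motion$t, nrow(structure@ca), 3, byrow = TRUE)
  structure@cb <- structure@cb %*% t(motion$R) +
    matrix(motion$t, nrow(structure@cb), 3, byrow = TRUE)
  structure
}
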