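# Model construction, parameter counting, graph-convolution properties,
# adaptive pooling, and the two forward heads.

test_that("default configurations reproduce the reference parameter counts", {
  expect_identical(countParameters(buildModel(residueModelConfig())),
                   1600387L)
  expect_identical(countParameters(buildModel(proteinModelConfig())),
                   1798895L)
})

test_that("parameter counts depend on config only, and compose from layer sizes", {
  # single dense layer 128 -> 1 with bias: 129 parameters
  cfg <- tinyResidueConfig()
  m <- buildModel(cfg)
  D <- cfg@embedDim; E <- cfg@nRbf + 7L
  expected <- cfg@inputDim * D + D +                       # projection
    cfg@nLayers * (cfg@edgeHidden * (2 * D + E + 1) + cfg@edgeHidden * D + D +
                   cfg@nodeHidden * (2 * D + 1) + cfg@nodeHidden * D + D) +
    D * cfg@decoderHidden + cfg@decoderHidden + cfg@decoderHidden + 1
  expect_identical(countParameters(m), as.integer(expected))
  expect_identical(length(m@weights$decoder$W2) + length(m@weights$decoder$b2),
                   cfg@decoderHidden + 1L)
})

test_that("weight initialization is seeded Normal(0, sigma)", {
  cfg <- tinyProteinConfig()
  m1 <- buildModel(cfg, seed = 7)
  m2 <- buildModel(cfg, seed = 7)
  expect_identical(m1@weights, m2@weights)
  m3 <- buildModel(cfg, seed = 8)
  expect_false(identical(m1@weights, m3@weights))
  big <- initWeights(buildModel(residueModelConfig()), seed = 1)
  v <- unlist(big@weights$layers[[1]])
  expect_gt(length(v), 1e5)
  expect_lt(abs(sd(v) - 0.02), 0.001)      # within 5% of sigma
  expect_lt(abs(mean(v)), 0.001)
})

test_that("graph-convolution layer is residual, deterministic, and permutes", {
  set.seed(31)
  n <- 9; D <- 6; E <- 5; k <- 3
  h <- matrix(rnorm(n * D), n, D)
  nb <- t(sapply(seq_len(n), function(i) sample(setdiff(seq_len(n), i), k)))
  ef <- array(rnorm(n * k * E), c(n, k, E))
  wl <- list(eW1 = matrix(rnorm((2 * D + E) * 7, 0, 0.3), 2 * D + E, 7),
             eb1 = rnorm(7), eW2 = matrix(rnorm(7 * D, 0, 0.3), 7, D),
             eb2 = rnorm(D),
             hW1 = matrix(rnorm(2 * D * 5, 0, 0.3), 2 * D, 5), hb1 = rnorm(5),
             hW2 = matrix(rnorm(5 * D, 0, 0.3), 5, D), hb2 = rnorm(D))
  # zero final node-update weights: residual identity
  wl0 <- wl; wl0$hW2[] <- 0; wl0$hb2[] <- 0
  expect_identical(egclForward(h, nb, ef, wl0), h)
  # determinism
  expect_identical(egclForward(h, nb, ef, wl), egclForward(h, nb, ef, wl))
  # two nodes with identical features and neighbour context update identically
  h2 <- h; h2[2, ] <- h[1, ]
  nb2 <- nb; nb2[2, ] <- nb[1, ]
  ef2 <- ef; ef2[2, , ] <- ef[1, , ]
  out2 <- egclForward(h2, nb2, ef2, wl)
  expect_equal(out2[1, ], out2[2, ], tolerance = 1e-12)
  # permutation compatibility
  perm <- sample(n)
  inv <- order(perm)
  nbP <- matrix(inv[nb[perm, ]], n, k)
  outP <- egclForward(h[perm, ], nbP, ef[perm, , , drop = FALSE], wl)
  expect_equal(outP, egclForward(h, nb, ef, wl)[perm, ], tolerance = 1e-10)
})

test_that("adaptive pooling matches the window formula", {
  poolOracle <- function(feats, targetLen) {
    L <- nrow(feats)
    out <- matrix(0, targetLen, ncol(feats))
    for (t0 in 0:(targetLen - 1)) {
      lo <- floor(t0 * L / targetLen)
      hi <- ceiling((t0 + 1) * L / targetLen) - 1
      out[t0 + 1, ] <- colMeans(feats[(lo + 1):(hi + 1), , drop = FALSE])
    }
    out
  }
  set.seed(5)
  for (L in c(1, 75, 149, 150, 151, 300)) {
    feats <- matrix(rnorm(L * 4), L, 4)
    expect_equal(adaptivePool(feats, 150), poolOracle(feats, 150),
                 tolerance = 1e-12)
  }
  # identity when L == target
  feats <- matrix(rnorm(150 * 3), 150, 3)
  expect_equal(adaptivePool(feats, 150), feats)
  # L = 300: out[t] = mean(in[2t-1], in[2t])
  feats <- matrix(rnorm(300 * 2), 300, 2)
  p <- adaptivePool(feats, 150)
  for (t0 in c(1, 7, 150))
    expect_equal(p[t0, ], colMeans(feats[c(2 * t0 - 1, 2 * t0), ]))
  # L = 75: each input row lands in exactly two output rows
  feats <- matrix(seq_len(75), 75, 1)
  p <- adaptivePool(feats, 150)
  expect_equal(as.vector(p), rep(seq_len(75), each = 2))
})

test_that("both heads emit probabilities and are invariant to rigid motion", {
  lp <- toyBinder(seed = 37)
  ex <- toyExample(lp, ks = c(6, 8))
  rmod <- buildModel(tinyResidueConfig(), seed = 1)
  rmod@config@kSchedule <- rep(8L, 2L)
  pmod <- buildModel(tinyProteinConfig(), seed = 2)
  pr <- predictResidues(rmod, ex$graph)
  expect_true(all(pr > 0 & pr < 1))
  expect_length(pr, nResidues(lp))
  pp <- predictProtein(pmod, ex$graph)
  expect_true(pp > 0 && pp < 1)
  # reproducibility: same weights, same input, identical output
  expect_identical(predictResidues(rmod, ex$graph), pr)
  # rigid motion
  s2 <- applyRigidMotion(labeledStructure(lp), randomRigidMotion(11))
  emb <- stubEmbedder(proteinSequence(s2), seed = 1,
                      signalLabels = residueLabels(lp), signalStrength = 3)
  g2 <- buildResidueGraph(s2, emb, ks = c(6, 8),
                          config = edgeFeatureConfig(nRbf = 8))
  expect_lt(max(abs(predictResidues(rmod, g2) - pr)), 1e-5)
  expect_lt(abs(predictProtein(pmod, g2) - pp), 1e-5)
})

test_that("protein head absorbs any input length and validates its k lists", {
  pmod <- buildModel(tinyProteinConfig(), seed = 3)
  for (seed in c(61, 62)) {
    lp <- generateToyProtein(syntheticSpec(nProteins = 1,
                                           lengthRange = c(40L, 40L),
                                           seed = seed), 1, binder = TRUE)
    ex <- toyExample(lp, ks = c(6, 8))
    expect_true(predictProtein(pmod, ex$graph) > 0)
  }
  lp <- toyBinder(seed = 63)
  exBad <- toyExample(lp, ks = c(8))   # missing the k = 6 stage
  expect_error(predictProtein(pmod, exBad$graph), "configuration error")
})

test_that("trunk transplant copies tensors and rejects shape mismatches", {
  rmod <- buildModel(tinyResidueConfig(), seed = 1)
  pmod <- buildModel(tinyProteinConfig(), seed = 2)
  before <- pmod@weights$conv1
  pmod2 <- transplantTrunk(pmod, rmod)
  expect_identical(pmod2@weights$proj, rmod@weights$proj)
  expect_identical(pmod2@weights$layers, rmod@weights$layers)
  expect_identical(pmod2@weights$conv1, before)   # head untouched
  other <- buildModel(residueModelConfig(nLayers = 2L, embedDim = 24L,
                                         inputDim = 1280L, k = 8L,
                                         edgeHidden = 32L, nodeHidden = 32L,
                                         decoderHidden = 16L, nRbf = 8L),
                      seed = 1)
  expect_error(transplantTrunk(pmod, other), "shape mismatch")
})
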