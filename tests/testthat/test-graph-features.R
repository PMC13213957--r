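# k-NN topology, local frames, RBF encoding, invariant edge features,
# and the stub embedder.

test_that("knn graph orders neighbours by distance with index tie-breaks", {
  coords <- cbind(c(0, 1, 2, 3), 0, 0)   # collinear points
  nb <- buildKnnGraph(coords, 2)
  expect_equal(nb[1, ], c(2L, 3L))
  expect_equal(nb[2, ], c(1L, 3L))       # ties at distance 1: lower index
  expect_equal(nb[4, ], c(3L, 2L))
  expect_error(buildKnnGraph(coords[1, , drop = FALSE], 2), "degenerate")
})

test_that("knn clamps to N-1 and matches a brute-force sort oracle", {
  set.seed(41)
  coords <- matrix(rnorm(5 * 3, 0, 10), 5, 3)
  expect_equal(ncol(buildKnnGraph(coords, 10)), 4L)
  coords <- matrix(rnorm(50 * 3, 0, 10), 50, 3)
  nb <- buildKnnGraph(coords, 16)
  for (i in 1:50) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    d[i] <- Inf
    expect_equal(nb[i, ], order(d)[1:16])
  }
})

test_that("local frames are orthonormal, right-handed, and equivariant", {
  lp <- toyBinder(seed = 13)
  coords <- cbCoords(labeledStructure(lp))
  fr <- localFrames(coords)
  n <- nrow(coords)
  for (i in seq_len(n)) {
    F <- fr[i, , ]
    expect_lt(max(abs(crossprod(F) - diag(3))), 1e-6)
    expect_equal(det(F), 1, tolerance = 1e-6)
  }
  # terminal residues copy their unique neighbour's construction
  expect_identical(fr[1, , ], fr[2, , ])
  expect_identical(fr[n, , ], fr[n - 1, , ])
  # equivariance: rotating coords maps every frame to R %*% frame
  m <- randomRigidMotion(7)
  fr2 <- localFrames(coords %*% t(m$R) +
                       matrix(m$t, n, 3, byrow = TRUE))
  for (i in seq_len(n))
    expect_lt(max(abs(fr2[i, , ] - m$R %*% fr[i, , ])), 1e-8)
  expect_error(localFrames(matrix(0, 5, 3)), "degenerate|frame")
})

test_that("rbf encoding matches the Gaussian formula", {
  centers <- seq(0, 20, length.out = 16)
  sigma <- centers[2] - centers[1]
  # at a center the matching component is exactly 1
  enc <- rbfEncode(centers[5], 16, 0, 20)
  expect_identical(dim(enc), c(1L, 16L))
  expect_equal(enc[1, 5], 1.0)
  # hand-evaluated Gaussian at arbitrary distances, including out of range
  for (d in c(0, 3.3, 12.7, 40)) {
    expect_equal(as.vector(rbfEncode(d, 16, 0, 20)),
                 exp(-((d - centers) / sigma)^2), tolerance = 1e-12)
  }
  expect_true(all(rbfEncode(40, 16, 0, 20) < 1e-6))
})

test_that("edge features are invariant and their blocks match direct arithmetic", {
  # generic point cloud: no exact distance ties, so edge ordering is stable
  set.seed(17)
  coords <- matrix(rnorm(40 * 3, 0, 6), 40, 3)
  fr <- localFrames(coords)
  nb <- buildKnnGraph(coords, 6)
  cfg <- edgeFeatureConfig(nRbf = 8)
  ef <- edgeFeatures(coords, fr, nb, cfg)
  expect_equal(dim(ef)[3], 8 + 3 + 4)
  # direction block equals t(frame_i) %*% unit(x_j - x_i)
  i <- 4L; s <- 2L; j <- nb[i, s]
  delta <- coords[j, ] - coords[i, ]
  unit <- delta / sqrt(sum(delta^2))
  expect_equal(ef[i, s, 9:11], as.vector(t(fr[i, , ]) %*% unit),
               tolerance = 1e-10)
  # identical frames give the identity quaternion
  efSame <- edgeFeatures(coords, array(rep(diag(3), each = nrow(coords)),
                                       c(nrow(coords), 3, 3)), nb, cfg)
  # quaternion of identity rotation: (1, 0, 0, 0)
  expect_equal(efSame[i, s, 12:15],
               c(1, 0, 0, 0), tolerance = 1e-10)
  # invariance under a rigid motion
  m <- randomRigidMotion(19)
  coords2 <- coords %*% t(m$R) + matrix(m$t, nrow(coords), 3, byrow = TRUE)
  ef2 <- edgeFeatures(coords2, localFrames(coords2), buildKnnGraph(coords2, 6),
                      cfg)
  expect_lt(max(abs(ef2 - ef)), 1e-5)
  # quaternion scalar part is always nonnegative (sign convention)
  expect_true(all(ef[, , 12] >= 0))
})

test_that("edge feature blocks can be disabled independently", {
  lp <- toyBinder(seed = 23)
  coords <- cbCoords(labeledStructure(lp))
  fr <- localFrames(coords)
  nb <- buildKnnGraph(coords, 4)
  expect_equal(dim(edgeFeatures(coords, fr, nb,
                                edgeFeatureConfig(nRbf = 5,
                                                  includeDirection = FALSE,
                                                  includeOrientation = FALSE)))[3],
               5L)
  expect_equal(dim(edgeFeatures(coords, fr, nb,
                                edgeFeatureConfig(nRbf = 5,
                                                  includeOrientation = FALSE)))[3],
               8L)
})

test_that("stub embedder is deterministic, 1280-wide, and plants its signal", {
  s <- "MKTAYIAKQR"
  e1 <- stubEmbedder(s, seed = 4)
  e2 <- stubEmbedder(s, seed = 4)
  expect_identical(e1, e2)
  expect_identical(dim(e1), c(10L, 1280L))
  expect_false(identical(e1, stubEmbedder(s, seed = 5)))
  # planted signal: labeled residues' channel 1 shifted by the stated amount
  set.seed(1)
  seqLong <- paste(sample(c("A", "G", "K", "L"), 400, replace = TRUE),
                   collapse = "")
  labels <- rep(c(1, 0), 200)
  e <- stubEmbedder(seqLong, seed = 9, signalLabels = labels,
                    signalStrength = 3)
  gap <- mean(e[labels == 1, 1]) - mean(e[labels == 0, 1])
  expect_equal(gap, 3, tolerance = 0.25)
})

test_that("graph builder assembles all requested neighbourhood sizes", {
  lp <- toyBinder(seed = 29)
  s <- labeledStructure(lp)
  emb <- stubEmbedder(proteinSequence(s), seed = 1)
  g <- buildResidueGraph(s, emb, ks = c(6, 10))
  expect_s4_class(g, "ResidueGraph")
  expect_equal(sort(as.integer(names(g@neighbors))), c(6L, 10L))
  expect_equal(dim(neighborIndices(g, 6)), c(nResidues(s), 6L))
  expect_equal(dim(edgeFeatureTensor(g, 10))[2:3], c(10L, 23L))
  expect_error(neighborIndices(g, 16), "not built")
})
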