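# Losses and metrics against direct-formula and enumeration oracles.

test_that("dice coefficient follows 2TP/(2TP+FP+FN)", {
  expect_equal(diceCoefficient(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1.0)
  # TP=2 FP=1 FN=1 -> 4/6
  expect_equal(diceCoefficient(c(1, 1, 1, 0), c(1, 1, 0, 1)), 2 / 3,
               tolerance = 1e-4)
  expect_equal(diceCoefficient(c(0, 1), c(1, 0)), 0.0)
  expect_warning(d0 <- diceCoefficient(c(0, 0), c(0, 0)), "undefined")
  expect_equal(d0, 0)
  # hard equals soft for exactly binary predictions
  p <- c(1, 0, 1, 1, 0); y <- c(1, 1, 0, 1, 0)
  expect_equal(diceCoefficient(p, y, mode = "hard"),
               diceCoefficient(p, y, mode = "soft"))
})

test_that("dice loss is 1 - soft dice, bounded and monotone in true-positive mass", {
  y <- c(rep(1, 5), rep(0, 5))
  # uniform 0.5 on half-positive labels: d = (2*0.5*P)/(0.5*N + 0.5*P + P)
  p <- rep(0.5, 10)
  expect_equal(diceLoss(p, y), 1 - (2 * 0.5 * 5) / (5 + 5 * 0.5 + 5 * 0.5))
  expect_equal(diceLoss(rep(0.999999, 5), rep(1, 5)), 0, tolerance = 1e-5)
  # raising predictions on true positives strictly lowers the loss
  losses <- vapply(seq(0.1, 0.9, by = 0.2), function(q) {
    p2 <- p; p2[y == 1] <- q
    diceLoss(p2, y)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  # analytic gradient matches finite differences
  set.seed(3)
  p <- runif(8, 0.05, 0.95); y <- rbinom(8, 1, 0.4)
  g <- carbnet:::diceLossGrad(p, y)
  for (i in c(1, 4, 8)) {
    eps <- 1e-6
    pp <- p; pp[i] <- p[i] + eps
    pm <- p; pm[i] <- p[i] - eps
    expect_equal(g[i], (diceLoss(pp, y) - diceLoss(pm, y)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("binary cross entropy matches the closed form and clamps", {
  expect_equal(bceLoss(0.5, 1), log(2))
  expect_equal(bceLoss(0.5, 0), log(2))
  expect_equal(bceLoss(0.999999, 1), 0, tolerance = 1e-5)
  expect_true(is.finite(bceLoss(1, 0)))   # clamped, not Inf
  # batch mean equals direct summation
  set.seed(9)
  p <- runif(20, 0.01, 0.99); y <- rbinom(20, 1, 0.5)
  expect_equal(bceLoss(p, y),
               mean(-(y * log(p) + (1 - y) * log(1 - p))))
})

test_that("confusion counts partition the items at the threshold", {
  cc <- confusionCounts(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(asCounts(cc), c(tp = 1L, fp = 0L, tn = 1L, fn = 0L))
  cc2 <- confusionCounts(c(0.9, 0.1), c(1, 0), 0.95)
  expect_equal(asCounts(cc2), c(tp = 0L, fp = 0L, tn = 1L, fn = 1L))
  set.seed(2)
  p <- runif(100); y <- rbinom(100, 1, 0.3)
  cc3 <- confusionCounts(p, y, 0.4)
  expect_equal(sum(asCounts(cc3)), 100L)
})

test_that("mcc and bacc/tpr/tnr match direct evaluation and enumeration", {
  perfect <- new("ConfusionCounts", tp = 5L, fp = 0L, tn = 5L, fn = 0L)
  expect_equal(mcc(perfect), 1.0)
  expect_equal(unname(baccTprTnr(perfect)), c(1, 1, 1))
  ones <- new("ConfusionCounts", tp = 1L, fp = 1L, tn = 1L, fn = 1L)
  expect_equal(mcc(ones), 0.0)
  # all-positive caller on a balanced set: tpr 1, tnr 0, bacc 0.5
  allpos <- new("ConfusionCounts", tp = 5L, fp = 5L, tn = 0L, fn = 0L)
  expect_equal(baccTprTnr(allpos)[["bacc"]], 0.5)
  ex <- new("ConfusionCounts", tp = 3L, fp = 2L, tn = 2L, fn = 1L)
  expect_equal(unname(baccTprTnr(ex)), c(0.625, 0.75, 0.5))
  # inverting predictions flips the mcc sign
  expect_equal(mcc(new("ConfusionCounts", tp = 1L, fp = 2L, tn = 4L, fn = 3L)),
               -mcc(new("ConfusionCounts", tp = 3L, fp = 4L, tn = 2L, fn = 1L)))
  # undefined classes are errors naming the class
  expect_error(baccTprTnr(new("ConfusionCounts", tp = 0L, fp = 1L, tn = 1L,
                              fn = 0L)), "positive")
  expect_error(baccTprTnr(new("ConfusionCounts", tp = 1L, fp = 0L, tn = 0L,
                              fn = 1L)), "negative")
  # exhaustive small-count enumeration against direct formulas and ranges
  for (tot in 0:8) {
    for (tp in 0:tot) for (fp in 0:(tot - tp)) for (tn in 0:(tot - tp - fp)) {
      fn <- tot - tp - fp - tn
      cc <- new("ConfusionCounts", tp = tp, fp = fp, tn = tn, fn = fn)
      m <- mcc(cc)
      den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      expect_equal(m, if (den == 0) 0 else
        (tp * tn - fp * fn) / sqrt(den))
      expect_true(m >= -1 && m <= 1)
      if (tp + fn > 0 && tn + fp > 0) {
        b <- baccTprTnr(cc)
        expect_equal(unname(b), c((tp / (tp + fn) + tn / (tn + fp)) / 2,
                                  tp / (tp + fn), tn / (tn + fp)))
        expect_true(all(b >= 0 & b <= 1))
      }
    }
  }
})

test_that("residue evaluation report averages per protein", {
  preds <- list(c(0.9, 0.9, 0.1), c(0.8, 0.2, 0.2, 0.1))
  labels <- list(c(1, 1, 0), c(1, 1, 0, 0))
  rep_ <- evaluateResidueReport(preds, labels, ids = c("a", "b"))
  expect_equal(nrow(rep_), 3L)
  expect_equal(rep_$id[3], "mean")
  d1 <- diceCoefficient(preds[[1]], labels[[1]])
  d2 <- diceCoefficient(preds[[2]], labels[[2]])
  expect_equal(rep_$dice[3], mean(c(d1, d2)))   # averaged, never pooled
})
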