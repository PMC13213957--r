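# Two-cycle training protocol: Adam with weight decay, batch size 1,
# patience-based early stopping, trunk transplant into the protein head.

#' Training configuration
#'
#' Cycle-1 defaults (learning rate 2e-6, weight decay 1e-7); the second
#' cycle uses rates ten times larger (2e-5 / 1e-6). Training stops at
#' `maxEpochs` or once the validation loss has not improved (strictly
#' decreased below the running minimum) for `patience` consecutive epochs.
#'
#' @param lr learning rate.
#' @param weightDecay L2 weight decay coupled into the Adam gradient.
#' @param maxEpochs epoch cap (default 1000).
#' @param patience early-stopping patience (default 35).
#' @param loss `"dice"` (residue head) or `"bce"` (protein head).
#' @param af2Prob predicted-structure sampling probability (default 0.6).
#' @param seed RNG seed for sampling and shuffling.
#' @param beta1,beta2,eps Adam moment parameters (conventional defaults).
#' @param clipNorm global gradient-norm clip; `Inf` (default) disables it.
#' @param restarts maximum number of re-initialized attempts when a cycle
#'   fails to escape the trivial optimum (0 disables restarts).
#' @param restartThreshold a finished cycle whose best validation loss
#'   stays above this value counts as collapsed and triggers a restart
#'   (requires a `reinit` callback in [trainCycle()]).
#' @return a list with class `trainConfig`.
#' @export
trainConfig <- function(lr = 2e-6, weightDecay = 1e-7, maxEpochs = 1000L,
                        patience = 35L, loss = c("dice", "bce"),
                        af2Prob = 0.6, seed = 1L,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                        clipNorm = Inf, restarts = 0L,
                        restartThreshold = Inf) {
  loss <- match.arg(loss)
  stopifnot(lr > 0, patience < maxEpochs, clipNorm > 0, restarts >= 0)
  structure(list(lr = lr, weightDecay = weightDecay,
                 maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience), loss = loss,
                 af2Prob = af2Prob, seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 clipNorm = clipNorm, restarts = as.integer(restarts),
                 restartThreshold = restartThreshold),
            class = "trainConfig")
}

zeroLike <- function(w) mapWeights(function(x) x * 0, w)

adamStep <- function(w, g, state, config) {
  state$t <- state$t + 1L
  b1 <- config$beta1; b2 <- config$beta2
  state$m <- mapWeights(function(m, gr, wt) b1 * m + (1 - b1) *
                          (gr + config$weightDecay * wt),
                        state$m, g, w)
  state$v <- mapWeights(function(v, gr, wt) {
    gg <- gr + config$weightDecay * wt
    b2 * v + (1 - b2) * gg * gg
  }, state$v, g, w)
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  w <- mapWeights(function(wt, m, v)
    wt - config$lr * (m / c1) / (sqrt(v / c2) + config$eps),
    w, state$m, state$v)
  list(w = w, state = state)
}

exampleLoss <- function(model, ex, config, withGrad = FALSE) {
  if (config$loss == "dice") {
    fw <- residueForwardCore(model, ex$graph, cache = withGrad)
    p <- fw$p
    loss <- diceLoss(p, ex$labels)
    if (!withGrad) return(list(loss = loss))
    dz <- diceLossGrad(p, ex$labels) * p * (1 - p)
    list(loss = loss, grads = residueBackward(dz, fw, model))
  } else {
    fw <- proteinForwardCore(model, ex$graph, cache = withGrad)
    p <- fw$p
    loss <- bceLoss(p, ex$label)
    if (!withGrad) return(list(loss = loss))
    dz <- p - as.numeric(ex$label)
    list(loss = loss, grads = proteinBackward(dz, fw, model))
  }
}

validationLoss <- function(model, valData, config) {
  mean(vapply(valData, function(ex) exampleLoss(model, ex, config)$loss,
              numeric(1)))
}

#' Run one training cycle with early stopping
#'
#' Streams one example at a time (batch size 1) through Adam. `sampler` is
#' a function of the epoch number returning the epoch's examples (e.g. one
#' per cluster, see [epochSample()]); each example is a list with `graph`
#' and `labels` (residue head) or `label` (protein head). Stops at
#' `maxEpochs` or after `patience` epochs without a strict improvement of
#' the validation loss, and returns the weights from the best validation
#' epoch.
#'
#' When `config$restarts > 0` and a finished attempt's best validation
#' loss stays above `config$restartThreshold`, the cycle is deemed
#' collapsed (stuck at the trivial constant predictor) and is retried from
#' a fresh initialization supplied by `reinit`; the attempt with the
#' lowest validation loss wins. This mirrors the multi-start convention of
#' other nonconvex fitters and is off by default.
#'
#' @param model a [CarbNetModel-class].
#' @param sampler function(epoch) -> list of training examples.
#' @param valData list of validation examples (fixed across epochs).
#' @param config a [trainConfig()].
#' @param verbose print a line per epoch.
#' @param reinit optional function(attempt) -> model giving the fresh
#'   starting point for restart attempt 2, 3, ...
#' @return list with `model` (best weights), `history` (data.frame of
#'   epoch, train and validation loss, best flag), `bestEpoch`,
#'   `stoppedBecause` and `attempts`.
#' @export
trainCycle <- function(model, sampler, valData, config = trainConfig(),
                       verbose = FALSE, reinit = NULL) {
  best <- NULL
  for (attempt in seq_len(1L + config$restarts)) {
    m0 <- if (attempt == 1L) model else reinit(attempt)
    r <- trainCycleOnce(m0, sampler, valData, config, verbose)
    if (is.null(best) || r$bestLoss < best$bestLoss) best <- r
    best$attempts <- attempt
    if (best$bestLoss <= config$restartThreshold || is.null(reinit)) break
  }
  best
}

trainCycleOnce <- function(model, sampler, valData, config, verbose = FALSE) {
  state <- list(t = 0L, m = zeroLike(model@weights),
                v = zeroLike(model@weights))
  bestLoss <- Inf
  bestWeights <- model@weights
  bestEpoch <- 0L
  sinceBest <- 0L
  hist <- list()
  stoppedBecause <- "max epochs reached"
  for (epoch in seq_len(config$maxEpochs)) {
    batch <- sampler(epoch)
    trainLosses <- numeric(length(batch))
    for (bi in seq_along(batch)) {
      r <- exampleLoss(model, batch[[bi]], config, withGrad = TRUE)
      if (!is.finite(r$loss))
        stop("non-finite training loss at epoch ", epoch, ", example ", bi)
      trainLosses[bi] <- r$loss
      if (is.finite(config$clipNorm)) {
        gn <- sqrt(sum(unlist(r$grads)^2))
        if (gn > config$clipNorm)
          r$grads <- mapWeights(function(g) g * config$clipNorm / gn, r$grads)
      }
      upd <- adamStep(model@weights, r$grads, state, config)
      model@weights <- upd$w
      state <- upd$state
    }
    vloss <- validationLoss(model, valData, config)
    if (!is.finite(vloss))
      stop("non-finite validation loss at epoch ", epoch)
    improved <- vloss < bestLoss
    if (improved) {
      bestLoss <- vloss
      bestWeights <- model@weights
      bestEpoch <- epoch
      sinceBest <- 0L
    } else sinceBest <- sinceBest + 1L
    hist[[epoch]] <- data.frame(epoch = epoch,
                                trainLoss = mean(trainLosses),
                                valLoss = vloss, best = improved)
    if (verbose)
      message(sprintf("epoch %d train %.4f val %.4f%s", epoch,
                      mean(trainLosses), vloss, if (improved) " *" else ""))
    if (sinceBest >= config$patience) {
      stoppedBecause <- sprintf("no improvement for %d epochs",
                                config$patience)
      break
    }
  }
  model@weights <- bestWeights
  list(model = model, history = do.call(rbind, hist), bestEpoch = bestEpoch,
       bestLoss = bestLoss, stoppedBecause = stoppedBecause)
}

#' Two-cycle training of both heads
#'
#' Cycle 1 trains the residue architecture from Normal(0, 0.02) weights on
#' small-molecule contact labels (Dice loss, lr 2e-6, weight decay 1e-7).
#' Cycle 2a fine-tunes the residue head on carbohydrate-only complexes at
#' ten-fold larger rates (lr 2e-5, wd 1e-6, Dice loss). Cycle 2b builds
#' the protein head by transplanting the cycle-1 trunk where available,
#' initializing the pooling head at Normal(0, 0.02), and training all
#' weights on binder/nonbinder labels with BCE (lr 2e-5, wd 1e-6).
#'
#' @param residueConfig,proteinConfig [ModelConfig-class] objects sharing
#'   the same trunk geometry.
#' @param stage1Sampler,stage2aSampler,stage2bSampler epoch samplers (see
#'   [trainCycle()]) for the three cycles.
#' @param stage1Val,stage2aVal,stage2bVal validation example lists.
#' @param seed initialization seed.
#' @param stage1Train,stage2aTrain,stage2bTrain [trainConfig()]s; defaults
#'   follow the protocol above (pass smaller `maxEpochs`/larger `lr` for
#'   toy runs).
#' @param verbose print epoch lines.
#' @return list with `residueModel`, `proteinModel` and the three
#'   training histories.
#' @export
twoStageTrain <- function(residueConfig, proteinConfig,
                          stage1Sampler, stage1Val,
                          stage2aSampler, stage2aVal,
                          stage2bSampler, stage2bVal,
                          seed = 1L,
                          stage1Train = trainConfig(lr = 2e-6,
                                                    weightDecay = 1e-7,
                                                    loss = "dice"),
                          stage2aTrain = trainConfig(lr = 2e-5,
                                                     weightDecay = 1e-6,
                                                     loss = "dice"),
                          stage2bTrain = trainConfig(lr = 2e-5,
                                                     weightDecay = 1e-6,
                                                     loss = "bce"),
                          verbose = FALSE) {
  res0 <- buildModel(residueConfig, seed = seed)
  s1 <- trainCycle(res0, stage1Sampler, stage1Val, stage1Train, verbose,
                   reinit = function(attempt)
                     buildModel(residueConfig, seed = seed + 1000L * attempt))
  s2a <- trainCycle(s1$model, stage2aSampler, stage2aVal, stage2aTrain,
                    verbose)
  prot0 <- buildModel(proteinConfig, seed = seed + 1L)
  prot0 <- transplantTrunk(prot0, s1$model)
  s2b <- trainCycle(prot0, stage2bSampler, stage2bVal, stage2bTrain, verbose,
                    reinit = function(attempt)
                      transplantTrunk(buildModel(proteinConfig,
                                                 seed = seed + 1L +
                                                   1000L * attempt),
                                      s1$model))
  list(residueModel = s2a$model, proteinModel = s2b$model,
       stage1History = s1$history, stage2aHistory = s2a$history,
       stage2bHistory = s2b$history)
}
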