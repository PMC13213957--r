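# Dice/BCE losses and the evaluation metrics (Dice, MCC, BACC/TPR/TNR).

#' Dice-Sorenson coefficient
#'
#' Hard mode computes `2TP / (2TP + FP + FN)` from thresholded predictions;
#' soft mode replaces the counts with sums of products over the raw
#' probabilities (the differentiable overlap used by the training loss).
#' When the denominator is zero (no positives in either vector) the
#' coefficient is defined as 0, with a warning.
#'
#' @param pred numeric vector: probabilities (soft) or binary calls (hard).
#' @param labels binary vector of the same length.
#' @param mode `"hard"` or `"soft"`.
#' @param threshold hard-mode threshold (call = `pred >= threshold`).
#' @return value in [0, 1].
#' @export
diceCoefficient <- function(pred, labels, mode = c("hard", "soft"),
                            threshold = 0.5) {
  mode <- match.arg(mode)
  stopifnot(length(pred) == length(labels))
  y <- as.numeric(labels)
  if (mode == "hard") {
    p <- as.numeric(pred >= threshold)
    tp <- sum(p == 1 & y == 1)
    num <- 2 * tp
    den <- 2 * tp + sum(p == 1 & y == 0) + sum(p == 0 & y == 1)
  } else {
    p <- as.numeric(pred)
    num <- 2 * sum(p * y)
    den <- sum(p) + sum(y)
  }
  if (den == 0) {
    warning("dice undefined (no positives in labels or predictions); returning 0")
    return(0)
  }
  num / den
}

#' Dice loss
#'
#' `1 - d` with `d` the soft Dice-Sorenson coefficient — the segmentation
#' loss that emphasizes the minority binding class. Differentiable with
#' respect to the predictions.
#'
#' @param predSoft numeric vector of probabilities in (0, 1).
#' @param labels binary vector.
#' @return value in [0, 1].
#' @export
diceLoss <- function(predSoft, labels) {
  1 - diceCoefficient(predSoft, labels, mode = "soft")
}

# dL/dp of the Dice loss (used by the trainer).
diceLossGrad <- function(p, y) {
  y <- as.numeric(y)
  S <- sum(p) + sum(y)
  if (S == 0) return(rep(0, length(p)))
  I <- sum(p * y)
  -(2 * y * S - 2 * I) / S^2
}

#' Binary cross entropy
#'
#' `-(y log p + (1 - y) log(1 - p))`, averaged over the inputs.
#' Probabilities exactly 0 or 1 are clamped at machine epsilon.
#'
#' @param pred probabilities.
#' @param label binary labels.
#' @return mean BCE.
#' @export
bceLoss <- function(pred, label) {
  stopifnot(length(pred) == length(label))
  eps <- .Machine$double.eps
  p <- pmin(pmax(pred, eps), 1 - eps)
  y <- as.numeric(label)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' Confusion counts at a threshold
#'
#' Calls are `pred >= threshold`. The four counts always partition the
#' scored items.
#'
#' @param pred probabilities.
#' @param labels binary labels.
#' @param threshold decision threshold (default 0.5).
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(pred, labels, threshold = 0.5) {
  stopifnot(length(pred) == length(labels))
  call <- pred >= threshold
  y <- as.logical(labels)
  new("ConfusionCounts",
      tp = sum(call & y), fp = sum(call & !y),
      tn = sum(!call & !y), fn = sum(!call & y))
}

#' Matthews correlation coefficient
#'
#' `(TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0
#' when any factor of the denominator vanishes.
#'
#' @param c a [ConfusionCounts-class].
#' @return value in [-1, 1].
#' @export
mcc <- function(c) {
  tp <- as.numeric(c@tp); fp <- as.numeric(c@fp)
  tn <- as.numeric(c@tn); fn <- as.numeric(c@fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Balanced accuracy and the class recall rates
#'
#' `TPR = TP / (TP + FN)`, `TNR = TN / (TN + FP)`,
#' `BACC = (TPR + TNR) / 2`. Requires at least one positive and one
#' negative item; an empty class is an error naming the class.
#'
#' @param c a [ConfusionCounts-class].
#' @return named numeric vector `(bacc, tpr, tnr)`.
#' @export
baccTprTnr <- function(c) {
  pos <- c@tp + c@fn
  neg <- c@tn + c@fp
  if (pos == 0L) stop("undefined metric: no positive items (TPR)")
  if (neg == 0L) stop("undefined metric: no negative items (TNR)")
  tpr <- c@tp / pos
  tnr <- c@tn / neg
  c(bacc = (tpr + tnr) / 2, tpr = tpr, tnr = tnr)
}

#' Per-protein residue-level evaluation report
#'
#' One row per protein with its hard Dice and MCC, plus a `mean` summary
#' row — metrics are averaged per protein, never pooled over concatenated
#' counts.
#'
#' @param predictions list of numeric probability vectors.
#' @param labels list of matching binary label vectors.
#' @param ids protein identifiers.
#' @param threshold decision threshold.
#' @return data.frame with columns `id`, `dice`, `mcc`.
#' @export
evaluateResidueReport <- function(predictions, labels,
                                  ids = seq_along(predictions),
                                  threshold = 0.5) {
  stopifnot(length(predictions) == length(labels))
  rows <- lapply(seq_along(predictions), function(i) {
    cc <- confusionCounts(predictions[[i]], labels[[i]], threshold)
    data.frame(id = as.character(ids[i]),
               dice = suppressWarnings(
                 diceCoefficient(predictions[[i]], labels[[i]],
                                 threshold = threshold)),
               mcc = mcc(cc))
  })
  df <- do.call(rbind, rows)
  rbind(df, data.frame(id = "mean", dice = mean(df$dice), mcc = mean(df$mcc)))
}
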