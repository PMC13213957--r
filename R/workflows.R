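# Predict / proteome / evaluate workflows tying the modules together. A
# thin command-line wrapper over these functions ships in inst/cli/.

requiredKs <- function(...) {
  ms <- Filter(Negate(is.null), list(...))
  sort(unique(unlist(lapply(ms, function(m) m@config@kSchedule))))
}

predictOne <- function(path, residueModel, proteinModel, embedder,
                       source, plddtMin, threshold, outDir, id = NULL) {
  s <- parseStructure(path, source = source, id = id)
  if (!is.null(plddtMin) && s@source == "predicted")
    s <- filterByPlddt(s, plddtMin)
  emb <- embedder(proteinSequence(s))
  cfg <- if (!is.null(residueModel)) residueModel@config
         else proteinModel@config
  graph <- buildResidueGraph(
    s, emb, ks = requiredKs(residueModel, proteinModel),
    config = edgeFeatureConfig(cfg@nRbf, cfg@dMin, cfg@dMax))
  rp <- if (!is.null(residueModel)) predictResidues(residueModel, graph)
        else NULL
  pp <- if (!is.null(proteinModel)) predictProtein(proteinModel, graph)
        else NA_real_
  writePredictions(s, rp, pp, outDir, threshold = threshold)
  list(id = structureId(s), proteinProb = pp,
       residueProbs = rp, n = nResidues(s))
}

#' Predict binding for structure files
#'
#' For each input structure: optional pLDDT trimming, graph build, one or
#' both heads, and report files via [writePredictions()]. A failing file
#' (unreadable, or no residues surviving the confidence filter) is
#' recorded and the batch continues.
#'
#' @param paths character vector of PDB/mmCIF files.
#' @param residueModel,proteinModel fitted [CarbNetModel-class] objects
#'   (either may be NULL to run a single head).
#' @param embedder function(sequence) -> embedding matrix; default the
#'   deterministic stub (see [makeStubEmbedder()]).
#' @param source structure provenance (`"crystal"` or `"predicted"`).
#' @param plddtMin optional confidence cutoff applied to predicted
#'   structures (the proteome analyses use 70).
#' @param threshold decision threshold for binary calls.
#' @param outDir report directory.
#' @return data.frame: one row per input with id, status, protein
#'   probability and call.
#' @export
runPredict <- function(paths, residueModel = NULL, proteinModel = NULL,
                       embedder = makeStubEmbedder(),
                       source = c("crystal", "predicted"), plddtMin = NULL,
                       threshold = 0.5, outDir = ".") {
  source <- match.arg(source)
  stopifnot(!is.null(residueModel) || !is.null(proteinModel))
  rows <- lapply(paths, function(p) {
    r <- tryCatch(
      predictOne(p, residueModel, proteinModel, embedder, source,
                 plddtMin, threshold, outDir),
      error = function(e) e)
    if (inherits(r, "error"))
      data.frame(id = sub("\\.[^.]*$", "", basename(p)), status = "error",
                 proteinProb = NA_real_, call = NA_integer_,
                 message = conditionMessage(r))
    else
      data.frame(id = r$id, status = "ok", proteinProb = r$proteinProb,
                 call = if (is.na(r$proteinProb)) NA_integer_
                        else as.integer(r$proteinProb >= threshold),
                 message = "")
  })
  do.call(rbind, rows)
}

#' Proteome-scale binder annotation
#'
#' Runs the protein head over a directory of predicted structures,
#' skipping (and counting) unreadable files, and writes a per-protein CSV
#' plus a summary: inputs, predicted, skipped, binder calls at the
#' threshold, and the binder fraction.
#'
#' @param dir directory of structure files.
#' @param proteinModel a fitted protein-head model.
#' @param embedder embedding function.
#' @param plddtMin confidence trimming cutoff (default 70).
#' @param threshold binder call threshold (0.5 default; 0.9 for
#'   conservative proteome annotation).
#' @param outDir output directory.
#' @param pattern file glob for structure files.
#' @return list with `perProtein` (data.frame) and `summary` (list).
#' @export
runProteome <- function(dir, proteinModel, embedder = makeStubEmbedder(),
                        plddtMin = 70, threshold = 0.5, outDir = dir,
                        pattern = "\\.(pdb|cif|mmcif)$") {
  paths <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(paths) == 0L) stop("no structure files found in ", dir)
  res <- runPredict(paths, proteinModel = proteinModel, embedder = embedder,
                    source = "predicted", plddtMin = plddtMin,
                    threshold = threshold, outDir = outDir)
  ok <- res$status == "ok"
  summary <- list(nInput = nrow(res), nPredicted = sum(ok),
                  nSkipped = sum(!ok),
                  nBinderCalls = sum(res$call[ok] == 1L),
                  binderFraction = if (any(ok))
                    sum(res$call[ok] == 1L) / sum(ok) else NA_real_)
  utils::write.csv(res, file.path(outDir, "proteome_predictions.csv"),
                   row.names = FALSE, quote = FALSE)
  list(perProtein = res, summary = summary)
}

#' Evaluate models against labeled proteins
#'
#' Residue-level report: per-protein Dice/MCC plus their means (metrics
#' averaged per protein). Protein-level report: BACC/TPR/TNR over the
#' binder calls.
#'
#' @param labeled list of [LabeledProtein-class] objects.
#' @param residueModel,proteinModel fitted models (either may be NULL).
#' @param embedder embedding function; to evaluate with planted-signal
#'   embeddings pass a closure over the labels.
#' @param threshold decision threshold.
#' @return list with `residueReport` (data.frame or NULL) and
#'   `proteinReport` (named vector or NULL), plus raw probabilities.
#' @export
runEvaluate <- function(labeled, residueModel = NULL, proteinModel = NULL,
                        embedder = makeStubEmbedder(), threshold = 0.5) {
  stopifnot(!is.null(residueModel) || !is.null(proteinModel))
  ks <- requiredKs(residueModel, proteinModel)
  resProbs <- list(); resLabels <- list(); ids <- character(0)
  protProbs <- numeric(0); protLabels <- integer(0)
  for (lp in labeled) {
    s <- lp@structure
    emb <- embedder(proteinSequence(s))
    cfg <- if (!is.null(residueModel)) residueModel@config
           else proteinModel@config
    graph <- buildResidueGraph(s, emb, ks = ks,
                               config = edgeFeatureConfig(cfg@nRbf, cfg@dMin,
                                                          cfg@dMax))
    ids <- c(ids, structureId(s))
    if (!is.null(residueModel)) {
      resProbs[[length(resProbs) + 1L]] <- predictResidues(residueModel, graph)
      resLabels[[length(resLabels) + 1L]] <- lp@residueLabels
    }
    if (!is.null(proteinModel)) {
      protProbs <- c(protProbs, predictProtein(proteinModel, graph))
      protLabels <- c(protLabels, lp@proteinLabel)
    }
  }
  residueReport <- if (!is.null(residueModel))
    evaluateResidueReport(resProbs, resLabels, ids, threshold) else NULL
  proteinReport <- if (!is.null(proteinModel))
    baccTprTnr(confusionCounts(protProbs, protLabels, threshold)) else NULL
  list(residueReport = residueReport, proteinReport = proteinReport,
       proteinProbs = protProbs, proteinLabels = protLabels)
}
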