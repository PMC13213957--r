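# Dataset curation rules, sequence-identity clustering, split assignment,
# and the per-epoch sampling scheme.

#' Reassign carbohydrate complexes out of the nonbinder set
#'
#' Any small-molecule entry whose structure carries a noncovalently bound
#' carbohydrate ligand is moved to the binder class with `hasBoundCarb`
#' set. Idempotent.
#'
#' @param manifest data.frame with at least columns `id`, `class`,
#'   `hasBoundCarb`.
#' @param structures named list of [ProteinStructure-class] objects with
#'   resolved ligand flags (see [resolveLigands()]), keyed by `id`.
#' @return the updated manifest.
#' @export
reassignCarbohydrateComplexes <- function(manifest, structures) {
  for (i in seq_len(nrow(manifest))) {
    s <- structures[[manifest$id[i]]]
    if (is.null(s)) next
    hasCarb <- any(vapply(s@ligands, function(lg) {
      if (is.na(lg@isCarbohydrate) || is.na(lg@isCovalent))
        stop("ligand flags unresolved for '", manifest$id[i], "'")
      lg@isCarbohydrate && !lg@isCovalent
    }, logical(1)))
    if (hasCarb) {
      manifest$class[i] <- "carb_binder"
      manifest$hasBoundCarb[i] <- TRUE
    }
  }
  manifest
}

#' N-linked glycosylation sequon
#'
#' `TRUE` iff the sequence contains N-X-(S/T) with X any residue except
#' proline (the biological sequon). Sequences shorter than 3 return
#' `FALSE`.
#'
#' @param sequence uppercase one-letter amino-acid string.
#' @export
hasNxstMotif <- function(sequence) {
  if (nchar(sequence) < 3L) return(FALSE)
  grepl("N[^P][ST]", sequence, perl = TRUE)
}

#' Global pairwise sequence identity
#'
#' Matches over alignment length of a global (Needleman-Wunsch) alignment
#' with match +1, mismatch 0, affine gaps (open 10, extend 0.5) — the
#' identity definition the clustering contract fixes.
#'
#' @param a,b amino-acid strings.
#' @return identity fraction in [0, 1].
#' @export
pairwiseIdentity <- function(a, b) {
  letters <- unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]]))
  mat <- diag(1, length(letters))
  dimnames(mat) <- list(letters, letters)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(pa == pb & pa != "-") / length(pa)
}

#' Greedy sequence-identity clustering
#'
#' Processes sequences longest-first; a sequence joins the first existing
#' cluster whose centroid (founding sequence) it matches at or above the
#' identity threshold, otherwise it founds a new cluster. An external
#' clustering tool with the same output contract may be substituted
#' upstream.
#'
#' @param sequences named character vector of sequences.
#' @param identity threshold fraction in (0, 1], e.g. 0.6.
#' @return list of character vectors of sequence names (the clusters).
#' @export
clusterSequences <- function(sequences, identity = 0.6) {
  stopifnot(identity > 0, identity <= 1)
  if (length(sequences) == 0L) return(list())
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  ord <- order(-nchar(sequences), names(sequences))
  centroids <- character(0)
  clusters <- list()
  for (i in ord) {
    s <- sequences[[i]]
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      if (pairwiseIdentity(s, centroids[[ci]]) >= identity) {
        clusters[[ci]] <- c(clusters[[ci]], names(sequences)[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, s)
      clusters[[length(clusters) + 1L]] <- names(sequences)[i]
    }
  }
  clusters
}

#' Assign clusters to train/validation/test splits
#'
#' Clusters containing pinned entries go to the pinned split (a cluster
#' pinned to two splits is a conflict error); the remaining clusters are
#' shuffled by seed and assigned greedily to whichever split has the
#' largest remaining entry deficit against the target fractions, so no
#' cluster ever spans two splits and the 80/5/15 entry fractions are met
#' as closely as achievable.
#'
#' @param clusters list of character vectors of entry ids.
#' @param fractions named fractions summing to 1
#'   (default `c(train = 0.80, val = 0.05, test = 0.15)`).
#' @param seed shuffle seed.
#' @param pinned optional named character vector entry id -> split.
#' @return list with `clusters`, `assignment` (split per cluster) and
#'   `entrySplit` (named split per entry).
#' @export
assignSplits <- function(clusters,
                         fractions = c(train = 0.80, val = 0.05, test = 0.15),
                         seed = 1L, pinned = NULL) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  splits <- names(fractions)
  nEntries <- sum(lengths(clusters))
  target <- fractions * nEntries
  assignment <- rep(NA_character_, length(clusters))
  got <- stats::setNames(numeric(length(splits)), splits)
  if (!is.null(pinned)) {
    for (ci in seq_along(clusters)) {
      pins <- unique(pinned[names(pinned) %in% clusters[[ci]]])
      if (length(pins) > 1L)
        stop("conflict: cluster ", ci, " pinned to splits ",
             paste(pins, collapse = " and "))
      if (length(pins) == 1L) {
        assignment[ci] <- pins
        got[pins] <- got[pins] + length(clusters[[ci]])
      }
    }
  }
  free <- which(is.na(assignment))
  free <- withSeed(seedKey(seed), free[sample.int(length(free))])
  for (ci in free) {
    deficit <- target - got
    pick <- splits[which.max(deficit)]   # ties: first split in order
    assignment[ci] <- pick
    got[pick] <- got[pick] + length(clusters[[ci]])
  }
  entrySplit <- stats::setNames(
    rep(assignment, lengths(clusters)), unlist(clusters))
  list(clusters = clusters, assignment = assignment, entrySplit = entrySplit)
}

#' Sample one training example per cluster for an epoch
#'
#' Draws exactly one entry uniformly from every cluster; for entries with a
#' predicted structure available, the predicted structure is chosen with
#' probability `af2Prob` (default 0.6) and the crystal structure otherwise.
#' Reproducible per (seed, epoch).
#'
#' @param entries data.frame with columns `id`, `cluster`, `hasPredicted`.
#' @param af2Prob probability of choosing the predicted structure.
#' @param seed,epoch integers keying the RNG.
#' @return data.frame with columns `id`, `structure`
#'   (`"crystal"`/`"predicted"`).
#' @export
epochSample <- function(entries, af2Prob = 0.6, seed = 1L, epoch = 1L) {
  stopifnot(af2Prob >= 0, af2Prob <= 1)
  withSeed(seedKey(seed, epoch), {
    out <- lapply(split(entries, entries$cluster), function(cl) {
      row <- cl[sample.int(nrow(cl), 1L), , drop = FALSE]
      usePred <- isTRUE(row$hasPredicted) && stats::runif(1) < af2Prob
      data.frame(id = row$id,
                 structure = if (usePred) "predicted" else "crystal")
    })
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df
  })
}
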