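# Structure parsing, ligand classification, contact labeling, confidence
# filtering and prediction reports.

WATER_CODES <- c("HOH", "WAT", "DOD", "H2O")

#' Default carbohydrate HET-code vocabulary
#'
#' Reads the shipped YAML list of monosaccharide HET codes (the pyranoses
#' that dominate the structural databases: glucose, galactose, mannose,
#' xylose, fucose, sialic acid, GlcNAc, GalNAc, KDO, ...). Users extend the
#' vocabulary by passing their own YAML file or concatenating codes.
#'
#' @param path YAML file holding a `sugar_codes` list; defaults to the
#'   vocabulary shipped with the package.
#' @return character vector of HET codes.
#' @export
defaultSugarCodes <- function(path = system.file("extdata", "sugar_codes.yaml",
                                                 package = "carbnet")) {
  cfg <- yaml::read_yaml(path)
  toupper(as.character(cfg$sugar_codes))
}

#' Parse a protein structure file
#'
#' Reads a PDB or mmCIF file (via bio3d) into a [ProteinStructure-class].
#' One residue record is produced per standard amino-acid residue with a
#' resolved C-alpha; the C-beta trace falls back to C-alpha for glycine or
#' when no C-beta atom is present. HETATM groups become
#' [LigandGroup-class] objects, excluding waters and monoatomic groups
#' (ions). Only altloc A is kept; hydrogens are dropped. For predicted
#' structures the B-factor column is read as per-residue pLDDT.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @param source `"crystal"` or `"predicted"`; controls pLDDT interpretation.
#' @param id structure identifier; defaults to the file base name.
#' @return a [ProteinStructure-class].
#' @export
parseStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                           source = c("crystal", "predicted"), id = NULL) {
  format <- match.arg(format)
  source <- match.arg(source)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  parsed <- tryCatch(
    if (format == "mmcif") suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    else bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
    error = function(e) stop("cannot parse '", path, "' as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at <- at[at$alt %in% c("", ".", "A"), , drop = FALSE]
  elesy <- at$elesy
  if (is.null(elesy)) elesy <- rep(NA_character_, nrow(at))
  guess <- sub("^[0-9]*", "", at$elety)
  elesy[is.na(elesy) | elesy == ""] <- substr(guess[is.na(elesy) | elesy == ""], 1, 1)
  at$elesy <- toupper(elesy)
  at <- at[!at$elesy %in% c("H", "D"), , drop = FALSE]

  prot <- at[at$type == "ATOM" & at$resid %in% AA3, , drop = FALSE]
  resKey <- paste(prot$chain, prot$resno, prot$insert, prot$resid)
  keys <- unique(resKey)
  resRows <- lapply(keys, function(k) prot[resKey == k, , drop = FALSE])
  hasCa <- vapply(resRows, function(r) any(r$elety == "CA"), logical(1))
  if (!any(hasCa))
    stop("empty structure: no standard residues with resolved C-alpha in '",
         path, "'")
  if (!all(hasCa))
    warning(sum(!hasCa), " residue(s) without C-alpha dropped from '", id, "'")
  resRows <- resRows[hasCa]

  n <- length(resRows)
  ca <- cb <- matrix(0, n, 3)
  resdf <- data.frame(chain = character(n), resno = integer(n),
                      seqIndex = integer(n), resname = character(n),
                      plddt = rep(NA_real_, n), stringsAsFactors = FALSE)
  atomList <- vector("list", n)
  for (i in seq_len(n)) {
    r <- resRows[[i]]
    caRow <- r[match("CA", r$elety), ]
    ca[i, ] <- c(caRow$x, caRow$y, caRow$z)
    cbRow <- if (r$resid[1] != "GLY" && "CB" %in% r$elety)
      r[match("CB", r$elety), ] else caRow
    cb[i, ] <- c(cbRow$x, cbRow$y, cbRow$z)
    resdf$chain[i] <- r$chain[1]
    resdf$resno[i] <- r$resno[1]
    resdf$seqIndex[i] <- i - 1L
    resdf$resname[i] <- r$resid[1]
    if (source == "predicted") resdf$plddt[i] <- caRow$b
    atomList[[i]] <- data.frame(res = i, name = r$elety,
                                x = r$x, y = r$y, z = r$z,
                                stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, atomList)

  het <- at[at$type == "HETATM" & !at$resid %in% c(AA3, WATER_CODES), ,
            drop = FALSE]
  ligs <- list()
  if (nrow(het) > 0) {
    ligKey <- paste(het$chain, het$resno, het$insert, het$resid)
    for (k in unique(ligKey)) {
      g <- het[ligKey == k, , drop = FALSE]
      if (nrow(g) < 2L) next  # monoatomic groups (ions) are not ligands
      ligs[[length(ligs) + 1L]] <- new("LigandGroup",
        resname = toupper(g$resid[1]), chainId = g$chain[1],
        atoms = cbind(g$x, g$y, g$z), elements = g$elesy,
        isCarbohydrate = NA, isCovalent = NA)
    }
  }

  new("ProteinStructure", id = id, residues = resdf, ca = ca, cb = cb,
      atoms = atoms, ligands = ligs, source = source)
}

#' Flag carbohydrate ligands by HET-code vocabulary
#'
#' Sets `isCarbohydrate` on every ligand group: `TRUE` iff its HET code is a
#' member of `sugarCodes`. An empty vocabulary is a configuration error —
#' silently flagging everything negative is forbidden.
#'
#' @param structure a [ProteinStructure-class].
#' @param sugarCodes character vector of HET codes treated as carbohydrates.
#' @return the structure with flags set.
#' @export
identifyCarbohydrateLigands <- function(structure,
                                        sugarCodes = defaultSugarCodes()) {
  if (length(sugarCodes) == 0L)
    stop("configuration error: the sugar-code vocabulary is empty")
  sugarCodes <- toupper(sugarCodes)
  structure@ligands <- lapply(structure@ligands, function(lg) {
    lg@isCarbohydrate <- lg@resname %in% sugarCodes
    lg
  })
  structure
}

#' Detect covalent ligand attachment
#'
#' A ligand group is treated as covalently attached (e.g. an N-linked
#' glycan) when any of its atoms lies within `bondCutoff` of any protein
#' heavy atom. Covalent groups are excluded from binding-site labels.
#'
#' @param ligand a [LigandGroup-class].
#' @param structure the host [ProteinStructure-class] (its heavy atoms are
#'   used).
#' @param bondCutoff bond-length threshold in Angstrom (default 1.8, an
#'   upper bound on common covalent bond lengths).
#' @return logical flag.
#' @export
detectCovalentAttachment <- function(ligand, structure, bondCutoff = 1.8) {
  stopifnot(bondCutoff > 0)
  pa <- as.matrix(structure@atoms[, c("x", "y", "z")])
  min(crossDist(ligand@atoms, pa)) <= bondCutoff
}

#' Resolve carbohydrate and covalency flags for all ligands
#'
#' Convenience wrapper: runs [identifyCarbohydrateLigands()] then
#' [detectCovalentAttachment()] on every group.
#'
#' @inheritParams identifyCarbohydrateLigands
#' @inheritParams detectCovalentAttachment
#' @return the structure with both flags resolved on every ligand.
#' @export
resolveLigands <- function(structure, sugarCodes = defaultSugarCodes(),
                           bondCutoff = 1.8) {
  structure <- identifyCarbohydrateLigands(structure, sugarCodes)
  structure@ligands <- lapply(structure@ligands, function(lg) {
    lg@isCovalent <- detectCovalentAttachment(lg, structure, bondCutoff)
    lg
  })
  structure
}

#' Derive per-residue binding labels from ligand contacts
#'
#' Residue i is labeled 1 iff the minimum heavy-atom distance between the
#' residue and any noncovalently bound in-scope ligand is at most
#' `contactCutoff` (4.2 Angstrom by default, inclusive). The protein-level
#' label is 1 iff the structure carries at least one noncovalent
#' carbohydrate. Flags must have been resolved first (see
#' [resolveLigands()]).
#'
#' @param structure a [ProteinStructure-class] with resolved ligand flags.
#' @param contactCutoff contact distance in Angstrom.
#' @param ligandScope `"carbohydrate"` labels contacts to carbohydrate
#'   ligands only; `"all"` labels contacts to any noncovalent ligand (the
#'   small-molecule pretraining labels).
#' @return a [LabeledProtein-class].
#' @export
labelBindingResidues <- function(structure, contactCutoff = 4.2,
                                 ligandScope = c("carbohydrate", "all")) {
  ligandScope <- match.arg(ligandScope)
  n <- nrow(structure@residues)
  labels <- integer(n)
  carbPresent <- FALSE
  pa <- as.matrix(structure@atoms[, c("x", "y", "z")])
  resIdx <- structure@atoms$res
  for (lg in structure@ligands) {
    if (is.na(lg@isCarbohydrate) || is.na(lg@isCovalent))
      stop("ligand flags unresolved; run resolveLigands() first")
    if (lg@isCovalent) next
    if (lg@isCarbohydrate) carbPresent <- TRUE
    inScope <- if (ligandScope == "carbohydrate") lg@isCarbohydrate else TRUE
    if (!inScope) next
    atomMin <- apply(crossDist(pa, lg@atoms), 1, min)
    resMin <- tapply(atomMin, resIdx, min)
    hit <- as.integer(names(resMin)[resMin <= contactCutoff])
    labels[hit] <- 1L
  }
  new("LabeledProtein", structure = structure, residueLabels = labels,
      proteinLabel = as.integer(carbPresent))
}

#' Filter residues by pLDDT confidence
#'
#' Keeps only residues with pLDDT strictly greater than `minPlddt` (order
#' preserved, `seqIndex` re-densified); ligands are untouched. Crystal
#' structures are returned unchanged with a warning since pLDDT is
#' undefined for them. An empty result is an error.
#'
#' @param structure a predicted-source [ProteinStructure-class].
#' @param minPlddt confidence cutoff (default 70; proteome trimming).
#' @return the trimmed structure.
#' @seealso [plddtGate()] for the structure-level training-augmentation gate.
#' @export
filterByPlddt <- function(structure, minPlddt = 70) {
  if (structure@source != "predicted") {
    warning("pLDDT is undefined for crystal structures; returning unchanged")
    return(structure)
  }
  keep <- which(structure@residues$plddt > minPlddt)
  if (length(keep) == 0L)
    stop("empty structure: no residues with pLDDT > ", minPlddt)
  res <- structure@residues[keep, , drop = FALSE]
  res$seqIndex <- seq_along(keep) - 1L
  rownames(res) <- NULL
  atoms <- structure@atoms[structure@atoms$res %in% keep, , drop = FALSE]
  atoms$res <- match(atoms$res, keep)
  rownames(atoms) <- NULL
  new("ProteinStructure", id = structure@id, residues = res,
      ca = structure@ca[keep, , drop = FALSE],
      cb = structure@cb[keep, , drop = FALSE],
      atoms = atoms, ligands = structure@ligands, source = structure@source)
}

#' Structure-level confidence gate
#'
#' `TRUE` iff the minimum pLDDT over residues exceeds `minPlddt` (default
#' 80) — the gate deciding whether a predicted structure enters the
#' training augmentation pool.
#'
#' @inheritParams filterByPlddt
#' @export
plddtGate <- function(structure, minPlddt = 80) {
  if (structure@source != "predicted") return(FALSE)
  all(!is.na(structure@residues$plddt)) &&
    min(structure@residues$plddt) > minPlddt
}

#' Write prediction reports
#'
#' Writes the per-residue report as TSV (chain, author residue number,
#' residue name, probability, binary call at `threshold`) and the one-line
#' protein report as CSV (id, probability, call). Probabilities are printed
#' to six decimals so identical inputs give bit-stable files.
#'
#' @param structure the predicted [ProteinStructure-class].
#' @param residueProbs numeric vector of per-residue probabilities in [0,1]
#'   (may be NULL when only the protein head ran).
#' @param proteinProb scalar protein probability (may be NA).
#' @param dir output directory (created if needed).
#' @param threshold decision threshold; calls are `probability >= threshold`.
#' @param id report identifier; defaults to the structure id.
#' @return invisibly, the written file paths.
#' @export
writePredictions <- function(structure, residueProbs, proteinProb, dir,
                             threshold = 0.5, id = structureId(structure)) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  paths <- character(0)
  if (!is.null(residueProbs)) {
    stopifnot(length(residueProbs) == nrow(structure@residues),
              all(residueProbs >= 0 & residueProbs <= 1))
    tsv <- file.path(dir, paste0(id, "_residues.tsv"))
    df <- data.frame(chain = structure@residues$chain,
                     resno = structure@residues$resno,
                     resname = structure@residues$resname,
                     probability = sprintf("%.6f", residueProbs),
                     call = as.integer(residueProbs >= threshold))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(residues = tsv)
  }
  if (!is.null(proteinProb) && !is.na(proteinProb)) {
    stopifnot(proteinProb >= 0, proteinProb <= 1)
    csv <- file.path(dir, paste0(id, "_protein.csv"))
    df <- data.frame(id = id, probability = sprintf("%.6f", proteinProb),
                     call = as.integer(proteinProb >= threshold))
    utils::write.table(df, csv, sep = ",", quote = FALSE, row.names = FALSE)
    paths <- c(paths, protein = csv)
  }
  invisible(paths)
}
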