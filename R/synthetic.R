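# Desk-scale synthetic structures, ligands and sequence families with
# controllable signal, so every module runs without downloads. Fixture
# labels always come from the production labeler, never hand-set.

#' Synthetic dataset specification
#'
#' Describes the toy corpus: helical residue traces, planted
#' carbohydrate-like ligand clusters within the contact shell of a chosen
#' pocket, pLDDT-like confidence values, and the signal strength planted
#' into the stub embeddings of binding residues.
#'
#' @param nProteins number of structures.
#' @param lengthRange residue-count range (inclusive).
#' @param pocketSize planted binding-site size (residues).
#' @param ligandAtoms ligand atom count (must be >= `pocketSize` so every
#'   pocket residue gets a contact atom).
#' @param contactRadius planted contact distance (Angstrom, < 4.2 so the
#'   planted contacts are guaranteed positive under the 4.2 labeling rule).
#' @param binderFraction fraction of structures carrying a ligand.
#' @param signalStrength shift planted into embedding channel 1 of binding
#'   residues (see [stubEmbedder()]).
#' @param plddtRange per-residue confidence range written to the B-factor
#'   column.
#' @param seed master seed.
#' @return list with class `syntheticSpec`.
#' @export
syntheticSpec <- function(nProteins = 50L, lengthRange = c(30L, 120L),
                          pocketSize = 5L, ligandAtoms = 8L,
                          contactRadius = 3.5, binderFraction = 0.5,
                          signalStrength = 3, plddtRange = c(85, 98),
                          seed = 1L) {
  stopifnot(pocketSize >= 1L, ligandAtoms >= pocketSize, ligandAtoms >= 2L,
            contactRadius > 0, contactRadius < 4.2,
            binderFraction >= 0, binderFraction <= 1,
            lengthRange[1] >= 10L, lengthRange[2] >= lengthRange[1])
  structure(list(nProteins = as.integer(nProteins),
                 lengthRange = as.integer(lengthRange),
                 pocketSize = as.integer(pocketSize),
                 ligandAtoms = as.integer(ligandAtoms),
                 contactRadius = contactRadius,
                 binderFraction = binderFraction,
                 signalStrength = signalStrength,
                 plddtRange = plddtRange, seed = as.integer(seed)),
            class = "syntheticSpec")
}

# Ideal helix trace: rise 1.5 A, radius 2.3 A, 100 degree turn per residue;
# C-beta offset 1.5 A radially outward.
helixTrace <- function(n) {
  i <- seq_len(n) - 1
  theta <- i * 100 * pi / 180
  ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  cb <- ca + 1.5 * cbind(cos(theta), sin(theta), 0)
  list(ca = ca, cb = cb, theta = theta)
}

#' Generate one toy protein
#'
#' Builds a helical structure (deterministic per `(spec$seed, index)`).
#' Binders carry a `GLC` ligand cluster placed so that each pocket
#' residue's nearest ligand atom lies within `spec$contactRadius` while all
#' other residues stay beyond the 4.2 labeling shell; the labels are then
#' derived by running [resolveLigands()] + [labelBindingResidues()], and
#' placement is retried (bounded) until the labeler reproduces exactly the
#' planted pocket.
#'
#' @param spec a [syntheticSpec()].
#' @param index structure index (1-based).
#' @param binder force binder/nonbinder; default draws from
#'   `spec$binderFraction`.
#' @return a [LabeledProtein-class].
#' @export
generateToyProtein <- function(spec, index, binder = NULL) {
  withSeed(seedKey(spec$seed, index), {
    n <- spec$lengthRange[1] +
      sample.int(spec$lengthRange[2] - spec$lengthRange[1] + 1L, 1L) - 1L
    if (is.null(binder)) binder <- stats::runif(1) < spec$binderFraction
    seqLetters <- sample(AA1, n, replace = TRUE)
    tr <- helixTrace(n)
    cb <- tr$cb
    cb[seqLetters == "G", ] <- tr$ca[seqLetters == "G", ]
    pl <- stats::runif(n, spec$plddtRange[1], spec$plddtRange[2])
    for (attempt in seq_len(25L)) {
      ligAtoms <- NULL
      pocket <- integer(0)
      if (binder) {
        start <- sample(seq_len(n - spec$pocketSize + 1L), 1L)
        pocket <- start:(start + spec$pocketSize - 1L)
        out <- cbind(cos(tr$theta[pocket]), sin(tr$theta[pocket]), 0)
        ligAtoms <- cb[pocket, , drop = FALSE] + 0.9 * spec$contactRadius * out
        extra <- spec$ligandAtoms - spec$pocketSize
        if (extra > 0L) {
          ctr <- colMeans(ligAtoms)
          dir <- normalize3(c(ctr[1], ctr[2], 0))
          ligAtoms <- rbind(ligAtoms, t(vapply(seq_len(extra), function(e)
            ctr + dir * (1 + 0.5 * e), numeric(3))))
        }
      }
      s <- makeToyStructure(sprintf("toy%04d", index), seqLetters, tr$ca, cb,
                            pl, ligAtoms)
      s <- resolveLigands(s)
      lp <- labelBindingResidues(s)
      want <- integer(n)
      want[pocket] <- 1L
      if (identical(lp@residueLabels, want)) return(lp)
    }
    stop("generation error: could not place ligand for index ", index)
  })
}

makeToyStructure <- function(id, seqLetters, ca, cb, pl, ligAtoms,
                             ligCode = "GLC", source = "predicted") {
  n <- length(seqLetters)
  resdf <- data.frame(chain = "A", resno = seq_len(n),
                      seqIndex = seq_len(n) - 1L,
                      resname = aa123(seqLetters), plddt = pl,
                      stringsAsFactors = FALSE)
  atoms <- rbind(
    data.frame(res = seq_len(n), name = "CA", x = ca[, 1], y = ca[, 2],
               z = ca[, 3], stringsAsFactors = FALSE),
    data.frame(res = seq_len(n), name = "CB", x = cb[, 1], y = cb[, 2],
               z = cb[, 3], stringsAsFactors = FALSE))
  atoms <- atoms[order(atoms$res, atoms$name), ]
  rownames(atoms) <- NULL
  ligs <- list()
  if (!is.null(ligAtoms))
    ligs <- list(new("LigandGroup", resname = ligCode, chainId = "B",
                     atoms = ligAtoms,
                     elements = rep("C", nrow(ligAtoms)),
                     isCarbohydrate = NA, isCovalent = NA))
  new("ProteinStructure", id = id, residues = resdf, ca = ca, cb = cb,
      atoms = atoms, ligands = ligs, source = source)
}

#' Generate a toy dataset with manifest
#'
#' Draws `spec$nProteins` structures (binder fraction ~
#' `spec$binderFraction`), optionally writes each as a toy PDB file, and
#' returns the manifest consumable by the data-pipeline functions.
#'
#' @param spec a [syntheticSpec()].
#' @param dir optional directory to write PDB fixtures into.
#' @return list with `proteins` (list of [LabeledProtein-class]) and
#'   `manifest` (data.frame: id, class, hasBoundCarb, sequence, path).
#' @export
generateDataset <- function(spec, dir = NULL) {
  binders <- withSeed(seedKey(spec$seed, 999983L),
                      stats::runif(spec$nProteins) < spec$binderFraction)
  proteins <- lapply(seq_len(spec$nProteins), function(i)
    generateToyProtein(spec, i, binder = binders[i]))
  ids <- vapply(proteins, function(p) p@structure@id, character(1))
  paths <- rep(NA_character_, length(proteins))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, paste0(ids, ".pdb"))
    for (i in seq_along(proteins))
      writeToyPdb(proteins[[i]]@structure, paths[i])
  }
  manifest <- data.frame(
    id = ids,
    class = ifelse(binders, "carb_binder", "putative_nonbinder"),
    hasBoundCarb = binders,
    sequence = vapply(proteins, proteinSequence, character(1)),
    path = paths, stringsAsFactors = FALSE)
  list(proteins = proteins, manifest = manifest)
}

#' Write a structure as a toy PDB file
#'
#' Fixed-width ATOM/HETATM records; the B-factor column carries the
#' per-residue pLDDT. Fixture plumbing: the writer covers exactly what the
#' toy structures contain.
#'
#' @param structure a [ProteinStructure-class].
#' @param path output file.
#' @export
writeToyPdb <- function(structure, path) {
  lines <- character(0)
  serial <- 0L
  res <- structure@residues
  for (i in seq_len(nrow(res))) {
    ra <- structure@atoms[structure@atoms$res == i, , drop = FALSE]
    b <- if (is.na(res$plddt[i])) 0 else res$plddt[i]
    for (j in seq_len(nrow(ra))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, ra$name[j], " ", res$resname[i], res$chain[i], res$resno[i],
        " ", ra$x[j], ra$y[j], ra$z[j], 1.00, b, "C"))
    }
  }
  hetno <- 900L
  for (lg in structure@ligands) {
    hetno <- hetno + 1L
    for (j in seq_len(nrow(lg@atoms))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "HETATM%5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, paste0("C", j), " ", lg@resname, lg@chainId, hetno, " ",
        lg@atoms[j, 1], lg@atoms[j, 2], lg@atoms[j, 3], 1.00, 0,
        lg@elements[j]))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a structure as a toy mmCIF file
#'
#' Minimal `atom_site` loop mirroring [writeToyPdb()]; used to exercise the
#' mmCIF reading path on identical coordinates.
#'
#' @inheritParams writeToyPdb
#' @export
writeToyCif <- function(structure, path) {
  hdr <- c(paste0("data_", structure@id), "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_alt_id", "_atom_site.label_comp_id",
           "_atom_site.label_asym_id", "_atom_site.label_entity_id",
           "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
           "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
           "_atom_site.pdbx_PDB_model_num")
  rows <- character(0)
  serial <- 0L
  res <- structure@residues
  for (i in seq_len(nrow(res))) {
    ra <- structure@atoms[structure@atoms$res == i, , drop = FALSE]
    b <- if (is.na(res$plddt[i])) 0 else res$plddt[i]
    for (j in seq_len(nrow(ra))) {
      serial <- serial + 1L
      rows <- c(rows, sprintf(
        "ATOM %d C %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 %.2f %d %s %s %s 1",
        serial, ra$name[j], res$resname[i], res$chain[i], res$resno[i],
        ra$x[j], ra$y[j], ra$z[j], b, res$resno[i], res$resname[i],
        res$chain[i], ra$name[j]))
    }
  }
  hetno <- 900L
  for (lg in structure@ligands) {
    hetno <- hetno + 1L
    for (j in seq_len(nrow(lg@atoms))) {
      serial <- serial + 1L
      rows <- c(rows, sprintf(
        "HETATM %d %s %s . %s %s 2 %d ? %.3f %.3f %.3f 1.00 %.2f %d %s %s %s 1",
        serial, lg@elements[j], paste0("C", j), lg@resname, lg@chainId,
        hetno, lg@atoms[j, 1], lg@atoms[j, 2], lg@atoms[j, 3], 0,
        hetno, lg@resname, lg@chainId, paste0("C", j)))
    }
  }
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}

#' Generate synthetic sequence families
#'
#' `nFamilies` random parents over (near-)disjoint residue alphabets (so
#' cross-family identity stays far below the clustering threshold); each
#' family contributes `copies` sequences mutated at a fixed position set so
#' every pair within a family sits close to `withinIdentity`.
#'
#' @param nFamilies,copies family count and copies per family.
#' @param withinIdentity target within-family identity, in (0.6, 1].
#' @param seed RNG seed.
#' @return named character vector of `nFamilies * copies` sequences; names
#'   are `fam<f>_<c>`.
#' @export
makeSequenceFamilies <- function(nFamilies = 20L, copies = 5L,
                                 withinIdentity = 0.9, seed = 1L) {
  stopifnot(withinIdentity > 0.6, withinIdentity <= 1)
  withSeed(seedKey(seed, nFamilies, copies), {
    out <- character(0)
    famLetters <- rep(AA1, length.out = nFamilies)
    for (f in seq_len(nFamilies)) {
      L <- sample(60:100, 1L)
      parent <- rep(famLetters[f], L)
      nMut <- round((1 - withinIdentity) * L)
      mutPos <- sample.int(L, nMut)
      for (cp in seq_len(copies)) {
        s <- parent
        s[mutPos] <- sample(setdiff(AA1, famLetters[f]), nMut, replace = TRUE)
        out[sprintf("fam%02d_%d", f, cp)] <- paste(s, collapse = "")
      }
    }
    out
  })
}
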