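# Parsing, ligand classification, contact labeling, confidence filtering.

writeThreeResidueFixture <- function(path, ligDist = 3.0) {
  # ALA-GLY-SER backbone plus a two-atom GLC ligand at a controlled distance
  lines <- c(
    sprintf("ATOM  %5d  CA  ALA A   1    %8.3f%8.3f%8.3f  1.00 90.00           C", 1, 0, 0, 0),
    sprintf("ATOM  %5d  CB  ALA A   1    %8.3f%8.3f%8.3f  1.00 90.00           C", 2, 1.5, 0, 0),
    sprintf("ATOM  %5d  CA  GLY A   2    %8.3f%8.3f%8.3f  1.00 80.00           C", 3, 3.8, 0, 0),
    sprintf("ATOM  %5d  CA  SER A   3    %8.3f%8.3f%8.3f  1.00 60.00           C", 4, 7.6, 0, 0),
    sprintf("ATOM  %5d  OG  SER A   3    %8.3f%8.3f%8.3f  1.00 60.00           O", 5, 8.6, 0, 0),
    sprintf("HETATM%5d  C1  GLC A 901    %8.3f%8.3f%8.3f  1.00  0.00           C", 6, 0, ligDist, 0),
    sprintf("HETATM%5d  C2  GLC A 901    %8.3f%8.3f%8.3f  1.00  0.00           C", 7, 1.5, ligDist, 0),
    "END")
  writeLines(lines, path)
  path
}

test_that("parsing preserves residue and ligand counts and the glycine rule", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeThreeResidueFixture(path)
  s <- parseStructure(path, source = "predicted")
  expect_equal(nResidues(s), 3L)
  expect_length(ligands(s), 1L)
  expect_equal(ligandResname(ligands(s)[[1]]), "GLC")
  # glycine without a C-beta: cb must equal ca bit-exactly
  gly <- which(residues(s)$resname == "GLY")
  expect_identical(cbCoords(s)[gly, ], caCoords(s)[gly, ])
  # pLDDT read from the B-factor column
  expect_equal(plddt(s), c(90, 80, 60))
  # seqIndex 0-based and strictly increasing
  expect_equal(residues(s)$seqIndex, 0:2)
})

test_that("parsing errors are informative", {
  expect_error(parseStructure(tempfile()), "not found")
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HETATM    1  C1  GLC A 901       0.0     0.0   0.0",
               "END"), bad)
  expect_error(parseStructure(bad), "empty structure")
})

test_that("PDB and mmCIF of the same coordinates parse identically", {
  lp <- toyBinder(seed = 21)
  s <- labeledStructure(lp)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  cif <- withr::local_tempfile(fileext = ".cif")
  writeToyPdb(s, pdb)
  writeToyCif(s, cif)
  p1 <- parseStructure(pdb, source = "predicted")
  p2 <- parseStructure(cif, source = "predicted")
  expect_equal(nResidues(p1), nResidues(p2))
  expect_lt(max(abs(caCoords(p1) - caCoords(p2))), 1e-3)
  expect_lt(max(abs(cbCoords(p1) - cbCoords(p2))), 1e-3)
  expect_equal(residues(p1)$resname, residues(p2)$resname)
})

test_that("carbohydrate flagging follows the vocabulary and rejects empty sets", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeThreeResidueFixture(path)
  s <- parseStructure(path)
  s2 <- identifyCarbohydrateLigands(s)
  expect_true(isCarbohydrate(ligands(s2)[[1]]))
  s3 <- identifyCarbohydrateLigands(s, sugarCodes = c("ATP"))
  expect_false(isCarbohydrate(ligands(s3)[[1]]))
  expect_error(identifyCarbohydrateLigands(s, sugarCodes = character(0)),
               "configuration error")
})

test_that("covalent attachment detection thresholds at the bond cutoff", {
  near <- parseStructure(
    writeThreeResidueFixture(withr::local_tempfile(fileext = ".pdb"),
                             ligDist = 1.4))
  far <- parseStructure(
    writeThreeResidueFixture(withr::local_tempfile(fileext = ".pdb"),
                             ligDist = 3.0))
  expect_true(detectCovalentAttachment(ligands(near)[[1]], near))
  expect_false(detectCovalentAttachment(ligands(far)[[1]], far))
})

test_that("covalently attached ligands contribute zero binding labels", {
  s <- parseStructure(
    writeThreeResidueFixture(withr::local_tempfile(fileext = ".pdb"),
                             ligDist = 1.4))
  s <- resolveLigands(s)
  expect_true(isCovalent(ligands(s)[[1]]))
  lp <- labelBindingResidues(s)
  expect_equal(sum(residueLabels(lp)), 0L)
  expect_equal(proteinLabel(lp), 0L)
})

test_that("contact labeling is inclusive at 4.2 A and matches brute force", {
  at42 <- parseStructure(
    writeThreeResidueFixture(withr::local_tempfile(fileext = ".pdb"),
                             ligDist = 4.2))
  lp42 <- labelBindingResidues(resolveLigands(at42))
  expect_equal(residueLabels(lp42)[1], 1L)   # exactly at the cutoff
  beyond <- parseStructure(
    writeThreeResidueFixture(withr::local_tempfile(fileext = ".pdb"),
                             ligDist = 4.3))
  lp43 <- labelBindingResidues(resolveLigands(beyond))
  expect_equal(sum(residueLabels(lp43)), 0L)
  expect_equal(proteinLabel(lp43), 1L)  # noncovalent carbohydrate present

  # random fixture: independent O(N*M) double-loop oracle
  lp <- toyBinder(seed = 8)
  s <- labeledStructure(lp)
  lig <- ligands(s)[[1]]
  atoms <- heavyAtoms(s)
  oracle <- integer(nResidues(s))
  for (i in seq_len(nResidues(s))) {
    ra <- atoms[atoms$res == i, , drop = FALSE]
    mind <- Inf
    for (a in seq_len(nrow(ra))) for (b in seq_len(nrow(ligandAtoms(lig)))) {
      d <- sqrt(sum((c(ra$x[a], ra$y[a], ra$z[a]) - ligandAtoms(lig)[b, ])^2))
      mind <- min(mind, d)
    }
    oracle[i] <- as.integer(mind <= 4.2)
  }
  expect_identical(residueLabels(lp), oracle)
})

test_that("pLDDT filtering is strict, monotone, and re-densifies indices", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeThreeResidueFixture(path)
  s <- parseStructure(path, source = "predicted")   # plddt 90, 80, 60
  f70 <- filterByPlddt(s, 70)
  expect_equal(nResidues(f70), 2L)
  expect_equal(residues(f70)$seqIndex, 0:1)
  expect_equal(nResidues(filterByPlddt(s, 50)), 3L)
  # strict inequality: cutoff exactly at a value drops it
  expect_equal(nResidues(filterByPlddt(s, 80)), 1L)
  # monotonicity: raising the cutoff never increases retained count
  counts <- vapply(c(0, 55, 65, 75, 85, 95),
                   function(m) tryCatch(nResidues(filterByPlddt(s, m)),
                                        error = function(e) 0L), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(filterByPlddt(s, 95), "empty structure")
  expect_warning(filterByPlddt(parseStructure(path), 70), "crystal")
  # structure-level augmentation gate uses the minimum residue confidence
  expect_false(plddtGate(s, 80))
  expect_true(plddtGate(filterByPlddt(s, 70), 75))
})

test_that("prediction reports round-trip and threshold correctly", {
  lp <- toyBinder(seed = 5)
  s <- labeledStructure(lp)
  dir <- withr::local_tempdir()
  probs <- seq(0.01, 0.99, length.out = nResidues(s))
  paths <- writePredictions(s, probs, 0.95, dir, threshold = 0.9)
  tsv <- read.delim(paths[["residues"]])
  expect_equal(nrow(tsv), nResidues(s))
  expect_equal(tsv$probability, probs, tolerance = 1e-6)
  expect_equal(tsv$call, as.integer(probs >= 0.9))
  csv <- read.csv(paths[["protein"]])
  expect_equal(csv$call, 1L)           # 0.95 >= 0.9
  paths2 <- writePredictions(s, probs, 0.85, dir, threshold = 0.9,
                             id = "thr2")
  expect_equal(read.csv(paths2[["protein"]])$call, 0L)  # 0.85 < 0.9
  # byte-stability on identical inputs
  before <- readLines(paths[["residues"]])
  writePredictions(s, probs, 0.95, dir, threshold = 0.9)
  expect_identical(readLines(paths[["residues"]]), before)
})
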