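# Accessors and show methods for the core classes.

#' @rdname ProteinStructure-class
#' @param object,x a \code{ProteinStructure}
#' @export
residues <- function(x) x@residues

#' Number of residues
#' @param x a \code{ProteinStructure} or \code{LabeledProtein}
#' @export
nResidues <- function(x) {
  if (is(x, "LabeledProtein")) x <- x@structure
  nrow(x@residues)
}

#' @rdname ProteinStructure-class
#' @export
caCoords <- function(x) x@ca

#' @rdname ProteinStructure-class
#' @export
cbCoords <- function(x) x@cb

#' @rdname ProteinStructure-class
#' @export
heavyAtoms <- function(x) x@atoms

#' @rdname ProteinStructure-class
#' @export
ligands <- function(x) x@ligands

#' @rdname ProteinStructure-class
#' @export
structureSource <- function(x) x@source

#' @rdname ProteinStructure-class
#' @export
structureId <- function(x) x@id

#' Per-residue pLDDT values (NA for crystal structures)
#' @param x a \code{ProteinStructure}
#' @export
plddt <- function(x) x@residues$plddt

#' One-letter sequence of a structure
#'
#' Concatenated over chains in file order; unknown 3-letter codes map to X.
#' @param x a \code{ProteinStructure} or \code{LabeledProtein}
#' @export
proteinSequence <- function(x) {
  if (is(x, "LabeledProtein")) x <- x@structure
  paste(aa321(x@residues$resname), collapse = "")
}

#' @rdname LigandGroup-class
#' @param x a \code{LigandGroup}
#' @export
isCarbohydrate <- function(x) x@isCarbohydrate

#' @rdname LigandGroup-class
#' @export
isCovalent <- function(x) x@isCovalent

#' @rdname LigandGroup-class
#' @export
ligandResname <- function(x) x@resname

#' @rdname LigandGroup-class
#' @export
ligandAtoms <- function(x) x@atoms

#' @rdname LabeledProtein-class
#' @param x a \code{LabeledProtein}
#' @export
residueLabels <- function(x) x@residueLabels

#' @rdname LabeledProtein-class
#' @export
proteinLabel <- function(x) x@proteinLabel

#' @rdname LabeledProtein-class
#' @export
labeledStructure <- function(x) x@structure

#' @rdname ResidueGraph-class
#' @param x a \code{ResidueGraph}
#' @export
graphCoords <- function(x) x@coords

#' @rdname ResidueGraph-class
#' @export
nodeFeatures <- function(x) x@nodeFeats

#' @rdname ResidueGraph-class
#' @param k neighbourhood size (integer); must be one the graph was built with
#' @export
neighborIndices <- function(x, k) {
  nb <- x@neighbors[[as.character(k)]]
  if (is.null(nb)) stop("graph was not built with k = ", k)
  nb
}

#' @rdname ResidueGraph-class
#' @export
edgeFeatureTensor <- function(x, k) {
  ef <- x@edgeFeats[[as.character(k)]]
  if (is.null(ef)) stop("graph was not built with k = ", k)
  ef
}

#' @rdname ResidueGraph-class
#' @export
localFrameArray <- function(x) x@frames

#' @rdname ConfusionCounts-class
#' @param x a \code{ConfusionCounts}
#' @export
asCounts <- function(x) c(tp = x@tp, fp = x@fp, tn = x@tn, fn = x@fn)

#' @rdname CarbNetModel-class
#' @param x a \code{CarbNetModel}
#' @export
modelConfig <- function(x) x@config

#' @rdname CarbNetModel-class
#' @export
modelWeights <- function(x) x@weights

setMethod("show", "ProteinStructure", function(object) {
  cat(sprintf("ProteinStructure '%s' (%s): %d residues, %d chains, %d ligand groups\n",
              object@id, object@source, nrow(object@residues),
              length(unique(object@residues$chain)), length(object@ligands)))
})

setMethod("show", "LigandGroup", function(object) {
  cat(sprintf("LigandGroup %s (chain %s): %d atoms, carbohydrate=%s, covalent=%s\n",
              object@resname, object@chainId, nrow(object@atoms),
              object@isCarbohydrate, object@isCovalent))
})

setMethod("show", "LabeledProtein", function(object) {
  cat(sprintf("LabeledProtein '%s': %d residues, %d binding residues, protein label %d\n",
              object@structure@id, length(object@residueLabels),
              sum(object@residueLabels), object@proteinLabel))
})

setMethod("show", "ResidueGraph", function(object) {
  cat(sprintf("ResidueGraph: %d nodes, %d-dim node features, k = {%s}\n",
              nrow(object@coords), ncol(object@nodeFeats),
              paste(names(object@neighbors), collapse = ", ")))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig (%s head): %d layers, dim %d, input %d, k = {%s}\n",
              object@head, object@nLayers, object@embedDim, object@inputDim,
              paste(unique(object@kSchedule), collapse = ", ")))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d FP=%d TN=%d FN=%d\n",
              object@tp, object@fp, object@tn, object@fn))
})

setMethod("show", "CarbNetModel", function(object) {
  cat(sprintf("CarbNetModel (%s head): %d trainable parameters\n",
              object@config@head, countParameters(object)))
})
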