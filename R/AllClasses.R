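#' @import methods
NULL

#' Ligand group
#'
#' One HETATM residue group of a structure: its HET code, chain, atom
#' coordinates and element symbols, plus two flags resolved by the curation
#' steps: whether the group is a carbohydrate (HET code membership in the
#' configured sugar vocabulary) and whether it is covalently attached to the
#' protein (any ligand heavy atom within the bond cutoff of a protein heavy
#' atom). `isCovalent` is `NA` until [detectCovalentAttachment()] (or
#' [resolveLigands()]) has run.
#'
#' @slot resname HET code (e.g. `"GLC"`).
#' @slot chainId chain identifier the group was read from.
#' @slot atoms numeric matrix (n x 3) of atom coordinates in Angstrom.
#' @slot elements character vector of element symbols, one per atom.
#' @slot isCarbohydrate logical flag, `NA` until resolved.
#' @slot isCovalent logical flag, `NA` until resolved.
#' @export
setClass("LigandGroup",
  representation(resname = "character", chainId = "character",
                 atoms = "matrix", elements = "character",
                 isCarbohydrate = "logical", isCovalent = "logical"),
  prototype(isCarbohydrate = NA, isCovalent = NA))

setValidity("LigandGroup", function(object) {
  if (nrow(object@atoms) < 1L) return("ligand group must contain atoms")
  if (ncol(object@atoms) != 3L) return("atoms must be an n x 3 matrix")
  if (length(object@elements) != nrow(object@atoms))
    return("one element symbol per atom required")
  TRUE
})

#' Protein structure
#'
#' A parsed protein structure: one row of `residues` per standard amino-acid
#' residue (chain, author residue number, 0-based `seqIndex` in concatenated
#' chain order, 3-letter code, optional pLDDT), the C-alpha and C-beta traces
#' as N x 3 matrices (C-beta equals C-alpha for glycine or when no C-beta
#' atom is present), all protein heavy atoms in a long-format data frame
#' keyed by 1-based residue row, and the HETATM ligand groups (waters and
#' monoatomic ions excluded).
#'
#' @slot id structure identifier.
#' @slot residues data.frame with columns `chain`, `resno`, `seqIndex`,
#'   `resname`, `plddt`.
#' @slot ca,cb numeric N x 3 coordinate matrices (Angstrom).
#' @slot atoms data.frame with columns `res` (1-based residue row), `name`,
#'   `x`, `y`, `z`: every protein heavy atom.
#' @slot ligands list of [LigandGroup-class] objects.
#' @slot source `"crystal"` or `"predicted"`; pLDDT is only defined for
#'   predicted structures.
#' @export
setClass("ProteinStructure",
  representation(id = "character", residues = "data.frame",
                 ca = "matrix", cb = "matrix", atoms = "data.frame",
                 ligands = "list", source = "character"))

setValidity("ProteinStructure", function(object) {
  n <- nrow(object@residues)
  if (n < 1L) return("structure must contain at least one residue")
  if (nrow(object@ca) != n || nrow(object@cb) != n)
    return("ca/cb traces must have one row per residue")
  if (!all(object@source %in% c("crystal", "predicted")))
    return("source must be 'crystal' or 'predicted'")
  si <- object@residues$seqIndex
  if (any(diff(si) <= 0)) return("seqIndex must be strictly increasing")
  if (nrow(object@atoms) < 1L) return("heavy atom table is empty")
  if (!all(seq_len(n) %in% object@atoms$res))
    return("every residue needs at least one heavy atom")
  gly <- object@residues$resname == "GLY"
  if (any(gly) && !identical(object@cb[gly, , drop = FALSE],
                             object@ca[gly, , drop = FALSE]))
    return("glycine C-beta must equal C-alpha")
  TRUE
})

#' Labeled protein
#'
#' A [ProteinStructure-class] together with its per-residue binary
#' binding-site labels and the protein-level binder label. Labels are always
#' derived by [labelBindingResidues()], never set directly.
#'
#' @slot structure the underlying [ProteinStructure-class].
#' @slot residueLabels integer 0/1 vector, one entry per residue.
#' @slot proteinLabel integer 0/1: does the structure carry a noncovalently
#'   bound carbohydrate.
#' @export
setClass("LabeledProtein",
  representation(structure = "ProteinStructure",
                 residueLabels = "integer", proteinLabel = "integer"))

setValidity("LabeledProtein", function(object) {
  n <- nrow(object@structure@residues)
  if (length(object@residueLabels) != n)
    return("one label per residue required")
  if (!all(object@residueLabels %in% c(0L, 1L)))
    return("residue labels must be 0/1")
  if (!object@proteinLabel %in% c(0L, 1L))
    return("protein label must be 0/1")
  TRUE
})

#' Residue graph
#'
#' The network-ready representation of a structure: C-beta node coordinates,
#' the node feature matrix (per-residue embeddings), directed k-nearest
#' neighbour index matrices for every required neighbourhood size, the
#' matching rigid-motion-invariant edge feature tensors, and the per-residue
#' local orthonormal frames the edge features were computed in.
#'
#' @slot coords numeric N x 3 matrix of C-beta positions (Angstrom).
#' @slot nodeFeats numeric N x D matrix of per-residue embeddings.
#' @slot neighbors named list (by k) of integer N x k' matrices, k' =
#'   min(k, N - 1); rows hold neighbour indices in ascending distance order.
#' @slot edgeFeats named list (by k) of numeric N x k' x E arrays.
#' @slot frames numeric N x 3 x 3 array; `frames[i, , ]` is the orthonormal
#'   right-handed basis at residue i (columns are the axes).
#' @export
setClass("ResidueGraph",
  representation(coords = "matrix", nodeFeats = "matrix",
                 neighbors = "list", edgeFeats = "list", frames = "array"))

setValidity("ResidueGraph", function(object) {
  n <- nrow(object@coords)
  if (nrow(object@nodeFeats) != n)
    return("node feature rows must match coordinate rows")
  for (k in names(object@neighbors)) {
    nb <- object@neighbors[[k]]
    if (nrow(nb) != n) return("neighbor matrix rows must equal N")
    if (any(nb == seq_len(n))) return("self-neighbors are not allowed")
  }
  if (!identical(sort(names(object@neighbors)), sort(names(object@edgeFeats))))
    return("neighbors and edgeFeats must cover the same k values")
  TRUE
})

#' Model configuration
#'
#' Full architecture hyper-parameters for the two heads. The trunk is shared:
#' a linear projection of the input embeddings to `embedDim`, then `nLayers`
#' residual equivariant graph-convolution layers whose layer-wise
#' neighbourhood sizes are `kSchedule`. `head = "residue"` appends a
#' two-layer dense decoder with a sigmoid per residue; `head = "protein"`
#' appends adaptive pooling of the sequence to `poolLen`, two stride-2
#' convolution layers and three dense layers to a single sigmoid.
#'
#' Defaults come from [residueModelConfig()] / [proteinModelConfig()], whose
#' hidden widths are calibrated so that [countParameters()] reproduces the
#' reference totals (1,600,387 and 1,798,895 trainable parameters).
#'
#' @slot head `"residue"` or `"protein"`.
#' @slot nLayers,embedDim,inputDim trunk depth, trunk width, embedder width.
#' @slot kSchedule integer vector of length `nLayers`: neighbourhood size
#'   used by each layer.
#' @slot edgeHidden,nodeHidden hidden widths of the edge-message and
#'   node-update MLPs inside each graph-convolution layer.
#' @slot decoderHidden hidden width of the per-residue decoder (residue head).
#' @slot poolLen,convChannels,convKernel,convStride,denseWidths protein-head
#'   geometry: pooled sequence length, the two conv channel counts, square
#'   kernel size, stride, and the two hidden dense widths.
#' @slot nRbf,dMin,dMax radial-basis edge encoding (count and range, Angstrom).
#' @slot initSigma standard deviation of the Normal(0, sigma) weight init.
#' @export
setClass("ModelConfig",
  representation(head = "character", nLayers = "integer",
                 embedDim = "integer", inputDim = "integer",
                 kSchedule = "integer", edgeHidden = "integer",
                 nodeHidden = "integer", decoderHidden = "integer",
                 poolLen = "integer", convChannels = "integer",
                 convKernel = "integer", convStride = "integer",
                 denseWidths = "integer", nRbf = "integer",
                 dMin = "numeric", dMax = "numeric", initSigma = "numeric"))

setValidity("ModelConfig", function(object) {
  if (!object@head %in% c("residue", "protein"))
    return("head must be 'residue' or 'protein'")
  if (length(object@kSchedule) != object@nLayers)
    return("kSchedule must name one k per layer")
  if (object@nRbf < 1L) return("nRbf must be >= 1")
  if (object@dMax <= object@dMin) return("dMax must exceed dMin")
  if (!is.na(object@initSigma) && object@initSigma <= 0)
    return("initSigma must be positive (or NA for fan-in scaling)")
  if (object@head == "protein") {
    if (object@poolLen < 1L) return("poolLen must be >= 1")
    if (length(object@convChannels) != 2L || length(object@denseWidths) != 2L)
      return("protein head needs 2 conv channel counts and 2 dense widths")
  }
  TRUE
})

#' Confusion counts
#'
#' The TP/FP/TN/FN counts underlying every classification metric.
#'
#' @slot tp,fp,tn,fn nonnegative integer counts.
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", fp = "integer", tn = "integer",
                 fn = "integer"))

setValidity("ConfusionCounts", function(object) {
  if (any(c(object@tp, object@fp, object@tn, object@fn) < 0L))
    return("counts must be nonnegative")
  TRUE
})

#' Fitted graph network
#'
#' A configuration plus its weight tensors (named nested list). Construct
#' with [buildModel()]; the weights are plain numeric arrays so that
#' checkpoints serialize portably.
#'
#' @slot config the [ModelConfig-class].
#' @slot weights nested named list of numeric arrays.
#' @export
setClass("CarbNetModel",
  representation(config = "ModelConfig", weights = "list"))
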