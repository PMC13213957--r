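---
title: "carbnet: residue-graph networks for carbohydrate-binding prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{carbnet: residue-graph networks for carbohydrate-binding prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbnet)
```

## The problem

Most proteins that bind carbohydrates are not lectins, and most structural
databases annotate the bound sugar, not the binding capability. carbnet
implements a two-headed geometric deep-learning approach to this problem:

* a **residue head** that labels which residues of a structure bind
  carbohydrates (an imbalanced segmentation task: typically ~5% of residues
  are positives), and
* a **protein head** that classifies whole structures as carbohydrate
  binders or nonbinders, enabling proteome-scale annotation of predicted
  structures.

Both heads share one trunk: a residual message-passing network over a
residue graph whose geometry enters only through rigid-motion-invariant
edge features.

## Input representation

A structure is reduced to its residues. Each residue contributes its
C-beta position (C-alpha for glycine) and a 1,280-value embedding from a
pluggable per-residue embedder. The embedder is a contract — any function
`f(sequence) -> N x 1280 matrix` works; the package ships a deterministic
stub ([stubEmbedder()]) whose planted-signal mode supports controlled
experiments, and a real protein-language-model adapter can be substituted
without touching the rest of the pipeline.

Residues are connected to their k nearest neighbours (directed; k-NN
graphs are not symmetric). For a directed edge (i, j) the edge feature
vector concatenates:

* a 16-component radial basis encoding of the distance, centers evenly
  spaced on [0, 20] Angstrom, width equal to the spacing;
* the unit direction to j expressed in the local frame of residue i
  (3 values);
* the quaternion of the relative rotation between the two local frames
  (4 values, scalar first, sign fixed by a nonnegative scalar part).

Local frames are built by Gram-Schmidt on the sequence-adjacent C-beta
difference vectors, the third axis being their cross product; terminal
residues copy the frame of their unique neighbour. Because the trace
stores only C-beta positions, frames from backbone atoms are not
available; sequence-adjacent differences keep the construction inside the
stored inputs while making orientation well defined. Every edge feature
is invariant under global rotation and translation, so both heads are
exactly invariant to rigid motion of the input — a property the test
suite checks numerically rather than assumes.

## Architecture

The trunk projects the 1,280-dim embeddings to width 128 and applies 12
residual graph-convolution layers. Each layer computes a message
`m_ij = MLP_e([h_i, h_j, e_ij])` for every neighbour, sums the k messages,
and updates `h_i' = h_i + MLP_h([h_i, a_i])`. Coordinates are never
updated: the prediction targets are invariant, the edge features are
invariant, and a coordinate stream would add cost without information.

* The **residue head** uses k = 16 for all layers, then a two-layer dense
  decoder (hidden width 129) to a per-residue sigmoid.
* The **protein head** widens its receptive field with a staged schedule —
  layers 1-3 use k = 10, 4-6 use 20, 7-9 use 40, 10-12 use 60 — then pools
  the residue dimension adaptively to a fixed length of 150, treats the
  resulting 150 x 128 map as a one-channel image, and applies two 3x3
  stride-2 convolutions (8 channels each) and three dense layers
  (22, 24, 1) to a single sigmoid.

Activations are SiLU throughout (a common default for this family of
networks; the choice is recorded in the configuration and swappable).

### Width calibration

The reference architecture publishes only its depth, trunk width and two
total parameter counts: 1,600,387 trainable scalars for the residue model
and 1,798,895 for the protein model. The internal MLP widths are
undocumented, so carbnet fixes them by integer search constrained to
reproduce both totals exactly with a shared trunk: edge-MLP hidden 161,
node-MLP hidden 136, decoder hidden 129, and the conv/dense head above.
`countParameters(buildModel(residueModelConfig()))` reproduces the counts
at runtime; they depend only on the configuration, never on input size.

## Labels and curation

Residue labels are geometric: residue i is positive iff its minimum
heavy-atom distance to any noncovalently bound carbohydrate (or, for the
pretraining cycle, any small-molecule ligand) is at most 4.2 Angstrom.
Choices the source text leaves open, fixed here:

* contact atoms are heavy atoms (hydrogens are absent from most crystal
  structures) and the cutoff is inclusive;
* a ligand group is covalent — and therefore excluded from labels — when
  any of its atoms is within 1.8 Angstrom of a protein heavy atom (an
  upper bound on common covalent bond lengths);
* "carbohydrate" is operational: membership of the HET code in a shipped,
  user-extensible vocabulary seeded with the pyranoses that dominate the
  structural databases (GLC, GAL, MAN, XYS/XYP, FUC, SIA, NAG, NGA, KDO
  and their anomers);
* waters and monoatomic HETATM groups (ions) are never ligands;
* only altloc A is kept; multi-model files reduce to model 1; pLDDT
  comparisons are strict (`> 70` for proteome trimming, `> 80` for the
  training-augmentation gate), matching the stated protocol.

Dataset curation follows the published rules: carbohydrate-bearing
entries found in the small-molecule nonbinder pool are reassigned to the
binder class; candidate nonbinder antibodies are excluded when the
antigen carries an N-X-(S/T) sequon, with X read as any residue except
proline (the biological sequon; the source writes only "NX(S/T)").

## Redundancy control and splits

Sequences are clustered greedily at 60% identity (longest sequence first,
join the first cluster whose founding sequence matches at or above
threshold). Identity is matches over alignment length of a global
alignment with match +1, mismatch 0, gap open 10, gap extend 0.5 — the
external clustering tool used by the original pipeline does not document
its identity definition, so the package fixes one and exposes an adapter
point. Clusters (never entries) are assigned to train/validation/test at
80/5/15 by entry count, greedily by largest remaining deficit after a
seeded shuffle, with pinned entries dragging their whole cluster to the
pinned split. Each training epoch samples one entry per cluster; when a
predicted structure is available it is chosen with probability 0.6
(crystal otherwise).

## Training protocol

Two cycles, Adam, batch size 1, early stopping with patience 35 against
a 1,000-epoch cap, all weights initialized i.i.d. Normal(0, 0.02):

1. **Cycle 1** trains the residue architecture on small-molecule contact
   labels with Dice loss (L = 1 - d, d the soft Dice-Sorenson overlap),
   learning rate 2e-6, weight decay 1e-7.
2. **Cycle 2a** fine-tunes the residue head on carbohydrate-only
   complexes at ten-fold larger rates (2e-5 / 1e-6).
3. **Cycle 2b** builds the protein head by transplanting the cycle-1
   trunk, initializing the pooling head at Normal(0, 0.02), and training
   all weights (the trunk is not frozen — the published protocol says the
   weights were "used where available", which we read as initialization
   only) with binary cross entropy at 2e-5 / 1e-6.

"Did not decrease" is read strictly: ties count as non-improvement, and
the returned weights are always the best-validation snapshot, never a
later one. Adam moments stay at the conventional defaults; gradient
clipping is available (`clipNorm`) but off by default. The validation
stream is never augmented with predicted structures; the 60/40 sampling
applies to training only.

## The synthetic generator

Full-scale training requires tens of thousands of structures and a real
language-model embedder; the package is exercised end to end on synthetic
fixtures instead. `generateToyProtein()` builds an ideal helical trace
(rise 1.5 Angstrom, radius 2.3, 100 degrees per residue, C-beta offset
1.5 outward — chosen over random coils for reproducible, clash-free
geometry). Binders receive a GLC-coded ligand cluster placed so that each
residue of a contiguous pocket (5 residues by default) has a ligand atom
within 3.5 Angstrom while every other residue stays beyond the 4.2
labeling shell. Critically, fixture labels are *always produced by the
production labeler* — the generator only proposes geometry and retries
until `labelBindingResidues()` reproduces exactly the planted pocket — so
fixtures and labeler cannot drift apart. Stub embeddings plant a +3 shift
on channel 1 of binding residues (signal strength 3, the planted-signal
study condition), each protein drawing its base embedding dictionary from
its own seed, as contextual embedders do in practice.

What the fixtures do **not** emulate: real secondary-structure variety,
side-chain atoms beyond C-beta, sugar stereochemistry, crystal contacts,
or the label noise of real complexes. Passing the synthetic recovery
tests therefore demonstrates that the optimization machinery and
information flow work, not that the shipped default configuration matches
published benchmark accuracy — that would require the full corpus, real
embeddings and GPU-scale training.

## Toy-scale training choices

The desk-scale two-cycle runs in the test suite use a 2-layer, width-16
trunk (edge/node MLP width 32, decoder width 16), k = 8 graphs for the
residue cycles and a 6/8 staged schedule for the protein head, 8 radial
basis functions, and a 32-channel stub embedding. The narrower embedding
matters: with 50 training proteins, 1,280 independent noise channels give
the optimizer far more memorization capacity than signal, and the planted
channel never wins; 32 channels keep the same contract (signal on channel
1, unit-variance noise elsewhere) at a capacity the toy corpus can
constrain. Cycle sizes are 50 binder complexes for pretraining (40
train / 10 validation), 50 fresh complexes for the carbohydrate
fine-tune, and 80 mixed binders/nonbinders (60/20) for the protein head
— residue cycles train on complexes only, since a protein without
positive labels contributes a constant Dice loss and a zero gradient.

Optimization: learning rate 1e-3 (cycle 1 and the protein cycle), 3e-4
for the residue fine-tune, weight decay 1e-4 (3e-3 for the protein cycle,
where confident overfitting otherwise corrupts validation-loss model
selection), gradient clipping at norm 2, epoch caps of 80-120 with
patience 30-40. These rates are three orders of magnitude above the
full-scale protocol because the toy problem takes three orders of
magnitude fewer gradient steps; the 10x cycle-1 to cycle-2 rate ratio of
the original protocol is preserved in the full-scale defaults of
`twoStageTrain()`.

Two further choices are specific to small widths. First, the protein
head's five stacked layers attenuate signal as the product of their
init-scale gains; the full-scale value sigma = 0.02 is nearly
gain-preserving at fan-ins of ~1,200-9,700 but collapses the toy head
(fan-ins 8-48) to a constant output, so toy configurations use the
fan-in-scaled initialization (`initSigma = NA`, sigma = 1/sqrt(fan-in),
zero biases). Second, whether the binder cycle escapes the trivial
constant predictor within its epoch budget depends on the interaction of
head draw and batch order, so the trainer supports multi-start restarts
(`restarts`, `restartThreshold` in `trainConfig()`): a finished cycle
whose best validation loss never beats the threshold (0.45 in the tests,
against ln 2 ≈ 0.69 for the constant predictor) is retried from a fresh
head, keeping the best attempt. Both features are off at the full-scale
defaults. A complete three-cycle run takes about two minutes on one CPU.

## Numerical conventions

* k-NN ties break deterministically toward the lower residue index;
  neighbour lists are directed and never symmetrized.
* The quaternion sign ambiguity is fixed by a nonnegative scalar part.
* Dice with an empty denominator (no positives in labels or predictions)
  is defined as 0 with a warning; MCC with a vanishing denominator factor
  is 0. Balanced accuracy refuses to evaluate when a class is empty.
* The printed forms of TPR and TNR in the reference table equal precision
  and NPV and contradict each other; the package implements the standard
  definitions TPR = TP/(TP+FN), TNR = TN/(TN+FP).
* Residue-level evaluation averages per-protein metrics; counts are never
  pooled across proteins.
* Probabilities exactly 0 or 1 are clamped at machine epsilon inside the
  cross-entropy.
* Binary calls are `probability >= threshold`; the default threshold is
  0.5, with 0.9 recommended for conservative proteome annotation.

## Known limitations

* The hidden widths are calibrated to the published parameter totals, but
  those totals do not uniquely determine the architecture; other width
  assignments reproduce the same counts.
* The greedy identity clustering is quadratic in the number of sequences
  and intended for desk-scale corpora; swap in an external clusterer
  through the same output contract for large datasets.
* The pure-R network code is fast enough for inference and toy training,
  not for full-corpus training.
* Glycan-tree topology, branched-glycan identity beyond HET codes, and
  symmetry-mate expansion are out of scope.
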