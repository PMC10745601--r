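---
title: "Structure-aware drug-target affinity prediction: model and methods"
author: "StructDTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-aware drug-target affinity prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StructDTA)
```

## The problem

Drug-target affinity (DTA) prediction asks: given a small molecule and a
protein, how tightly do they bind? The label is pKd, the negative decadic
logarithm of the dissociation constant in mol/L; higher means tighter
binding. Purely sequence-based predictors (1D convolutions or recurrent
networks over SMILES strings and residue sequences) ignore the geometry of
the binding event, yet binding is decided in a small three-dimensional
pocket whose residue composition and shape select the ligand. StructDTA
implements a heterogeneous architecture that fuses sequence-derived
semantic features with graph-structural features of the target, its
binding pocket and the drug, and regresses pKd end to end.

## Data model

Three entities enter the model per complex:

* **Target**: the protein's C-alpha trace. Residues are graph vertices;
  an undirected edge joins two residues whenever their C-alpha Euclidean
  distance is at most 8 Angstrom. The comparison uses a closed boundary
  (`<=`) in double precision; the cutoff is a config key
  (`contactCutoff`).
* **Pocket**: the subset of target residues lining the binding site,
  supplied as a second PDB file and matched to the target by (chain,
  residue number, insertion code) — never by coordinates, which serve only
  as a cross-check. The pocket graph is built over the pocket residues
  alone with the same distance rule; edges are recomputed within the
  subset, not inherited from the target graph.
* **Drug**: heavy atoms are vertices, the covalent bonds written in the
  SDF/MOL2 file are the edges. Hydrogens and their bonds are removed by
  default; no bond-order or protonation perception beyond the input file
  is attempted.

Sequences are encoded over a 20-symbol residue vocabulary (alphabetical
one-letter order) and a 27-symbol atom vocabulary (26 elements plus
`UNK`). Unknown symbols encode as all-zero rows rather than a dedicated
one-hot column: this keeps the feature dimension at exactly 20/27, which
the convolution input channels require. Label, one-hot,
physico-chemical and profile (PSSM/HHM) encoders share this convention.
The 24 amino-acid properties ship as a CSV populated from published
AAindex scales and the 9 atom properties from standard periodic-table
data; both files record the provenance of every column and are editable
stand-ins — the package standardizes each column to zero mean and unit
variance across the vocabulary itself, deterministically, so exchanging
the tables never changes the encoding contract.

Fixed sequence lengths of 2100 (targets) and 125 (pockets) with zero
padding are the dataset conventions the architecture was designed around;
`padOrTruncate()` implements them and records truncation. Because the
convolution uses zero `same` padding, the encoder output at positions
below the true sequence length is identical whether the input is padded
to 2100 or merely to its own length — the model therefore runs the
convolution at true length and slices, which is mathematically equivalent
and far cheaper on short synthetic chains (a property pinned by a test).

## Architecture

Per stream the model computes, with LeakyReLU (negative slope 0.01)
after every trainable layer:

1. **Sequence module** (targets and pockets only): a 1D convolution with
   128 output channels, stride 1, kernel 5 for targets and 3 for pockets,
   over the one-hot sequence. Variants: LSTM (hidden 128), BiLSTM (64 per
   direction, concatenated), CNN followed by LSTM, or `none` (one-hot fed
   straight to the graph network, whose first layer is then sized for
   20 input channels). Drugs skip this module; their 27-dim one-hot atom
   features go directly to the graph network.
2. **Structure module**: three independent three-layer GNN stacks
   (widths 32, 64, 128) over the drug, target and pocket graphs. Target
   and pocket vertex i carries row i of the sequence-module output, so
   sequence position and graph vertex stay aligned. The default layer is
   GraphSAGE with mean neighbor aggregation plus an explicit self term;
   GCN (symmetrically normalized adjacency with self-loops), single-head
   GAT (the customary slope-0.2 LeakyReLU on the attention logits) and
   GIN (sum aggregation, two-layer MLP update, epsilon fixed at 0) are
   selectable for ablations. Self-loops are never stored in the graph
   object; layer types that need them add them transparently.
3. **Readout and projection**: a permutation-invariant mean readout
   (max by config) pools vertex embeddings to one 128-vector per stream,
   followed by a per-stream affine projection to 256 dimensions with
   unshared weights.
4. **Fusion head**: the three 256-vectors concatenate to 768; a linear
   layer maps 768 to 256, then LeakyReLU, dropout 0.4, and a final linear
   layer to the scalar pKd. (A literal reading of the source description
   would concatenate to "256"; three 256-dim streams cannot, so the head
   maps 768 to 256, which reconciles the stated layer sizes.)

The parameter count depends only on the configuration, never on input
sizes: the model is fully inductive and evaluates on graph sizes never
seen in training.

**Bidirectional attention.** For interpretability the model computes
unparameterized scaled dot-product attention between the pre-pooling
drug and target vertex embeddings: S = D T'/sqrt(128), with a row
softmax of S giving atoms-to-residues scores and a row softmax of S'
giving residues-to-atoms scores. Attention is taken on the final
per-vertex embeddings — matrices indexed by atoms x residues require
per-vertex resolution, which pooled vectors no longer have — and the dot
product is unparameterized because no learned attention projection is
part of the regression path.

## Implementation of the network

No automatic-differentiation framework is involved: every layer
(convolution via an unrolled input matrix, LSTM with backpropagation
through time, the four GNN families over sparse batched adjacency
operators, pooling, dropout, the fusion head) implements an explicit
analytic backward pass, and Adam (beta 0.9/0.999, eps 1e-8) performs the
updates. Minibatches are processed as block-diagonal disjoint unions of
graphs (`Matrix` sparse operators), so no edge ever crosses a sample
boundary and evaluation results are invariant to batch composition.
Gradient correctness for every architecture variant is pinned against
central finite differences in the test suite; permutation invariance and
batch-composition invariance are tested to 1e-5.

## Training regime

Defaults follow the reference regime: Adam, learning rate 1e-4, batch
size 128, dropout 0.4, MSE loss, 300 epochs ("iterations" is read as
epochs, the standard usage in the DTA literature; it is a config key).
The final incomplete batch is kept. There is no gradient clipping; a
non-finite loss aborts immediately with a diagnostic naming the batch.
The data split reserves a seeded 10% validation fraction for checkpoint
selection (`best_val` by validation loss; `last` available) — the
reference work names only train/test sets, so the validation split is
this package's choice. All randomness (initialization, shuffling,
dropout, synthetic data) flows from one seed; two runs with identical
seed, data and configs produce bit-identical histories.

## The synthetic complex generator

Real PDBbind-scale training is out of reach for a test suite, so the
package ships a generator whose outputs exercise every pipeline stage
through the same file formats real data would use:

* **Proteins**: C-alpha traces as 3D self-avoiding random walks with the
  canonical 3.8 Angstrom virtual bond length and a 3.5 Angstrom
  non-consecutive clearance, written as fixed-column PDB. Sequences are
  uniform over the 20 standard residues.
* **Pockets**: a contiguous seeded residue window, written as a PDB
  subset with original residue numbering.
* **Drugs**: random spanning trees over 6-15 heavy atoms (C/N/O/S at
  0.6/0.15/0.15/0.1) plus up to two ring-closing bonds, ~1.5 Angstrom
  bond lengths, written as SDF V2000.
* **Affinity**: the mean of per-residue-type planted weights over the
  pocket residues, plus Gaussian noise. The planted weights span 2 to 11
  so labels sit on a realistic pKd scale; the default noise SD of 0.2
  pKd units is small against the between-complex label spread (about
  0.8), giving a planted signal that a correct implementation should
  recover but noise enough that trivial memorization does not.

The law depends on the *pocket only*, by design: the finding that pocket
knowledge drives affinity prediction thereby has a synthetic analogue a
test can assert — a model that ignores pocket composition cannot beat
noise-level correlation on held-out complexes. Ordinary least squares of
the affinity on pocket composition recovers the planted weights (a test
verifies this within three standard errors), which makes the generator
itself, not just the network, an oracle-checked component.

What the generator does **not** emulate: real fold topology and secondary
structure, chemically valid valences and bond orders, docking poses, any
geometric drug-pocket complementarity, sequence conservation, and
realistic length scales (30-60 residues versus thousands). Passing the
recovery tests therefore demonstrates that the pipeline is implemented
correctly and can extract a composition-level pocket signal; it says
nothing about accuracy on real protein-ligand complexes.

## Desk-scale experiment settings

The bundled experiments (test suite and `scripts/acceptance.R`) run on
one CPU in minutes, so their problem sizes and optimizer settings are
scaled to the data: the planted-signal experiment trains on 200
complexes (50 held out) for 150 epochs with batch size 32 and learning
rate 1e-3, and the memorization check trains 16 complexes for 300 epochs
at the same rate. With only a few hundred tiny samples, the reference
regime's 1e-4 at batch 128 would take an order of magnitude more epochs
to converge; raising the rate to 1e-3 at smaller batches is the standard
small-data adaptation and exercises identical code paths. The paper-scale
defaults remain the package defaults.

## Numerical choices and degenerate inputs

* Distance cutoff comparisons are closed (`<=`) in double precision.
* Weight initialization is Glorot-uniform from the seeded global RNG;
  biases start at zero.
* Top-k attention rankings break ties by ascending index, making
  interpretability reports deterministic.
* The concordance index excludes pairs tied in the true affinity and
  scores tied predictions 0.5 (the standard DTA-benchmark convention);
  all-tied truths give NaN with a warning rather than a silent number.
* Zero variance in either vector makes the correlation metrics NaN with
  a warning; R-squared is the coefficient of determination against the
  mean of the true values and may be negative.
* Empty graphs are rejected; molecules reduced to nothing by hydrogen
  stripping raise an error rather than producing an empty stream.
* Residues lacking a C-alpha are skipped and counted, never silently
  dropped: `skipCount()` exposes the number, and the synthetic round-trip
  tests assert it is zero.
* Multi-model PDB files contribute only their first model; alternate
  locations other than blank or "A" are dropped; multi-chain targets
  concatenate in file order into one residue list.
* On the residue side, dataset-level attention statistics are reported
  both pooled over all picks and as the mean of per-complex fractions
  (the two disagree when complexes differ in size, and either reading is
  defensible); on the atom side the statistic is the coverage of
  distinct picked atoms among heavy atoms, the only reading under which
  such percentages grow monotonically with k.

## Known limitations

* The sequence-profile parsers (PSSM, HHsuite HHM) only read existing
  files; generating profiles requires external search tools.
* No edge features: bond orders and inter-residue distances beyond the
  cutoff threshold are not used.
* Single-head GAT, fixed-epsilon GIN and mean-aggregation GraphSAGE are
  deliberate minimal variants for ablation comparisons, not tuned
  reimplementations of their papers.
* Training is single-threaded and desk-scale; the implementation favors
  auditability (explicit backward passes, finite-difference pinning)
  over throughput, and PDBbind-scale training is out of scope.
* mmCIF input is not supported; structures must be PDB-format text.
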