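---
title: "Tertiary-structure-based RNA sequence design: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tertiary-structure-based RNA sequence design: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnadesign)
```

## The problem

RNA inverse folding asks for a nucleotide sequence $S^N$ over
$\{A, U, C, G\}$ that folds into a given tertiary structure. The structure
is represented by the six backbone atoms per nucleotide,
$\{P, O5', C5', C4', C3', O3'\}$, with coordinates
$x_i^\omega \in \mathbb{R}^3$, and the design task is a learnable mapping
$\mathcal{F}_\Theta : \mathcal{X}^N \mapsto \mathcal{S}^N$. This package
implements that mapping end to end: backbone parsing, an SE(3)-invariant
graph featurization, a message-passing encoder with an iteratively refined
sequence decoder and an auxiliary secondary-structure head, a seeded
training loop, and a three-level evaluation protocol.

## Featurization

Each nucleotide gets a local reference frame $Q_i = [b_i, n_i, b_i \times
n_i]$ built from the unit bond vectors $u_i$ between successive P atoms:
$b_i$ is the normalized difference $u_i - u_{i+1}$ (the negative bisector of
the two rays meeting at $P_i$) and $n_i$ the normalized cross product
$u_i \times u_{i+1}$. The structure becomes an attributed graph with each
node connected to its $K = 30$ spatially nearest neighbours (Euclidean
distance between P atoms, ties broken by lower index).

Node features (107 with defaults): $\sin$ and $\cos$ of the six backbone
dihedrals $\alpha \ldots \zeta$ (atom quadruples follow the IUPAC
nucleic-acid convention), Gaussian radial-basis encodings of the distance
from each non-P atom to $P_i$, and the unit direction of each non-P atom
from $P_i$ expressed in $Q_i$. Edge features (99): the scalar-first unit
quaternion of $Q_i^T Q_j$ (sign fixed so the scalar part is nonnegative),
RBF-encoded distances from neighbour $j$'s non-P atoms to $P_i$, and their
local-frame directions.

The RBF grid (16 Gaussian kernels, centers linearly spaced on 0–20 Å, width
equal to the center spacing) follows standard inverse-folding practice and
is deliberately configurable rather than treated as ground truth: it is
exposed in `graph_config()`.

**Degenerate frames.** Chain termini, chain breaks (from residues dropped
for missing atoms) and collinear P triples have no well-defined frame.
These positions keep the identity rotation with `valid = FALSE`, and every
feature that needs a valid frame is masked: direction vectors become zero
and orientation quaternions the identity. This choice is forced by
invariance: no deterministic fallback frame can commute with rotations
about its own bisector axis, so any feature built from one would break the
package's exact SE(3) invariance guarantee. Zero-length direction vectors
(below $10^{-8}$ Å) also encode as zero, and near-collinear is defined by a
cross-product norm below $10^{-8}$.

## Network

The encoder stacks three message-passing layers in the style of modern
graph-based inverse-folding encoders; the layer internals are a documented
design choice behind a stable interface. Per edge, an MLP with one
ReLU hidden layer maps the concatenated sender state, receiver state and
edge features to a message vector and an attention score; messages are
aggregated with a masked softmax over each node's neighbours, followed by a
residual connection and layer normalization. Padded positions are excluded
from attention and produce zero state vectors throughout.

The decoder is deliberately minimal: one affine map from each position's
latent vector concatenated with its linearly embedded previous-iteration
distribution to four logits, softmax-normalized. Decoding is strictly
per-position; all context comes from the encoder.

**Iterative refinement.** The distribution starts uniform ($p_{i,j} =
0.25$). Each of the $K = 3$ iterations (configurable) re-encodes the graph
with the previous distribution injected into the node states (a learned
linear embedding added to the input projection — the simplest
differentiable route for the distribution to re-enter the network) and
decodes a new distribution. The designed sequence is the argmax of the final iteration,
with ties resolved alphabetically ($A < C < G < U$); a seeded sampling mode
exists behind a flag.

**Secondary-structure head.** One multi-head self-attention layer (4 heads)
over the final latent, residual + layer normalization, then a per-position
3-way classification over the dot-bracket alphabet $\{., (, )\}$. The head
reads encoder latents, not decoder outputs. Its argmax string may be
unbalanced; it is repaired by converting unmatched brackets to dots, and
the raw string is reported alongside.

## Training

The objective is
$\mathcal{L} = \mathcal{L}_{sup} + \mathcal{L}_{sec}$ with
$\mathcal{L}_{sup} = -\sum_{k=1}^{K}\sum_{i=1}^{N} \log p^k_{i,s_i^*}$
summed over all refinement iterations and
$\mathcal{L}_{sec} = -\sum_i \log a_{i,a_i^*}$, both with probabilities
clamped at $10^{-9}$ before the log. The sums are the written form of the
objective and what the tests pin; a per-term mean reduction is available
for optimization stability. Weights between the two terms are configurable
(defaults 1/1).

No automatic differentiation framework is used: reverse-mode gradients of
the full network — through all refinement iterations, including the path
where iteration $k$'s probabilities feed iteration $k+1$ — are derived
analytically and verified against central finite differences in the test
suite (worst relative error around $10^{-8}$ on small configurations).

The optimizer is Adam at learning rate $10^{-3}$ with no schedule — a
plain, dependable default for a model of this size. Batches are
length-bucketed: items sorted by
length, padded to the batch maximum, with padded positions excluded from
message passing and from every loss (the suite checks that padding changes
no loss value). Everything — initialization, shuffling, dropout — derives
from explicit integer seeds, so a rerun reproduces the training record
bit-for-bit on one platform. Ground-truth dot-brackets are caller-supplied
files; deriving them from 3D coordinates is out of scope, as is any
structural-similarity dataset split.

## Synthetic fixtures

`toy_dataset()` makes the whole stack testable without downloads. Each item
is a helical backbone at roughly A-form scale (rise 2.8 Å, radius ~9 Å,
inter-P spacing ~5.5–6.5 Å) whose per-residue geometry encodes its own
nucleotide label twice over: the label sets the helical twist of the step
leaving the residue (30/32.5/35/37.5° for A/U/C/G) and a small rotation of
the residue's atom offsets (−12/−4/+4/+12°). Both signatures are visible in
the graph features (dihedrals, distances, directions), so the
structure-to-sequence mapping is learnable from exactly the information the
model sees. Gaussian coordinate noise (default σ = 0.1 Å) keeps distances
tie-free; secondary structures are simple hairpins consistent with length.

What this emulates — and does not. The fixtures exercise geometry,
featurization, learning and evaluation machinery. They are not real RNA:
no loops, non-canonical pairs, tertiary contacts, or the ambiguity of real
structure-sequence relationships. A model that overfits the toy mapping
demonstrates that the features carry local geometry and that training
works; it says nothing about recovery rates on crystallographic data,
which would require the full benchmark corpus and far longer training.

Problem sizes in the shipped tests and the acceptance script are chosen for
desk-scale runs: chains of 10–60 nt for property checks, and an overfit
demonstration with hidden dimension 64 on three 30-nt structures for 300
epochs (reaching ≥90% training recovery from the 25% chance level), plus a
six-structure training run with three held-out structures in the
acceptance script.

## Evaluation protocol

Three levels:

* **Sequence:** recovery (percent of exactly matching positions) and
  Macro-F1 ×100. Macro-F1 over a test set defaults to pooling positions
  into one global confusion matrix (classes absent from both truth and
  prediction are excluded; classes with support but no true positives
  score 0); per-sample averaging is available behind a flag. Aggregates
  are stratified into Short [0, 50), Medium [50, 100), Long [100, ∞)
  length bins, half-open at 50 and 100.
* **Secondary structure:** fold each designed sequence with a pluggable
  backend, compare dot-brackets position-wise (accuracy), and report the
  recovered-sequence rate — the percentage of designs the backend folded at
  all. "Could not fold" is operationalized as process failure, empty or
  malformed output, or a length-mismatched structure. The default test
  backend is a deterministic stub so CI needs no external tool; an RNAfold
  (ViennaRNA) adapter is provided and used when the program is on the PATH.
* **Tertiary:** superposed RMSD (Kabsch via SVD, reflections excluded)
  between backbones, as the utility metric for downstream folding checks.
  Running tertiary structure predictors themselves is out of scope; the
  folding interface is the abstraction point.

## Numerical choices and edge-case policy

* Residues missing any of the six backbone atoms are dropped and counted,
  never imputed; drops (and residue-number gaps) sever the chain for frame
  and dihedral purposes. Altloc goes to highest occupancy, ties to the
  first record; only MODEL 1 of multi-model files is read.
* Modified nucleotides map through a documented table (PSU→U, 5MC→C, …);
  unmapped names become N, which is excluded from losses and metrics.
* Pseudoknot brackets in dot-bracket input remap to '.' with a warning: the
  secondary-structure alphabet here is exactly three symbols.
* Dihedral masks encode as $\sin = \cos = 0$; masked neighbour slots carry
  zero features; k-NN padding repeats the nearest neighbour index but is
  masked out of every computation.
* Layer-norm epsilon $10^{-5}$; probability clamp $10^{-9}$; frame
  validity thresholds $10^{-8}$; quaternion extraction uses the
  numerically stable largest-component branch.
* R's native 1-based indexing is used throughout; residue numbers are
  displayed as authored in the source file.

## Limitations

Single chains only (complexes and RNA–protein conditioning are out of
scope); no pretrained weights are shipped, and none are claimed compatible
with external releases; chains longer than 500 nt are outside the intended
regime; the toy fixtures cannot certify performance on real structures.

## A worked call

```{r example, eval = FALSE}
ds <- toy_dataset(3, c(30, 30), seed = 11)
fit <- train(ds,
             model_config(hidden_dim = 64, dropout = 0, seed = 11),
             train_config(epochs = 300, learning_rate = 1e-3, seed = 11))
res <- design(ds[[1]]$structure, fit$model)
recovery_rate(res$sequence, ds[[1]]$sequence)
```
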