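# rnadesign

Tertiary-structure-based RNA sequence design (inverse folding) in R.

Given the backbone of an RNA tertiary structure — the six atoms P, O5',
C5', C4', C3', O3' per nucleotide — the package designs a nucleotide
sequence expected to fold back into that structure, and evaluates designs
at the sequence, secondary-structure and tertiary levels. It is aimed at
structural bioinformaticians who want a self-contained, fully seeded,
CPU-scale implementation of the graph-based design approach: every piece,
from the SE(3)-invariant featurization to the network gradients, is
implemented and tested in this package.

## Method

The design task is a learnable mapping F_Θ : X^N → S^N from backbone
coordinates to sequences over {A, U, C, G}.

* **Featurization.** Each nucleotide gets a local frame
  Q_i = [b_i, n_i, b_i × n_i] from the unit bond vectors between
  successive P atoms (b_i the negative bisector, n_i the plane normal).
  The structure becomes a k-nearest-neighbour graph (K = 30) with
  107 node features (sin/cos of the six backbone dihedrals α…ζ, Gaussian
  RBF encodings of intra-nucleotide atom–P distances, local-frame
  direction vectors) and 99 edge features (relative-orientation
  quaternion q(Q_i^T Q_j), inter-nucleotide RBF distances, directions).
  All features are invariant to global rotation and translation.
* **Network.** Three message-passing encoder layers (MLP messages,
  attention-gated neighbour aggregation, residual + layer norm), a linear
  per-position sequence decoder, and a self-attention secondary-structure
  head over the dot-bracket alphabet {., (, )}.
* **Iterative refinement.** The per-position distribution starts uniform
  (0.25 each) and is refined over K = 3 iterations, each re-encoding the
  graph with the previous distribution injected; the loss sums the
  cross-entropy over all iterations, plus the secondary-structure
  cross-entropy: L = L_sup + L_sec.
* **Training.** Adam with analytically derived reverse-mode gradients
  (verified against finite differences in the tests), length-bucketed
  padded batches, full seeding.
* **Evaluation.** Sequence recovery and Macro-F1 (×100, pooled), with
  Short [0,50) / Medium [50,100) / Long [100,∞) stratification;
  dot-bracket accuracy and recovered-sequence rate through pluggable
  folding backends (deterministic stub, or RNAfold from ViennaRNA);
  superposed RMSD (Kabsch) at the tertiary level.

A synthetic fixture generator (`synth_helix()`, `toy_dataset()`) produces
helical backbones whose sequence is a deterministic function of local
geometry, so the entire stack trains and tests without any downloads. See
the methods vignette (`vignettes/rna-inverse-folding.Rmd`) for the full
account of the model, its assumptions and the design decisions.

## Worked example

```r
library(rnadesign)

ds  <- toy_dataset(3, c(30, 30), seed = 11)          # toy structures, 30 nt
fit <- train(ds,
             model_config(hidden_dim = 64, dropout = 0, seed = 11),
             train_config(epochs = 300, learning_rate = 1e-3, seed = 11))
fit
#> RNA design fit: 300 epochs, final loss 0.162, final training recovery 100.0%

res <- design(ds[[1]]$structure, fit$model)
res$sequence                    # designed sequence, argmax of iteration 3
recovery_rate(res$sequence, ds[[1]]$sequence)
#> [1] 100
```

The training record shows the model moving from the 25% chance level to
complete recovery of the toy mapping:

```r
fit$record[c(1, 10, 50, 300), c("epoch", "loss", "recovery_pct")]
#>     epoch       loss recovery_pct
#> 1       1 547.159428     25.55556
#> 10     10 271.277275     67.77778
#> 50     50  14.204781    100.00000
#> 300   300   0.161542    100.00000
```

`loss` here is the summed objective L_sup + L_sec over the epoch; the
recovery percentage is the fraction of training positions whose final
iteration argmax matches the native nucleotide.

A command-line interface wrapping the same functions is installed at
`inst/cli/rnadesign.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "rnadesign.R", package = "rnadesign"))') \
    design --pdb structure.pdb --chain A --checkpoint model.rds --out design1
```

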