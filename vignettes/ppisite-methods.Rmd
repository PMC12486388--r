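---
title: "Predicting protein-protein interaction sites with multiview graph embeddings"
author: "ppisite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein interaction sites with multiview graph embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ppisite)
```

## The problem and the model

Interface residues — the amino acids through which a protein physically
contacts a partner protein — are the positive class of a heavily imbalanced
binary node-classification task on the protein's tertiary structure.
`ppisite` casts each single chain as an undirected residue graph
$G = (V, A, E)$ and predicts a per-residue interface probability.

**Graph.** Every residue is represented by one pseudo-position: the
unweighted centroid of its side-chain atoms (C$\alpha$ for glycine).  Two
residues are connected when their pseudo-positions lie within a 14 Å
cutoff; self-edges are always included so that attention normalisation is
defined for every node.  Each edge carries two dimensionless features: the
Euclidean distance divided by the cutoff, and the cosine of the angle
between the two centroid-centered position vectors.

**Node features (62 per residue).** Five blocks, concatenated in fixed
order: PSSM log-odds (20, min–max normalised), profile-HMM match emissions
(20, transformed by $2^{-s/1000}$ then normalised), DSSP descriptors (14:
a 9-state secondary-structure one-hot including an unknown class,
$\sin/\cos$ of $\phi$ and $\psi$, and relative solvent accessibility), mean
atomic attributes (7: mass, B-factor, side-chain flag, partial charge,
bonded hydrogens, ring flag, van der Waals radius), and a pseudo-position
embedding (1: normalised distance from the protein centroid).

**Local view (EGAT).** Five edge-aware graph attention layers over a
128-wide node embedding:
$$ e_{ij}' = \mathrm{LeakyReLU}(A\,[h_i \,\|\, e_{ij} \,\|\, h_j]), \qquad
   \alpha_{ij} = \mathrm{softmax}_{j \in N(i)}(F \cdot e_{ij}'), \qquad
   h_i' = \mathrm{ReLU}\!\Big(h_i + \sum_{j \in N(i)} \alpha_{ij} W h_j\Big). $$
The per-layer outputs $h^1,\dots,h^5$ are concatenated into a 640-wide
multiscale local feature, so each node carries its 1- through 5-hop
neighbourhood summaries side by side.

**Global view (EGNN).** Seven equivariant graph convolutional layers over
a 256-wide embedding:
$$ m_{ij} = \phi_e(h_i, h_j, \|x_i - x_j\|^2, e_{ij}), \quad
   x_i' = x_i + \tfrac{1}{M-1}\sum_{j \ne i} (x_i - x_j)\,\phi_x(m_{ij}), $$
$$ m_i = \sum_{j \ne i} m_{ij}, \quad
   h_i' = \mathrm{ReLU}(h_i + \phi_h(h_i + m_i)). $$
Node features depend on coordinates only through squared distances, so the
final-layer $h$ (the global feature) is invariant to rotations, reflections
and translations, while the internal coordinate stream transforms
equivariantly.

**Fusion (MUSE).** The 896-wide concatenation of both views passes through
a multiscale attention block that sums a residual with three parallel
branches — single-head scaled dot-product self-attention, a dynamic
depth-wise separable convolution along the chain, and a position-wise
feed-forward network:
$$ X_{\mathrm{muse}} = X + \mathrm{Attention}(X) + \mathrm{Conv}(X) +
   \mathrm{Pointwise}(X). $$
The value projection $W^V$ is shared between the attention and convolution
branches; the dynamic convolution softmax-mixes depth-wise kernels of
several widths.

**Head and loss.** An MLP (896 → 256, ReLU, dropout 0.1 → 1, sigmoid)
yields $p_i \in (0,1)$.  Training minimises the focal loss
$\mathrm{FL}(p_t) = -\alpha (1-p_t)^\gamma \log p_t$ with $\alpha = 0.25$,
$\gamma = 2$, and $p_t = p$ for interface residues, $1-p$ otherwise,
averaged over residues — down-weighting the abundant easy negatives that
dominate interface data sets.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `cutoff` | 14 | Å | contact radius of the residue graph |
| `egat_layers` | 5 | – | neighbourhood scales in the local view |
| `egnn_layers` | 7 | – | depth of the global view |
| `focal_alpha` | 0.25 | – | positive-class weight in the focal loss |
| `focal_gamma` | 2 | – | focusing strength (0 recovers cross-entropy) |
| `threshold` | 0.5 | prob. | binary call threshold |
| `kernels` | 1, 3, 5 | residues | dynamic-convolution widths |
| `lr` | 2e-4 | – | Adam learning rate |
| `max_grad_norm` | 1 | – | global gradient-norm clip |
| `patience` | 15 | epochs | early stopping on validation AUPRC |

Layer counts, widths (128/256/896), $\alpha$, $\gamma$ and the cutoff
follow the published configuration.  Everything in the optimiser row block
is a package choice: with full-batch-per-protein Adam in pure R, a learning
rate of 2e-4 with gradient clipping at norm 1 converges in a handful of
epochs on the synthetic task, whereas larger rates drive the sigmoid head
into saturation (where focal-loss gradients vanish numerically) and
smaller ones waste the CPU budget.

## Design choices where the design was open

* **Angle vertex.** The "cosine of the angle between two nodes" is
  computed at the protein centroid after centering.  This makes both edge
  features translation-invariant and bounded; a node exactly at the
  centroid gets cosine 0 by convention, self-edges get $(0, 1)$.
* **Ninth secondary-structure class.** The one-hot block has nine slots
  for eight DSSP letters; the ninth encodes unknown/missing assignments,
  which also covers residues DSSP cannot assign.
* **Attention normalisation** runs over the incoming edges of each node
  including its self-loop, so isolated residues are well-defined.
* **Edge stream.** Edge features update without a residual, exactly as the
  printed update; the edge width inside EGAT is 128 so node and edge
  channels are commensurate (the raw 2-wide features are first projected).
* **EGNN coordinate update.** The difference form $(x_i - x_j)$ is the
  default because it is what makes the coordinate stream equivariant — the
  property the architecture is named for; the sum form is available as
  `egnn_coord_sum = TRUE` for comparison and demonstrably breaks
  translation equivariance (see `test-egnn.R`).
* **$\phi$ networks.** Two-layer perceptrons with ReLU hidden units,
  hidden width 128, message width 256 (forced by the $h_i + m_i$ sum);
  $\phi_x$ ends in a single linear unit.
* **Initialisation.** Glorot-uniform throughout, with the output layer of
  every residual branch damped (EGAT $W$, the $\phi$ output layers, MUSE
  $W^O$/$W^{out}$/FFN $W_2$ at 0.1; $\phi_x$ at $10^{-3}$) so the 12-layer
  residual network starts near the identity.  At full Glorot scale the
  neighbourhood sums amplify activations geometrically with depth and the
  coordinate stream diverges at initialisation.  The layer equations are
  untouched; only starting values are scaled.
* **MUSE internals.** Single attention head with $d_k = 896$; kernel
  widths $\{1, 3, 5\}$ with learnable mixing logits; zero padding at chain
  ends; no layer normalisation inside the block, matching the printed
  fusion equation.
* **Labels.** Files use 0/1; internally the focal loss uses the
  $y \in \{+1, -1\}$ convention.  Probabilities are clipped to
  $[10^{-7}, 1-10^{-7}]$ before logarithms.

## What the synthetic generator emulates — and what it does not

`make_dataset()` fabricates every external input the pipeline needs: PDB
chains (self-avoiding C$\alpha$ walks with 3.8 ± 0.1 Å consecutive spacing
and ≥ 4 Å non-consecutive separation, plus dummy side-chain atoms),
PSI-BLAST-dialect ASCII PSSMs, HHsuite-dialect `.hhm` profiles, DSSP-like
TSV records, and per-residue 0/1 labels.  Labels are geometric: a surface
residue seeds a patch and everything within the patch radius (10 Å) is
interface.  A feature signal (`signal_strength`, default 0.8) is baked
into the first eight PSSM columns of positive residues at the file level,
so the planted structure flows through the production readers, the
normalisation, and both graph pathways.

The defaults — 40 proteins of 20–35 residues — are the study conditions of
the package's learnability experiment and were sized for a single CPU.
What passing tests show: the full pipeline (files → features → graphs →
EGAT/EGNN/MUSE → focal-loss training) can recover a planted, spatially
coherent, feature-correlated interface signal, and cannot learn anything
from the same data with shuffled labels.  What they do not show: accuracy
on real complexes.  The toy chains have no realistic secondary structure,
no evolutionary couplings, no true solvent geometry, and peptide-scale
lengths, so published benchmark numbers are far outside what this desk
scale can or should reproduce.

For the shuffled-label control the package reports the *epoch-mean*
validation AUROC rather than the selected epoch's: model selection
maximises validation AUPRC, so under the null the best-epoch value is the
maximum of a handful of noisy draws and is biased above 0.5 by
construction; the trajectory mean is the honest summary of where shuffled
training stays.

## Numerical and engineering notes

* Gradients come from a small reverse-mode autodiff engine over dense
  matrices (`R/autograd.R`), with analytic backward rules verified against
  central finite differences in the test suite.
* Softmaxes (rows, and edge-grouped) subtract the per-group maximum before
  exponentiation.
* The Adam update runs as an in-place compiled kernel (`src/adam.cpp`) on
  one flat parameter vector (~7.6 M parameters); a vectorised R update
  allocates several full-size temporaries per step and is garbage-collection
  bound.
* Degenerate inputs: single-residue proteins freeze the EGCL coordinate
  update (with a message); constant feature columns normalise to 0;
  single-class validation labels switch model selection to the validation
  loss with a warning; zero metric denominators return 0 with a warning.
* Problem sizes used by the test suite and the acceptance script: 40
  proteins of 20–35 residues for the learnability experiment (one
  cross-validation fold, ≤ 30 epochs, early stopping patience 5–6), 20
  random 30-residue graphs for the invariance checks, 1,000 random
  confusion tables and 200 random score sets for the metric oracles.

## Known limitations

* Desk-scale only: no GPU, no batching across proteins, peptide-length
  synthetic chains; wall-clock cost grows roughly with edge count times
  network width.
* The DSSP reader consumes the TSV record format (`res_index`, `ss`,
  `phi`, `psi`, `asa`), not raw `mkdssp` output.
* mmCIF files, multi-model NMR ensembles (beyond the first model), ligands
  and waters are out of scope; profiles must be precomputed (the package
  never invokes PSI-BLAST/HHblits/mkdssp).
* The atom-attribute and max-ASA tables are fixed conventions shipped with
  the package; swapping in other force-field conventions would shift the
  7-wide atomic block.
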