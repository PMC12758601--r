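---
title: "Building a coarse-grained protein language: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a coarse-grained protein language: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scglang)
```

## The model

`scglang` turns a protein chain into a short sentence of discrete tokens.
The pipeline has four stages, each with a small number of modeling
commitments that this vignette makes explicit.

### 1. Segmentation

A fragment is a maximal run of consecutive residues sharing one 8-state
secondary-structure class (H, B, E, G, I, T, S, C — coil is stored as the
letter `C` although DSSP prints it as a blank). Fragments are represented
as 0-based half-open intervals so that tiling arithmetic is unambiguous:
fragments of a chain are ordered, disjoint and cover `[0, L)` exactly.
Singleton runs are kept as fragments of length 1; nothing is merged. A
chain break always starts a new fragment, even when the class matches
across it, because a fragment is meant to be a spatially contiguous unit;
this rule is applied to the random ablation segmenters as well, which is a
choice this package makes rather than something the segmentation schemes
themselves dictate.

The three ablation segmenters serve comparison studies only: uniform
random (one length drawn from 3..60 per chain, even division, shorter
tail), dynamic random (a fresh 3..60 draw per step; the final fragment may
be shorter than 3), and length shuffling (the SS-run length multiset,
permuted, then used to tile the chain). Each chain uses an independent
random stream derived from the global seed and the chain identifier, so
corpus-level results do not depend on processing order.

### 2. Fragment features

Each fragment becomes a 74-vector in three blocks.

* **Composition (20).** Fractions of the standard amino acids among the
  fragment's standard residues. Nonstandard residues (`X`) are excluded
  from numerator and denominator; an all-`X` fragment gets a zero block
  rather than an error, since such fragments do occur in real structures.
* **Evolution (40).** Column means over the fragment's rows of (a) the
  PSSM after elementwise sigmoid `1/(1+exp(-s))` of the log-odds scores,
  and (b) the HMM match-emission matrix with scores converted by
  `2^(-s/1000)` and `*` mapped to 0 — the HH-suite conventions. When no
  profiles are available the block is imputed as zeros and flagged, so a
  vocabulary can be trained structure-only.
* **Geometry (14).** An 8-state one-hot of the fragment's class, then
  fragment means of six per-residue DSSP fields: accessibility divided by
  the residue's theoretical maximum accessible surface area (Tien et al.
  2013 values, clipped to [0, 1]), TCO as-is (already in [-1, 1]), and
  the KAPPA/ALPHA/PHI/PSI angles divided by 180°. DSSP marks undefined
  angles with the sentinel 360; parsing keeps the sentinel untouched and
  featurization maps it to 0 before averaging, which centralizes
  imputation in one place. For the non-homogeneous fragments produced by
  the ablation segmenters the one-hot uses the majority class, ties
  resolved by the fixed alphabet order.

The six DSSP fields are the six numeric per-residue columns of classic
DSSP output (ACC, TCO, KAPPA, ALPHA, PHI, PSI) — the natural six-tuple
covering accessibility and torsion-angle character. The PSSM block uses
the log-odds half of the ASCII PSSM (the block a sigmoid is meaningful
for), not the percentage half.

Because the three blocks live on heterogeneous scales, features are
z-scored per dimension before vocabulary training; the means and scales
are stored in the vocabulary artifact and re-applied verbatim at
tokenization time, with constant columns given scale 1 so standardization
never divides by zero.

### 3. Vocabulary

The vocabulary is the codebook of a vector-quantized autoencoder: K
learnable vectors `e_1..e_K` in `R^d`. The encoder maps the standardized
74-vector to `z_e`; the token is the index of the nearest code vector in
Euclidean distance (ties to the lowest index, for determinism); the
decoder reconstructs the input from the selected code. The training loss
is

L = L_recons + ||sg[z_e] − z_q||² + β·||z_e − sg[z_q]||² ,

with squared distances summed over the code dimension and averaged over
the batch. The stop-gradient contracts are structural, not numerical: the
codebook term moves only code vectors, the commitment term only the
encoder, and reconstruction gradients reach the encoder through the
straight-through estimator (the quantization step treated as identity on
the backward pass). The test suite verifies all three contracts directly
— a training step on one term leaves the other components bitwise
unchanged — and checks every hand-derived gradient against central finite
differences of the surrogate objective that the straight-through /
stop-gradient graph defines.

Two reconstruction losses are available. The KL option maps input and
reconstruction to probability vectors by a softmax over the 74 standardized
dimensions and computes KL(p‖q); this treats the feature vector as a
distribution-like object and is mathematically the stated objective, but a
softmax over heterogeneous feature blocks is a somewhat artificial reading.
The MSE option is the numerically plain default used for the recovery
properties; both satisfy the same decomposition and gradient contracts.

**Encoder.** The default encoder must turn a single 74-vector into
something attention can act on. The construction here projects the input
into T = 3 slot tokens (one per feature block, conceptually), runs
multi-head self-attention over the slots with a residual connection,
mean-pools, and projects to `R^d`. This slot design is this package's own;
hidden width 32, 4 heads, d = 64 and a two-layer decoder are deliberately
desk-scale. An MLP encoder (two hidden layers) is the ablation variant,
and a plain k-means clustering of the standardized features is the
no-encoder baseline.

**Defaults.** K = 1024 and β = 0.25 are the shipped defaults; both are
overridable. Optimization is minibatch Adam (learning rate 1e-3, batch
256, 30 epochs by default) with all stochasticity — initialization and
shuffling — derived from the single config seed.

**Initialization and dead codes.** The codebook is initialized from
encoder outputs of an initial sample using greedy k-means++ seeding
refined by a few Lloyd iterations. Plain random initialization (and even
plain D²-weighted seeding) occasionally double-seeds one cluster and
leaves another without a code; the greedy variant — choosing each new
center among several D²-weighted candidates by resulting potential, as
scikit-learn does — removes nearly all such failures. No dead-code
restarting is done during training; the codebook is updated only by its
loss term, matching the printed objective rather than an EMA variant. The
k-means baseline likewise uses greedy k-means++ seeding with the best of
five Lloyd runs.

### 4. Serialization

Tokenization freezes the trained encoder and codebook: segment, featurize,
standardize with the stored parameters, encode, quantize. One token per
fragment, in sequence order; a sentence is never longer than its chain.
Corpora are plain text (`chain_id<TAB>t1 t2 ...`), with truncation (default
512 tokens) applied at corpus-writing time, not at tokenization, so the
full sentence is always recoverable upstream. Every vocabulary carries a
manifest hash computed from its codebook, standardization and encoder
parameters; artifacts are verified against it on load.

## The synthetic generator

The generator exists so that every stage can be exercised and tested
without downloads. It emulates:

* chains as no-repeat Markov sequences of SS runs with per-class
  geometric run-length laws (mean run lengths H 9, E 5, C 4, ... — chosen
  to give corpus compression ratios around 5, in the range observed for
  real SS segmentations);
* class-conditional DSSP fields centred on textbook values (helix phi/psi
  near −60/−45, strand near −120/135), clipped to legal ranges and rounded
  to DSSP print precision so files and memory agree exactly;
* profile files whose integer scores are biased toward the residue's own
  column, written in the exact ASCII dialects the readers parse;
* cluster-structured 74-d feature fixtures: a Gaussian mixture with
  minimum centre separation, post-processed so every row satisfies the
  fragment-feature invariants (composition on the simplex, valid one-hot
  sub-block).

It does **not** emulate real-PDB redundancy, crystallographic gaps beyond
simple chain breaks, correlated evolution along the chain, or the true
joint distribution of DSSP fields. Passing tests therefore demonstrate
that the machinery is correct and deterministic under controlled
conditions — not that any particular vocabulary quality will be achieved
on real structures.

## Numerical choices and degenerate inputs

* Quantization ties break to the lowest index everywhere (including the
  k-means tokenizer), making token assignment deterministic.
* The DSSP missing-angle sentinel 360 is preserved by the parser and
  imputed (to 0 after normalization) only at featurization.
* Unknown structure summary letters fall back to coil; lower-case DSSP
  letters in the amino-acid column (SS-bonded cysteines) map to `C`, other
  unknown residues to `X`.
* Empty chains, empty codebooks, out-of-range profile indices, negative β
  and token/vocabulary mismatches raise classed errors rather than
  propagating NA.
* Non-finite training losses abort with a diagnostic naming the epoch and
  batch.
* Exact text round-trips: codebooks are written with `%.17g` so reloaded
  artifacts tokenize bitwise identically and manifests verify by hash.

## Problem sizes used by the tests

The suite runs at desk scale by choice: cluster-recovery tests use a
16-component mixture with 4,000 samples and separation 10 times the
within-component deviation (adjusted Rand index thresholds 0.95 for
k-means and 0.9 for the VQ-VAE); the encoder-utilization comparison
averages 3 seeds at K = 64 on 3,000 samples; segmentation invariants are
fuzzed over 500 random chains; the end-to-end determinism check uses a
5-chain corpus and a 12-code vocabulary. The full suite and the
acceptance script each finish in about a minute on one CPU.

## Known limitations

* The KL reconstruction view (softmax over standardized features) is one
  reading of a distribution-matching objective over non-distributional
  inputs; MSE is the tested default.
* The attention encoder's slot construction is this package's design; no
  claim is made that it matches any particular reference architecture
  beyond being a multi-head-attention encoder over a single feature
  vector.
* Only classic fixed-width DSSP output is parsed (no mmCIF dialect), and
  PSI-BLAST/HHblits are consumed as files, never invoked.
* Residues unresolved in a crystal simply never appear in DSSP output, so
  fragments silently span them unless DSSP marks a break.
* Training is plain minibatch Adam on CPU; there is no EMA codebook,
  Gumbel quantization, residual VQ, or GPU path.
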