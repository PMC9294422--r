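---
title: "Models and methods behind rbpscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rbpscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model, the
loss and metrics, the transfer strategies, the calibration and screening
stage, the synthetic-data design, and the numerical conventions that a
careful user (or a reimplementer) needs to know. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The prediction problem

RNA-binding proteins (RBPs) are the positive class of a binary
sequence-classification problem with two defining difficulties: annotated
positives are scarce for most species, and the positive:negative ratio is
roughly 1:10. The package's answer is a two-stage transfer scheme — train a
classifier on a large cross-species annotated dataset, fine-tune it on the
target species — combined with a class-weighted loss so the minority class
is not drowned out.

## Featurization

Proteins enter as sequences over the 20 standard amino acids (FASTA).
Nonstandard residues (B, Z, X, U, O, `*`, …) are handled by an explicit
policy: `drop_nonstandard` (the default; silently removes them),
`map_to_X_then_drop`, or `reject` for strict pipelines. All residue-indexed
structures in the package — PSSM columns, composition vectors, feature
blocks — use one fixed alphabetical one-letter ordering (`aa_alphabet()`).
Mixing residue orderings across components is the classic silent featurization
bug; a single documented ordering everywhere is the defense.

Four hand-crafted encoders are provided:

* **PSSM-400** (width 400). An L×20 evolutionary profile is collapsed by
  summing, for each residue type, the profile rows at the positions holding
  that residue, then concatenating the twenty 20-wide blocks. When no
  PSI-BLAST profile is available the BLOSUM62 substitution rows (from
  Biostrings) stand in per residue — the standard fallback. Profiles are
  read from PSI-BLAST ASCII layout (scores reordered from PSI-BLAST residue
  order to alphabetical) or from plain L×20 matrix files.
* **CTD** (width 147). Seven physicochemical groupings (hydrophobicity,
  polarity, normalized van der Waals volume, polarizability, charge,
  secondary-structure propensity, solvent-accessibility propensity) each
  map residues into 3 classes; per grouping the descriptor is 3 class
  frequencies, 3 adjacent-pair transition frequencies, and, per class, the
  positions (as % of L) of its 1st/25%/50%/75%/100% occurrence. The
  structure and accessibility groupings are residue-propensity classes; no
  structure predictor is run, a deliberate simplification. The active
  groupings are configurable because published CTD variants differ in
  which subset they use.
* **Conjoint triad** (width 343). Residues map into 7 classes clustering
  side-chain dipole and volume; the feature counts all class-triads over
  the L−2 windows. Counts are max-normalized by default (a common
  convention); raw counts are available because normalization conventions
  vary across the literature.
* **PAAC** (width 20+λ). Type-1 pseudo amino acid composition from
  standardized hydrophobicity, hydrophilicity and side-chain mass tables;
  defaults λ = 30, weight = 0.05 (the method's conventional defaults,
  recorded in the output metadata rather than presented as anything else).

Precomputed protein language-model embeddings are consumed from TSV tables
(per-protein vectors, or per-residue rows sharing an id). The language
models themselves are never run here. Per-residue tables can be pooled
(`mean`, `last`) or passed through (`none`) to the recurrent stack; the
default path treats one pooled vector per protein as a length-1 sequence,
matching how a fixed-width embedding per protein is consumed downstream.

## The classifier

A stack of GRU layers (default 6) is followed by a discriminator head:
linear → batch normalization → leaky ReLU (slope 0.01) → linear → scalar
score → sigmoid probability. The GRU cell uses the standard reset-gated
candidate `h̃_t = tanh(W·[r_t ⊙ h_{t-1}, x_t] + b)` and the blend
`h_t = (1−z_t)⊙h_{t-1} + z_t⊙h̃_t`; the blend orientation (candidate
weighted by `z_t`) differs from some references only by the relabeling
`z ↔ 1−z` and does not affect capacity. `h_0 = 0`. With zero GRU layers
the network reduces to a pure linear network (the head applied to the raw
input), which is the degenerate case of the layer-count ablation.

The exact stacking order inside the head and its hidden width are repo
choices (width 64 by default), as is the GRU hidden width (32): where a
published architecture leaves such details to supplementary material, this
package fixes them explicitly as configurable defaults rather than
guessing them as someone else's settings. Batch-norm uses ε = 1e-5 and
running-moment momentum 0.1; evaluation mode normalizes with running
moments and is a pure function of its inputs, training mode uses batch
moments.

Forward, backward and Adam are base R matrix code. Training consumes one
fixed-width feature vector per protein (a length-1 sequence); with
`h_0 = 0` each GRU layer then reduces to a gated feed-forward map, whose
recurrent columns and reset gate receive zero gradient and stay at their
initialization. Per-residue sequences of any length are supported in the
forward/predict path; backpropagation through time for T > 1 is not
implemented because no training path in the package consumes it — a known
limitation. Gradients are verified against central finite differences in
the test suite, and the batched forward pass against the per-sample GRU
composition.

## Loss and metrics

The loss is the class-weighted binary cross-entropy with
`w = (1 − pos_ratio)/pos_ratio` computed from the training part actually
being optimized (direct training, pooled training and fine-tuning each see
their own positive ratio). The weight multiplies the positive term only:
that is what equalizes the expected contribution of the two classes — a
variant that multiplies both terms by `w` merely rescales the loss and is
kept behind `weight_both = TRUE` for fidelity experiments only. The model
emits both the pre-sigmoid score and the probability; the loss consumes
probabilities, clamped to `[1e-7, 1 − 1e-7]`.

Metrics: BACC, MCC, ROC AUC (midrank Mann–Whitney form) and AUPRC
(step-wise average precision over distinct score thresholds; trapezoidal
interpolation is avoided because it overestimates PR area). Conventions:
confusion counts threshold at 0.5 with ties counted positive; MCC is 0
when any denominator factor vanishes; an absent class contributes 0 to
BACC with a warning. AUPRC is the model-selection metric throughout, the
appropriate primary measure under heavy imbalance.

## Training and transfer strategies

Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8), initial learning rate 1e-3, batch
size 64, plateau factor 0.5 with patience 5, early-stop patience 10, at
most 200 epochs — repo defaults, all configurable. After each epoch the
validation AUPRC is recorded; the learning rate halves after a plateau and
training stops when the monitor stalls past the early-stop patience.

Model selection returns the parameters of the best monitored epoch, and
**the initial parameters count as the epoch-0 candidate**. This matters
for fine-tuning: when the target validation set is small, no fine-tuning
epoch may improve on the transferred checkpoint, and returning a
worse-than-start checkpoint would be a selection artifact, not a modeling
result. With zero fine-tuning epochs the TSTL output is therefore exactly
the pre-trained checkpoint.

The four strategies: `DT` trains on the species data only; `SP` on the
pre-training data only; `GM` on the concatenation without fine-tuning;
`TSTL` pre-trains and then fine-tunes on the species data, optionally with
the GRU layers frozen (frozen parameters are excluded from optimizer
updates and are bit-identical afterwards). `cross_domain_matrix()`
measures transfer as AUPRC increments of foreign-domain models over each
domain's own model.

## Calibration and screening

The screening stage needs scores that read as confidences, so validation
scores are calibrated by temperature scaling: one parameter T minimizing
the validation negative log-likelihood of `sigmoid(score / T)`, found by
1-D search over log T. Temperature scaling is strictly monotone, so the
ranking — and therefore AUC — is unchanged by construction. The published
screening pipeline cites a calibration method without describing it;
single-parameter temperature scaling is this package's explicit
realization, with the method recorded in the output so alternatives can be
added compatibly.

Proteome screening excludes training overlap (exact id or exact sequence
match — either triggers exclusion), truncates survivors to 6000 residues
keeping the N-terminal prefix (truncation is logged; prefix retention is
an assumption, stated rather than silent), scores, calibrates, and counts
confidence bins at thresholds 0.5–0.9 with strict `>` (the ">50%"
reading). Outputs are sorted by id and byte-for-byte reproducible in
evaluation mode.

## Synthetic data: what it emulates, what it does not

The generators exist so every stage is testable offline.

* `gen_embedding_domain()` draws labels Bernoulli(pos_ratio, default 1/11)
  and features `mu_y + σ·noise`, with the class-mean difference of length
  δ along a unit direction rotated by θ in the fixed plane of the first
  two coordinates. Domain shift is thus a single interpretable knob
  (rotation of the discriminative direction), chosen over covariance
  changes because it cleanly produces the cross-species phenomenology:
  domains sharing θ transfer well, distant θ transfer poorly, and
  fine-tuning can realign a pre-trained model.
* `gen_transfer_benchmark()` mirrors the 1 pre-training + 4 species
  layout at desk scale: pretrain n = 5000 (θ = 0); a "eukaryote-like" pair
  A, B with n = 600 (θ = 0.15); a "prokaryote-like" pair C (n = 300) and D
  (n = 200) at θ = 0.45; all at pos_ratio 1/11, D = 16, δ = 2, σ = 1.
  D = 16 rather than the 1024 of real embeddings keeps every test
  sub-minute; the geometry of real language-model embeddings (anisotropy,
  cluster structure, length effects) is *not* mimicked, so passing tests
  demonstrate the correctness and the qualitative transfer behavior of the
  machinery, not real-data performance.
* `gen_sequences()` biases the residue composition of positives (default:
  glutamate, serine, proline upward, echoing reported human RBP residue
  preferences); `gen_pssm()` makes diagonal-favoring random profiles for
  encoder tests.

All generators are pure functions of spec + seed and write the same
TSV/FASTA/profile dialects the loaders read.

## Numerical conventions and edge cases

* Split sizes follow largest-remainder apportionment (remainder ties
  toward the training part); with labels present the split is stratified,
  with a minimal repair step so the overall part sizes still equal the
  whole-dataset apportionment exactly while each stratum stays within one
  record of its own share. Stratification keeps the 1:10 imbalance in
  every part, which the weighted loss presumes.
* Redundancy removal is a greedy longest-first pass over a k-mer identity
  estimate (shared 3-mers / 3-mers of the shorter sequence), with
  representatives chosen longest-first and ties broken by id so the result
  is input-order independent. It is a documented approximation of
  identity-threshold clustering for dataset construction, not a CD-HIT
  replication, and says so in its log line.
* CTD distribution percentiles use occurrence index
  `max(1, floor(frac · count + 0.5))`.
* Conjoint-triad entry (a, b, c) sits at index `(a−1)·49 + (b−1)·7 + c`.
* Probability ties at the confusion threshold count positive; confidence
  bins use strict `>`.
* Degenerate inputs error early and loudly: empty sequences, single-class
  training or validation parts, T = 0 input sequences, ragged embedding
  tables, id mismatches in feature concatenation.
* Everything stochastic (initialization, shuffling, generators, splits) is
  seeded and restores the caller's RNG state; identical config + seed
  reproduces training histories bit-identically on CPU.

## Problem sizes used by the tests and the acceptance script

The benchmark runs used for the seed-averaged transfer comparisons train
with max_epochs 40, plateau patience 3 and early-stop patience 6 over 5
seeds — the package's desk-scale choice, at which all four strategies
converge on the synthetic domains in seconds each. The smallest species
domain (n = 200) yields a 20-protein test set, so individual-seed AUPRC
values are coarse; all transfer comparisons are therefore asserted on
seed-averaged means, with per-seed values visible in the acceptance
output.

## Known limitations

* No backpropagation through time: training consumes fixed-width
  per-protein representations (the default embedding path); per-residue
  recurrent training would require BPTT.
* The k-mer dedup is a heuristic stand-in for alignment-identity
  clustering; at permissive thresholds on short sequences it can
  under-merge relative to true alignment identity.
* CTD's structure/accessibility groupings are propensity classes, not
  predictions.
* Synthetic domains are isotropic Gaussians; conclusions about real
  proteome screening performance require real embeddings and labels.
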