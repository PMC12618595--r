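---
title: "Mapping structural to functional connectomes: models, generator, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping structural to functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfcmap)
```

## The problem

How well can a person's functional connectome be predicted from their
structural connectome? `scfcmap` implements two per-subject predictors of
MEG-band functional connectivity (FC) from diffusion-MRI-style structural
connectivity (SC), together with the statistical battery used to compare
them in health and in psychosis:

* an **analytical communication model**: ordinary least squares of the
  observed FC edges on weighted shortest-path length (SPL), search
  information (SI) and inter-regional Euclidean distance (ED);
* a **graph multi-head-attention autoencoder (GMHA-AE)**: an attention
  encoder over the SC graph producing per-node latent vectors, decoded
  pairwise into a reconstructed FC matrix, trained with participant-level
  five-fold cross-validation.

All matrices live on one fixed parcellation (84 cortical + subcortical
regions by default). Five structural edge weightings are distinguished
(NS, NS/v, FA, iRD, FRt) and four MEG bands (delta 1-4 Hz, theta 4-8 Hz,
alpha 8-13 Hz, beta 13-30 Hz). The atom of every downstream statistic is
the per-subject Pearson correlation `r` between observed and predicted FC
edges for one (model, band, weight) condition.

## The analytical model

Edge lengths default to the reciprocal of the structural weight
(`to_lengths()`, `transform = "inv"`), the convention of the communication-
model literature: strong connections are short. SPL is computed by
Dijkstra's algorithm on these lengths. SI measures how *hidden* the
shortest path is to a random walker that steps with probability
proportional to structural weight: `SI = -log2 Pr(walker follows the
path)`. Both directions are averaged because FC is symmetric. Two walker
variants are provided: the default memoryless walker, and a `memory`
variant whose denominator excludes the edge just traversed at every step
after the first. Which variant the field's implementations use differs;
both are exposed and tested against brute-force enumeration.

Because SI depends on *which* shortest path is taken, ties must be broken
deterministically: among equal-length paths the lexicographically smallest
node sequence is chosen (greedy reconstruction certified by the distance
matrix). Without this, results would depend on floating-point traversal
order.

The per-subject regression (`fit_fc()`) is OLS with intercept on the raw
(unnormalized) observed FC edges; by the OLS identity the reported Pearson
r equals the multiple correlation R and is nonnegative. Max-normalizing
the FC first would not change r (affine invariance). Predictors enter
untransformed; the generator's ground truth uses z-scored negated
predictors, which spans the same column space, so the regression is exactly
well-specified on generated data.

Degenerate inputs: disconnected SC graphs raise a named error (SPL would
be infinite); constant FC raises an error (correlation undefined);
collinear predictors fall back to the pseudo-inverse with a warning.

## The autoencoder

No automatic-differentiation stack is part of the package's dependency
set, so the GMHA-AE is implemented as explicit forward/backward matrix
code with an Adam optimizer; the backward pass is verified against
numerical differentiation in the test suite (relative error below 1e-5 on
spot-checked parameters, ~1e-10 in full-vector checks during development).

Architecture (defaults; all grid-searchable via `gmha_config()`):

* **Node features** (from ED and SC): mean distance to all other nodes,
  sample SD of those distances, distance to the nearest anatomical
  neighbour, SC strength, SC degree, optionally the node's full SC row;
  z-scored across nodes per subject.
* **Encoder**: 2 attention layers, 4 heads. Attention scores are additive
  GAT-style, `e_ij = LeakyReLU(a1.(W x_i) + a2.(W x_j)) + u log(1 + w_ij)`,
  softmax-normalized over each node's structural neighbourhood plus a
  self-loop. The `u log(1+w)` term lets SC strength modulate attention, so
  the SC acts as a *weighted* adjacency rather than a mask. Head outputs
  pass through an ELU and are concatenated in hidden layers and averaged
  in the final layer (latent dimension 32 per node).
* **Decoder**: symmetric pairwise MLP on `[z_i * z_j || |z_i - z_j|]` with
  one hidden layer; symmetry and a zero diagonal hold by construction.
* **Loss**: edge-wise MSE against the max-normalized observed FC plus
  `gamma * ||theta||^2` with `gamma = 0.01`; training defaults are 200
  epochs, batch size 32 graphs, Adam at learning rate 1e-3.

Cross-validation is at the participant level: five disjoint folds; within
each fold's development set a 75/25 train/validation split supports the
(optional) grid search, which by default contains only the default
combination. Out-of-cohort subjects (patients) are scored by averaging the
five fold models, and an id-based leakage guard refuses to score any
subject seen during training unless explicitly overridden.

## The synthetic cohort generator

The generator exists so that every stage has a recoverable ground truth;
it emulates the *matrix-level statistical structure* of the study cohort,
not raw MEG or tractography. Defaults are the study conditions: 126
healthy subjects aged 18-50, 5 psychosis patients aged 18-35 with integer
PANSS scores (totals 30-60), 84 regions, structural density 0.35.

* **Geometry**: centroids uniform in two mirrored hemispheric ellipsoids
  (semi-axes 25 x 35 x 30 mm); ED is their metric, shared cohort-wide.
* **Topology**: a cohort backbone with edge probability proportional to
  `exp(-d / 40mm)`, calibrated to the target density and repaired to be
  connected; each subject deviates by sparse edge flips (2% of plausible
  edges) so inter-subject connectome similarity is high, as in healthy
  cohorts.
* **Weights**: NS is heavy-tailed log-normal decaying with distance (so NS
  anticorrelates with ED and is far more skewed than the bounded
  variants); NS/v divides by simulated region-volume pair sums; FA, iRD,
  FRt are Beta-distributed with variant-specific means and latent
  correlation 0.6, as microstructural measures are mutually correlated.
* **FC**: for each band, `beta0 + b_spl(-z SPL) + b_si(-z SI) +
  b_ed(-z ED) + noise`, rescaled into [0, 1]. Negation encodes that
  shorter/cheaper communication routes couple more strongly. Per-band
  noise SDs (2.8, 2.0, 1.5, 1.35 from delta to beta, on the scale of the
  roughly unit-variance linear predictor) were chosen once so that the
  analytical model's accuracy regime matches the study's qualitative
  pattern -- higher bands predicted better, delta worst and most variable
  across subjects -- and are recorded in `ground_truth.json`.
* **Patients** follow the *same structural law*; only their mapping
  coefficients are shifted (delta strengthened, alpha/beta weakened,
  theta untouched). This reproduces the study's headline signature: the
  SC-FC *relationship* diverges while matrix summaries (total strength)
  do not.

**Individuality.** The spec-level knob `individuality_sd` jitters the
per-subject mapping coefficients. A subtlety: because both models refit
per subject, coefficient jitter alone is invisible to the SC-shuffling
analysis -- the refit absorbs any coefficient vector, and only differences
between subjects' *predictor matrices* (their structural fingerprints)
are detectable. The generator therefore also scales the subject-specific
structural weight jitter by `individuality_sd`, so that individuality is
expressed where the shuffling design can see it. With
`individuality_sd = 0` subjects share the mapping and near-identical
structure, and shuffling is a statistical no-op (mean shuffled r within
0.02 of unshuffled); with large values the own-SC advantage appears for
the overwhelming majority of subjects.

What the generator does *not* emulate: realistic spectral content,
geodesic cortical geometry, hemispheric asymmetries, lognormal FC tails,
or any biological mechanism behind the band differences. Passing tests
demonstrate internal consistency and statistical power under the stated
generative law, not validity on real MEG/MRI data.

## Numerical choices and scaled problem sizes

* Symmetry tolerance 1e-8 absolute on input matrices; asymmetric input is
  rejected rather than silently symmetrized (an explicit `symmetrize`
  flag averages when the user opts in).
* Matrix CSVs carry 15 significant digits; round-trips are stable to
  1e-12 relative. The pipeline always works from the on-disk cohort so
  cached and fresh runs are bit-identical.
* Shortest-path tie-breaking tolerance is 1e-9 relative, ample for
  continuous weights where exact ties have measure zero, and exact on the
  integer-weight toy cases.
* Mann-Whitney is exact when the smaller group has at most 8 observations
  and no ties (the 5-patient comparisons require this); otherwise the
  tie-corrected normal approximation is used with a warning. The
  label-permutation test enumerates all relabelings up to C(20,10) and
  switches to seeded Monte-Carlo with an add-one estimator beyond that.
  BH-FDR is the step-up procedure with realized-threshold semantics; a
  Benjamini-Yekutieli variant is available.
* The test suite runs at reduced sizes chosen once: 200 oracle graphs at
  n <= 8; analytical exactness on 20 subjects at 32 regions; autoencoder
  recovery on 40 subjects at 32 regions with 50 epochs; shuffling on 40
  subjects at 48 regions with 500 permutations; group divergence on 20
  replicates of the full default cohort. The autoencoder's scaled runs
  use batch size 2, learning rate 5e-3, hidden width 32, latent 16 and
  `gamma = 1e-4`: with ~30 training graphs, the paper-default batch of 32
  would give a single gradient step per epoch, and the default `gamma`
  would over-regularize the much smaller parameter vector. The package
  defaults remain the full-scale protocol values.

## Known limitations

* The autoencoder's published architectural details beyond layer counts
  and training hyperparameters are not fully specified anywhere we could
  follow; the attention formula, decoder form, and regularizer here are
  the package's own defensible choices, exposed in `gmha_config()`.
* Training is single-threaded R matrix code: ample for the scaled
  problem sizes above, slow for 200-epoch full-cohort runs (hours, not
  minutes).
* The analytical model's r is reported for the memoryless SI variant by
  default; switching variants changes SI values substantially (the toy
  example drops from 1.32 to 0.32 bits) but rarely the qualitative
  comparisons.
* Healthy/patient comparisons use all healthy subjects by default; the
  age-matched-subset analysis is available by filtering ids upstream.
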