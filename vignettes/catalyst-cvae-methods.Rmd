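---
title: "Conditional VAE catalyst design: models, assumptions, and numerical choices"
author: "catvae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional VAE catalyst design: models, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Homogeneous catalysts — often multi-fragment organometallic complexes —
determine the outcome of a reaction jointly with its other components
(reactants, reagents, product identity, reaction time). `catvae` implements a
joint generative/predictive model for this setting: a conditional variational
autoencoder (CVAE) whose condition vector embeds the surrounding reaction, so
that the same latent space supports (i) predicting a catalytic endpoint
(percent yield, binding energy, activation free-energy differences) and
(ii) generating new catalysts appropriate to a given reaction context, with
Bayesian optimization over the latent space for inverse design.

## Molecular representation

A catalyst is encoded as a one-hot triple `M = (T, A, B)` over at most `S`
graph nodes:

* `T` (length `S`) — size indicator; the set index equals the number of
  occupied nodes, index 0 meaning "empty". A consequence of this convention
  is that the largest encodable molecule has `S - 1` atoms.
* `A` (`S x A_t`) — atom type per node, with channel 0 reserved for no-atom.
* `B` (`S x S x B_t`) — bond type per node pair, channel 0 no-bond, symmetric
  in its first two indices, with no-bond diagonal.

The defaults are `S = 100`, `A_t = 68` (67 curated elements plus no-atom:
organic elements, main-group elements, and the transition metals and
lanthanides common in catalysis) and `B_t = 6` bond categories
(no-bond, single, double, triple, aromatic, other/coordination), giving a
flattened dimensionality of `100 + 100*68 + 100*100*6 = 66900`. The
"other" category absorbs dative and otherwise unclassifiable bonds, so
organometallic inputs do not inflate the channel count. Element membership
of a vocabulary built from data is frequency-ranked with alphabetical
tie-breaks and padded with curated elements, and the vocabulary is
serialized (JSON) with every checkpoint so decoding stays reproducible.

Node order for encoding is the toolkit's canonical atom ranking
(canonical SMILES order as produced by OpenBabel); node-shuffle
augmentation randomizes the order of occupied nodes during training (the
pre-training schema uses five orderings per molecule, counted as five total
copies including the canonical one — the canonical copy is always present).
The representation deliberately carries **no formal charge, stereochemistry
or isotope channels**; charges produced by valence repair during decoding
therefore cannot round-trip through re-encoding, and the package's
idempotence guarantees are scoped to charge-free structures.

Reactants, reagents and products are represented as attributed graphs. The
default feature scheme uses element-group one-hots (12), degree one-hots (6)
and formal-charge sign (3) per node, and bond-category one-hots (5) per
edge. The widths are declared by `graph_feature_scheme()` and asserted in
tests rather than copied from any external table.

## Model

With catalyst embedding `x` and condition `c`, the model is

* **Catalyst embedding** — each of `T`, `A`, `B` passes through its own
  network (a linear map for `T`, two-layer perceptrons for `A` and `B`) and
  the three outputs are summed into `x`.
* **Condition embedding** — each condition molecule is embedded by a
  two-layer graph attention encoder with mean pooling; within-role multiple
  molecules are mean-pooled; absent reagents use a learned default vector;
  the concatenation with the reaction-time scalar and the catalyst
  molecular-weight cluster one-hot (quantile bins computed from the
  training set, 8 by default) gives `c`.
* **Encoder** `Q(z | x, c)` — an MLP with mean and log-variance heads;
  samples use the reparameterization `z = mu + exp(logvar/2) * eps`.
  Log-variances are clamped to `[-8, 8]` for numerical stability.
* **Decoder** `P(M | z, c)` — three sequential heads. The size head
  consumes `(z, c)`. The annotation head consumes `(z, c)` and the size
  probabilities. The annotation output is then *enhanced*: each node row is
  concatenated with a positional one-hot, `z`, and `c`, passed through a
  linear map, and the resulting per-node features form symmetric pairwise
  features (elementwise product and sum — the outer-product initial
  adjacency) refined by the adjacency MLP into per-pair bond-type logits,
  symmetrized by averaging. The positional one-hot matters: without it, two
  nodes of the same atom type would receive identical features and the
  outer product could not express asymmetric connectivity.
* **Teacher forcing** — during training each stage independently consumes
  the true upstream block with probability 0.25 (one Bernoulli draw per
  stage and sample).
* **Predictor** `f(z, c)` — an MLP on the latent *mean* concatenated with
  `c`. Yield-kind outputs are reported in percent and clamped to [0, 100].
  Targets are standardized internally; the centering/scale live in the
  checkpoint.

The training loss is
`L_total = alpha * L_recons + beta * L_KL + L_prediction`, with `L_recons`
the sum of categorical cross-entropies over the `T`, `A` and `B` fibers,
`L_KL` the closed-form Gaussian KL to the standard normal, and
`L_prediction` the squared error on the standardized target. Because the
adjacency tensor is extremely sparse (almost all of the `S^2` fibers are
no-bond), the no-bond channel is down-weighted by the observed
bond/no-bond frequency ratio; without this the decoder collapses to
predicting no-bond everywhere.

### A deliberate deviation: fixed condition encoders

The graph attention condition encoders use fixed, seeded random weights — a
deterministic random-feature graph embedding — rather than being trained
jointly. The trainable encoder/decoder/predictor adapt to this fixed
embedding. Rationale: conditions are inputs, never reconstruction targets,
so the information they must carry is preserved by a random nonlinear
projection (in the random-features sense), while joint backpropagation
through thousands of variable-size molecular graphs per epoch in
interpreted R would dominate the runtime by orders of magnitude. The
practical consequence is that condition embeddings can be precomputed once
per record, which is what makes desk-scale CPU training fast. All
condition-encoder weights ship in the checkpoint, so embeddings are
reproducible.

### Training engine

No deep-learning framework is available to this package, so the dense
layers, block-softmax cross-entropies, analytic backward passes and Adam
are implemented in base R matrix algebra. The backward pass is verified
against central finite differences in the test suite (worst relative error
below 1e-4 across every layer). Training uses minibatch Adam with a step
learning-rate decay (full rate for the first 60% of epochs, then 1/3, then
1/10).

## Reconstruction (decoding with validity correction)

Decoded logits become molecules by: reading the size from the argmax of
`T`; assigning atom types by per-row argmax of `A` (rows won by the
no-atom channel are dropped and counted in the report); collecting all
candidate non-no-bond pairs `i < j`, sorting them by probability
descending (ties broken lexicographically by indices and channel), and
adding them in that order with valence checking after each addition. A
violating bond is removed — except when adding a permitted formal charge
legalizes the local valence (+1 on N/P/O, -1 on B; carbon is never
charged). Rejected pairs become no-bond; lower-probability bond types are
not re-offered for a rejected pair. Finalization demotes aromatic bonds
that are not part of a cycle of the aromatic-bond subgraph to single
bonds (always valence-safe), removes fragments consisting of exactly one
uncharged carbon, re-checks valences, and round-trips the structure
through canonical SMILES; if the round trip fails, all aromatic bonds are
demoted to single and it is retried once; a second failure yields an
empty output, which is a legal result counted as invalid by the
generation metrics.

Fiber scores are interpreted as probabilities when they are non-negative
(normalized by their sum) and passed through a softmax otherwise, so
one-hot matrices, probability tensors and raw logits all decode
consistently.

Valence accounting uses a standard element table (aromatic bonds count
1.5); metals are treated permissively as coordination centres with a cap
of 8. Chemistry I/O (SMILES parsing, canonicalization, molfile round
trips) goes through OpenBabel; "sanitization" in this package means the
conjunction of valence-table legality and a successful canonical-SMILES
round trip.

## Data curation

Reaction tables (a SURF-like delimited dialect) are normalized and curated
in a fixed order: parse and canonicalize (dropping rows with missing
roles, non-positive times, or unparseable SMILES, each drop logged with a
machine-readable reason), average duplicates over the order-insensitive
(reactants, product, catalyst, reagents, time) key, remove IQR outliers
(`k = 1.5`, quartiles by linear interpolation — quantile type 7 — over
catalyst molecular weight, catalyst atom count and target), clip
yield-kind targets to [0, 100], and downsample overrepresented catalysts
(default cap: 1% of the records, at least 1). Splitting is a seeded exact
partition at 90:5:5. Re-running any earlier stage on curated output is a
no-op, which the tests assert.

## Generation and metrics

Three sampling schemes: random latents drawn uniformly inside the
per-dimension integer-bounded box (`[floor(min), ceil(max)]`) of the
training latent means with a random training condition; Gaussian
perturbations (default sigma 0.5 latent units) around an anchor catalyst's
latent mean with a random condition; and the same perturbation with the
anchor's own condition.

Metrics are all reported as fractions of the generated set size, so the
chain `novel <= unique <= valid <= 1` holds by construction: Valid
(chemically sane), Unique (distinct canonical structures among the valid),
Novel (distinct valid structures absent from the training set), IntDiv
(mean pairwise Tanimoto distance among distinct valid structures), SNN
(mean over valid molecules of the maximum Tanimoto similarity to the
training set — computed over valid molecules, a documented choice since
the averaging set is otherwise ambiguous), and task-specific validity
(single-fragment; palladium-acetate presence; the L1-M-L2 three-fragment
motif with exactly one lone metal). Fingerprints are ECFP4; OpenBabel's
4096-bit implementation is folded to the conventional 2048 bits by OR-ing
the two halves, a convention pinned in code so similarity values are
bit-exact reproducible. A Fréchet-distance plugin hook exists
(`fcd_fn` argument) but no network ships with the package; the field is
omitted, never fabricated.

## Inverse design

The objective at a latent point decodes the latent under a fixed
condition, re-embeds and re-encodes the decoded catalyst, predicts its
performance from the re-encoded latent mean, and adds reward terms,
subtracts penalty terms (named structural predicates cover the
cross-coupling case-study constraints: wrong fragment count, missing
P/N/O, overcoordinated heteroatoms, 3-/4-membered rings) and optionally
subtracts a similarity term `w * (1 - max Tanimoto to a reference set)`.
In `match_value` mode the base score is `-|prediction - target|`; the
cross-coupling case targets the midpoint (-27.55 kcal/mol) of the
effective binding-energy window (-32.1 to -23.0 kcal/mol).

The optimizer is sequential model-based: an exact Gaussian process (RBF
kernel on inputs rescaled to the unit box, standardized outputs,
lengthscale 0.25, jitter 1e-4) proposes points by expected improvement
over a 128-point random candidate pool; below 10 observations it falls
back to pure random search. No Bayesian-optimization package exists in
this R environment, so the GP and acquisition are implemented in-package
(~40 lines, Cholesky-based). Empty decodes receive a finite failure score
(running `min - 3*IQR`, floor-capped) so the GP stays numerically stable.
Per round, duplicate decoded molecules are collapsed before the top-k are
retained; the case-study protocol (50 rounds, top 10) therefore yields 500
candidates when enough distinct valid molecules appear. The best-so-far
trace is non-decreasing by construction and asserted on every run in the
tests.

## Synthetic fixtures: what they emulate and what they do not

The fixture generator grows random valence-legal molecules atom-by-atom
from an element palette (occasional double bonds and one optional ring
closure), assembles catalysts that are optionally ligand–metal(–ligand)
multi-fragment complexes, draws positive lognormal reaction times, and
computes targets as `100 * sigmoid(w . (d - d0) + b) + N(0, sigma)`
clipped to [0, 100], where `d` collects catalyst MW/100, heteroatom count,
ring count and log time, and `(w, b)` are drawn once from the seed and
recorded with the dataset. This gives every downstream stage a recoverable
ground truth: surrogate regressors fitted on the descriptors reach
held-out R² ≥ 0.99 without noise and approach the noise floor with it.

What the fixtures do **not** emulate: realistic reaction-class
distributions, correlated roles (the reactants and products are unrelated
molecules), condition-dependent mechanisms, charged species, or
stereochemistry. Passing tests on fixtures therefore demonstrates the
correctness of the machinery — codec, curation, training dynamics,
metrics, optimization — not chemical accuracy on real reaction corpora.

## Problem sizes and numerical choices

The desk-scale study conditions used across the tests and the acceptance
script are: 200 single-fragment records of at most 12 heavy atoms, noise
sigma 5, latent width 32, adjacency feature width 40, 600 training epochs
of minibatch-64 Adam at rate 3e-3 with step decay, `alpha = 1`,
`beta = 1e-3`. Under these conditions the trained model reconstructs
essentially all of its training catalysts exactly and the training loss
and prediction RMSE fall by far more than half. The KL weight is kept
small at desk scale because with 200 molecules the model must operate as
a near-deterministic autoencoder for reconstruction to be measurable;
larger corpora warrant larger `beta`.

Other numerical choices: quantile type 7 everywhere a quartile is taken;
molecular weights from standard atomic weights with implicit hydrogens
filled to the smallest allowed valence; all indices 0-based in the matrix
semantics (1-based in R storage); bins half-open left-closed; equal bond
probabilities broken lexicographically; and every stochastic function
takes an explicit seed, with an internal RNG wrapper that never perturbs
the caller's RNG stream.

## Known limitations

* No charge, stereochemistry or isotope channels in the matrix
  representation (charged repairs decode correctly but cannot re-encode).
* The condition encoders are fixed random-feature embeddings, not jointly
  trained (see above).
* OpenBabel, not RDKit, defines canonicalization and aromaticity
  perception here; canonical forms differ between toolkits, so structure
  comparisons are only meaningful within the package.
* The GP in the optimizer uses a fixed lengthscale; no hyperparameter
  marginalization.
* Pre-training at the scale of public reaction corpora is out of scope;
  the package targets desk-scale corpora and transfer of the architecture.
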