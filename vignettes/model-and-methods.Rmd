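---
title: "The diffusion model behind pldiffuser: assumptions, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The diffusion model behind pldiffuser}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pldiffuser)
```

## What the package models

`pldiffuser` treats a protein–ligand complex as a single 3D point cloud:
one Cα per residue followed by one point per ligand heavy atom, in that
fixed token order everywhere. Two generative mechanisms are coupled:

* a **variance-preserving diffusion** on the coordinates, defined on the
  zero-centroid linear subspace so that translations never enter the
  model, and
* a **masked sequence channel**: part of the amino-acid sequence is
  replaced by a MASK token and re-predicted from the learned
  representation, so the same network that denoises coordinates also
  proposes residues compatible with the ligand.

The denoiser never sees absolute coordinates. All geometry enters through
radial-basis embeddings of inter-token distances, so the predicted noise
field — a weighted sum of unit difference vectors with the centroid
subtracted — commutes with rotations and ignores translations by
construction. The test suite measures this rather than assumes it: over
random complexes, rotations and translations, the deviation
`‖ε̂(Rz + t) − R ε̂(z)‖∞` stays below 1e−5 (in practice it is at machine
precision).

## The noise schedule

The schedule supplies `alpha(t)` and `sigma(t)` with
`alpha² + sigma² = 1`, `alpha` monotone decreasing, `alpha(0) ≈ 1`,
`alpha(1) ≈ 0`. Two parametrizations are registered:

* `"cosine"` (default): `alpha(t) = cos(pi/2 (eps0 + t(1 − 2 eps0)))` with
  `eps0 = 0.005`. The endpoint shift keeps `alpha` strictly inside (0, 1)
  on the whole grid — without it the last reverse step divides by
  `alpha(1) = 0`. With this value `alpha(0) ≈ 0.99997` and
  `alpha(1) ≈ 0.0079`, satisfying the endpoint conditions
  (`alpha(0) ≥ 1 − 1e−4`, `alpha(1) ≤ 1e−2`) with margin.
* `"linear_logsnr"`: log signal-to-noise ratio linear from +10 to −10.

A note on a linear shorthand one sometimes sees for such schedules,
`alpha = 1 − sigma²`: taken literally it contradicts variance preservation
everywhere except at `sigma ∈ {0, 1}` (substituting it into
`alpha² + sigma² = 1` forces `sigma⁴ = sigma²`). The package therefore
reads it as the variance-preserving identity `alpha² = 1 − sigma²`, which
is also what the transition and posterior formulas require to be
self-consistent. The literal map is kept as the diagnostic
`literal_alpha_from_sigma()` and is deliberately *not* a registered
schedule kind, since every registered kind must satisfy the invariants
above.

The reverse process uses the standard Gaussian posterior; the package
implements both the posterior form (`posterior_params()` with the denoised
estimate) and the noise-prediction form (`reverse_step()`) and asserts
their algebraic identity to 1e−10 in the tests. One subtlety of the
zero-centroid subspace is worth knowing when writing Monte-Carlo checks:
after centering, the per-coordinate variance of an n-token standard
Gaussian is `(n−1)/n`, not 1 — the conditional-moment tests account for
this factor explicitly.

## Featurization

* **Sequence tokens**: 22-letter alphabet (20 canonical, UNKNOWN `X`,
  MASK `-`). Residue rows combine a learned token embedding with the
  per-residue-normalized output of a pluggable embedder mapped linearly
  into `c_m` channels. The embedder contract is "sequence in, n × d matrix
  out, deterministic"; the shipped `stub_embedder()` draws each vector
  from a hash of (token, position, seed), so identical prefixes embed
  identically. A protein language model can be dropped in through the
  same contract; the package builds and tests with the stub only. The
  embedder is fed the *masked* sequence — feeding the unmasked one would
  leak the residues the cross-entropy loss is supposed to predict.
* **Ligand chemistry**: SMILES are parsed with OpenBabel (via ChemmineOB).
  Nine atom fields (atomic number, tetrahedral parity, degree, formal
  charge, attached hydrogens, radical electrons, hybridization,
  aromaticity, ring membership) and three bond fields (type, stereo code,
  conjugation), each with its own embedding table and an out-of-vocabulary
  bucket. Hybridization and aromaticity come from OpenBabel's MOL2 atom
  typing; ring membership is graph-theoretic (an edge is in a ring iff it
  is not a bridge); conjugation is a documented heuristic (aromatic bond,
  or both endpoints sp/sp2/aromatic). MOL2 also labels delocalized
  carboxyl bonds "ar", so a bond is only called aromatic when both of its
  atoms are. The masked ligand `"*"` contributes zero tokens (rather than
  a placeholder token), which keeps the denoiser's weighted sum
  well-defined with no special cases.
* **Pair features**: clipped relative-position one-hots for
  residue–residue pairs (offset clamped to ±`r_max = 32`, the established
  convention for this encoding; one extra bin for any pair touching a
  ligand atom), bond embeddings injected symmetrically at (i, j) and
  (j, i), 16 Gaussian RBFs with centers evenly spaced on [0, 20] Å and
  width equal to the spacing, and a sinusoidal time embedding
  (frequencies `pi·2^k`; at t = 0 the sine channels are exactly 0 and the
  cosine channels exactly 1). Distances are recomputed from the current
  latent at every sampling step, i.e. the trunk is re-run inside the
  reverse loop.

## The trunk and its printed defaults

Each trunk block applies, residually and in this order: gated
single-representation attention with pair bias → outer-product update →
outgoing triangle update → incoming triangle update. The composition order
within a block is a design choice (the residual-update scheme itself does
not fix one); attention-before-pair-updates lets the pair bias of block k
see block k−1's pair state.

* The attention defaults are the architecture's stated ones: per-head
  width `C = 65` and `N_head = 4`. 65 is an unusual width (not a power of
  two) and may well be a typo for 64 in the source material, but it is
  what is printed, so it is the default and fully configurable.
* The outer-product update computes `flatten(a_i ⊗ b_j)` for every token
  pair — the *cross* form. Note that a per-token form `a_i ⊗ b_i` cannot
  produce a pairwise tensor at all, so the cross form is the only reading
  that type-checks; width `C = 32` as printed. No mean is taken over any
  axis.
* The triangle multiplicative equations (gated projections, k-sum over
  outgoing edges `a_ik ⊙ b_jk` or incoming edges `a_ki ⊙ b_kj`,
  layer-normalized and gated output) follow the canonical published form
  of that mechanism, since only the mechanism's name is fixed by the
  architecture description; hidden width defaults to `c_z`.
* Weights are per-block (not shared across blocks), the standard choice
  for this family of trunks. No dropout. The default block count is 4 at
  desk scale; the tests mostly run 1–2 blocks.

One identity worth recording: with the two triangle projections tied
(a ≡ b) and direction weights shared, the outgoing update on `z` equals the
transposed incoming update on `t(z)` — the tests check this numerically, and
it is a useful canary for index conventions in the k-sum.

## Denoiser and sequence head

The final pair tensor is symmetrized, `(z + t(z))/2`, *then* passed through
a per-entry MLP to a scalar, making W exactly symmetric. (Producing W per
ordered pair and symmetrizing afterwards would also be equivariant; the
symmetrize-first variant was chosen as it guarantees symmetry regardless of
the MLP.) The noise field excludes the j = i term (it is 0/0 otherwise) and
regularizes the denominator with `delta = 1e−6` Å, so exactly coincident
tokens contribute nothing rather than failing. Centroid subtraction runs
over all tokens jointly — protein and ligand share one zero-centroid
subspace. The sequence head is a single linear map `c_m → 20` on residue
rows only: the smallest head that the losses can train; the configuration
can deepen it.

## Losses and training

`L = L_WS + L_KL + L_CE`, an unweighted sum (checked exactly additive):

* **L_WS**: the Euclidean norm `‖ε − ε̂‖` per sample, with one diffusion
  time drawn uniformly from the grid per step — the Monte-Carlo estimate
  of the sum over time steps.
* **L_KL** is the least-specified component and its concretization is a
  package choice: the forward process on sequences is taken as
  interpolation toward the uniform distribution with signal level
  `alpha(s)²`, the prediction is blended the same way, and the mean
  row-wise KL is weighted by the discrete step weight
  `beta(t) = 1 − alpha(t)²/alpha(t − Δ)²` with `Δ = 1/T`. This weight is
  non-negative for any decreasing schedule and vanishes as the step size
  does. Predicted probabilities are floored at 1e−8 before the log.
* **L_CE**: mean cross-entropy over the masked positions only (an
  all-positions variant is a one-line change); an empty mask set scores 0
  with a warning.
* **Masking**: the effective ratio is redrawn each step as
  Uniform(0, ratio) and positions are chosen without replacement, so a
  length-100 sequence at ratio 0.15 masks 7.5 positions on average;
  `fixed_ratio = TRUE` gives the simpler fixed-fraction variant. Whether
  masks should be fixed per example or redrawn per step is genuinely open;
  redrawing was chosen as the stronger regularizer and is what the
  training step does.

Training uses Adam (plain defaults, learning rate ~1e−2 at toy scale) on
every parameter, with gradients from the package's tape-based reverse-mode
autodiff. Each primitive's backward rule and the full end-to-end gradient
are finite-difference checked (relative error below 1e−4 on a tiny model;
in practice ~1e−10).

## Sampling

Ancestral sampling from the centered Gaussian prior over `T = 64` grid
steps by default. The decoder outputs the mean `z_0/alpha(0)` — no final
noise injection. Masked tokens stay masked in featurization throughout the
loop and are decoded (argmax by default, sampling optional) from the final
step's logits; continuous co-diffusion of the sequence channel during
sampling is a possible extension the current sampler deliberately avoids
in favor of the simplest consistent scheme. Every random draw derives from
the one user seed.

## What the synthetic generator does and does not emulate

`generate_toy_complex()` produces random sequences, self-avoiding Cα
random walks (step 3.8 ± 0.3 Å, non-consecutive clearance ≥ 2.5 Å — so
consecutive distances land in the 3.0–4.5 Å band by construction) and
ligand points placed in a 2.5–4 Å shell around a surface residue. This
exercises every code path (chain geometry, chemistry featurization,
masking, diffusion, losses, metrics, I/O) but has no secondary structure,
no rotamers, no physical binding pose and no evolutionary signal. Passing
tests therefore certify the *mathematics and the implementation* — they do
not certify design quality on real proteins, which additionally requires
large-scale training data and an actual language-model embedder.

## Problem sizes and numerical choices in the tests

The suite and the acceptance script run tiny configurations chosen as the
smallest sizes that make each property measurable: 1–2 trunk blocks,
channels 8–24, complexes of 5–12 residues, `T = 16` for training draws and
`T = 64` for the sampler recovery experiment; the Monte-Carlo posterior
check uses 20 000 draws and the masking law 10 000 seeds. The overfit
experiment trains a one-block model on a single 12-residue masked-ligand
complex for 500 steps at learning rate 2e−2; its total loss settles at
roughly a third of its initial moving average. Degenerate inputs are
handled explicitly: coincident tokens (regularized denominator), empty
mask sets (zero loss, warning), all-identical point sets in the Kabsch fit
(identity rotation by convention), empty contact sets on both sides
(overlap 1, vacuous agreement), and `d0` floored at 0.5 Å for very short
structures in the TM-score.

## Known limitations

* The trunk is O(r²)–O(r³) in tokens per step and the sampler re-runs it
  `T` times; the pure-R implementation is for desk-scale studies, not
  production-scale training.
* The ligand is a point set: no bond-length or angle restraints at the
  denoiser level, no protonation, conformers or partial charges.
* Chirality featurization uses SDF parity codes from the input SMILES;
  molecules whose stereo information OpenBabel cannot perceive fall into
  the out-of-vocabulary bucket.
* The TM-score optimizer (Kabsch initialization + iterative reweighting)
  can in principle miss the global optimum on pathological pairs; a
  rotation-grid brute force bounds it from below in the tests.
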