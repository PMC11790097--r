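---
title: "Adaptive wavelet base selection by policy gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive wavelet base selection by policy gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rlwbs)
```

## The model

ECG classification pipelines that feed scalograms to a neural network
must first commit to a mother wavelet ψ.  `rlwbs` treats that commitment
as a *per-signal decision* learned by reinforcement.  The decision
process is a contextual bandit (a stateless Markov decision process):
each training iteration is a single-step episode in which

* the **state** is the sampled mini-batch together with the current
  policy,
* the **action** for signal \(x_i\) is a catalog index
  \(a_i \in \{1,\dots,N_a\}\) drawn from the policy's softmax output
  \(P(a\mid x_i)\),
* the **reward** \(\eta_t \in [0,1]\) is the multi-label classification
  score, on a held-out evaluation split, of a backbone classifier trained
  in this iteration on the selected-base scalograms.

The policy ascends the REINFORCE gradient
\[
\theta \leftarrow \theta +
\alpha\,(\eta_t - b_t)\sum_{i=1}^{B} \nabla_\theta \log p(a_i \mid x_i),
\]
where \(b_t\) is an optional exponential-moving-average baseline.
Because episodes are single-step, the discounted return collapses to the
immediate reward; the discount factor is kept in the configuration for
fidelity with the episodic formulation but is inert (`gamma`, default 1).
Every signal in the batch shares the iteration's scalar advantage — the
joint-log-probability form of the objective — so credit assignment is
statistical, through the correlation between assignments and rewards
across iterations.

At evaluation time selection is greedy: the base with the maximal policy
probability (ties broken toward the lowest index, for determinism).

## The action space and the sampled transform

The catalog fixes 35 candidate bases: haar (1), db2–db20 (2–20),
sym3–sym8 (21–26), sym10 (27), sym20 (28), coif3–coif5 (29–31), and
bior1.1/2.2/3.3/4.4 (32–35).  These compactly supported wavelets have no
closed form (haar aside), so ψ is sampled by the cascade algorithm — one
synthesis step with the high-pass filter followed by repeated upsample +
low-pass refinements — at depth 8 (256 samples per unit support,
configurable).  For the biorthogonal family the *analysis* (decomposition)
wavelet is sampled, since the transform here is an analysis transform.
The filter coefficients are the standard published constants, embedded at
full double precision; tests verify the sampled functions against frozen
independent references and filter-bank identities.

The sampled CWT is a discrete convolution: scale is expressed in samples,
ψ is rescaled per scale by linear interpolation of its cascade samples,
boundaries are zero-padded, and rows are normalised by \(1/\sqrt{c}\).
Scales sit on a log-spaced pseudo-frequency grid
\(f = f_c f_s / c\) spanning a configurable band (defaults 0.5–40 Hz at
`M = 64` scales, covering the clinically relevant ECG bands; the recovery
study uses 1–30 Hz at `M = 32`).  Backbone features are coefficient
magnitudes, resampled by corner-aligned bilinear interpolation to a fixed
`feat_height x feat_width` image (default 16 × 32) and min–max scaled to
[0, 1] per scalogram; signed coefficients remain available for the
linearity contracts.

## Network architectures

No deep-learning framework is assumed: both networks are compact dense
networks with explicit backpropagation, sized for desk-scale experiments
and deliberately pluggable.

**Policy.**  The raw leads-by-time signal first passes a spectral front
end: the per-lead magnitude spectrum, block-averaged to `pool_len` bins
(default 64) and log-compressed.  The spectrum is invariant to the beat
phase of the record, which a small dense network needs in order to judge
morphology — it plays the role a convolutional stack plays in larger
models.  A normalisation layer whose statistics are fitted on the
training split (the role of batch normalisation) feeds the dense layers
and a single softmax head of width \(N_a\).  Two initialisation choices
matter: the head's weights are damped so the fresh policy is near-uniform
(maximum-entropy start), and the head's bias is set to a family-balanced
prior — uniform over the five wavelet families, then uniform within each
family.  Without the prior, the 19-member Daubechies family holds 54% of
a uniform prior's mass and early exploration differentiates classes
*within* that family; with it, cross-family differentiation dominates.
For the recovery study the default head is linear (`policy_hidden =
integer(0)`): the spectral input is linearly class-separable there and
the convex per-class credit assignment is markedly more reliable at a
200-iteration budget than a hidden-layer head.

**Backbone.**  A multi-label classifier over flattened scalogram
features: ReLU hidden layers (default one of width 32) and one sigmoid
output per class, trained by mini-batch SGD on binary cross-entropy for
`E` epochs per iteration (default 5) and hard-thresholded at 0.5.  Its
construction-time weights are kept as an immutable snapshot and restored
bitwise at the end of every iteration, so each iteration's reward is
measured from an identical starting point.

## Reward and metrics

The reward is a configurable scalar of the evaluation-split report:
macro-F1 by default (macro-AUROC and subset accuracy are alternatives;
"accuracy" alone is ill-defined for multi-label records).  The metric
suite computes per-class precision, recall, sensitivity, specificity, F1
and MCC from confusion counts, with macro (unweighted per-class mean) and
micro (pooled counts) averages.  AUROC is the rank-based Mann–Whitney
statistic with ties counted one half; the sensitivity-times-specificity
product is additionally exposed as `auc_sens_spec` for comparability with
reports that use that summary in place of a ROC-based area.  Zero-denominator
conventions: precision, recall and F1 are 0 when undefined; MCC is 0 when
any marginal vanishes.

## The synthetic recovery task

The generator produces fixed-length (10 s at 100 Hz), single-lead beat
trains: a strong shared background beat (sym5 atoms, amplitude 1) common
to both classes, plus a weak class-specific atom per beat — db4 for class
A, bior3.3 for class B, amplitude 0.35 at an offset of 0.35 beat periods —
with a uniformly random beat phase per record, per-beat timing jitter
(0.05 s), log-normal amplitude jitter (0.2), additive white noise
(sd 0.1) and a 0.3 Hz sinusoidal baseline wander.  Atoms are built from
the same cascade-sampled ψ functions used for feature extraction, so the
optimal analysis wavelet genuinely differs by class.

This design is deliberate.  Two classes built from *strong* wavelet atoms
are separable under any base (every probe reached macro-F1 1.0 — no
selection signal), whereas under this design the backbone's per-iteration
budget (16 records, 5 epochs) leaves every single fixed base near chance
while class-differentiated per-record assignments reach macro-F1 0.8–1.0.
Two mechanisms contribute: matched-filter detection (the noise-normalised
response to a class atom peaks at its generating base — sharply so for
bior3.3) and base-specific scalogram texture, which lets the backbone
exploit *consistent* class-to-base assignments.  Both reward per-class
differentiation, which is the behaviour under study.  A caveat the tests
respect: the texture mechanism makes haar an anomalously strong *fixed*
base, so the well-posedness check (matched base beats mismatched by
≥ 0.05 macro-F1 at a full training budget) compares db4 against smooth
foreign-family bases (coif4, sym20).

What passing does **not** show about real data: the generator has no
PQRST dynamics, no inter-patient variability, no label noise, and its
class evidence is exactly wavelet-shaped; results transfer to clinical
ECG only in the qualitative sense that per-signal base selection can beat
any fixed base when classes differ in time–frequency morphology.

## Study configuration and numerical choices

The recovery study (`recovery_experiment()`) runs, per seed: 240 records
(120 per class, split 60/20/20 by record), `B = 16`, `E = 5`, `M = 32`
scales over 1–30 Hz, 16 × 32 features, 200 iterations, linear policy head,
`alpha = 0.4` decayed by 0.995 per iteration, EMA baseline (decay 0.9)
on, backbone SGD batch 4 at learning rate 0.5.  The 35 fixed-base
controls run the identical budget.  Feature transforms are cached once
per dataset–catalog pair (`build_feature_store()`); cached features agree
with `cwt()` to floating-point rounding (shared kernel FFTs).

Other numerical choices: three named RNG streams (policy-init,
action/mini-batch sampling, backbone) make ablations independent and runs
bitwise reproducible; mini-batches are drawn without replacement within
an iteration, with replacement across iterations; training stops when the
standard deviation of the last `term_window` rewards falls below
`term_eps` or at `max_iterations`; a failed iteration restores the stream
snapshot, leaving policy and backbone untouched; checkpoints (policy,
catalog hash, stream states) are written every 25 iterations and refuse
to load against a different catalog.

## Known limitations

* The policy's spectral front end discards phase; selection cannot
  condition on where in the record the evidence lies.
* With a shared scalar reward, credit assignment degrades as \(N_a\) or
  the reward noise grows; at 200 iterations roughly nine in ten seeds
  recover class-specific families, not all.
* The backbone is intentionally small; the interfaces accept drop-in
  replacements, and conclusions about large published architectures are
  out of scope.
* The energy-to-entropy comparator (`ee_wbs_select()`) is provided as the
  classical static baseline, not as a validated diagnostic tool.
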