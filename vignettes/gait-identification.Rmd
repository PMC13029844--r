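---
title: "Rank-based ensemble fusion for GRF gait identification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based ensemble fusion for GRF gait identification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When a person walks over a force plate, the plate records the ground
reaction force (GRF): the anterior--posterior (AP), vertical (V) and
medial--lateral (ML) components of the force the ground exerts on the foot.
These waveforms are shaped by the person's mass, posture and neuromuscular
control, and are distinctive enough to identify individuals in a closed,
enrolled set. `gaitrank` implements a complete identification pipeline for
six-channel GRF gait cycles (two plates, one stance per limb, three
components each), with particular attention to a *covariate* that a
deployed system must tolerate: a few-kilogram load carried in one hand,
which raises and skews the forces without changing who is walking.

The pipeline has five stages, each usable on its own:

1. a data model and file formats for stance-only, zero-padded GRF cycles;
2. a synthetic gait-population generator;
3. four stance-aware augmentation operators and a x9 training-set
   expansion;
4. a harness of trainable 1D classifiers emitting class posteriors;
5. rank-based ensemble fusion with tie resolution, a tunable
   position/quality trade-off, ablation and error analysis.

# Signal representation

A gait cycle is stored as an `N x 6` matrix in **raw newtons**, channel
order `L_AP, L_V, L_ML, R_AP, R_V, R_ML`, aligned at the left heel strike.
Outside each limb's stance interval the signals are exactly zero (a plate
reads nothing while the foot is airborne). Cycles in a dataset are padded
with trailing zeros to the length of the longest cycle; at the default
960 Hz a typical reference length is about 1.5 s of samples.

Two deliberate conventions:

* **No body-weight normalization.** A deployed identification system sees
  only the plate signal; the subject's mass is not available to divide by.
  Body mass is kept as roster metadata (it is needed for *analysing*
  errors, never for rescaling signals), and no operation in the package
  divides a force by it.
* **Stance intervals** are 1-based, inclusive `[start, end]` index pairs,
  the convention of R and of the field's interval containers. Stance is
  detected on the vertical channel as the envelope from the first to the
  last sample above a threshold (default 10 N: far above plate noise, far
  below any body weight), deliberately tolerating brief sub-threshold dips
  inside the stance.

# The synthetic population generator

The study data such systems are built on are rarely public, so the
generator is a first-class, tested module: every downstream stage is
exercised on populations whose ground truth is known. It emulates a cohort
with body mass drawn from Normal(74.33, 16.63^2) kg truncated to
[45, 130] kg, height Normal(174.41, 9.49^2) cm, 14--20 trials per walking
condition, and a 4.6 kg briefcase carried in a fixed, self-chosen hand
(a fair coin per subject) as the loading covariate.

Per limb, the vertical channel is a plateau-windowed two-peak ("M") shape:

* peak amplitudes `a1`, `a2 ~ U(1.05, 1.25)` x body weight,
* a mid-stance valley `~ U(0.70, 0.85)` x body weight,
* peak timings `t1 ~ U(0.22, 0.28)`, `t2 ~ U(0.72, 0.78)` of stance,
* Gaussian peak widths `~ U(0.06, 0.10)` of stance.

The AP channel is the braking/propulsion "S" shape (lobes of
0.15--0.25 body weight), the ML channel a small two-bump profile
(0.03--0.10 body weight). A plateau window with 4% linear ramps forces
exact zeros at the stance edges while keeping the loading edge fast, so
threshold stance detection recovers the generated stance duration to
within a few samples. Because amplitudes are multiples of body weight,
absolute peak forces grow monotonically with mass across subjects --
exactly the "weak biometric" property that makes body mass both helpful
for identification and the axis along which confusions concentrate.

**Placement of the right stance.** The two single-stance plate records
must be composed onto one cycle axis; the left stance opens the cycle and
the right stance is placed so that the total vertical impulse of both
limbs equals effective weight x stride period (taking the stride period as
twice the right-stance offset). This is the defining property of steady
walking and pins the stance/stride ratio at a realistic ~60% without a
separate parameter. A 10% trailing margin follows the right stance.

**Load model.** Under load the effective weight includes the briefcase;
the carrying-side limb's vertical share is inflated by `delta_carry = 0.06`
against `delta_contra = 0.02` contralaterally, ML gain 1.3 on the carrying
side, and stance lasts 3% longer. The magnitudes are configurable: the
direction (carrying side works harder, asymmetry grows) is what the
literature agrees on, the sizes are round numbers chosen once.

**Trial-to-trial variability** is multiplicative amplitude noise
(sd 0.02 per limb and channel), peak-timing jitter (sd 0.01 of stance) and
stance-duration jitter (sd 0.03 s). With all three at zero, two trials of
a subject are bit-identical -- the property tests rely on this switch.

**Reproducibility.** One master seed; each cycle's seed is derived by a
fixed integer counter scheme over (subject index, condition, trial), so a
whole study regenerates byte-identically and any single cycle can be
regenerated alone.

What the generator does *not* emulate: footwear, walking-speed and fatigue
effects, sensor drift, heteroscedastic within-subject structure, and the
rich subject-specific waveform detail of real plates. Passing the
end-to-end tests therefore shows the pipeline's machinery is sound under a
plausible data model, not that any particular accuracy will be attained on
real recordings.

# Augmentation operators

All four operators act on stance samples only, preserve length, channel
count and label, and are deterministic given a seed.

* **Band-limited noise injection** (`augment_jitter`):
  `x'[n] = x[n] + a * RMS(x) * s[n]`, `s` white Gaussian noise filtered by
  a 4th-order Butterworth low-pass at 30 Hz -- the noise is filtered, never
  the signal -- and `a = 0.01` for vertical channels, `0.02` for the four
  shear channels. Two choices the formula itself leaves open: the filtered
  noise is rescaled to unit RMS over the stance window before scaling
  (otherwise the perturbation size would inherit the filter's gain), and
  `RMS(x)` is computed over stance samples only (over the padded vector it
  would shrink with padding length, an artifact). With these choices the
  realized perturbation/signal RMS ratio equals `a` exactly.
* **Time shift** (`augment_time_shift`): an integer shift
  `~ U{-15..15}` samples drawn *independently per leg* (the legs
  desynchronize, as they do between real strides); each leg's three
  channels move as one unit; vacated samples are zero-filled. +/-15 samples
  at 960 Hz is about +/-15.6 ms.
* **Window crop with resampling** (`augment_window_crop`): up to 3% of the
  left stance is removed (the cut split uniformly between the two stance
  ends) and the shortened stance is linearly resampled back to its
  original length. Left leg only, so the operator adds temporal variability
  without compounding natural bilateral asymmetry.
* **Same-class mixup** (`augment_mixup`):
  `x' = gamma x1 + (1 - gamma) x2` with `gamma ~ U(0.85, 0.95)`, restricted
  to two cycles of the *same* subject -- the output must stay a plausible
  instance of one identity.

`expand_scenario_c()` emits, per original cycle, the original plus eight
variants: jitter; shift; crop; jitter+shift; jitter+crop; shift+crop;
jitter+mixup; jitter+shift+crop (operators applied in that order; the
mixup partner is a raw same-subject, same-condition cycle). Mixup appears
only combined with jitter, the one pairing in the protocol this implements.
Test data are never augmented.

# The classifier harness

Six backends share one interface: input is the six stacked channels over
the unified length, output a row-stochastic posterior matrix over the
enrolled subjects.

`nearest_centroid` is the deterministic reference backend: per-class mean
waveform, posteriors proportional to inverse Euclidean distances. It
trains in milliseconds, which is what makes exhaustive ensemble testing
cheap, and the fusion layer is agnostic to which backend produced a
posterior matrix.

The five deep templates -- `cnn`, `cnn_lstm_fc`, `resnet1d`, `convmixer1d`,
`inception_time` -- are built on a small neural-network engine written for
this package (1D convolution via im2col, depthwise convolution, LSTM,
max pooling, global average pooling, dropout, residual and parallel
blocks). Every backward pass is verified against central-difference
numerical gradients in the test suite. Training is minibatch Adam with
categorical cross-entropy, early-stopped on the loss of a stratified 20%
validation split held out at trial level; the best-validation snapshot is
kept. Design notes:

* Templates use He-initialized convolutions and ReLU/GELU without batch
  normalization; at the small depths the package targets, normalization
  layers are unnecessary and their omission keeps the engine small.
* Inputs are standardized per channel (mean/sd estimated on the training
  portion and stored with the model). This is a fixed affine conditioning
  transform -- it uses no subject-level quantity such as body weight, and
  between-subject amplitude differences pass through intact.
* `random_search()` samples configurations from each template's bounded
  hyperparameter space (block counts, filter and kernel sets, LSTM sizes,
  dropout ranges, batch sizes, log-uniform learning rate in
  [1e-5, 1e-3]) and returns the best validation Top-1. Direct calls to
  `fit_classifier()` accept smaller configurations than the search
  bounds -- deliberately, so smoke-scale models exist.
* The split indices and the model's posteriors on its own validation split
  are persisted in the fitted object: ensemble weights are later estimated
  on exactly the data the model was not fitted on.

# Rank-based fusion

For sample `m`, classifier `j` sorts its posteriors and keeps the Top-T
class list (ties broken by ascending class id, so every backend is
deterministic). Let `d_{j,p,i}^m = 1` iff classifier `j` ranked class `i`
at position `p`. On a labelled evaluation set -- the persisted validation
split -- each classifier's Top-p accuracy `Acc_{j,p}` is the fraction of
samples whose true class sits within its first `p` positions.

Per position `p`, classifiers are ranked:
`R_{j,p} = 1 + #{l : Acc_{l,p} > Acc_{j,p}}`; classifiers tied at `p` are
ordered by their Top-1 accuracy, and a tie that survives that too is
shared. Quality weights are `w_{j,p} = (K + 1 - R_{j,p}) / K in [1/K, 1]`,
and position weights `f_p = (T + 1 - p) / T` fall linearly from 1 to
`1/T`.

Two voting rules:

* **Weighted rank-order vote**: every classifier casts one vote, for its
  Top-1 class, with weight `w_{j,1}`; the maximal summed weight wins.
* **Additive weighted Top-T vote**: every classifier casts `T` votes; the
  vote at position `p` carries `lambda f_p + (1 - lambda) w_{j,p}`. With
  `T = 1, lambda = 0` this is exactly the rank-order vote (a tested
  identity). `lambda > 1` is allowed and taken literally -- the
  `(1 - lambda)` term goes negative, so large `lambda` actively discounts
  low-quality classifiers' deep positions; optima slightly above 1 are
  common, meaning position information deserves slightly more than full
  weight.

**Ties.** Two classes attaining the maximal fused score within a relative
tolerance of 1e-12 (floating-point near-ties are ties) are resolved by the
Top-1 indication of the best base classifier -- the one with maximal
validation Top-1; if several classifiers share that maximum they must
indicate unanimously, and the indicated class must be among the tied set.
Otherwise the ensemble outputs `None`, which every accuracy in this
package counts as an error. Tie events are counted and reported, because
they concentrate exactly where the ensemble is fragile.

`sweep_lambda()` evaluates the Top-T rule over the grid
`0.1, 0.2, ..., 5.0` (ties in the argmax go to the smallest `lambda`).

# Evaluation protocols

* **Scenario A** (reference): train and test on unloaded gait, k-fold
  cross-validation (default 10) with folds drawn at trial level *within*
  each subject -- closed-set identification requires every subject in every
  training fold; means and standard deviations across folds are reported.
* **Scenario B** (covariate stress): train on all unloaded, test on all
  loaded cycles.
* **Scenario C**: B with the x9 augmented training set; test data remain
  untouched.

`ablate_leave_one_out()` removes each classifier in turn and *recomputes*
ranks, weights and (for Top-T) the swept `lambda` with the remaining
`K - 1` -- the fusion coefficients are not inherited from the full
ensemble, consistent with re-deriving the method for the smaller
committee. `mass_confusion_analysis()` pairs each concrete
misclassification with the body-mass difference between the true and
predicted subject and reports the histogram, the ECDF at 4.6 kg (the
briefcase mass) and 11 kg, and medians against the all-pairs baseline;
`None` outputs carry no predicted identity and are excluded from the
pairing (but still counted as errors).

# Problem sizes and numerical choices

The test suite and the acceptance script run a desk-scale study: 30
subjects x 15 trials per condition (900 cycles), one small CNN (2 blocks,
16/32 filters, decimation 32, 25--30 epochs) with either the
nearest-centroid backend (tests, across 3 seeds) or small instances of all
five deep templates (acceptance script). These sizes were chosen so the
whole pipeline -- including 10-fold cross-validation and the x9 augmented
training run -- completes in minutes on one CPU core while leaving every
qualitative contrast measurable. Fusion-arithmetic tests are exhaustive at
small sizes instead: both voting rules are compared against an independent
brute-force scorer over *all* ranking tuples with `K <= 3`, `C <= 4`,
`T <= 3`.

Fixed numerical choices: stance threshold 10 N; score-tie tolerance 1e-12
relative; mass truncation [45, 130] kg; `K = T = 5` defaults (clamped to
the class count when a toy problem has fewer classes); histogram bin width
1 kg; ECDF thresholds 4.6 and 11 kg.

# Known limitations

* The deep templates run on a pure-R engine: correct (gradient-checked)
  but slow beyond desk scale; the full-width configurations of the search
  spaces are expressible but not practical on one core.
* Fusion weights are estimated on *unloaded* validation data. Under the
  loading covariate, validation quality is an imperfect proxy for transfer
  quality, and with base models of very unequal robustness the fused vote
  can trail the single best-transferring model -- visible in the
  acceptance script's five-template Scenario B run. The method's gains
  materialize when base classifiers are of comparable quality, as in the
  reference scenario; this is a property of rank-weighted voting, not a
  defect of the implementation.
* On small committees with coarse weights, `lambda` optima sit at the grid
  edge more often than they would with strong, well-separated base models.
* The generator's realism caveats above bound what synthetic results say
  about real plates: contracts and directions, not attainable accuracies.
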