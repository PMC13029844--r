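# gaitrank

Closed-set person identification from force-plate gait signals, with
rank-based ensemble fusion that stays accurate when the walker carries an
asymmetric load.

## What this is for

A force plate records, for each stance, the three components of the ground
reaction force (GRF): anterior–posterior, vertical, medial–lateral. Over
one gait cycle the six channels (left + right limb) form a waveform that is
distinctive enough to identify a person within an enrolled set — and
fragile enough that an everyday covariate like a 4.6 kg briefcase in one
hand measurably degrades recognition: the effective weight rises, the
carrying side works harder, and timing shifts. `gaitrank` is for
researchers in gait biometrics and biomechanical signal analysis who want
a complete, testable pipeline for this problem: data model and formats,
a synthetic population generator (GRF study datasets are rarely public),
stance-aware augmentation, trainable 1D classifiers, and the fusion layer
that combines them.

## The method

Each of `K` base classifiers turns its posterior vector for a sample into
a Top-`T` ranked class list. On a held-out validation split, classifier
`j`'s Top-`p` accuracy `Acc_{j,p}` is computed for `p = 1..T`; per
position, classifiers are ranked (`R_{j,p} = 1 + #{l: Acc_{l,p} >
Acc_{j,p}}`, ties broken by Top-1 accuracy, persistent ties shared) and
weighted `w_{j,p} = (K + 1 − R_{j,p}) / K`. Two fusion rules:

* **Weighted rank-order vote** — one vote per classifier, for its Top-1
  class, with weight `w_{j,1}`;
* **Additive weighted Top-T vote** — `T` votes per classifier; the vote at
  position `p` carries `λ f_p + (1 − λ) w_{j,p}`, where
  `f_p = (T + 1 − p)/T` and `λ` trades position information against
  classifier quality (`λ > 1` allowed, taken literally; swept over
  `0.1 … 5.0`).

Score ties are resolved by the best base classifier's Top-1 indication,
else the output is `None` (counted as an error). Both rules are verified
in the test suite against an independent brute-force scorer, exhaustively
over all small ranking configurations.

## Worked example

Simulate a 10-subject study, train two base classifiers on unloaded gait,
and test on briefcase-carrying gait (scenario B):

```r
library(gaitrank)

cfg <- generator_config(n_subjects = 10, trials_min = 12, trials_max = 12,
                        seed = 42)
study <- build_study(cfg)

configs <- list(
  nearest_centroid = list(architecture = "nearest_centroid"),
  cnn = list(architecture = "cnn",
             config = list(n_blocks = 2, filters = c(16, 32),
                           kernels = c(7, 3), downsample = 32, epochs = 30,
                           patience = 10, lr = 3e-3, batch_size = 64)))

report <- run_scenario("B", study$unloaded, study$loaded, configs, seed = 42)
print(report)
#> <scenario_report> Scenario B
#> base classifiers (Top-1 / Top-5):
#>   nearest_centroid 0.4583  /  0.9083
#>   cnn              0.4000  /  1.0000
#> ensemble:
#>   rank_order   accuracy 0.4583, ties 0
#>   topT         accuracy 0.4667 (lambda* = 1.3), ties 18
```

Reading this: under the load covariate the centroid model keeps 45.8%
Top-1 and the small CNN 40.0% (both with high Top-5 — the right person is
almost always among the top candidates), and the additive Top-T vote at
its swept optimum `λ* = 1.3` edges past the best single model. The 18
ties are samples where fused scores collided and the best base
classifier's Top-1 decided.

Errors concentrate among subjects of similar body mass, because GRF
amplitudes scale with weight:

```r
mg <- mass_confusion_analysis(report$decisions$topT, report$test_labels,
                              study$unloaded$manifest)
print(mg)
#> <mass_gap_analysis> 64 errors (8 None)
#>   median mass gap of confused pairs: 12.29 kg (all pairs: 14.61 kg)
#>   ECDF(4.6 kg) = 0.054
#>   ECDF(11.0 kg) = 0.429
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/gaitrank.R` (`simulate`, `augment`, `evaluate` subcommands).

## Package layout

| Where | What |
|---|---|
| `R/grf-data.R` | cycle/dataset types, stance detection, padding, CSV/RDS I/O |
| `R/synthetic.R` | population generator and study builder |
| `R/augment.R` | jitter, time shift, window crop, mixup, ×9 expansion |
| `R/nn-engine.R`, `R/architectures.R`, `R/classifiers.R` | neural engine, the five templates, fitting/prediction/random search |
| `R/ensemble.R` | rankings, Top-p accuracy, rank/weight tables, both votes, tie rule, λ sweep |
| `R/evaluation.R` | scenarios A/B/C, ablation, mass-gap analysis |
| `vignettes/gait-identification.Rmd` | the model and every design decision, in detail |
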