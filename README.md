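# chasedot

Simulation and mixed-model analysis of the wolf/sheep chase-detection
paradigm used in animacy-perception research.

In this task an observer watches four identical dots move for three seconds
and judges whether one of them (the *wolf*) was chasing another (the
*sheep*). Two dots always move haphazardly (heading resampled within a 120°
window roughly every 170 ms, constant speed 14.5 °/s); the wolf's heading is
confined to a window of half-width *s* — the **chasing subtlety** (15°, 45°
or 75°; 0° would be perfect "heat-seeking") — centred on the bearing to its
sheep. On chase-absent trials the wolf chases a fifth, invisible sheep.
Displays can carry a **social** cue (eyes; the wolf's eyes point at the
sheep) or a **non-social** cue (wolf and sheep share a 3 Hz luminance
modulation, distractors 0.5 Hz). The study this package models compared
matched groups of 24 adolescents with and without ASD on this task.

The package provides:

* **Display generator** — `simulate_trial()`: random-walk distractors, the
  subtlety-constrained wolf, per-frame collision (≥ 1°) and wolf–sheep
  floor (≥ 5°) constraints, reflecting 48 × 30° arena, fully reproducible
  from a trial seed; `eye_track()` / `color_track()` for the cue signals.
* **Experimental design** — `build_design()`: three counterbalanced
  condition blocks per participant, each 6 practice + 75 test trials
  (20 chase-present + 5 chase-absent per subtlety).
* **Synthetic observers** — `simulate_study()` draws trial-by-trial accuracy
  from the random-intercept logistic model
  `logit P(correct) = β₀ + β_G·G + β_A·Age + β_T·Present + β_S·Subtlety +
  β_soc·Social + β_non·Nonsocial + β_GS·G·Subtlety + u`,
  with the published reference estimates as defaults; `pair_scores()` /
  `heuristic_observer_response()` implement trajectory-based, item-by-item
  search observers.
* **Analysis** — `fit_random_intercept_logistic()` (lme4 Laplace fit with
  exact back-transform to raw units, Wald Z tests, 95% CIs),
  `dprime_table()` (d′ with loglinear / half-count corrections for the
  5-absent-trial cells) and `accuracy_summary()` (cell means ± SEM).

## Worked example

```r
library(chasedot)
bundle <- run_pipeline(run_config(n_per_group = 24, seed = 1))
bundle$fit
```

```
<chase_glmm_fit> 10800 obs, 48 participants; sigma_u = 0.832; logLik = -5539.7
           term    estimate          se            z             p p_label
    (Intercept) -0.08190119 1.494905260  -0.05478688  9.563083e-01   0.956
          group -0.25129168 0.259285769  -0.96916882  3.324610e-01   0.332
            age  0.09190808 0.102876649   0.89338139  3.716530e-01   0.372
     trial_type  0.15138372 0.059103926   2.56131422  1.042770e-02   0.010
       subtlety -0.05207072 0.001589489 -32.75940891 2.230330e-235  <0.001
         social  0.69520219 0.057819621  12.02363794  2.669540e-33  <0.001
      nonsocial  0.05929828 0.058194280   1.01897097  3.082167e-01   0.308
 group:subtlety  0.01015640 0.002158247   4.70585903  2.527992e-06  <0.001
```

One synthetic study of 48 participants × 225 trials was generated from the
reference parameters (subtlety −0.05, social 0.66, random-intercept SD 0.8)
and refit: the subtlety slope (−0.052 logits/degree), the social-condition
advantage (0.70 logits) and the intercept SD (0.83) are recovered, the
non-social dummy stays non-significant, and the positive group × subtlety
interaction reproduces the crossover in which the TD group's accuracy
depends more strongly on subtlety than the ASD group's. Cell summaries:

```r
subset(accuracy_summary(bundle$responses), group == "TD" & condition == "baseline")
```

```
 group condition subtlety mean_accuracy sem_accuracy  n
    TD  baseline       15    0.64500000   0.03965887 24
    TD  baseline       45    0.28833333   0.03148307 24
    TD  baseline       75    0.09833333   0.01849076 24
```

Accuracy falls steeply with subtlety, as the generative slope dictates.

Single displays are just as direct:

```r
tr <- simulate_trial(trial_spec("social", subtlety = 15, chase_present = TRUE, seed = 7))
min(dot_distance(tr, tr$wolf, tr$sheep))  # never below 5 degrees
cues <- eye_track(tr)                     # wolf gaze = bearing to sheep
write_trajectory(tr, "trial7.csv")        # long CSV + JSON sidecar
```

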