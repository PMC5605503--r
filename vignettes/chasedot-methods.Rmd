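---
title: "Simulating and analysing chase-detection displays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing chase-detection displays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chasedot)
```

## The paradigm

In the chase-detection task an observer watches four identical dots move for
three seconds and judges whether one of them (the *wolf*) was chasing another
(the *sheep*). Two dots always move haphazardly; the wolf's heading is
confined to an angular window centred on the bearing to its sheep. The
half-width of that window is the *chasing subtlety*: at 0° the wolf is
perfectly "heat-seeking", at 15°/45°/75° (the study values) its pursuit is
increasingly disguised. On chase-absent trials the wolf chases a fifth,
invisible sheep, so the visible display differs from a chase-present trial
only in whether the chased dot can be seen. Two cue conditions decorate the
same motion: a *social* condition in which all dots carry eyes and the wolf's
eyes point at the sheep, and a *non-social* condition in which wolf and sheep
share a 3 Hz luminance modulation while the distractors modulate at 0.5 Hz.

`chasedot` implements the display generator, the within-participant design,
two families of synthetic observers, and the study's statistical analysis —
a random-intercept logistic regression on trial-by-trial accuracy — so the
whole paradigm can be exercised end to end without human data.

## The display generator

`simulate_trial()` advances every dot by `dot_speed / frame_rate` degrees per
frame (defaults 14.5 °/s at 60 Hz, 180 frames for a 3000 ms trial). Headings
are resampled at staggered update events every `direction_update_interval`
(170 ms ≈ 10 frames, a uniformly random per-dot phase avoids lock-stepped
turning): distractors draw uniformly within a 120° window centred on their
own heading; the wolf draws uniformly within ±subtlety of the instantaneous
bearing to its sheep. For its first 170 ms the wolf follows the distractor
rule (the chase is *delayed*, not frozen), which also gives it a less bumpy
entry into pursuit.

Two hard constraints are enforced on every frame, not only at update events:
no two dots may come within `dot_diameter` (1°) of each other, and the
wolf–sheep pair may never come within `wolf_sheep_min_dist` (5°). A dot
whose sampled heading would violate a constraint keeps its previous heading
instead; if that also violates, it steers directly away from the object
whose constraint margin (distance minus threshold) is smallest, and if
several objects violate at once it takes the heading that maximises the
minimum margin over a 3° grid of candidates. Every such replacement is
flagged in the trajectory's `override` log, so analyses of the angular
windows can exclude exactly the frames on which the sampler's draw was not
the realised heading.

Two choices here deserve comment, because the display is under-determined by
its published description:

* **Arena and boundaries.** No arena size or wall behaviour is stated for
  the original display. We use a 48 × 30° rectangle — a 24-inch, 16:10
  monitor at 57 cm — with specular reflection: a step that would exit the
  arena mirrors the offending heading component *before* moving, so every
  realised step has exactly the nominal length. Both are configurable
  (`sim_config()`), including a `resample` boundary mode that redraws a
  random heading at the wall.
* **Bilateral distance floor.** The published rule has the wolf maintain its
  direction when a turn would violate the 5° floor. In a bounded arena that
  one-sided rule is not sufficient: a randomly walking sheep can run down a
  wolf pinned in a corner, and dips of several degrees below the floor
  occur. Because the floor is a property of the generated *pair* of
  trajectories, both members of the pair treat closing below 5° as a
  violation. With this rule a scan of thousands of trials shows no frame
  below 5°.

The wolf's heading is guaranteed to lie inside the subtlety window *at its
update events*, measured against the sheep's position at that instant.
Between updates the sheep keeps moving, so the instantaneous deviation can
drift outside the window; that is a property of any discrete-update pursuit,
not a violation. Consequently the window-width checks in the tests and the
acceptance script measure at update events, excluding overrides.

Each trial is reproducible from the integer seed in its `trial_spec`: one
seeded generator drives the whole trial, with dots updated in a fixed order
(sheep, distractors, wolf last, so the wolf reacts to the sheep's
current-frame position). Per-dot sub-streams would add bookkeeping without
changing any guarantee, so a single stream is used.

## Cue tracks

`eye_track()` gives every visible dot a gaze equal to its own heading; on
chase-present trials the wolf's gaze is replaced by the exact bearing to the
sheep on every frame. On chase-absent trials the wolf, too, gazes along its
heading — if it tracked the invisible sheep, gaze incoherence would betray
trial type; an option restores that behaviour for exploration.

`color_track()` assigns each visible dot a luminance `sin(2π f t + φ)`.
Chase-present: wolf and sheep at 3 Hz, distractors at 0.5 Hz; the
same-frequency pair differs in phase by 0.15 rad, other phases are
independent and uniform. Chase-absent trials would otherwise contain only
one fast dot, so the wolf plus one randomly chosen distractor carry 3 Hz —
counting fast dots cannot solve the task. Luminance is an abstract signal in
[−1, 1]; the mapping to an on-screen colour ramp is out of scope. Note that
a 3 s window gives 1/3 Hz periodogram bins: 3 Hz is an exact bin, 0.5 Hz is
not, which is why `dominant_frequency()` zero-pads before locating peaks.

## Design and generative observers

`build_design()` produces each participant's three condition blocks in a
counterbalanced order (the six permutations of baseline/social/non-social
cycled across participants — the original assignment rule is unstated, and
balanced cycling is the standard choice), each block holding 6 practice
trials followed by 75 test trials: 20 chase-present and 5 chase-absent per
subtlety, shuffled.

`simulate_study()` draws trial-by-trial accuracy from the logistic model

$$\mathrm{logit}\, P(\text{correct}) = \beta_0 + \beta_G G + \beta_A A +
\beta_T T + \beta_S S + \beta_{soc} I_{soc} + \beta_{non} I_{non} +
\beta_{GS} G S + u_i,$$

with group \(G\) (ASD = 1), age \(A\) in years, trial type \(T\)
(chase-present = 1), subtlety \(S\) in degrees, condition dummies against
baseline, and participant intercepts \(u_i \sim N(0, \sigma_u^2)\). The
default fixed effects (−1.13, −0.39, 0.17, 0.23, −0.05, 0.66, 0.15, 0.01)
are the paradigm's published reference estimates; covariates are raw-unit
coded, with the ASD = 1 coding forced by the published direction of the
group-by-subtlety crossover. \(\sigma_u\) is not published; 0.8 logits is a
typical between-participant spread for accuracy data of this kind and is
configurable (recovery checks are run at 0.4 and 0.8). Correctness is
modelled directly — the present/absent response is derived from `correct`
and the trial's true type, exactly as in the trial-by-trial accuracy
analysis — and the quadrant response is bookkeeping only, never analysed.

Cohorts (`sample_cohort()`) use group-specific truncated-normal ages (ASD
14.08 ± 1.47, TD 14.33 ± 1.27, truncated to 12–16.5 years, matching the
study's matched adolescent groups of 24).

The heuristic observers (`chase_statistics()`, `pair_scores()`,
`heuristic_observer_response()`) operationalise the item-by-item visual
search account of the task: for each of the 12 ordered visible pairs they
score heading alignment (mean cosine between candidate-wolf heading and
bearing to candidate sheep), proximity (normalised closing rate) and,
optionally, cue consistency (gaze–bearing agreement, or 3 Hz coherence of
the luminance pair, estimated over three periodogram segments because a
single DFT bin is trivially coherent). The observer responds "present" when
the best pair's weighted score, plus Gaussian decision noise, clears a
criterion. These observers make no claim of fitting human accuracies; they
are used to show qualitative effects (the subtlety ordering, the value of an
informative gaze cue) emerge from the trajectory statistics themselves.

Two properties of the paradigm temper these statistics. First, a
low-subtlety wolf soon reaches the 5° floor and spends much of the trial
with clamped, tangential headings, which attenuates its full-trial heading
alignment. Second, a chase-absent display is not random motion — it
contains a genuine chase of an invisible target — so absent-trial pair
scores also rise as subtlety falls. A single fixed criterion therefore
confounds sensitivity with bias, and the observer checks compare
detectability criterion-free (ROC area, or accuracy at a
per-subtlety-calibrated criterion), where the subtlety ordering is clear.

## The analysis

`fit_random_intercept_logistic()` fits the reference accuracy model with a
participant random intercept by maximising the Laplace-approximated marginal
likelihood (lme4; adaptive Gauss–Hermite via `nAGQ`), and reports Wald Z
tests, two-sided normal p-values (printed as "<0.001" below that threshold)
and ±1.96 SE intervals. Raw covariate units (years, degrees) put the
optimisation badly off-scale, so internally age is centred at 14 and
subtlety scaled by 30; estimates and their covariance are transformed back
exactly, which is a pure reparameterisation — the σ<sub>u</sub> = 0 fit
agrees with ordinary logistic regression to <10⁻³, and relabelling the
groups flips the group effects while leaving fitted probabilities unchanged.
A singular fit (σ̂<sub>u</sub> = 0) is reported as converged with a boundary
estimate; very large standard errors set a `separation` flag.

`dprime_table()` computes per-participant hit and false-alarm rates per
(group, condition, subtlety) cell — by design 20 present and only 5 absent
trials per cell, so extreme rates are common and the correction choice
matters. `loglinear` uses (k + 0.5)/(n + 1); `half_count` replaces 0 and 1
by 1/(2n) and 1 − 1/(2n); `none` leaves extreme cells infinite.
`accuracy_summary()` gives per-cell means over participants with the SEM
(defined as 0 for a single participant).

## Problem sizes and checks

The test suite verifies, among others: exact step length on every frame; the
5° floor and 1° non-overlap over 1500 scanned trials (500 per subtlety);
window containment at update events (≤ 30° span at subtlety 15, ≤ 120° for
distractors); the closed form E[cos θ] = sin(s)/s for the wolf's deviation
at update events; d′ corrections against independently computed normal
quantiles; and parameter recovery — 20 replicate studies of 48 × 225 trials
refit at each σ<sub>u</sub> ∈ {0.4, 0.8}, with mean recovered subtlety and
social coefficients required to sit within two Monte-Carlo standard errors
of the generating values, plus 95% interval coverage within [0.90, 0.99]
over 200 replicates of a 48 × 45 design.

One published pattern needs care: the group-by-subtlety crossover (TD better
at 15°, ASD better at 75°). At the published effect sizes the raw group
difference at a single subtlety has a per-replicate sign probability of
roughly 0.85 — between-participant intercept and age variability do not
cancel between groups — so the crossover is checked as the within-replicate
interaction contrast (the group gap at 15° minus the gap at 75°, in which
intercepts cancel) plus the endpoint signs on the replicate average.

What passing these checks shows is that the generator and the analysis are
faithful to the stated model and display constraints; it does not show that
the generative model captures human strategy (lapses, learning across
blocks, criterion shifts and response bias are all absent), and the
heuristic observers are deliberately simple. Real-data idiosyncrasies —
participant exclusions, practice effects, monitor gamma — have no
counterpart here.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
bundle <- run_pipeline(run_config(n_per_group = 24, seed = 1))
bundle$fit
accuracy_summary(bundle$responses)
```
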