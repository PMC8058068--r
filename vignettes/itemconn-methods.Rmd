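---
title: "Item-series connectivity for slow event-related fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Item-series connectivity for slow event-related fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itemconn)
```

## The problem

Repetition priming — faster, more accurate identification of previously
encountered stimuli — co-occurs with repetition suppression, a reduction of
the neural response to repeated stimuli. Competing mechanistic accounts make
distinct predictions about what else should change with repetition: coupling
between regions (functional and effective connectivity), the spatial overlap
of neural representations, and the latency of the evoked response. Testing
these predictions with BOLD fMRI requires a chain of bespoke computations on
single-trial responses in a slow event-related design. `itemconn` implements
that chain as reusable, tested components, and pairs it with a synthetic-data
generator that plants known effects at every stage, so each component can be
validated by parameter recovery rather than by eyeballing.

The substrate of all connectivity analyses here is the **item series**: for
each voxel (or region), the ordered vector of single-trial peak BOLD
responses, one number per correct trial. Working with trial peaks rather
than full time series removes the shared temporal contour of the evoked
response, which would otherwise dominate any time-series correlation between
task-driven regions.

## Behavioral machinery

Naming trials carry a response time (ms) and a correctness flag. Incorrect
trials and trials slower than 2000 ms are excluded from behavioral summaries
(`filter_trials()`; the boundary is strict, so exactly 2000 ms is kept), and
the slow trials are handed to the GLM stage as error trials because they are
likely to contaminate several volumes.

Item norms (`compute_item_norms()`) average correct first-exposure (NEW)
response times per item across participants, using overt-naming sessions
only (button presses run systematically faster). The **Primeability** median
split (`primeability_split()`) labels the slowest-named half of the items
`Strong` and the fastest half `Weak`; items named slowly when novel show the
largest subsequent priming, so the split is a normative, within-participant
proxy for priming potential. Ties at the median are broken by item id
(deterministic across platforms); with an odd item count the Strong class
takes the extra item. Leave-one-out norms (excluding the analyzed
participant) are available so that item classification is independent of
that participant's data.

Priming magnitude is summarized per participant and Primeability class as
Cohen's *d*: the NEW−OLD mean difference over the Bessel-corrected
two-sample pooled SD (`priming_effect_size()`); the pooled-SD convention is
ours, chosen for testability.

## FIR deconvolution and single-trial extraction

`fit_tent_glm()` estimates the hemodynamic response empirically: one stick
regressor per condition and post-onset lag (8 lags, 0–14 s at TR = 2 s), so
no response shape is assumed, plus a per-run polynomial baseline (default
order 0, as inputs are assumed de-noised; the heavy detrending belongs to
preprocessing, which is out of scope). Error trials form their own
condition of no interest, modeled with the same basis. Onsets must sit on
the TR grid — the slow event-related design guarantees it, and the function
refuses to interpolate. Overlapping responses (trials 8–14 s apart with a
14-s response support) are unmixed exactly by least squares; this is
verified to 1e-8 against forward-generated data.

Three single-trial quantities follow:

* **Peak betas** (`extract_peak_beta()`): the mean of the 4-s and 6-s lag
  betas, i.e. activity 4–8 s post onset, per voxel and condition. The
  1-based "3rd and 4th timepoints" convention counts from lag 0.
* **Item series** (`extract_item_series()`): per correct trial, the mean of
  the GLM *residuals* at onset + 4 s and + 6 s. Because condition means
  were regressed out, item series have exactly zero mean within each
  condition; what remains is the trial-to-trial fluctuation that
  connectivity is computed on.
* **Trial patterns** (`extract_trial_patterns()`): on data prior to
  condition-mean removal, the peak (onset + 4, + 6 s) minus baseline
  (onset − 2–0 s and 0–2 s) voxel pattern per trial, with the per-trial
  baseline patterns retained for the SNR estimator.

## Connectivity

`connectedness()` reduces the all-pairs correlation structure to one value
per voxel: the mean Pearson correlation of its item series with every voxel
in a cohort (the task-responsive voxels, `task_responsive_mask()`), computed
within condition. Self-correlations are excluded (they carry no
information; with them the map would simply be shifted toward 1).
`seed_map()` correlates a seed region's average item series with every
voxel and Fisher-z transforms the result, clipping |r| = 1 at
`atanh(1 - 1e-7)`.

`compute_gcor()` is the global correlation level — the mean of all N²
entries of the voxel-pair correlation matrix, self-pairs included, used as
a per-condition nuisance covariate for residual global artifacts. It is
computed by the identity GCOR = ||mean of the de-meaned, unit-normalized
voxel series||², which the tests verify against the brute-force double loop
to 1e-12.

Spherical ROIs (`sample_sphere_roi()`) collect voxels whose center-to-center
distance (mm, via the grid affine) is at most the radius (inclusive;
default 6 mm), matching the common practice of sampling regions around a
peak statistic.

Group tests of connectedness and seed maps go through the shared LME
(below) with GCOR as covariate. Cluster-size Monte-Carlo correction is not
implemented; FDR is offered instead.

## Structural equation modeling

Effective connectivity among regions is estimated by covariance-based SEM:
for a recursive (acyclic) path structure with coefficients `A` and diagonal
residual variances `Psi`, the implied covariance is
`(I − A)^{-1} Psi (I − A)^{-T}`. `fit_path_model()` minimizes the ML
discrepancy `F = log|Σ(θ)| − log|S| + tr(S Σ(θ)^{-1}) − p` by quasi-Newton
(BFGS) from two starts: the empty model, and the node-wise regression
solution (each region regressed on its parents using S), which is the exact
ML solution for this model class and makes the polish essentially
instantaneous. Fit statistics follow the classical conventions:
`chi² = (n−1) F`, `df = p(p+1)/2 − free parameters`, and the model AIC
`chi² − 2 df`; any fixed monotone variant of the AIC ranks structures
identically for fixed S and n. Non-convergence is reported in a flag, never
fatal — per-condition cells that fail are excluded and logged, mirroring
how failed parameterizations are handled in practice.

`model_search()` finds a structure for the pooled covariance. *Forest*
growth enumerates all acyclic edge sets up to `max_edges` and ranks them by
AIC — exhaustive, feasible only for small networks, and guarded against
combinatorial explosion. *Tree* growth is greedy: starting from the
edgeless model it repeatedly adds the single acyclicity-preserving edge
that most improves the AIC; we follow growth with a backward-pruning sweep
(dropping edges made redundant by later additions) and an orientation
polish (reversing an edge, at equal AIC, when re-pruning then strictly
improves). The exact historical search algorithms are not published; ours
is a documented reconstruction, and the tree remains a heuristic — on a
minority of exact-covariance instances it still ends above the true
structure's AIC, which is why the forest is the reference. Note also that
distinct edge orientations can be Markov-equivalent (identical fit and
AIC); "recovering the structure" therefore means attaining the optimal AIC,
not matching arrows one-for-one.

`fit_per_condition()` parameterizes a fixed structure on each
participant × condition cell, using correlation matrices of the region item
series by default (the functional-connectivity scale; covariance is a
switch), with a minimum of 10 trials per cell.

## MVPA similarity and the SNR adjustment

`spatial_similarity()` correlates every unordered pair of same-condition
trial patterns across voxels and keeps the median (robust to skew);
self-pairs are excluded since their r ≡ 1 would only bias the median
upward. Measurement noise attenuates these correlations, and conditions
with weaker responses (repetition suppression!) have lower SNR — so a lower
OLD similarity may be pure attenuation rather than sharper representations.

`estimate_snr()` implements the four-step trialwise variance-ratio
estimator: signal variance = variance across voxels of the trial's
peak-minus-baseline pattern; noise variance = variance of the difference of
two randomly drawn baseline patterns; their ratio per trial; median over
trials. Because the trial pattern carries its own noise, the estimate is an
upper bound on the true signal-to-noise ratio — for the generator's
construction the bias is exactly +1, and `pattern_set()` reports both the
noise-free ratio (`snr_signal`) and the value the estimator targets
(`snr_expected`). The baseline pairing is seeded and the seed recorded.

`adjusted_similarity_test()` fits the factorial LME to the median
correlations twice — without and with the mean peak amplitude and the SNR
estimate as covariates. The linear covariate adjustment can only remove an
attenuation effect that is approximately linear in the covariates over the
observed range; with extreme SNR contrasts a residual repetition effect can
survive adjustment even when no true pattern change exists. The validation
scenarios are configured accordingly: the attenuation scenario plants a
0.6× OLD amplitude (the ~40% suppression regime), participant-level true
overlap varying uniformly in [0.35, 0.65] (people genuinely differ), and a
narrow within-participant noise band, under which adjustment nulls the
repetition effect in the clear majority of replicates; the sharpening
scenario lowers the true overlap for OLD Strong items at matched amplitude,
and that effect survives adjustment in every replicate.

## Gamma-variate response timing

`gamma_variate()` evaluates `h(t) = h0 + a · t^b · e^{−t/c}`; the response
peaks at `t_peak = b · c` (`peak_time()`), where the derivative vanishes.
`fit_hrf()` least-squares fits the four parameters to the FIR betas in two
stages: a coarse grid over log-spaced `b ∈ [0.5, 8]`, `c ∈ [0.25, 6]` s
(16 × 16), with the linear parameters `h0`, `a` profiled out exactly at
each grid point; then gradient descent with backtracking line search from
the best grid point, capped at 300 iterations or a relative SSE change
below 1e-10, with the linear parameters re-solved exactly after each step.
Fitting is done on unit-scaled data, which makes the result exactly
equivariant under rescaling the betas (`b`, `c`, `t_peak` unchanged; `h0`,
`a` scale). Flat inputs yield a flagged degenerate fit (`a ≈ 0`). With 8
samples and realistic noise the ML estimate of `t_peak` itself has
appreciable spread — our fitter matches an independent Levenberg–Marquardt
fit to the same optimum — so timing contrasts are run at the group level:
`peak_time_contrasts()` feeds the fitted peak times into the factorial LME
per region and FDR-corrects the Repetition and Repetition × Primeability
terms across regions.

## Group inference

`fit_lme()` fits `dv ~ Task * Repetition * Primeability (+ covariates) +
(1 | participant)` with sum-to-zero contrasts, reporting per-term F tests
with Satterthwaite denominator degrees of freedom (on balanced one-value-
per-cell data these agree exactly with classical repeated-measures ANOVA,
which the tests verify). When the mixed model cannot be estimated — e.g.
zero residual variance in noise-free recovery tests — it degrades to the
fixed-effects model with exact type-III F tests and flags the fallback.
Adjusted condition means are predictions at covariate means, averaged over
tasks. `fdr_bh()` wraps Benjamini–Hochberg step-up control;
`condition_contrasts()` runs the follow-up paired OLD/NEW contrasts within
Primeability classes, FDR-corrected within that family;
`brain_behavior_cor()` provides plain and partial Pearson correlations
(partialling by residualization) for across-participant brain–behavior
relationships. The familywise split of alpha across the two primary test
families (main effect and interaction) is a policy argument, not hard-wired.

## The synthetic-data generator

`sim_config()` fixes the study conditions: 200 items (100 OLD / 100 NEW per
participant, assignment counterbalanced by seeded permutation, stratified
within Primeability class so the four cells stay balanced), 5 runs of 40
trials, TR 2 s, trial lengths jittered over 8/10/12/14 s, 30 + 30
participants across overt and covert tasks, 5% planted errors and 2%
over-2000-ms responses to exercise the filtering paths.

Behaviorally (`simulate_behavior()`), item baseline NEW naming times are
drawn around 900 ms (SD 120 ms) and each item's expected priming benefit
is `80 + 0.35 · (baseline − 900)` ms with 20 ms of scatter — the
benefit-grows-with-baseline structure that motivates the median split. The
scatter SD is a free parameter because real data constrain it only loosely.
Participant and trial variability (60 and 110 ms SD) are typical of overt
naming; covert button presses are shifted 250 ms faster.

For imaging (`simulate_bold()`), each voxel's series is a sum over trials
of amplitude × gamma-variate kernel (region- and condition-specific peak
latency; kernel truncated at 14 s so the FIR window spans the response
exactly — the truncation discards the last ~15% tail of the kernel, a
deliberate trade for exact identifiability), plus a global nuisance signal
shared by all voxels (so GCOR has variance to explain) and white noise.
Critically, coupling acts on *latent per-trial amplitudes*, propagated
along a directed graph as `z = (I − A)^{-1} ε` with condition-dependent
weights — because trial-peak connectivity measures exactly that quantity,
not time-series mixing. The default network plants the headline structure:
the temporoparietal → cingulate edge couples at 0.8 for OLD Strong items
versus 0.3–0.4 elsewhere, and the four suppression regions respond at
0.5–0.6× amplitude to OLD items, with the left fusiform (and left frontal)
peaking 0.6 (0.4) s earlier for OLD. `simulate_item_series()` generates the
same latent structure directly at the region level for group-scale studies
where voxel time series would be wasted effort.

What the generator does **not** emulate: spatial autocorrelation and
smoothness, physiological noise spectra, motion, scanner drift, nonlinear
HRF saturation, and any preprocessing imperfection — inputs are "already
de-noised" by construction. Passing tests therefore demonstrate that the
*computations* are correct and well-calibrated under the stated statistical
structure, not that the pipeline is robust to real-data artifacts.

## Problem sizes and determinism

All validation runs on one CPU in minutes: oracle equivalence on 5–20
voxels × 20–100 trials; SEM round-trips and forest searches on 3–5-node
networks (20 instances); chi-square calibration at n = 500 over 500
replicates; HRF recovery over 200 replicates; group power and null
calibration at 60 simulated participants over 25 and 250 replicate studies;
MVPA scenarios over 20 seeded replicates of 60 participants. Every source
of randomness flows through explicit seeds; a fixed configuration and seed
reproduce outputs byte-identically, and generator functions restore the
caller's RNG state.

## Known limitations

* Only recursive SEMs with diagonal residual covariance are supported; no
  latent variables, mean structure, reciprocal edges or multi-group
  constraints. Markov-equivalent structures are not distinguishable from
  covariance data.
* The tree search is a reconstruction and remains a heuristic; use the
  forest where feasible.
* The SNR estimator is an upper bound by construction; the covariate
  adjustment using it is linear and therefore approximate.
* The LME uses a random intercept only (no random slopes), matching the
  target analyses but assuming compound symmetry.
* Voxel grids are small rectangular blocks per region; no whole-brain
  geometry beyond what sphere sampling and NIfTI round-trips require.
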