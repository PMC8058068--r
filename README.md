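# itemconn

Single-trial "item series" connectivity and repetition-priming analysis for
slow event-related fMRI, in R.

When people name a pictured object they have seen before, they are faster
(repetition priming) while their neural responses shrink (repetition
suppression). Competing accounts of this pair of effects make different
predictions about inter-regional coupling, representational overlap, and
response timing. Testing them requires a chain of computations on
single-trial BOLD responses: an FIR ("TENT") deconvolution GLM, extraction
of per-trial peak responses ("item series"), whole-brain connectedness and
seed maps with a GCOR artifact covariate, covariance-based structural
equation modeling (SEM) with AIC-guided structure search, multi-voxel
pattern similarity with a trialwise signal-to-noise adjustment,
gamma-variate hemodynamic response fitting, and linear mixed-effects
inference with FDR correction — plus the behavioral machinery
(2000-ms trial filtering, item norms, the "Primeability" median split, and
Cohen's *d* priming effect sizes).

`itemconn` implements that whole chain for researchers who analyze slow
event-related designs (or who want to study these estimators), and pairs it
with a synthetic-data generator that plants known ground truth at every
stage, so every component is validated by parameter recovery.

## The core quantities

* **Item series**: for voxel *v*, the vector over correct trials of the
  mean GLM residual at onset + 4 s and + 6 s — the single-trial peak
  response with condition means removed. All trial-level connectivity is
  computed on these.
* **Connectedness**: mean Pearson correlation of a voxel's item series with
  all task-responsive voxels (per condition).
* **SEM**: for a recursive path structure with coefficients *A* and
  residual variances Ψ, the implied covariance is
  Σ(θ) = (I − A)⁻¹ Ψ (I − A)⁻ᵀ; fitting minimizes
  F = log|Σ| − log|S| + tr(S Σ⁻¹) − p, with χ² = (n−1)F and model AIC
  χ² − 2·df used to search structures.
* **HRF timing**: h(t) = h₀ + a·t^b·e^(−t/c), whose peak falls at
  t_peak = b·c; fitted by a coarse grid plus gradient descent (≤ 300
  iterations).
* **SNR adjustment**: per trial, var(peak-minus-baseline pattern) over
  var(difference of two random baseline patterns); the median over trials
  covaries out correlation attenuation in MVPA comparisons.

## Worked example

```r
library(itemconn)

cfg <- sim_config(n_participants_per_task = c(overt = 8, covert = 8), seed = 7)

## behavior: filter, norms, Primeability, priming effect sizes
beh  <- simulate_behavior(cfg)
keep <- filter_trials(beh$trials)
keep$log
#> incorrect       slow missing_rt
#>       306        131          0
norms <- primeability_split(compute_item_norms(keep$trials))
cor(norms$mean_new_rt, norms$mean_priming, use = "complete.obs")
#> [1] 0.647          # slower-named-when-NEW items prime more
dtab <- priming_by_primeability(beh$trials, norms)
tapply(dtab$d, dtab$primeability, mean, na.rm = TRUE)
#>    all Strong   Weak
#>  0.503  0.779  0.362  # Cohen's d, larger for Strong Primeable items

## imaging: FIR GLM, peak betas, item series
sim <- simulate_bold(cfg, participant = 1)
fit <- fit_tent_glm(sim$runs, sim$events, tr = sim$tr)
fit
#> FIR deconvolution fit: 189 voxels, 5 conditions x 8 lags (0-14 s), 1135 TRs
pk <- extract_peak_beta(fit)
acc <- which(sim$voxel_map$region == "ACC")[1]
round(pk[acc, c("NEW_Strong", "OLD_Strong")], 3)
#> NEW_Strong OLD_Strong
#>      1.071      0.439   # ~60% repetition suppression + trial noise
isr <- extract_item_series(fit)
isr
#> Item series: 189 voxels x 189 trials (NEW_Strong=44, NEW_Weak=48,
#>   OLD_Strong=48, OLD_Weak=49)

## connectivity and effective connectivity at the region level
st <- simulate_item_series(cfg, 16)
pp <- st$participants[[1]]
sel <- pp$condition == "OLD_Strong" & pp$correct == 1
connectedness(pp$series[, sel])      # per-region mean coupling
compute_gcor(pp$series[, sel])
#> [1] 0.197
region_names <- vapply(cfg$region_spec, `[[`, "", "name")
edges <- cbind(match(cfg$coupling_spec$from, region_names),
               match(cfg$coupling_spec$to, region_names))
fit_path_model(cor(t(pp$series[, sel])), sum(sel), edges)
#> Recursive SEM fit: 7 regions, 3 edges | F_ML = 0.326, chi2(18) = 15.3, AIC = -20.7
#>   rTP -> ACC : 0.6103      # planted OLD_Strong coupling 0.8, one participant
#>   ACC -> rFus : 0.3142
#>   rSTG -> rTP : 0.3229

## hemodynamic response timing
y <- gamma_variate(seq(0, 14, 2), 0.1, 0.05, 2.5, 4.4 / 2.5)
fit_hrf(y)
#> Gamma-variate fit: h0=0.1 a=0.05 b=2.5 c=1.76 | t_peak=4.400 s, SSE=7.48e-13
```

The numbers above were produced by running exactly this code. The
`rTP -> ACC` coefficient estimates the planted latent coupling for
OLD-Strong trials from one simulated participant's 48 trials; group-level
analyses (`fit_per_condition()` + `fit_lme()`) recover the planted
Repetition × Primeability interaction with essentially full power at 60
participants.

See `vignettes/itemconn-methods.Rmd` for the models, assumptions, default
parameters and their rationale, and known limitations.

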