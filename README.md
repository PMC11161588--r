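# attnconn

Background connectivity and dynamic causal modeling of the attentional
spotlight in retinotopic visual cortex.

## What it does

When spatial attention is focused on a small target, processing is
enhanced at the attended location and suppressed in the surrounding
visual field. `attnconn` implements, end to end, an fMRI analysis chain
that measures this center–surround signature in **background
connectivity** — Pearson correlations between residual BOLD fluctuations
of V1 vertices and downstream areas (V2–V4), computed after removing
nuisance signals and the stimulus-evoked response with an FIR model —

```
r(v, area | condition) ,   z = atanh(r) averaged over runs,
profile(bin) = mean z over vertices at eccentricity bin ∈ {stim, 4–6°, 6–8°, 8–10°}
```

and then localizes the attentional modulation with a **bilinear DCM**

```
dz/dt = (A + u₂B) z + C u₁,     y = balloon(z)
```

comparing feedforward, feedback and recurrent placements of the
modulation B by random-effects Bayesian model selection (exceedance
probabilities from a Dirichlet-multinomial hierarchy over variational
free energies). A moment-based estimator of the stimulus-field center
E(x) = Σ xᵢ p(xᵢ) and size 2·Sd(x) over eccentricity provides an
eye-movement control.

Because no public dataset accompanies this design, the package includes a
first-class synthetic cohort generator (block design: 12 s stimulus /
12 s fixation, TR = 1 s, 8 runs per attention condition, plus localizer
runs) with a latent background-coupling field whose eccentricity gradient
differs between attention conditions, and ground truth stored for every
latent quantity. All statistical machinery — FIR and nuisance GLMs,
eccentricity-binned ROI definition, repeated-measures ANOVA, paired t
tests with Benjamini–Hochberg FDR, variational-Laplace DCM inversion,
RFX model selection — is exercised against that ground truth.

Intended users: researchers who want a reproducible, fully synthetic
testbed for attention/connectivity analyses, or a desk-scale, readable
reference implementation of background connectivity + DCM model
comparison.

## Worked example

```r
library(attnconn)

cohort  <- make_cohort(8, "weak_crowding", seed = 7, n_vertices = 240)
profiles <- cohort_profiles(cohort)      # residualize -> ROIs -> binned z
st <- profile_group_stats(profiles)
subset(st$anova, effect == "bin:condition")
#>         effect statistic df1 df2         p area
#>  bin:condition     32.69   3  21 4.243e-08   V2
#>  bin:condition     21.99   3  21 1.106e-06   V3
#>  bin:condition     29.71   3  21 9.557e-08   V4
subset(st$contrasts, area == "V4")[, c("bin", "statistic", "p", "mean_diff")]
#>   bin statistic         p mean_diff
#>  stim    2.8056 2.631e-02   0.02143
#>   4-6   -7.4764 1.401e-04  -0.03635
#>   6-8   -9.3623 3.298e-05  -0.04172
#>  8-10   -0.7849 4.583e-01  -0.00566
```

The visual-field × attention interaction is significant in every area,
and the focal − diffused contrast is positive at the stimulated bin,
negative at 4–6° and 6–8°, and near zero at 8–10° — the center-enhancement
/ surround-suppression gradient the generator encodes.

The DCM arm (three-node preset: stimulated V1, non-stimulated V1, one
extrastriate node):

```r
sim <- simulate_dcm_cohort(8, "recurrent", seed = 7)   # truth: recurrent
res <- dcm_cohort_analysis(sim$Y)                      # fits 3 models/subject
res$bms          # exceedance probabilities; recurrent wins
res$modulation   # V1_S vs V1_NS pathway contrasts, FDR-adjusted
```

Stimulus-field control:

```r
field <- do.call(rbind, lapply(cohort, estimate_field))
aggregate(cbind(center_deg, size_deg) ~ condition, field, mean)
#>   condition center_deg size_deg
#> 1  diffused      2.691    2.170
#> 2     focal      2.611    1.889
compare_fields(field)   # centers near the 2.5 deg stimulus; no condition difference
```

A single-call driver with TSV/report output:

```r
run_pipeline(list(scenario = "weak_crowding", n_subjects = 8, seed = 7,
                  out_dir = "out"))
```

and a thin CLI at `inst/cli/attnconn.R`
(`Rscript attnconn.R simulate|run ...`).

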