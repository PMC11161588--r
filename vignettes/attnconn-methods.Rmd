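---
title: "Methods: background connectivity and DCM of the attentional spotlight"
author: "attnconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: background connectivity and DCM of the attentional spotlight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Focal spatial attention is thought to act like a zoom lens: processing is
enhanced at the attended location and suppressed in a surrounding annulus.
`attnconn` implements an analysis chain that looks for this signature not in
evoked response amplitudes but in *background connectivity* — the
correlation between residual BOLD fluctuations of retinotopic V1 locations
and downstream visual areas (V2–V4) after stimulus-evoked responses and
nuisance signals have been removed — and then asks, with dynamic causal
modeling (DCM), whether the attentional modulation sits on feedforward,
feedback, or recurrent cortico-cortical connections. A third, independent
check estimates the center and size of the stimulus/attention field from
the spatial distribution of evoked responses over eccentricity, as an
eye-movement control.

Because no public dataset accompanies this design, the package ships a
synthetic-data generator that reproduces the statistical structure the
analysis assumes, with ground truth recorded for every latent quantity.
All claims the test suite makes are claims about recovery of known ground
truth from data generated under the package's own assumptions — they are
evidence of the pipeline's internal correctness, not of any property of
real cortex.

# The synthetic cohort

A subject is a set of runs of a block design: 12 s stimulus blocks
alternating with 12 s fixation at TR = 1 s, ten cycles per run, eight runs
per attention condition (focal, diffused), plus two localizer runs
reserved for region-of-interest definition. Vertex geometry covers
eccentricities 0–12° with stratified-uniform sampling in 2° strata. Polar
angles are sampled with a fixed fraction (25%) inside the ±10° window
around the horizontal meridian that the ROI rule uses; a fully uniform
polar distribution would put only ~6% of vertices in that window and leave
the peripheral bins empty at the few hundred vertices a desk-scale
simulation affords. The stimulated zone is a 1.5°-radius disc centered at
2.5° eccentricity on the horizontal meridian (a central element plus a
ring of flankers at 0.75° spacing).

Per run, each vertex's series is

    bold(v, t) = evoked(v, t) + gain(bin(v), condition) * g(t)
                 + sum_k w_k(v) * nuisance_k(t) + noise(v, t)

* `evoked` is the steady-state response to the ongoing periodic block
  design: the stimulus boxcar circularly convolved with a double-gamma HRF
  (peak 6 s, undershoot 16 s), nonzero only for vertices inside the
  stimulated disc. Using the steady-state (periodic) shape rather than an
  onset-transient convolution makes the evoked component exactly
  cycle-locked, which is what an FIR basis models.
* `g(t)` is **one shared latent fluctuation per run** — temporally filtered
  white noise with all power below 0.1 Hz (the cutoff is a configuration
  knob; resting-state BOLD coherence concentrates below this band). It is
  injected into every downstream area with unit gain and into V1 vertices
  with a gain that depends on the vertex's eccentricity bin and the
  attention condition. This single-latent structure is deliberately the
  simplest mechanism that produces graded bin-level connectivity profiles;
  the analysis only measures connectivity strength, not its mechanism.
* The nuisance space is six motion-like smoothed random walks plus two
  slow sinusoids (white-matter and ventricle surrogates), with weights
  drawn once per vertex from N(0, 0.25).
* `noise` is iid Gaussian per vertex with standard deviation
  `sd(signal)/snr`, so the signal-to-noise *variance* ratio is `snr^2`
  exactly. The default snr = 1.

The scenario profiles fix the per-bin gains. `weak_crowding` encodes
center enhancement with surround suppression under focal attention (stim
0.60, 4–6° 0.15, 6–8° 0.15, 8–10° 0.30) against a flat diffused profile
(0.35 everywhere). `strong_crowding` uses a single graded profile for both
conditions — the attention contrast is zero by construction while the
eccentricity main effect survives. `null` is flat in both conditions.
These generator defaults are study conditions, fixed once; tests never
tune them.

What the generator does **not** emulate: spatial autocorrelation between
neighboring vertices beyond the shared latent, physiological (cardiac,
respiratory) noise structure, inter-subject variability in HRF shape or in
the coupling profile, scanner drifts beyond what the nuisance space spans,
and any vertex-level structure within downstream areas (V2–V4 enter as
single aggregate series). Passing tests therefore demonstrate correct
recovery under these idealizations, nothing more.

# Residualization

Per run, in sequence: (1) high-pass filtering by projection onto the
complement of a discrete-cosine basis (all DCT regressors with period
longer than the cutoff; default 100 s, the common convention when the
acquisition high-pass is unspecified); (2) an OLS nuisance GLM removing
the eight nuisance series plus intercept; (3) optionally, removal of the
evoked response with a finite-impulse-response (FIR) basis of 24 indicator
regressors, one per TR position in the 24 s block+fixation cycle. Because
the FIR columns are orthogonal indicators, the fitted evoked response per
vertex is exactly the mean cycle-phase pattern, so any deterministic
cycle-locked signal is annihilated to machine precision and the procedure
is idempotent.

The three steps are fit sequentially, matching the narrated order of the
emulated procedure, not as one joint GLM (a joint fit is available by
combining the regressors manually; sequential and joint OLS differ when
regressor groups correlate). A consequence worth knowing: the FIR
subtraction can reintroduce small components along the nuisance
directions, so exact orthogonality of the final residuals holds for the
last-applied basis only. DCT projection is likewise a projection, not a
brick-wall filter: components on the DCT grid are passed or removed
exactly, off-grid sinusoids show a few percent spectral leakage.

# ROIs and connectivity profiles

The stimulated V1 region is defined statistically: a stimulus > fixation
GLM (boxcar convolved with the HRF) on the two localizer runs, pooled by
fixed-effects inverse-variance combination, thresholded at one-sided
p < 0.01 (uncorrected, as is conventional for localizers). Peripheral bins
are defined by geometry alone: vertices within ±10° of the horizontal
meridian, binned at 4–6°, 6–8°, 8–10° eccentricity. Bins are half-open
[lo, hi), the last closed at 10°; the localizer criterion overrides the
geometric bins. Main-run data never touch ROI definition, avoiding
selection bias in the connectivity estimates.

Background connectivity is the Pearson correlation between each V1
vertex's residuals and each downstream area's residual series, computed
per run, Fisher z-transformed (with correlations clipped at
±(1 − 1e−12)), and averaged over runs of the same condition; averaging z
per run is robust to run-level offsets, and a concatenated-correlation
variant is available. Profiles are mean z per ROI bin. Group inference
uses the classical two-way within-subject ANOVA (visual field ×
attention), each effect tested against its own subject-interaction error
stratum with no sphericity correction (the convention this package
follows; the output flags this), paired t tests per bin, and
Benjamini–Hochberg FDR across the per-bin family.

# The DCM engine

The neuronal model is the standard bilinear form

    dz/dt = (A + u2 * B) z + C u

with `u1` the stimulus boxcar driving the stimulated V1 node only and `u2`
the attention input: 1 during stimulus blocks of focal runs, 0 elsewhere
(a mean-centered variant is a configuration option; with this coding, B is
referenced to the diffused state). Hemodynamics follow the balloon model
per node (vasodilatory signal, flow, venous volume, deoxyhemoglobin;
κ = 0.65 s⁻¹ and transit time τ = 0.98 s free on a log scale with tight
priors, γ = 0.41 s⁻¹, α = 0.32, E₀ = 0.34, V₀ = 0.04 fixed), with BOLD
output in percent-signal units. Integration uses a fixed step of TR/16,
classical RK4, with flow, volume and deoxyhemoglobin propagated in log
space for positivity; runs are integrated independently from rest and
run means are removed, mirroring run-wise confound regressors.

The three candidate structures share the intrinsic mask (bidirectional
V1_S/V1_NS ↔ extrastriate connections, the lateral V1 pair, self
connections; no extrastriate–extrastriate links) and the driving mask, and
differ only in which directions `u2` modulates: feedforward (V1 →
extrastriate), feedback (extrastriate → V1), or recurrent (both); all
three include the lateral within-V1 modulation. Since the emulated report
names five regions but speaks of four nodes, the engine is N-node generic:
the five-node configuration is the default and a three-node preset (V1_S,
V1_NS, one extrastriate node) keeps simulation studies desk-scale.

Priors (standard DCM conventions; the emulated design does not state
them): off-diagonal A and B ~ N(0, 1/16) Hz, self connections
−0.5·exp(θ) with θ ~ N(0, 1/256), C ~ N(0, 1), log hemodynamic scales
~ N(0, 0.01). Inversion is variational Laplace: iterated Gauss–Newton
ascent on the free energy F = expected log-likelihood − KL(posterior ‖
prior), with central finite-difference sensitivities (step 1e−4), per-node
noise precisions re-estimated by an E/M alternation at every step, and
Levenberg–Marquardt trust-region damping. A step is accepted only if it
improves the best F seen, so F is non-decreasing over accepted steps;
convergence is declared after three successive improvements below 0.01
nat (cap 64–128 iterations). Unstable proposals (any eigenvalue of A with
positive real part, or integrator divergence) are rejected inside the
line search. Like all Laplace schemes this one can settle in local
optima. Two numerical choices in the cohort-level driver address this and
the cost: inversion integrates on a TR/8 grid (simulation stays at TR/16;
the integration error, around 1e−6, is orders of magnitude below the
observation noise and identical across candidate models), and a model
whose modulatory mask nests another candidate's is warm-started from the
best nested fit whenever its cold start lands below it — a recurrent
model must reach at least the feedback optimum it contains, and the warm
start makes the ascent find it.

Random-effects Bayesian model selection treats the generating model as
varying across subjects: a variational Dirichlet-multinomial scheme
(prior concentration 1) alternates subject-wise model weights
∝ exp(F + digamma terms) with the concentration update, and exceedance
probabilities — the posterior probability that each model is the most
frequent in the population — are computed by seeded Monte Carlo from the
Dirichlet posterior (default 10⁶ draws).

Group statistics on the winning structure compare the modulatory
parameters of the V1_S pathway against the V1_NS pathway (paired t per
area and direction), test each against zero, run the visual-field ×
cortical-area repeated-measures ANOVA when more than one extrastriate
node is modeled, and adjust the t-test family by Benjamini–Hochberg.

## Generating values for DCM simulation studies

The simulation default couples the hierarchy asymmetrically: intrinsic
feedforward 0.4 Hz, feedback 0.1 Hz, lateral 0.1 Hz, driving gain 0.8,
modulation +0.3 Hz on V1_S pathways and −0.2 Hz on V1_NS pathways, with
observation noise at snr 2. The asymmetry keeps the system comfortably
stable (slowest eigenvalue about −0.16 s⁻¹) while making extrastriate
activity vigorous enough that feedback modulation is identifiable — with
weak symmetric coupling the feedback direction is nearly collinear with
the feedforward one in BOLD, and no model comparison can separate
directions the data do not distinguish. DCM simulation studies use the
three-node preset and two runs per condition (960 volumes); this is a
computational scaling of the full eight-runs-per-condition session and is
the problem size at which the packaged studies and their runtimes are
calibrated.

# Stimulus-field estimation

Per condition, a stimulus-vs-fixation GLM beta is computed for every
vertex on nuisance-regressed, evoked-retained main runs, pooled across
runs by fixed effects, and averaged within 1°-wide eccentricity bins from
0–10° (bin width is not dictated by the emulated design; 1° matches the
geometry's resolution). Truncation of negative responses happens after
within-bin averaging and before normalization to a unit-sum distribution
p. The field center is E(x) = Σ xᵢ p(xᵢ) and the field size is twice the
probability-weighted standard deviation. Moments of a discretized,
truncated density are compared against fine-grid quadrature in the tests;
with 1° bins the center is accurate to about half a bin.

# Numerical and design choices

* Correlations are clipped before atanh; undefined correlations
  (zero-variance series) become missing values and are excluded from bin
  means with a warning.
* Eccentricity-bin tie rule: half-open bins, final bin closed.
* The degenerate ANOVA case (effect sum of squares at machine zero) is
  reported as F = 0, p = 1; a zero *error* stratum with a non-zero effect
  is an error, since no valid test exists.
* Paired/one-sample t tests with exactly zero-variance differences return
  t = 0, p = 1 when the mean difference is also zero, and fail otherwise.
* The canonical on-disk format is a plain-text dataset directory (TSV
  matrices, JSON attributes) that round-trips to full double precision;
  volumetric NIfTI import is provided for real data, surface formats are
  out of scope.
* Problem sizes in the packaged studies: connectivity cohorts use 8
  subjects with 240 vertices (120–160 for repeated calibration batches);
  these vertex counts are scaled relative to real cortical meshes, and the
  per-bin vertex counts (roughly 5–20 in the meridian window) are the
  quantity that matters for profile stability.

# Known limitations

* The generator's single shared latent makes all same-bin vertices
  exchangeable; it cannot express distance-dependent connectivity within a
  bin.
* The localizer t test assumes white residuals; vertices carrying the
  autocorrelated latent background have mildly inflated localizer
  statistics, as they would in real data without prewhitening. The
  stimulated-region definition is statistical and inherits this. Because
  those false selections share one latent source, they are correlated
  within a subject: at small vertex counts a run of localizer luck can
  occasionally absorb an entire peripheral bin into the stimulated ROI,
  which the ROI stage reports as an error (simulation studies replace
  such cohorts deterministically).
* Variational Laplace reaches local optima; model discrimination at low
  snr relies on the random-effects aggregation across subjects.
* The five-node DCM at full session length is computationally heavy
  (minutes per subject); the three-node preset is the supported scale for
  simulation studies.
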