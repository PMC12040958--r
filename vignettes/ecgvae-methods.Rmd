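---
title: "Conditional 12-lead ECG generation and latent-space cardiovascular risk: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional 12-lead ECG generation and latent-space cardiovascular risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`ecgvae` models the relationship between cardiac anatomy and 12-lead ECG
morphology, and uses it for two tasks: generating subject-specific median
beats conditioned on heart pose, electrode placement and demographics, and
ranking subjects by future cardiovascular risk from the latent representation
of their beats. Because real biobank-scale ECG/MRI data cannot be
redistributed, the package ships a dipole volume-conductor simulator that
produces pose- and electrode-dependent beats with proportional-hazards
outcomes; every quantitative claim made by the test suite is a claim about
cohorts from this simulator.

# Geometry

A cardiac MRI study determines three imaging planes: a mid short-axis (SAX)
plane and the 2-chamber and 4-chamber long-axis views. Each plane is stored
as a unit normal and a point, $n \cdot (X - P) = 0$. The heart center is the
unique intersection of the three planes, obtained by solving the stacked
$3 \times 3$ linear system; triples whose normal matrix has condition number
above $10^8$ are rejected as degenerate (parallel or duplicated views), a
threshold chosen so that mm-scale coordinates in double precision still leave
~8 significant digits.

The heart-local frame sets $e_X$ along the SAX/4CH intersection line
($e_X = n_{SAX} \times n_{4CH}$, normalized), $e_Z$ as the 4CH normal with
its $e_X$-component projected out, and completes the triad with
$e_Y = e_Z \times e_X$. The cross-product order is a deliberate
sign-convention choice: it makes $(e_X, e_Y, e_Z)$ right-handed
($\det[e_X\,e_Y\,e_Z] = +1$), which the alternative order
$e_X \times e_Z$ would violate. Orientation is summarized by three
projection angles in degrees,
$\alpha = \arccos(e_X \cdot \hat{x})$,
$\beta = -\arccos(e_Z \cdot \hat{z})$,
$\gamma = -\arccos(e_X \cdot N)$ with $N = \hat{z}$ the normal of the
anatomical XOY plane. These are *not* a rotation decomposition: each arccos
discards the sign of the rotation component it measures, a limitation that
matters for conditioning (below). Arccos arguments are clamped to
$[-1, 1]$ to absorb rounding.

Electrode coordinates are expressed in the heart frame by the rigid map
$p \mapsto ((p - P_{heart}) \cdot e_X, \ldots)$, so each subject's electrode
cloud carries heart position, orientation and torso habitus in one
30-dimensional vector (fixed flattening order RA, LA, RL, LL, V1–V6).

# Preprocessing

Raw records are 12×T matrices in the stored "mV/100" amplitude scale (100
units = 1 mV) at 500 Hz. Baseline drift is removed with a linear-phase
Hamming-window FIR band-pass, 3–45 Hz. The tap count is $4 f_s / f_{low}$
rounded up to an odd integer (667 taps at the defaults) so the group delay is
an integer number of samples and can be compensated exactly by an index
shift; the small residual DC gain of the windowed design is nulled by
subtracting the tap mean, which perturbs the 10 Hz passband by under
$3\times10^{-5}$.

Quality control excludes any record whose absolute amplitude exceeds 800 raw
units (8 mV) in any lead; a value exactly at 800 passes ("exceeding" is read
strictly). R peaks are detected on lead II by a squared-derivative energy
envelope (150 ms moving average) whose strict local maxima, separated by at
least 200 ms, are thresholded at 0.3× the 85th-percentile candidate height —
robust both to many sub-QRS candidates (T waves) and to a single dominating
artifact — then refined to the signal maximum within ±75 ms. This detector
is package plumbing: it is deliberately simple and stated in full here
because biobank pipelines use vendor median beats whose detectors are not
public.

The median beat windows each detected beat from 300 ms before to 500 ms
after the R peak (exactly 400 samples at 500 Hz), takes the per-sample
median across beats, and resamples to 400 columns when the rate differs.
The median's 50%-contamination breakdown is what the spike-rejection test
exercises. With the simulator's default observation noise (2 raw units RMS
white noise, 30 units of 0.25 Hz wander on 12 beats per record), the
recovered beat correlates ≈0.990 with the clean-pipeline template — the
residual is the white-noise floor of a 12-beat median, not detector error.

Cohort filtering applies, in order: amplitude QC, exclusion of subjects
missing from the diagnosis table, exclusion of prevalent cases (event date
on or before the ECG date — the boundary day counts as prevalent), then
labels the remainder incident or healthy. Stratified splitting draws
`round(n * test_frac)` subjects per stratum (the seven ICD-10 subtypes plus
healthy); strata smaller than `ceiling(1/test_frac)` stay in training.

# The synthetic cohort generator

Cardiac electrical activity is reduced to a single time-varying current
dipole in an infinite homogeneous conductor (σ = 0.2 S/m): the potential at
an electrode is $\phi = p \cdot r / (4\pi\sigma |r|^3)$. The dipole
trajectory is a sum of five Gaussian deflections per spatial axis (P, Q, R,
S, T at beat fractions 0.15, 0.33, 0.375, 0.42, 0.70), expressed in the
heart frame, so rotating or translating the heart changes every lead in a
physically coherent, monotone way — the ground truth against which
conditional generation is judged. Amplitudes are scaled so precordial R
waves land around 100–150 raw units (1–1.5 mV). Twelve leads derive from
ten electrodes via the Einthoven/Goldberger/Wilson equations; RL is recorded
but serves only as ground. The identities III = II − I and
aVR + aVL + aVF = 0 hold machine-exactly by construction and are enforced in
tests.

What the simulator does *not* model: torso boundary effects (no bounded
conductor), multi-dipole or bidomain electrophysiology, rhythm and beat-to-
beat variability, and pathology-specific morphology. Tests passing on this
simulator therefore demonstrate that the pipeline recovers structure the
generator put in; they do not certify performance on real ECGs.

Populations jitter the pose (rotations uniform ±30° per axis, positions
±30 mm), electrodes (±20 mm, radially clamped to a 0.1–0.4 m shell around
the heart), trajectory amplitudes (log-normal, ~15% overall and 5% per
wave), and demographics (age U(40, 80), sex Bernoulli(0.5), BMI N(27, 4²)
truncated to [16, 45]). Survival times are exponential with rate
$h_0 \exp(\beta^T x_{std})$ over standardized covariates — by default the
noise-free lead-II R amplitude (so risk is genuinely ECG-linked), age and
sex — with uniform censoring whose upper bound is tuned by root-finding to
the requested censoring fraction (default 70%).

# The conditional VAE

The encoder takes a 1×12×400 beat through two convolutional blocks (2-D
convolution, batch normalization, ELU): the first convolves each lead
separately with a length-7 temporal kernel; the second spans all 12 leads
with a length-5 kernel, collapsing the lead dimension. Each block is
followed by average pooling (factor 4 in time). The condition vector is
concatenated to the flattened features before the two fully connected layers
that produce the 64-dimensional posterior mean and log-variance. The decoder
mirrors this: the condition is concatenated to $z$, a dense layer restores
the coarse feature map, nearest-neighbour upsampling and a lead-expanding
deconvolution rebuild the 12-lead structure, and a stride-4 transposed
temporal convolution returns 12×400. Channel widths (8, 16) are sized for
single-CPU training; all architecture hyperparameters live in
`cvae_config()`. Conditions are z-scored over the training set because they
mix mm, degrees and years; the statistics are stored in the model.

Training minimizes reconstruction (mean squared error over all 4,800
entries) plus the closed-form KL divergence of the diagonal Gaussian
posterior from N(0, I), with equal weights, by Adam (learning rate 0.001,
batch 64), all randomness flowing from one seed. The layers are hand-written
(vectorized R with compiled kernels for the convolutions); every backward
pass is validated against finite differences in the test suite, and the
compiled kernels against pure-R reference implementations.

## The signal-scale choice

With the loss weights fixed at 1:1, the objective is not scale-invariant in
the signal units: in raw units (amplitudes ~100) the KL term is negligible,
the posterior drifts far from the prior and decoding $z \sim N(0, I)$ is
out-of-distribution; standardized to unit variance, the KL term dominates
and the posterior collapses onto the prior, leaving the latent empty.
`signal_scale` divides the beats before the loss; the default of 4 (0.04 mV
units) keeps the latent informative — on default cohorts the trained mean KL
sits around 0.3–0.5 nats/subject, comfortably above the 0.1-nat collapse guard — while
reconstructions remain faithful. Generation-oriented experiments (the pose
and electrode sweeps) use scale 8, trading latent information for a tighter
posterior/prior match so that prior samples decode in-distribution. Both
values were fixed from reconstruction/KL diagnostics on default simulator
cohorts and are stated here as the package's study conditions.

## Conditioning parameterizations, and why sweeps use electrodes

A long-axis rotation sweep changes the heart frame but not the position, so
a pose-conditioned model sees it only through $(\alpha, \beta, \gamma)$.
Because these are unsigned projection angles, they are nearly *even* in the
rotation angle around typical poses ($\alpha$ traverses 49°→28°→46° as the
rotation goes −40°→0°→+40°): the conditioning input cannot transmit the
rotation's sign, and the conditional mean beat is correspondingly flat. The
heart-frame electrode coordinates do not have this defect — the 30-vector
rotates rigidly and injectively with the heart — which is why the
directional-fidelity checks condition on electrodes alone. This mirrors the
observation that electrode conditioning improves the consistency of
generated trends, and is a genuine limitation of projection-angle pose
encodings worth knowing about.

# The survival head and joint objective

A single dense layer maps the latent to a scalar passed through a sigmoid,
$r = \sigma(w \cdot z + b) \in (0, 1)$ — the bounded surrogate for the
log-relative hazard; the bound prevents the exponentials in the partial
likelihood from overflowing while preserving risk order. The survival loss
is the negative scaled log partial likelihood
$-\frac{1}{N}\sum_i \delta_i\,(r_i - \log \sum_{j: t_j \ge t_i} e^{r_j})$
computed within each minibatch (so batch composition affects gradients;
batches are reshuffled each epoch under the global seed). The negation is
deliberate: summed as printed, the total objective would reward a poor
survival fit. Ties share the full risk set (Breslow). The total loss is the
unweighted sum of reconstruction, KL and survival terms.

Two head-specific choices: the head reads the posterior *mean* during both
training and evaluation (the gradient is then free of reparameterization
noise, and reported risks are deterministic), and its Adam learning rate is
multiplied by 10 (`risk_lr_mult`) because the sigmoid bounds its gradients
far below the reconstruction path's — without it the head is visibly
undertrained at desk-scale epoch counts.

Evaluation uses Harrell's concordance over comparable pairs
($t_i < t_j$, $\delta_i = 1$; risk ties count ½), Kaplan–Meier curves with
Greenwood log-log 95% bands (via the survival package), and median-risk
stratification with ties assigned to the low-risk group.

# Experiment harness and problem sizes

`run_experiment()` reproduces three designs: E1 — pose-conditioned
generation sweeps (rotation ±40°, translation ±4 cm grids) against the
forward model's per-lead peak-amplitude slopes; E2 — the same with
electrodes as the only condition; E3 — joint training across four
conditioning arms (none, electrodes, sex+age, sex+age+electrodes) on one
shared stratified split, reporting per-arm C-index, group event fractions
and KM tables. Trend agreement is quantified as the sign match of per-lead
regression slopes across the sweep grid, a deliberately coarse statistic
matching the qualitative nature of such comparisons.

Default problem sizes are chosen for a single CPU core: acceptance-scale
cohorts of 2,000 subjects (80/20 split), 20–25 training epochs for risk
models (~6 minutes), 15 epochs for generation models, and smaller cohorts
(100–200 subjects, 1–4 epochs) in unit tests that exercise contracts rather
than asymptotics. The chance-level concordance check uses 2,000 subjects and
20 score draws.

# Known limitations

- The infinite-medium dipole gives physically plausible but not
  biophysically accurate lead fields; absolute amplitudes and the relative
  sizes of precordial leads should not be over-interpreted.
- The Euler-angle conditioning loses rotation signs by construction (see
  above); applications that need signed pose should condition on electrode
  coordinates.
- The Cox head ranks; no baseline hazard is estimated, so absolute risks
  are not calibrated.
- Within-batch risk sets bias the partial likelihood slightly relative to
  full-cohort risk sets; at batch 64 with ~30% events this is negligible for
  ranking but would matter for coefficient inference.
- Reported behaviour (C-indices, sweep agreements) is measured on the
  internal simulator; no claim is made about real-data performance.
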