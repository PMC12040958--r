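# ecgvae

Personalized 12-lead ECG modelling in R: conditional generation of median
beats from cardiac anatomy, and cardiovascular risk prediction from the
learned latent space.

## The problem

The 12-lead ECG is shaped not only by cardiac electrophysiology but by where
the heart sits in the torso, how it is oriented, and where the ten recording
electrodes were placed. Models that ignore this anatomical context can
mistake normal positional variation for pathology, and discard prognostic
signal. `ecgvae` implements a pipeline for studying and exploiting that
relationship:

1. **Geometry** — heart position as the intersection of the mid short-axis,
   2-chamber and 4-chamber MRI planes ($n_i \cdot (X - P_i) = 0$ solved as a
   3×3 linear system); a heart-local orthonormal frame
   $e_X \propto n_{SAX} \times n_{4CH}$,
   $e_Z \propto n_{4CH} - (n_{4CH} \cdot e_X) e_X$, $e_Y = e_Z \times e_X$;
   projection Euler angles
   $\alpha = \arccos(e_X \cdot \hat{x})$,
   $\beta = -\arccos(e_Z \cdot \hat{z})$,
   $\gamma = -\arccos(e_X \cdot \hat{z})$; and rigid transforms of electrode
   coordinates into the heart frame.
2. **Preprocessing** — 3–45 Hz linear-phase FIR band-pass, amplitude quality
   control (|amplitude| ≤ 800 on the stored mV/100 scale), R-peak detection,
   R-aligned 12×400 median beats, incident/prevalent cohort filtering and
   stratified train/test splits.
3. **Conditional VAE** — convolutional encoder to a 64-dimensional Gaussian
   latent, symmetric decoder, anatomical/demographic conditions concatenated
   at the first dense layers, trained on
   $L = \mathrm{MSE}(x, \hat{x}) + D_{KL}(q_\phi(z|x,y)\,\|\,N(0,I))$.
4. **Survival head** — $r = \sigma(w \cdot z + b)$ trained with the negative
   Cox partial likelihood
   $-\frac{1}{N}\sum_i \delta_i (r_i - \log\sum_{j \in R(t_i)} e^{r_j})$
   added to the ELBO with equal weights; evaluation by Harrell's C-index,
   Kaplan–Meier curves with Greenwood 95% bands, and median-risk
   stratification.
5. **Simulator** — a single-dipole infinite-medium volume conductor
   ($\phi = p \cdot r / 4\pi\sigma|r|^3$) driving pose- and
   electrode-dependent synthetic beats, plus a proportional-hazards survival
   generator whose hazard is linked to a beat amplitude feature — so the
   whole method is trainable and testable without access to restricted
   biobank data.

The neural network is implemented natively (vectorized R with
Rcpp/RcppArmadillo convolution kernels); every backward pass is validated
against finite differences in the test suite.

## Worked example

```r
library(ecgvae)

# heart pose from three imaging planes (normals + points, mm)
sax <- plane3d(c(0.26, 0.93, -0.26), c(21, -8, 40))
ch2 <- plane3d(c(0.94, -0.22, 0.26), c(21, -8, 40))
ch4 <- plane3d(c(0.22, -0.29, -0.93), c(21, -8, 40))
pose_from_planes(sax, ch2, ch4)
#> <heart_pose> position (21.0, -8.0, 40.0) mm; euler (160.4, -158.6, -106.3) deg

# simulated cohort -> joint generative/survival model -> risk evaluation
cohort <- simulate_cohort(320, seed = 1)
surv <- cohort$survival
cfg <- cvae_config(epochs = 6, seed = 1)
idx_te <- 1:64; idx_tr <- 65:320
model <- train_joint(cohort$beats[idx_tr, , ], cohort$cond[idx_tr, ],
                     surv[idx_tr, ], cfg)
risks <- risk_score(model, cohort$beats[idx_te, , ], cohort$cond[idx_te, ])
concordance_index(risks, surv[idx_te, ])
#> test C-index: 0.649
groups <- stratify_by_median(risks, surv[idx_te, ])
c(mean(groups$low$event), mean(groups$high$event))
#> event fraction low/high risk: 0.19 / 0.31
```

The pose is recovered exactly (the planes were built through (21, −8, 40)),
and even this deliberately small model (320 subjects, 6 epochs) ranks risk
above chance and separates event rates between the median-split groups. At
the package's study scale (2,000 subjects, 25 epochs — a few minutes on one
CPU) the joint model's test C-index reaches ≈0.80 against ≈0.82 for the
true hazard ranking; see the methods vignette
(`vignettes/ecgvae-methods.Rmd`) for the full experimental setup.

`run_experiment()` orchestrates the three built-in experiments: pose- and
electrode-conditioned generation sweeps (rotation ±40°, translation ±4 cm)
compared against the simulator's forward model, and multi-arm joint survival
training with Kaplan–Meier stratification. A thin command-line wrapper lives
at `inst/scripts/ecgvae-cli.R` (`simulate-cohort`, `pose`,
`transform-electrodes`, `train`, `evaluate`).

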