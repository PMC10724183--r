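# rjsmlm

Bayesian multi-emitter fitting for 3D single-molecule localization
microscopy (SMLM), built to expose point-spread-function (PSF) degeneracy.

In densely labelled or thick samples, the images of several fluorophores
overlap inside one region of interest, and classical single-molecule fitting
returns the wrong model and biased positions. Worse, in 3D the PSF changes
shape with depth, so *different* emitter configurations can produce
statistically equivalent images. `rjsmlm` treats the problem fully
Bayesianly: a reversible-jump MCMC sampler draws from the joint posterior

P(θ, k | D) ∝ P(D | θ, k) · P(θ | k) · P(k),

where k is the emitter count, θ = (x_j, y_j, z_j, I_j)_{j=1..k}, b collects
the 3D positions, photon intensities and the shared background, and the
likelihood is an independent-pixel Poisson model with expected counts

μ_i = Σ_j I_j ∫_{A_i} H(x_j, y_j, z_j) dA + b,

with H a pixel-integrated Gaussian PSF whose per-axis width follows
σ(z) = s₀ √(1 + u² + A·u³), u = (z − γ)/d (astigmatic or biplane
calibrations). The sampler uses nine move types — random-walk parameter
moves plus trans-dimensional split/merge, prior/data-driven g-split/g-merge
and birth/death — with exact Metropolis–Hastings–Green acceptance, selects
the maximum-a-posteriori emitter count, and conditions a fixed-dimension
MCMC run on it. Histogram reconstructions of the conditioned chains *are*
the posterior density of emitter positions: when the problem is degenerate,
they show it as extra modes.

The package is intended for analysing imaging modalities (which PSFs suffer
from degeneracy, and when), not as a production localization tool.

## A worked example

Fit a simulated frame containing two overlapping emitters, 1.5 PSF widths
apart, under astigmatic imaging:

```r
library(rjsmlm)

calib <- astigmatic_calibration()            # s0 = 1.2 px, range +/-1.3 um
truth <- frame_params(x = c(9.1, 10.9), y = c(10, 10), z = c(0, 0),
                      I = c(2000, 2000), b = 20)
frame <- simulate_frame(truth, calib, roi = 20, seed = 7)

fit <- fit_emitters(frame, calib, seed = 7)
fit
#> emitter_fit: MAP model k = 2
#> frame_params: k = 2 emitters, background 20.15414 photons/px
#>           x        y            z        I
#> 1  9.128824 10.00941  0.066656740 2139.616
#> 2 10.986640 10.01418 -0.009751941 1843.681
```

The MAP model is two emitters; the posterior means land on the true lateral
positions to within a few hundredths of a pixel, and the intensities near
2000 photons. The depth estimates illustrate the astigmatic problem: with
the pair in focus, depth is only weakly constrained, and the posterior
spread in z is an honest report of that. Standard generics work as usual:
`coef(fit)`, `predict(fit)` (expected counts), `residuals(fit)` (Pearson),
`logLik(fit)`, `simulate(fit)`, `plot(fit)` (posterior reconstruction), and
`summary(fit)` adds the posterior over k, acceptance rates and a chi-square
representativeness check.

Degeneracy analysis of a whole experiment:

```r
design <- make_design("astigmatic", n_frames = 20, seed = 1)
ex <- run_experiment(design, separation = 1.5)
experiment_separability(ex)[c("accuracy", "n_modes")]
#> $accuracy
#> [1] 1
#> $n_modes
#> [1] 4
```

All 20 frames select the correct two-emitter model, yet the pooled 3D
reconstruction has **four** modes: the true pair plus a statistically
equivalent pair perpendicular to it at greater depth — the astigmatic
degeneracy. `find_alternate_mode()` computes that counterpart analytically
and `mode_error_probability()` shows a likelihood comparison between the
two hypotheses errs at chance. Run the biplane design (`"biplane"`) the same
way to see a modality that stays unimodal down to 0.75 PSF widths.

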