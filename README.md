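# bowmove

An R package for the full analysis chain applied to Argos/GPS satellite
telemetry of Arctic whales (bowhead whales in particular): from raw,
error-prone, irregularly timed location fixes to movement behaviour, habitat
selection and space use. It is aimed at movement ecologists who want each
stage of that chain as a tested, reusable function rather than a one-off
script, together with a synthetic seascape-and-track generator so every
stage can be verified by parameter recovery against known ground truth.

## What it computes

**Track regularization.** Fixes are quality-filtered (forward-pass speed
filter, gap splitting, a minimum-length floor of 54 locations per segment)
and fitted with continuous-time state-space models by maximum likelihood:
a random walk (per-axis diffusion variance) or a correlated random walk
(integrated Ornstein–Uhlenbeck velocity), Kalman-filtered over the exact
irregular-interval discretization with each fix's Argos error ellipse as
its observation covariance. Model choice uses AICc plus one-step-ahead
residual (OSAR) diagnostics, with an over-smoothing guard favouring the
random walk. Smoothed locations are predicted on a regular 4-h grid and
re-routed around land (land eroded by a 10 km buffer so fjord locations
stay put).

**Move persistence.** A hierarchical move-persistence model: step vectors
follow `d_t = γ_t d_{t−1} + N(0, σ_d² I)` with `logit(γ_t)` a latent
Gaussian random walk whose innovation variance is pooled across all tracks,
estimated by Laplace-approximated marginal ML. `γ_t ∈ (0,1)` reads as
area-restricted movement (low) versus directed travel (high).

**Habitat selection.** A used–available ("modified") resource-selection
function: 100 availability tracks are simulated per segment from the fitted
movement model with land as a barrier, the 20 most similar (net
displacement and bearing) retained, and 20 Monte-Carlo logistic regressions
fitted, each pairing all used locations with one availability track per
segment and a per-segment random intercept:

    logit(η_ij) = β₀ + β₁x₁,ij + … + β_p x_p,ij + v_j ,  use_ij ~ Binomial(η_ij, 1)

Coefficients are the mean across the 20 fits, SEs the SD across fits, with
normal-theory p-values and backward stepwise selection (the depth spline —
natural cubic, knots at 220/500/2500 m — is kept or dropped as a block).

**Behaviour vs environment.** `logit(γ_t)` is modelled against
environmental covariates with an individual random intercept and AR1
residuals,

    logit(γ_tj) = β₀ + β₁x₁,tj + … + β_p x_p,tj + V_j + ε_tj ,  ε ~ AR1(φ),

fitted by ML/REML (candidate ranking by AICc, winner reported under REML),
with VIF collinearity checks, whitened-residual diagnostics, partial
response curves, and leave-one-individual-out cross-validation (5%/95%
coefficient quantiles and the percentage of refits inside the full model's
95% CI).

**Space use.** Kernel utilization distributions on an 8,000 m grid with the
ad-hoc bandwidth rule (shrink `h_ref` in 0.1 steps until the 95% home range
fragments), home range / core area / hotspot contours (95/50/25%), seasonal
Bhattacharyya overlap rescaled by its attainable maximum (0.95 or 0.50),
and Wilcoxon rank-sum comparisons of conditions inside vs outside hotspots
(exact enumeration with midranks at small n).

## Worked example

```r
library(bowmove)

ss    <- generate_seascape(seed = 1)          # synthetic Arctic seascape
start <- c(ss$origin[1] + 0.6 * ss$nx * ss$cell,
           ss$origin[2] + 0.5 * ss$ny * ss$cell)
sim   <- simulate_observed_track(ss, start, duration_days = 20, seed = 2)

fx   <- read_fixes(sim$fixes)                 # parse + project + dedup
prep <- filter_and_segment(fx, max_speed = 2, min_length = 54)
prep$audit
#>              retained         removed_speed removed_short_segment
#>                   130                    70                     0

seg  <- prep$segments[[1]]
fits <- list(fit_ssm(seg, "rw"), fit_ssm(seg, "crw"))
sel  <- validate_and_select(fits, n_replicates = 100, seed = 3)
sel$fit
#> ssm_fit [crw] segment W1_W1-d1_s1: 130 fixes
#>   parameters: beta = 0.1481, sigma2_v = 5751000
#>   logLik -2716.24  AICc 5436.58  converged: TRUE

pred <- predict_regular(sel$fit, step_hours = 4)
mpm  <- fit_mpm_joint(pred)
mpm
#> mpm_fit: 1 track(s), pooled sigma_d = 4416.6 m, sigma_g = 0.000
#>   marginal logLik -2315.60, converged: TRUE

mean(sim$truth$gamma); mean(mpm$tracks[[1]]$gamma)
#> [1] 0.807
#> [1] 0.826
```

The speed filter removes the fixes whose Argos error implies >2 m/s
displacement; the correlated random walk wins selection on this
persistent track (velocity autocorrelation time 1/β ≈ 6.8 h); and the
estimated mean move persistence (0.826) recovers the generator's truth
(0.807). `run_pipeline(seed = …)` wires all stages — including the
availability simulation, the Monte-Carlo RSF and the AR1 mixed model —
into one deterministic call on a population of synthetic whales.

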