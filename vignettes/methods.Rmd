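---
title: "Models and methods behind bowmove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bowmove}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

bowmove chains five statistical stages that together turn raw satellite
telemetry of Arctic whales into estimates of behaviour, habitat selection
and space use. This vignette describes each model, its assumptions, the
tunable parameters and their defaults, the numerical choices made in the
implementation, and what the synthetic-data generator does and does not
emulate. All computations here are planar: coordinates are projected
(north polar stereographic by default) before any movement arithmetic, and
distances are Euclidean metres in that plane.

## Track state-space models

Two continuous-time movement models are fitted to each filtered track
segment by maximum likelihood.

The **random walk (RW)** treats the true position as Brownian motion with a
diffusion variance per axis, so over an interval $\Delta$ the position
innovation is $N(0, \sigma^2_x \Delta)$ (hours and metres throughout;
$\sigma^2$ in m$^2$/h). The **correlated random walk (CRW)** is the
integrated Ornstein–Uhlenbeck velocity model: velocity reverts to zero at
rate $\beta$ (1/h) with stationary variance $\sigma^2_v$ ((m/h)$^2$), and
position integrates it. Both are discretized *exactly* at the observed
irregular intervals, so no interpolation error enters the likelihood. For
small $\beta\Delta$ the CRW position-innovation variance suffers
catastrophic cancellation in its closed form; below $\beta\Delta < 10^{-3}$
a third-order series is used instead.

Each fix contributes a $2\times2$ observation covariance: the Argos error
ellipse (semi-major/semi-minor as 1-sigma axes, orientation degrees from
north) rotated to the coordinate axes, or, when ellipse metadata is
missing, an isotropic per-class fallback from `argos_class_table`. A ridge
of $10^{-6}$ m$^2$ guards against exactly singular ellipses.

The likelihood is evaluated by a Kalman filter (compiled code) and smoothed
states by fixed-interval (RTS) smoothing; regular-interval prediction runs
the same smoother over the union of observation times and a 4-h grid
anchored at the first fix, with grid-only times treated as missing
observations. The initial state is centred on the first fix with a vague
position variance of $10^9$ m$^2$ (SD ≈ 32 km). This is a deliberate
compromise: it is diffuse relative to any fix error while keeping both the
filter and the dense joint-Gaussian oracle used in the tests well
conditioned; a much larger value degrades the agreement between the two
routes for purely numerical reasons.

Optimization is Nelder–Mead on log-transformed parameters from
moment-based starting values, with a deterministic restart and a BFGS
polish; the CRW reversion rate is clamped to $[10^{-4}, 10]$ h$^{-1}$, and
a straight constant-velocity track drives $\beta$ to its lower clamp
(velocity autocorrelation at its maximum), which the tests assert.
Candidate fits are compared by AICc with
one-step-ahead-residual diagnostics; because an over-smoothed CRW can beat
the RW on AICc while leaving autocorrelated residuals, the selection
prefers the RW whenever the CRW's OSAR lag-1 autocorrelation is worse by
more than 0.1.

Replicate tracks for uncertainty assessment are drawn from the joint
smoothing distribution by forward-filter backward-sampling, which is
exactly the distribution the smoother summarizes.

**Availability simulation.** For the selection analysis, 100 tracks per
segment are simulated from the *unconditional* fitted process at the
parent's timestamps, started at the parent's first location, with the land
mask as a barrier (steps into land are re-proposed up to 50 times, then
reversed). Similarity to the parent is the negative standardized Euclidean
distance in (net displacement, net bearing); the top 20 are retained with a
deterministic index tie-break. The similarity metric itself is a design
choice — the notion of "most similar by displacement and bearing" admits
several formalizations — and the standardized two-feature distance was
chosen for being parameter-free and symmetric in its two features.

**Re-routing.** Land is represented as a raster mask. Erosion by the 10 km
buffer marks land cells whose distance to the nearest sea cell exceeds the
buffer; only points inside that eroded interior are moved (to the nearest
non-interior cell centre) and flagged. Points in the coastal band — fjord
arms narrower than the buffer — are intentionally left in place. A
polygon-based reroute would differ in detail near complex coastlines; the
raster realization keeps the same semantics without a vector-geometry
dependency.

## Move persistence

Move persistence is estimated on the first differences of the 4-h
predicted locations: $d_t = \gamma_t d_{t-1} + N(0, \sigma_d^2 I)$, with
$\mathrm{logit}(\gamma_t)$ a latent Gaussian random walk. In a joint fit
*both* variance parameters are pooled across tracks: the latent innovation
variance (which controls how fast behaviour can change) and the step-noise
variance. Pooling the latter is a parsimony choice — it makes the joint
fit a two-parameter problem and the tests show the behavioural contrast
survives it — but heterogeneous populations with very different movement
scales would argue for a per-track $\sigma_d$.

Estimation is marginal maximum likelihood with a Laplace approximation:
an inner Newton smoother maximizes the penalized objective over the latent
series (tridiagonal Hessian, Thomas solves, step-halving line search, the
latent scale clamped to $\pm15$ logits), and the outer 2-parameter
optimization runs Nelder–Mead on log variances with warm-started inner
solutions. The true Hessian is used when positive definite, otherwise the
Gauss–Newton approximation. Pointwise standard errors come from the
curvature at the mode; they are reporting-only and are not propagated into
the behaviour model (which, like the analysis this package operationalizes,
models the point estimates). Each track's $\gamma_t$ series is defined at
interior locations and padded at the two ends.

Two degenerate regimes deserve note: a perfectly straight track drives
$\gamma_t \to 1$ and $\sigma_d \to 0$ (the optimizer's iteration cap bounds
the divergence; estimates remain usable), and an uncorrelated position
series wants $\gamma_t < 0$, which the logit link truncates at 0 — both
limits are asserted in the tests (mean $\hat\gamma \ge 0.9$ on straight
tracks, $\le 0.3$ on white noise, over 20 seeds of 200 steps).
Normalization for display is min–max, global across individuals by default
(a single location anywhere maps to 1) or per individual; constant series
map to 0.5 with a warning.

## Monte-Carlo resource selection

The used–available design pairs every predicted location (`use = 1`) with
the retained availability tracks (`use = 0`). Transforms: depth enters as
a natural cubic spline with interior knots at 220, 500 and 2500 m and
boundary knots at the pooled data range (widened marginally when the data
do not span a knot, e.g. shelf-only track sets — otherwise the basis is
undefined); `in_ice` is the indicator of a negative signed distance to the
15% ice-concentration edge; `ice_sq` is the square of the standardized ice
column, itself re-standardized (the squaring-then-scaling order is a
documented choice). All continuous columns are standardized once on the
pooled used+available rows so coefficients are comparable across the
Monte-Carlo fits, and the scaling record is returned for reuse.

Each of the 20 model datasets holds all used rows plus one availability
track per segment, assigned by a per-segment random permutation (without
replacement across datasets — whether the reference procedure replaces is
unstated, and a permutation uses each simulation exactly once). Each
dataset is fitted as a logistic regression with a per-segment random
intercept (Laplace approximation via lme4); when the estimated
random-effect variance collapses below $10^{-8}$ the fit falls back to a
plain logistic, and with the variance forced to zero each fit reproduces an
iteratively-reweighted-least-squares oracle to $10^{-6}$ (a test). Fits
showing separation (non-finite or absurdly large coefficients) are excluded
with a warning. Aggregation: coefficient = mean across fits, SE = SD across
fits, CI = mean ± 1.96 SE, p = two-sided normal. A zero SD across fits is
reported as an undefined p with a degeneracy warning rather than a
significant zero.

Backward stepwise selection drops the term with the largest p above
$\alpha = 0.05$, refitting the entire Monte-Carlo procedure with fresh
random assignment under a derived seed each round; the four depth-spline
columns form one term, droppable only when all four exceed $\alpha$, and
p-ties drop the later term in declaration order. The aggregated p-value is
calibrated: under a null with no selection its rejection rate at
$\alpha = 0.05$ falls within [0.01, 0.12] over 100 replicates (an
acceptance check; the calibration run uses the variance-zero limit of the
same code path, since a null with iid rows has no segment effect).

## Behaviour against environment

$\mathrm{logit}(\gamma_t)$ is regressed on environmental covariates with a
per-individual random intercept (variance $V$) and AR1 residuals
($\phi$, innovation variance $\sigma^2(1-\phi^2)$), indexed by observation
order within individual — regular 4-h steps make order and time
equivalent — with the correlation resetting at segment boundaries. The
marginal likelihood is evaluated analytically: AR1 whitening in innovation
form plus a rank-one Woodbury identity for the random intercept, so each
evaluation is $O(n)$ per individual with fixed effects profiled out by
GLS. ML and REML are both implemented; candidates are ranked by AICc under
ML and the winner refitted by REML for reporting. AICc uses $n$ = total
observations and $k$ = fixed effects + $\phi$ + two variances.
Optimization is Nelder–Mead over $(\tanh^{-1}\phi, \log\sigma^2, \log V)$
with three deterministic restarts (Brent when only one parameter is free).
The test suite pins this implementation against nlme's
`lme(..., correlation = corAR1())` — the reference implementation for this
model class — to $10^{-6}$ in log-likelihood, and against lme4 in the
$\phi = 0$ reduction.

Diagnostics: generalized (determinant-based) VIFs with the spline block
scored jointly, exact-collinearity detection that names both offending
columns, whitened residuals (inverse Cholesky of the fitted per-individual
covariance) summarized by mean, variance and pooled lag-1 autocorrelation,
and partial response curves per design column with delta-method bands.
Leave-one-out cross-validation refits once per individual and reports the
5% and 95% coefficient quantiles plus the estimated trend — the percentage
of refits whose coefficient lies inside the full model's 95% CI.

## Kernel space use

The utilization distribution is a bivariate Gaussian kernel density
evaluated at cell centres (8,000 m default) over the point bounding box
padded by four bandwidths — enough that truncation stays below the
$10^{-6}$ normalization tolerance — then renormalized to unit mass.
The reference bandwidth is the bivariate normal rule
$h_{ref} = \sqrt{(\mathrm{var}_x + \mathrm{var}_y)/2}\, n^{-1/6}$. The
ad-hoc selection rule evaluates multipliers 1.0 down to 0.1 and stops
before the number of 8-connected components of the 95% contour first
exceeds its baseline at 1.0 — a deterministic surrogate for the visual
"began to separate" judgement; baseline components (small separated areas
present from the start) do not trigger the stop. The fixed multiplier 0.6
is the pipeline default, with the selection procedure always available and
its trace logged.

Contour levels take the smallest set of cells whose mass reaches the level,
ties broken by cell index; areas are cell counts times cell area. For
overlap, each UD is masked to its own level contour and the retained mass
normalized to exactly the level, so Bhattacharyya affinity attains the
level (and the rescaled index exactly 1) for identical inputs — without
that normalization the discrete level set slightly overshoots the level and
"identical inputs" would not reach the theoretical maximum. Seasonal UDs
share one bandwidth computed on the pooled data and one grid, which is what
makes affinities comparable across season pairs. Seasons are meteorological:
spring March–May, summer June–August, fall September–November, winter
December–February.

The Wilcoxon rank-sum test enumerates the exact null distribution with
midranks whenever $\min(n) \le 10$ (and the enumeration is below $2\times
10^5$ arrangements), so exact p-values remain valid under ties; larger
samples use the normal approximation with tie correction and no continuity
correction.

## The synthetic seascape and tracks

The generator exists so that every stage above is testable by parameter
recovery. `generate_seascape()` builds spatially autocorrelated fields as
Gaussian-smoothed white noise plus deterministic gradients: a land block
along the western edge (thresholded at the exact requested land fraction),
a shelf-like depth ramp deepening eastward (quadratic mapping, so a broad
shallow shelf precedes the slope), a meridional SST ramp (colder north),
an ice field increasing northward with the ice edge at the community-
conventional 15% concentration contour, and derived distance layers
(to the 500 m isobath, to glacier-front coastal cells, signed to the ice
edge with negative inside). Everything is deterministic given the seed.

`simulate_observed_track()` inverts the behavioural model: covariates plus
AR1 noise set $\mathrm{logit}(\gamma_t)$, which drives the first-difference
correlated walk at a 1-h step (finer than the 4-h analysis step, so
regularization is meaningful), with land as a barrier. Observations are
thinned Bernoulli with injected multi-hour gaps and jittered times, then
perturbed by class-dependent elliptical errors whose per-class magnitudes
are defaults chosen in the range of published Argos accuracy studies
(class B ≈ 8 km semi-major) — real deployments carry per-fix ellipses that
override them. Default class frequencies mirror the strongly B-dominated
composition typical of whale deployments.

What the generator does *not* emulate: real bathymetry or ice dynamics
(fields are smoothed noise with gradients), geodesic geometry (planar
only), tag duty cycling or diel patterns in fix acquisition, and
class-dependent *time* clustering of fixes. Passing recovery tests
therefore demonstrates the estimators are correct under their assumed
models at realistic noise levels — not that those models capture every
feature of field data.

## Problem sizes and determinism

The test and acceptance runs use desk-scale sizes chosen to give each
check adequate power while keeping the whole suite fast: 50 replicate
segments of 200 fixes for state-space recovery; 20 seeds of 200-step
tracks for the move-persistence contrast and 50 for change-point
localization; 200 segments × 25 locations for selection-coefficient
recovery and 100 small replicates for null calibration; 20 individuals ×
200 steps × 20 seeds for the mixed model; and a 10-whale, 30-day synthetic
population for the end-to-end run. Every stochastic function takes an
explicit seed, restores the caller's RNG state, and is bit-reproducible;
the end-to-end pipeline is asserted identical across independent runs of
the same seed.

## Known limitations

Single best track per segment: prediction uncertainty is quantified
(replicate tracks) but not propagated into the RSF or the behaviour model.
No discrete behavioural-state HMM alternative; the package reports
$\gamma_t$ only. The speed/gap/minimum-length filter defaults (2 m/s,
72 h, 54 locations) are configurable and logged, since published analyses
rarely print their final filter settings. The similarity filter's metric
and the raster re-routing are documented approximations to procedures that
are usually specified only loosely. Observation-error magnitudes per Argos
class are synthetic defaults, clearly overridden by per-fix ellipses
whenever present.
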