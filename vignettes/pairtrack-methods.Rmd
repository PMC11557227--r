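---
title: "From signal strength to spatial cohesion: the methods behind pairtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From signal strength to spatial cohesion: the methods behind pairtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairtrack)
```

## The problem

Automated radio-telemetry grids record, for every beacon a tag emits, which
receivers heard it and at what received signal strength (RSS). From those
raw detections one wants tag positions with honest uncertainty, and from
simultaneously tracked individuals one wants to know whether they move
*together* — the question behind studies of pair cohesion in monogamous
birds, where mated partners may share home ranges and maintain close
proximity while neighbours merely overlap. `pairtrack` implements that
chain: RSS-to-distance calibration, windowed multilateration with error
ellipses, trajectory cleaning, home-range overlap, and a dyadic proximity
statistic, together with a synthetic-scene generator so every step can be
validated against known ground truth.

## The observation model and calibration

Signal strength decays approximately log-linearly with distance, so the
calibration is an ordinary least-squares fit of `log10(distance)` on RSS:

```{r calib}
obs <- observation_model(rss_noise_sd = 0)
calib <- simulate_calibration(obs = obs, reps_per_distance = 1, seed = 1)
fit_calibration(calib)
```

The default coefficients (`b0 = -1.27009` log10-m, `b1 = -0.03302`
log10-m/dB) invert to `distance = 10^(b0 + b1 * RSS)` metres. Two numerical
rules matter:

* **Truncation.** The relationship is calibrated only up to the largest
  reference distance (150 m by default); weaker signals would extrapolate
  to absurd distances (an RSS of −130 dB implies over a kilometre), so
  predictions are capped at `d_max`. Truncation biases the contribution of
  far receivers toward the solver, which is one reason realistic median
  localization error sits in the tens of metres rather than metres.
* **Standard errors.** The calibration's residual SD on the log10 scale is
  converted to a distance SE by the delta method, `d_se = d ln(10) s`. The
  deployment protocol does not define a distance SE, so this propagation is
  our choice; per-RSS prediction intervals would be the obvious
  alternative and would scale the ellipses, not reorder them.

## Windowing, receiver retention, multilateration

RSS is averaged in tumbling 15 s windows whose boundaries are shifted 5 s
early (interval *k* covers `[15k - 5, 15k + 10)` s). The source protocols
do not pin down window alignment; the shift is a configuration constant
(`lag`) and the tests pin this package's convention. Sliding windows were
rejected to keep fixes statistically independent between intervals.

Within a window, only receivers within 200 m of the strongest-signal
receiver are retained (RSS ties break to the lexicographically smallest
receiver id — arbitrary but deterministic), and at least three receivers
are required for a planar position. The position estimate minimises

$$\sum_i \left( \lVert p - r_i \rVert - \hat d_i \right)^2$$

by damped Gauss–Newton from a signal-weighted centroid start (weights
`1/d_hat`, the monotone image of RSS). The problem is non-convex;
solutions landing more than two bounding-box diagonals outside the
retained receivers are declared non-converged, and a fix is abandoned if
more than half of the replicates fail, which makes pathological geometry
explicit rather than silent. The solver iterates all replicates
simultaneously as a vectorised 2-by-2 normal-equation update, which is
what keeps 100 replicates per interval affordable.

Uncertainty is obtained by re-solving with each distance perturbed within
its SE — Gaussian `N(0, d_se)` by default (a `uniform` switch exists),
truncated below at 0.1 m — and summarising the replicate cloud by its
covariance eigendecomposition: semi-axes `2 * sqrt(eigenvalues)`, the
2-sigma ellipse containing `1 - exp(-2) ≈ 86.5%` of a bivariate normal's
mass. The Gaussian perturbation was chosen over uniform because the
ellipse summary itself assumes bivariate normality.

## Trajectories and dyad summaries

Fixes further than 2.5 km from an individual's component-wise median
coordinates are removed (marginal medians, not the geometric median — the
difference is immaterial at this threshold and the marginal version is
exactly reproducible). "Simultaneous" fixes are fixes in the same 15 s
interval; the fraction of simultaneous fixes uses the mean of the two
individuals' fix counts as its denominator, and the gap statistic is the
median over all fixes (both directions) of the time to the partner's
nearest fix. These definitional choices are stated because several
conventions circulate; all are deterministic functions of the windowing
already fixed above.

## Utilization distributions and overlap

Home ranges use plain Gaussian-kernel UDs on a regular grid (default 25 m
cells) padded three bandwidths beyond the fixes, with Silverman's
rule-of-thumb bandwidth per axis inflated in quadrature by the mean
1-sigma scale of the fixes' error ellipses. This is a deliberate
simplification of autocorrelated kernel density estimation with
information-criterion model selection: full AKDE corrects home-range areas
for autocorrelation-induced undersmoothing, and our areas will run small
at short tracking durations. The partner-versus-neighbour *contrasts* the
package is built to test are insensitive to this choice because both
groups are estimated identically; absolute overlap values are therefore
not comparable to AKDE-based field numbers and are not treated as targets.

The 95% home range is the smallest set of cells holding 95% of UD mass;
overlap is the Bhattacharyya coefficient `BC = sum(sqrt(p * q))`. UDs on
different grids are aggregated onto a common grid at the coarser cell size
by mass-preserving binning (each source cell's mass goes to the target
cell containing its centre; half-cell ties break upward so commensurate
grids map exactly). Bilinear resampling was rejected because it does not
preserve total mass exactly.

## Movement fitting and the proximity ratio

Each track gets a reduced stationary Ornstein–Uhlenbeck (OU) fit: centre =
mean position, `sigma_pos` = pooled per-axis SD, and `tau` from a
through-origin regression of log autocorrelation on lag (for an OU process
`ACF(k) = exp(-k dt / tau)` exactly), using lags with ACF above 0.2. A
non-positive lag-1 ACF floors `tau` at the sampling interval with a
warning. This replaces a continuous-time movement-model zoo with the one
model the proximity null needs.

The proximity ratio divides the observed mean separation over simultaneous
fixes by the mean separation of `n_sims` pairs of *independently*
simulated OU tracks, one per individual from its own fit, sampled at the
observed fix times. Ratios below 1 mean the dyad is closer than
independent movement predicts. The CI divides the observed mean by the
97.5% and 2.5% null quantiles, so it excludes 1 exactly when the observed
mean leaves the central 95% of the null. Two properties make this
self-calibrating: the null tracks inherit each fit's centre (so
between-centre distance is part of the null), and they inherit the fix
times (so the null has the same effective sample size as the
observation). The null is an *unconditional* stationary simulation, not a
path-conditioned one; this shifts absolute ratios slightly but not the
partner/neighbour ordering, which is what the comparisons use.

## Partner-versus-neighbour comparison

Group contrasts use a within-site permutation test of the weighted mean
difference (weights = time simultaneously tracked), with the add-one
p-value correction. Permuting relationship labels within sub-colony sites
conditions on site structure; it does not reproduce crossed
individual-level random effects (no permutation scheme exactly does when
individuals appear in several dyads), so p-values are interpreted as
scene-level evidence, not as a reproduction of mixed-model inference. A
descriptive median-separation-by-hour table replaces time-of-day smooths,
which are out of scope.

## The synthetic scene

`run_pipeline()` wires everything to a generator whose defaults describe
the reference deployment: a triangular receiver grid at 150 m spacing over
~1.5 km² (~85 nodes), tags beaconing every 5 s, RSS noise of 5 dB (the
field noise level is not published; this is an explicit free parameter),
a hard 400 m detection radius (a falsifiable stand-in for an unpublished
detection-probability curve), and two sub-colony sites of three pairs
each, tracked for one hour of simulation time at `dt = 5` s. Movement is
OU with a 600 s timescale, composed of a site-shared component (SD 75 m),
a pair-shared component (SD 125 m) and a within-pair separation process
(SD 25 m). The site-shared component is the generative analogue of
neighbours jointly exploiting shared water and foraging patches: it makes
neighbour dyads mildly attracted (most proximity ratios at or below 1)
while partners remain far more cohesive, which is the qualitative
structure observed in wild zebra finch colonies. Exact discrete-time AR(1)
transitions are used rather than Euler steps so stationarity holds at any
`dt` and closed-form variances are testable.

What the generator does *not* emulate: solar duty-cycling and antenna
failures, detection-probability decay with distance, topographic and
vegetation effects on RSS, multipath beyond white RSS noise, and
behaviourally structured movement (foraging trips, nest attendance).
Passing tests therefore demonstrate the *pipeline's* correctness and
calibration under a known movement model, not field performance; the one
field anchor available — median localization error of a few tens of metres
under 5 dB noise — emerges at the right order without being tuned.

Problem sizes in the shipped tests were chosen to give stable Monte-Carlo
margins at interactive runtimes: 50-replicate calibration/power checks for
the proximity ratio, 200-replicate type-I-error checks for the permutation
test, ten-seed ordering checks for the full scene, and `1e5`–`1e6` draw
oracles for the closed-form checks.

## Known limitations

* Truncated distances keep their pre-truncation SE; whether a truncated
  distance should carry inflated uncertainty is undecidable from the
  protocol and is noted rather than guessed.
* KDE home ranges undersmooth relative to AKDE at short durations (above).
* The proximity CI inherits the finite-window variance of a mean over an
  autocorrelated path; with tracking bouts much shorter than `tau`,
  ratios for truly independent dyads are noisy (the null quantiles widen
  accordingly, which is the point of matching fix times).
* Coordinates are local planar metres throughout; project geographic data
  before use.
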