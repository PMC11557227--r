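# pairtrack

Automated radio-telemetry analysis for questions of the form *"do these two
animals move together?"* — built for receiver-grid deployments tracking
tagged songbird pairs, and for anyone who needs received-signal-strength
(RSS) multilateration with honest uncertainty plus dyadic cohesion
statistics.

## What it computes

Given receiver coordinates, raw tag detections (`tag, receiver, time, RSS`)
and a calibration exercise, the package:

1. **Calibrates** the path-loss relationship by least squares,
   `log10(d) = b0 + b1·RSS` (defaults `b0 = −1.27009`, `b1 = −0.03302`),
   truncating predictions at the largest calibrated distance (150 m) and
   propagating the residual SD to distance SEs by the delta method.
2. **Localizes** each tag in tumbling 15 s windows (−5 s lag): averages RSS
   per receiver, retains receivers within 200 m of the strongest signal,
   and — when ≥ 3 receivers remain — minimises
   `Σᵢ (‖p − rᵢ‖ − d̂ᵢ)²` by damped Gauss–Newton, re-solving 100
   perturbed replicates to summarise each fix as a 2-sigma error ellipse
   (axes `2√λ` of the replicate covariance).
3. **Cleans trajectories** (2.5 km median-distance outlier rule) and
   summarises dyads: median separation over simultaneous (shared-interval)
   fixes, fraction simultaneous, median nearest-fix gap.
4. **Estimates space use**: gridded Gaussian-KDE utilization distributions
   with ellipse-inflated bandwidths, 95% home-range areas, and pairwise
   overlap via the Bhattacharyya coefficient `BC = Σ√(pq)`.
5. **Tests cohesion**: the proximity ratio — observed mean separation over
   the mean separation of independently simulated Ornstein–Uhlenbeck (OU)
   tracks fitted per individual (< 1 ⇒ attraction) — and within-site
   permutation tests of partner vs neighbour differences.

A fully seeded synthetic-scene generator (receiver grids, coupled-pair and
independent OU movement, RSS noise, detection dropout, calibration data)
provides ground truth for every stage; `run_pipeline()` composes the whole
chain.

## Worked example

```r
library(pairtrack)
report <- run_pipeline(pipeline_config(), seed = 11, quiet = TRUE)
print(report)
#> Synthetic-scene tracking report (seed 11)
#>   12 tags, 2892 fixes; median localization error 33.8 m
#>   mean 95% home range 0.239 km^2
#>   median BC: partner 0.985 vs neighbour 0.604 (p = 0.001)
#>   median proximity ratio: partner 0.200 vs neighbour 0.947 (p = 0.001)
#>   median separation: partner 24.9 m vs neighbour 271.0 m
#>   dyads with ratio < 1: 77%
```

The scene: two sub-colony sites, three tagged pairs each, on a ~1.5 km²
triangular receiver grid at 150 m spacing, tags beaconing every 5 s with
5 dB RSS noise. Partners share a movement path (plus a 25 m-SD separation
process); all birds at a site share a slower site-level component. Reading
the numbers: localization error of a few tens of metres is what 5 dB of
RSS noise buys on this grid; partner dyads show near-total home-range
overlap (BC 0.99) and are five times closer than independent movement
predicts (ratio 0.20), while neighbours overlap substantially less (0.60)
and sit near independence (0.95); both contrasts are as significant as 999
within-site permutations can make them (p = 0.001). Per-dyad tables live
in `report$dyads`; individual fixes in `report$localizations`.

Lower-level entry points (`fit_calibration()`, `localize_all()`,
`estimate_ud()`, `bhattacharyya()`, `proximity_ratio()`,
`permutation_test()`, CSV readers/writers, ASCII-raster and GeoJSON UD
exports) are documented individually; the methods vignette
(`vignettes/pairtrack-methods.Rmd`) explains the models, conventions and
their limitations.

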