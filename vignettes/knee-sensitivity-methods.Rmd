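---
title: "Methods: one-at-a-time sensitivity analysis of FE knee simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-at-a-time sensitivity analysis of FE knee simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneesense)
```

## The study design

`kneesense` analyzes one-at-a-time (OAT) sensitivity studies of
tibiofemoral finite-element models under varus–valgus loading. A
calibrated model is re-run once per perturbed parameter value, changing
exactly one parameter at a time, and each perturbed run is compared to
the unperturbed ("original") run of the same loading direction.

The design spans four categories, 101 perturbed configurations per model:

| category | axes | plans |
|---|---|---|
| ligament/meniscus | prestretch (±0.1 in 0.025 steps, per ligament), Young's modulus (±100 MPa in 25 MPa steps, per ligament), attachment node sets (3 combinations per ligament), meniscal horn stiffness (5/10/20 N/mm per spring) | 32 + 32 + 12 + 3 = 79 |
| cartilage contact | Augmented Lagrangian on, penalty factor (0.5/2/5/10), auto-penalty on, two-pass off, search radius 1 | 8 |
| simulation control | quasi-Newton update (BFGS/Broyden, with `max_ups = 10`), displacement tolerance 0.001 | 3 |
| rigid cylindrical joint | force penalty (5,000/20,000 N/mm), moment penalty (5,000/10,000/20,000 Nmm/rad), gap tolerance (1e-4/1e-3/0.1), angular tolerance (0.001/0.01/0.1) | 11 |

The perturbation grids exclude the calibrated value itself (that run
already exists: it is the baseline). Contact-formulation, solver and RCJ
settings are *enumerated design axes*, not algorithms this package
implements — the FE solve is out of scope.

Two modelling rules need care:

* **Attachment halving.** The tied-contact node set of each ligament end
  is halved by keeping the nodes extremal along the proximal anatomical
  axis: the most proximal half at the femur, the most distal half at the
  tibia/fibula. For an odd set size the kept half is
  `ceiling(n / 2)` (round-half-up) — the convention is not forced by the
  protocol, and round-half-up is the deterministic choice closest to
  "half" that never empties a two-node set. Projection ties break by
  ascending node id so results do not depend on node ordering.
* **Loading schedule.** Prestretch application, rotation to the
  robot-data flexion angle (the `oks` family adds a −20 N axial settling
  phase; its sign convention toward compression vs. distraction is kept
  as a labelled value only), rotation to 0° flexion, half-body-weight
  axial load (`0.5 · mass · 9.81` N, rounded to 0.01 N), then a linear
  moment ramp to ±40,000 Nmm over time steps 2.0–3.0. At t = 2.25 the
  applied moment is 10,000 Nmm; that time is the convergence threshold
  below which a run is excluded from the quantitative outcome analysis.

## Outcome extraction

Four outcomes per run, compared against the baseline:

1. **Convergence**: percentage difference of the last converged time
   step, `100 |t_int − t_orig| / t_orig`. Reported as a magnitude (the
   signed value is available as a diagnostic); the direction of a
   convergence change is of secondary interest to its size, and
   magnitudes aggregate without cancellation.
2. **Valgus kinematics RMSE**: computed on the converged time steps of
   the run of interest, restricted to the moment phase (t ≥ 2.0) and
   clipped to the baseline's time span (no extrapolation). The baseline's
   valgus rotation is linearly interpolated between its own converged
   steps — linear being the minimal-assumption scheme for an
   unspecified interpolant. The settling phases before t = 2.0 are shared
   by all group members and would only dilute the RMSE, hence the window.
3. **Peak contact pressure**: per compartment (medial/lateral tibial
   cartilage analyzed separately), faces with pressure > 0 are selected
   and the top 10 % highest-pressure faces — `ceiling(0.1 · n)`, so at
   least one face whenever there is any contact — are averaged,
   unweighted. Averaging a face set rather than taking the single maximum
   avoids spikes from single deformed elements. Area weighting is
   deliberately not applied: the definition is over *faces*. Ties at the
   top-set cutoff are resolved by ascending face id and truncated to the
   ceiling count, making the extraction deterministic and
   permutation-invariant.
4. **Peak-pressure location**: the unweighted mean centroid of the same
   top faces; compared by Euclidean distance per compartment, then
   averaged over compartments. Locations live in each model's fixed
   global frame; no cross-model comparison is ever made, so no
   registration layer exists.

**Group analysis time.** Pressure and location are evaluated at a single
time step per parameter of interest: the *latest* time step converged by
every non-excluded run of that parameter and the baseline, required to be
\> 2.25. "Latest" maximizes the applied moment and therefore the
discriminative power of the comparison; any common converged step would
satisfy the protocol, which does not pin the choice down. Runs whose last
converged step is ≤ 2.25 are excluded beforehand: they still enter the
convergence aggregate, but never the RMSE/pressure/location aggregates.
A baseline that itself fails to pass 2.25 makes the group unanalyzable
and is a hard error.

## Rating

Aggregated metrics (arithmetic mean per parameter of interest and
loading direction) map onto a 0–3 scale per metric kind, with bins
inclusive at their upper bound (a location distance of exactly 1.25 mm
scores 1.5, not 2):

| score | convergence % | valgus RMSE (°) | pressure % | location (mm) |
|---|---|---|---|---|
| 0 none | = 0 | = 0 | = 0 | = 0 |
| 0.5 negligible | ≤ 1 | ≤ 0.2 | ≤ 1 | ≤ 0.2 |
| 1 small | ≤ 5 | ≤ 0.5 | ≤ 5 | ≤ 0.5 |
| 1.5 small–medium | ≤ 10 | ≤ 0.9 | ≤ 10 | ≤ 1.25 |
| 2 medium | ≤ 20 | ≤ 1.4 | ≤ 20 | ≤ 2.5 |
| 2.5 medium–large | ≤ 40 | ≤ 2 | ≤ 40 | ≤ 4 |
| 3 large | > 40 | > 2 | > 40 | > 4 |

The order of operations is fixed: aggregate quantitative metrics per
direction → score each direction → average the two scores. Averaging
scores (not metrics) across directions is what produces quarter-point
combined ratings such as 0.75. "Exact zero" is implemented as
`|x| < 1e-12` in the metric's own unit to absorb floating-point noise;
the tolerance ships in the scale's YAML config
(`inst/extdata/rating_scale.yaml`) and is user-overridable together with
the bin bounds. When only one direction can be rated (e.g. the other
direction never converged), the single-direction score is reported with a
`partial` flag rather than imputing the missing direction.

## The synthetic generator

Real inputs are solver result bundles; the generator stands in for them
with the statistical structure the analysis assumes, so every stage is
testable end-to-end:

* **Surface**: two elliptical patches (default semi-axes 12 × 18 mm,
  200 face centroids each) on a sunflower spiral — deterministic,
  near-uniform, no RNG needed.
* **Kinematics**: valgus rotation `θ(t) = c · k · M(t)` during the
  moment ramp, with compliance `k = 1e-4` °/Nmm by default (4° at the
  full 40,000 Nmm — plausible frontal-plane laxity) and `M(t)` the
  scheduled moment. The other five DOF carry simple deterministic
  profiles; they are stored but never rated.
* **Contact**: per-face Gaussian pressure bump of amplitude 3 N/mm²
  (typical cartilage contact pressure under load), width
  `ρ = 0.4 × min(patch radii)`, zeroed below 35 % of the *unscaled*
  amplitude. Applying the cutoff before the injected scale `s` keeps the
  contacting-face set — and with it the top-10 % subset — identical
  between baseline and perturbed run, which is what makes the recovered
  pressure difference exactly `100|s − 1|` at zero noise. About a fifth
  of each patch is in contact, so the top-10 % subset is a meaningful
  average.
* **Injected effects** per axis (optionally per ligament or per value):
  pressure scale `s`, location shift `d` (mm), compliance multiplier
  `c`, truncation time `T`. Recovery has closed forms at zero noise;
  a location shift is recovered to within one face-centroid spacing
  (≈ `sqrt(π a b / n)`), the discretization limit of a face-based mean.
* **Noise**: additive Gaussian, truncated at zero for pressures and
  applied only to contacting faces. FE output is deterministic — noise
  exists purely to harden the pipeline and exercise tolerance handling,
  and defaults to zero.
* **Time grid**: uniform 0.05 step over [0, 3], truncated at `T`. This
  emulates adaptive stepping only as far as the analysis needs;
  irregular grids are exercised separately in the interpolation tests.

What the generator does **not** emulate: real contact-patch shapes and
their load-dependent migration, meniscal load sharing, coupled DOF,
model-specific mesh topology, or any actual mechanics. Passing recovery
tests therefore demonstrates that the *analysis* is correct and
internally consistent — not that any particular FE model is.

## File formats and numerical choices

Bundles are plain text: `kinematics.csv` (time + 6 DOF), `contact.csv`
(time, side, face_id, centroid xyz, pressure), `convergence.json` (with
a schema version; readers reject unknown major versions). Units are
fixed: mm, degrees, N/mm² (MPa), Nmm. Floats are written as `%.10g`, so
round-trips agree to better than 1e-9 relative error and identical
results produce byte-identical files. Time values are rounded to 1e-9
before set operations, since decimal grids are not binary-exact.
Degenerate inputs are explicit, not crashes: a frame with no contacting
faces yields a "no contact" summary; a compartment without baseline
contact is dropped from the pressure average (flagged per side); an
interest run that loses contact on a compartment reads as a 100 % drop
for pressure but contributes no location distance (no location exists);
an empty RMSE overlap window returns `NA` and marks the comparison
excluded.

The perturbed Young's modulus grid refuses calibrated values ≤ 100 MPa
(they would generate non-positive moduli); clamping instead would
silently change the design.

## Interfaces

The pipeline stages are exported functions
(`enumerate_design` → `simulate_study`/`read_result_bundle` →
`compare_study` → `aggregate_study` → `rate_study`, wrapped by
`run_pipeline`, with `plot_rating_heatmap`/`render_report` for figures);
as a library, these and the scripts under `scripts/` are the intended
entry points rather than a shell command. `run_pipeline` records
provenance (package and R versions, seed, and an FNV-1a fingerprint of
the configuration) so tampered configurations are detectable, and all
randomness sits behind a single seed: reruns with the same configuration
are table-identical.

## Problem sizes

The shipped tests run the full 101-plan design end-to-end on reduced
synthetic models (12–100 faces per compartment, 0.25 time step) and use
200-face patches for recovery checks and 100 replicate seeds for the
noise-bias check; these sizes were chosen so the closed-form and
statistical tolerances above are binding while the whole suite stays
fast on a single CPU. They are analysis-scale choices — the pipeline
itself is linear in faces, frames and plans and runs unchanged on
solver-scale outputs.

## Known limitations

* Only the valgus/varus rotation DOF is rated; the other five DOF are
  carried but unanalyzed.
* The exclusion rule ties to a fixed 2.25 threshold; protocols with a
  different moment schedule need a different threshold
  (`ANALYSIS_TIME_THRESHOLD` is a package constant, the functions accept
  it as an argument).
* Percentage-based metrics are undefined for baselines with zero
  denominator (no contact, zero last-converged time); these surface as
  dropped sides or hard errors, never silent zeros.
* The rating bins are a fixed convention; different bins change the
  qualitative conclusions, which is why the scale is a shipped,
  overridable config rather than code.
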