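---
title: "Methods: sensor-subset optimization for insole CoP estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor-subset optimization for insole CoP estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(insolecop)
```

## Problem and model

A 16-cell pressure insole samples plantar pressures $P_i(t)$
(N·cm$^{-2}$) at 100 Hz. Each cell $i$ has a fixed centroid $(x_i,
y_i)$ (mm; origin at the posterior-medial corner of the insole bounding
box, $x$ anterior, $y$ lateral) and sensing area $A_i$ (cm$^2$). The
center of pressure is modelled as the pressure-weighted barycenter

$$\mathrm{CoP}_x(t) = \frac{\sum_i P_i(t) A_i x_i}{\sum_i P_i(t) A_i},
\qquad
\mathrm{CoP}_y(t) = \frac{\sum_i P_i(t) A_i y_i}{\sum_i P_i(t) A_i}.$$

This assumes each cell's load acts at its centroid and that uncovered
insole area carries no information — both standard for discrete-cell
insoles. The full 16-sensor trajectory serves as the reference: it is a
*relative* ground truth (no force platform is involved), so all errors
quantify the cost of sparsification, not absolute accuracy.

A reduced layout $C_k \subseteq \{1..16\}$ re-evaluates the same
barycenter with the excluded sensors' weights set to zero. Because the
weights are non-negative, every defined estimate lies in the convex
hull of the member centroids — a property the test suite enforces.

Right-foot insoles use a strictly mirrored numbering, so sensor $i$ of
a right insole sits at $(x_i, w - y_i)$ of the left layout ($w$ =
insole width). Pooling both feet therefore amounts to evaluating right
recordings against the left layout; `mirror_layout()` (an exact
involution) provides the reflected geometry when right-foot coordinates
are needed explicitly.

## Preprocessing and gait segmentation

Raw recordings may contain dropouts (`NA`). Two fills are applied in a
fixed order:

1. **gap-limited linear interpolation** (`interpolate_missing()`, limit
   5 frames = 50 ms): internal runs up to the limit are linearly
   bridged; longer or edge runs are left missing;
2. **zero-order hold** (`hold_no_contact()`): whatever interpolation
   could not recover repeats the last valid value, with leading gaps
   set to 0 (no contact observed yet).

Interpolation runs first because it is the more informative fill; the
hold is the fallback. Both operations are idempotent and never touch
observed samples. The order of the two fills, and the reading of
"no contact detected" as "still missing after interpolation", are
package design choices; the alternative order is obtainable by calling
the two functions explicitly.

A candidate step is a maximal run of frames with total force
$F(t) = \sum_i P_i(t) A_i$ **strictly above 15 N**, flanked on both
sides by at least one sub-threshold frame (a stance must be surrounded
by swing; recording edges do not qualify), lasting **at least 200 ms**
measured in whole frames (20 frames at 100 Hz). The candidate is
retained only if the full-array CoP-X performs a physiological
heel-to-toe roll-over:

* first value in the posterior third ($< L/3$, $L$ = insole length),
* last value in the anterior third ($> 2L/3$),
* maximal backward excursion (running maximum minus current value)
  at most 5% of $L$.

Strict monotonicity would reject virtually every real (noisy) signal;
the bounded-excursion rule is the package's operationalization of
"monotone progression", with the tolerance (`regression_tolerance`,
default 0.05) exposed as a parameter. Finally the first and last
retained steps of each recording are discarded
(`crop_steady_state()`), removing gait initiation and termination.

## Exhaustive search and metrics

All $2^{16} - 1 = 65{,}535$ non-empty subsets are evaluated — the full
set is included as the zero-error reference row, which reconciles a
subset count of $2^{16}-1$ with optimization over $k = 1..15$.
`evaluate_all()` precomputes the per-frame moment triples $P_i A_i$,
$P_i A_i x_i$, $P_i A_i y_i$ once and reduces them per subset with
chunked matrix products (2,048 subsets per block, ~65 MB peak per
block); the result is identical, metric for metric, to a naive
per-subset loop, which the tests verify on small arrays where the loop
is affordable.

Errors are pooled over **all retained frames of all recordings** in one
computation (not averaged per subject), per axis and as the per-frame
Euclidean distance, so the Pythagorean identity
$\mathrm{RMSE}_{XY}^2 = \mathrm{RMSE}_X^2 + \mathrm{RMSE}_Y^2$
holds exactly on a shared frame set. P95 is the 95th percentile of the
per-frame absolute (or Euclidean) error, with the linear-interpolation
definition (type 7) — the convention is a package choice, stated here
because percentile definitions differ across software.

**Zero-denominator frames.** A subset whose members carry no load in a
frame ($\sum P_i A_i < \varepsilon$, $\varepsilon = 10^{-12}$ N)
cannot define a barycenter. Two policies are implemented:

* `hold_last` (default): repeat the last valid estimate, flag the frame
  `substituted`. Small subsets then produce finite (large) errors
  rather than silently dropping their hardest frames, which keeps the
  $k \le 3$ part of the convergence curve honest;
* `exclude`: mark the frame invalid and drop it from the metrics.

The fraction of frames *not* needing fallback is reported as
`coverage` for every subset, so the two policies can be compared.

Per size $k$ and target (X, Y, XY), `best_per_k()` selects the
metric-minimizing subset; exact ties resolve to the lexicographically
smallest sorted id tuple, making the argmin total and the whole search
deterministic.

## Downstream analyses

* **Marginal gains** (`marginal_gains()`): $g(k) =
  \mathrm{best}(k{-}1) - \mathrm{best}(k)$ for $k \ge 2$; the gains
  telescope to $\mathrm{best}(1) - \mathrm{best}(16)$. The *inflection
  point* is reported as the smallest sufficient count: the smallest $k$
  whose $k \to k{+}1$ transition gains less than the threshold
  (default 1.5 mm). For a constant curve this is the first size; if no
  gain falls below threshold it is `NA`.
* **Selection frequency** (`selection_frequency()`): per sensor and
  target, the number of sizes $k \in 2..15$ whose optimum contains the
  sensor. Raw counts are exported; normalization is left to
  presentation.
* **Cross-performance** (`cross_performance()`): all three RMSE
  metrics for each target-optimal layout at a fixed $k$, exposing the
  trade-off between axis-specific and global optimization; by
  construction each row minimizes its own target column.
* **Error maps** (`spatial_error_map()`): mean absolute error binned
  by the *reference* CoP position on a 40 × 20 grid over the bounding
  box (resolution chosen to resolve heel/forefoot structure at
  ~7 × 5 mm cells; configurable). Empty cells are `NA`, distinct from
  zero error; the 99th percentile of the per-frame errors is attached
  as a display clip value. The frame-count-weighted mean of occupied
  cells equals the overall mean absolute error.

## The synthetic gait generator

No public dataset accompanies the study design this package targets,
so `simulate_recording()` provides a seeded stand-in with the
structural features the pipeline depends on:

* stance/swing alternation (defaults 0.6 s / 0.4 s, a typical
  self-selected cadence) at 100 Hz;
* sequential heel-to-toe loading: each zone (rearfoot, midfoot,
  forefoot, toes) is driven by a raised-cosine pulse over a stance
  fraction window (defaults 0–0.45, 0.15–0.65, 0.35–0.90, 0.55–1.00),
  with within-zone onsets staggered by centroid position (posterior
  sensors load first) plus ±0.02 per-sensor jitter — the simplest
  smooth model that yields ordered per-sensor peaks and a monotone
  CoP-X roll-over;
* amplitude calibration: the noise-free peak total force is scaled to
  `body_weight` (default 700 N), with ±10% per-sensor variation; the
  per-zone relative amplitudes (1.4 / 0.9 / 1.2 / 0.8) are plausible
  fixtures, not calibrated values — no per-sensor magnitudes exist to
  calibrate against;
* additive Gaussian noise on loaded samples (0.3 N·cm$^{-2}$, clipped
  at zero) and independent per-sample dropout (probability 0.01,
  encoded `NA`) to exercise the interpolation path;
* anomaly modes, each producing one step that segmentation must
  reject: `shuffle` (rearfoot-only loading — fails roll-over),
  `short_contact` (150 ms — fails duration), `low_force` (peak ~10 N —
  fails threshold).

With `anomaly = "none"` every simulated stance passes both
segmentation criteria, so seeded fixtures have known step counts;
identical configurations are bit-identical.

**What the generator does not emulate** — and hence what green tests do
*not* establish about real data: subject-specific pressure
distributions and anthropometric variation, midfoot kinematics and
arch collapse, speed- and task-dependence, left/right asymmetry,
sensor hysteresis and calibration drift. Tests on synthetic data
validate the *machinery* (segmentation logic, search correctness,
metric definitions), not clinical error magnitudes; the bundled layout
geometry is likewise a clearly-labelled synthetic stand-in, since no
manufacturer coordinates are public.

## Numerical choices and degenerate inputs

* $\varepsilon = 10^{-12}$ N for the zero-denominator test, far below
  any physical load but above accumulation noise;
* run duration in whole frames; force threshold strict ($> 15$ N);
* fewer than three detected steps leave an empty steady-state set;
* subsets with no valid frame at all get `NA` metrics and are excluded
  from argmins (`compute_cop()` raises an error instead, since a
  single-subset call has no table to be `NA` in);
* type-7 percentiles; MD5 manifests for pipeline reproducibility;
* the layout file is YAML with explicit units in the field names
  (`x_mm`, `area_cm2`); recordings are plain CSV with empty fields for
  missing samples — inspectable and losslessly round-tripping.

## Problem sizes

The shipped analysis (`analysis/01..04`) simulates 12 subjects × 12
steps (10 steady-state each), pooling ~6,500 stance frames, and sweeps
all 65,535 subsets in a few minutes on one core. The test suite uses
smaller cohorts (4–10 steps, toy arrays of 4–8 sensors for
brute-force comparisons ~500 frames) and one full sweep over ~1,800
frames for the planted-subset recovery check; `scripts/acceptance.R`
re-runs the headline computations on a 4-subject cohort (~2,200
pooled frames). These sizes are the package's reporting choices and
scale linearly in frames.

## Known limitations

The reference is the full array itself, so errors measure information
lost to sparsification only. RMSE over the whole stance weighs long
phases (midstance, propulsion) more than brief transients (heel
strike); a transient-focused weighting would likely select different
layouts. Results on synthetic gait demonstrate correctness of the
pipeline, not recommended hardware layouts; with real recordings the
same code answers the hardware question directly.
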