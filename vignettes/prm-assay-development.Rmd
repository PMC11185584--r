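---
title: "Building scheduled PRM assays from DIA chromatogram libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building scheduled PRM assays from DIA chromatogram libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prmflow)
```

## The problem

Targeted proteomics by parallel reaction monitoring (PRM) trades coverage
for precision: the instrument repeatedly fragments a scheduled list of
peptide precursors and records full product-ion spectra for each. Two
constraints cap how many peptides one assay can carry. First, the duty
cycle: every concurrent target costs one MS2 scan per cycle, and the cycle
must stay short enough to sample each chromatographic peak several times
(six points per peak is the conventional quantification floor). Second,
chromatographic drift: scheduling windows must be wide enough that a peak
does not escape its window as the column ages, and every minute of window
width multiplies concurrency.

`prmflow` implements the workflow that turns a deep DIA chromatogram
library (typically acquired by gas-phase fractionation, GPF) into a
schedulable, quality-filtered PRM assay, simulates the real-time
retention-time alignment that makes narrow windows safe, and computes the
matrix-matched calibration-curve figures of merit used to qualify the
resulting assay.

## The duty-cycle model

The cycle time is set by chromatography and the desired sampling density:

$$t_\mathrm{cycle} = \frac{w}{p}$$

with $w$ the expected base peak width (seconds) and $p$ the points per
peak. A 12.9 s peak at 6 points per peak gives a 2.15 s cycle. Each
target's scan costs

$$t_\mathrm{target} = \frac{m_\mathrm{hi} - m_\mathrm{lo}}{r} +
\frac{t_\mathrm{inj} + t_\mathrm{isd}}{1000}$$

seconds, where $r$ is the analyzer scan rate in Th/s (a linear ion trap
scanning 200-1500 Th at 125,000 Th/s sweeps in 10.4 ms), $t_\mathrm{inj}$
the minimum injection time and $t_\mathrm{isd}$ the inter-scan overhead in
ms. The sustainable concurrency is
$\lfloor t_\mathrm{cycle} / t_\mathrm{target} \rfloor$:

```{r}
params <- acquisition_params()  # 125 kDa/s, 200-1500 Th, 15 ms, 6 pts, 12.9 s
c(cycle = round(compute_cycle_time(12.9, 6), 2),
  per_target = per_target_time(params),
  capacity = capacity(params))
```

Instruments with dynamic maximum injection time are modeled at the fixed
minimum target injection time, which is conservative: real cycles can only
be faster. The default 2 ms inter-scan overhead is hardware dependent and
configurable.

## Precursor quality filtering

A library precursor is worth targeting when it carries enough signal
(summed transition area), elutes as a well-formed peak (base width inside
a plausible range), and has at least three transitions that co-elute free
of interference. "Interference-free" is operationalized as a Pearson
correlation of at least `coelution_r_min` (default 0.9) between the
transition's chromatographic trace and the pointwise median trace of all
transitions of that precursor, after linear resampling onto the union time
grid; a co-eluting contaminant changes a transition's shape and
decorrelates it. When traces are unavailable the package falls back to a
weaker relative-intensity test (observed area fraction within a factor of
the library-expected relative intensity, default 3), and flags that it did
so. Both criteria are provided because published filtering tools do not
document a formula; correlation is the default.

The default thresholds (area >= 500, width 5.2-45 s, >= 3 clean
transitions) are the ones appropriate for an ion-trap-derived CSF library;
an Orbitrap-derived library typically uses a higher area floor and a
tighter width ceiling (1000, 5.2-26.1 s). The boundary span is treated as
the base peak width throughout; it is not a full-width-at-half-maximum.

Replicate-based refinement (`refine_by_replicate_cv()`, total-ion-current
normalized percent CV below 30 across triplicates) and calibration-based
refinement (`refine_by_curve_performance()`, CV under 20% and observed
ratio within 50% of expected) implement the second-pass rules used to
shrink a survey assay into a robust small assay. All CVs use the sample
(n-1) standard deviation.

## Window scheduling

Every precursor gets a window of at least `min_window` minutes (0.75 by
default) centered on its reference retention time — itself the median of
the transition apexes, which one interfered transition cannot drag. The
published tooling "optimizes" window widths without stating the algorithm;
this package's documented stand-in is symmetric greedy growth: windows
widen in 0.05 min increments, processed in ascending retention-time order
with ties broken by peptide string, in round-robin passes, each precursor
stopping when growth anywhere would push concurrency past capacity, exceed
`max_window`, or leave the gradient. The procedure is deterministic, and
feasibility is always reported against the exact event-point concurrency
profile; the test suite cross-checks it against a brute-force 0.1 s grid
sweep.

When a library exceeds capacity there are two outs. `select_targets()`
drops precursors greedily — by clean-transition count then area for the
`max_precursors` objective, or protein-fair round robin (quota first, then
priority overflow) for `max_proteins`. `split_injections()` instead
partitions the library into the fewest first-fit injections, each
individually feasible. The first-fit heuristic (ascending retention time,
first injection that stays feasible) is simple and deterministic; it makes
no optimality claim. `wide_to_narrow_reschedule()` implements the
two-stage pattern of scheduling wide (e.g. 2.4 min) windows first, then
re-centering narrow windows on the apexes actually observed.

## Real-time adaptive retention-time alignment

The alignment scheme embeds a compressed reference of a prior DIA run —
here, per wide isolation window (twelve 50-Th windows over precursor m/z
400-1000 by default), fragment intensities binned to `bin_width` Th,
resampled to a uniform retention-time grid, and L2-normalized — and
compares incoming DIA cycles against it during the run. The vendor's
compression and scoring are proprietary; this package's documented analog
scores candidate reference positions within a ±2 min search band by mean
cosine similarity across windows, accepts the best candidate as an anchor
pair (reference time, observed time) unless the score is below 0.2, and
maintains a monotone reference-to-observed mapping by weighted
pool-adjacent-violators over the anchors, with anchor weight decaying over
a 5 min horizon so the map can follow nonlinear drift. Near-tied scores
resolve to the candidate nearest the current prediction: while a single
peptide elutes alone, its normalized spectrum is the same at every point
of its own elution, so similarity is genuinely uninformative there and the
prediction is the only evidence available.

The active target set is refreshed 3.5 times per peak width (the grid step
defaults to the same cadence, ~3.97 s for 13.9 s peaks), and a target is
active when the current time falls inside its warped window.
`simulate_run()` replays a library through a known warp and logs, per
target, whether the apex fell inside an active window and how many
sampling cycles landed across the peak base, which is how the package's
claims about adaptation are tested: identity warps must recover zero shift
to within one grid step, smooth +1 min drifts must be tracked to a mean
absolute error within two grid steps after a 10% burn-in, and adaptive
capture must dominate static capture on drift fixtures where static
0.75 min windows provably miss late peaks.

## Calibration-curve figures of merit

Matrix-matched calibration curves dilute the study matrix (human CSF or
plasma) into a surrogate (chicken serum or plasma) over a 13-point
volumetric ladder from 100% down to 0.1%, in triplicate, so that analytes
dilute while background stays constant. Figures of merit per precursor:

* **CV per level**: percent sample CV of summed selected-transition areas
  across replicates.
* **Accuracy**: log2 ratio of the mean summed area at each level to the
  undiluted mean; expected `log2(level/100)` for a linear response.
* **LOD**: the change point of a two-segment fit of mean area versus
  level — a constant noise floor below, a straight line through the origin
  above, chosen by grid search over the levels minimizing `1/y^2`-weighted
  squared error. The zero intercept reflects the design of the curve (zero
  human fraction means zero analyte signal); it also prevents constant
  co-eluting interference from being absorbed as an intercept, which would
  collapse the change point to the lowest level. The relative weighting
  keeps the undiluted levels, orders of magnitude more intense, from
  swamping the floor region. A fit whose slope is non-positive or
  statistically indistinguishable from zero is reported as the `Inf`
  ("not quantifiable") sentinel.
* **LOQ**: the smallest level at or above the LOD with CV at most 20%
  where every smaller tested level failed the CV bound or sat below the
  floor. The 20% gate is configurable; it is the bound used throughout
  assay qualification.
* **Transition optimization**: greedy backward elimination from the full
  transition set, removing whichever transition most improves the LOQ
  (ties remove the lower-area one), stopping at no improvement or three
  transitions. The result can never quantify worse than the full set.

The LOD/LOQ procedure is this package's concrete operationalization — the
literature it descends from defines the limits through related piecewise
fits and bootstrap intervals — and is validated by parameter recovery on
synthetic curves with known change points rather than by comparison to an
external implementation.

Integration-boundary propagation (`propagate_boundaries()`) mirrors the
practice of trusting only the undiluted samples' peak boundaries: each
dilute run's boundaries are the reference boundaries shifted by that run's
median apex offset over high-abundance anchor precursors, and areas are
re-integrated inside the mapped boundaries when traces are available (the
trace is clipped at the exact boundary positions so no partial grid slice
is lost).

## What the synthetic data does and does not emulate

All validation rests on `generate_library()`,
`generate_dilution_series()` and `generate_warped_run()`. Choices, made
once:

* **Gaussian peaks** (sigma = base width / 4, boundaries at ±2 sigma).
  Analytic truth for areas, apexes and widths is then exact, which the
  oracles need. Real peaks tail; nothing here tests robustness to tailing.
* **Scale presets**: "csf" (~2,300 precursors, 13.9 s mean width, 30 min
  gradient) and "magnet" (~3,500 precursors, 10.5 s peaks) mirror the two
  target applications; unit tests run a "small" preset for speed.
* **Dilution noise**: 10% CV run-level multiplicative noise shared across
  a precursor's fragments (injection effects move all transitions
  together), a 5% independent per-fragment component, and a per-precursor
  noise floor drawn log-uniformly between 0.3% and 10% of the undiluted
  signal with 35% CV. Below its floor a precursor's measured area *is*
  the floor: the analyte peak is lost in background and integration
  returns background. The mean response is therefore a flat-floor/linear
  hinge, matching the model the estimator fits; the floor fraction's
  range places true change points across the lower half of the ladder.
* **Constructed interference** (for the optimization tests): the largest
  transition of a contaminated precursor becomes contaminant-dominated
  below the undiluted level, with independent 80%-scale log-normal noise,
  because a contaminant from an unrelated co-eluting analyte does not
  share the target's run effects.
* **Drift**: run-to-run offsets are N(0, 0.05 min); warps for the
  alignment tests are smooth monotone functions reaching +1 min at
  gradient end, the scale of drift the alignment is designed to absorb.

Passing tests on these fixtures demonstrates that the algorithms recover
what they claim under Gaussian, interference-structured, smoothly
drifting conditions at realistic sizes. They do not demonstrate
robustness to peak tailing, detector saturation, charge-state crosstalk,
or abrupt (non-smooth) retention-time jumps.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run: 50 random libraries of
60-500 precursors against the brute-force duty-cycle oracle; 100 random
threshold pairs for filter monotonicity; ~100-precursor alignment
simulations (about 450 cycles of 12 windows × 1300 bins); and
~100-precursor calibration curves (13 levels × 3 replicates). These sizes
exercise every code path at the scale of the real assays' building blocks
while keeping a full run in minutes.

Degenerate inputs are handled explicitly: zero-variance traces score `NA`
and count as interfered; single-transition precursors count zero clean
transitions; empty reports produce empty libraries with a warning, and
malformed rows are collected with line numbers rather than dropped
silently; a reference map with an empty grid cannot be saved; truncated
or version-mismatched reference files fail without producing a partial
object; per-target times exceeding the cycle give capacity zero with a
warning. Window coordinates are rounded to 1e-6 min when plans are built
so target lists round-trip byte-identically. Reported cycle times are
rounded to 0.01 s for display only; scheduling uses full precision.

## Known limitations

* The window-growth and injection-splitting heuristics are greedy and
  deterministic, not provably optimal.
* The alignment stand-in claims no equivalence with the vendor's
  on-instrument implementation; it reproduces the behavior class (binned
  50-Th reference, cosine scoring, 3.5-per-peak-width updates, monotone
  warp) well enough to study scheduling consequences.
* Figures of merit are relative (dilution percent); absolute
  quantification with stable-isotope standards is out of scope, as are
  cohort-level differential-abundance statistics.
* The duty-cycle model ignores automatic gain control and ion statistics;
  capacity is a scan-time argument only.
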