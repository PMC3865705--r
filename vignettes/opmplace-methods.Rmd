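---
title: "Place-cell analysis for the object place memory task: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Place-cell analysis for the object place memory task: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opmplace)
```

## The problem

In the object place memory (OPM) task a rodent first explores an empty,
familiar square arena (familiarization trial T1, 15 min), then the same arena
with two identical objects placed at quadrant centers (sample trial T2,
5 min), and finally the arena after one object has been moved to the adjacent
quadrant center (choice trial T3, 5 min), with 10-min delays between trials.
Healthy animals preferentially explore the displaced object on T3; this bias
is abolished by systemic NMDA-receptor antagonists such as CPP when given
before the sample phase. In parallel, hippocampal CA1 pyramidal cells behave
as *place cells* — each fires within a restricted region of the arena, its
*place field* — and the question is how their spatial code responds to object
introduction and displacement, and which of those responses require NMDAR
activation.

`opmplace` implements the full analysis chain for such experiments: from
position tracks and spike timestamps to rate maps, spatial-coding metrics,
unit-class dynamics across trials, behavioral discrimination indices, and a
normality-gated statistical comparison scheme. Because raw tetrode recordings
of this kind are rarely shared, the package also contains a first-class
synthetic-session generator with known ground truth, which is what all
recovery tests run on.

## Rate maps

The arena (default 40 cm square) is discretized into a 20 × 20 grid of 2-cm
pixels. Binning is half-open — `[i·bin, (i+1)·bin)` with the last bin closed
and the south-west corner at the origin — so pixel identities are exactly
reproducible: a sample on an interior bin edge belongs to the higher bin.

Each 30-Hz video frame contributes one frame period of dwell to its pixel;
each spike is assigned to the pixel of its temporally nearest frame (a spike
exactly midway between frames goes with the earlier frame; the 33-ms frame
period is far below behavioral timescales, so the assignment rule is
immaterial in practice but must be fixed). The per-pixel rate is spike count
over dwell time. Pixels occupied for less than 0.1 s are excluded outright:
they carry no rate value, and any between-trial metric is restricted to the
pixels valid in *both* trials.

Maps are smoothed with a Gaussian kernel of radius 2 bins (5 × 5 support,
σ = 1 bin). The kernel weights are renormalized over the valid pixels under
the kernel, so invalid pixels neither receive nor contribute values, a
constant map is a fixed point, and positivity is preserved. A 3 × 3 variant
(radius 1) is available through `gaussian_kernel(1, sigma)` for workflows
that prefer the smaller support. Exclusion happens *before* smoothing — the
alternative order is not distinguishable from published descriptions of this
style of analysis, and excluding first avoids manufacturing rate values in
pixels that were never reliably sampled. All downstream metrics (information,
fields, centers of mass, similarity) operate on the smoothed map; raw maps
remain available from `rate_map_set()`.

## Spatial metrics

**Peak and mean rate.** Maximum and occupancy-weighted mean rate over valid
pixels. The occupancy weighting makes the mean equal to total spikes over
total dwell on the valid support, exactly.

**Spatial information.** The Skaggs information rate
$I(R\mid X) = \sum_i p_i\, f_i \log_2 (f_i / F)$, with $p_i$ the occupancy
probability of pixel $i$, $f_i$ its rate, and $F = \sum_i p_i f_i$, using the
$0\log 0 = 0$ convention. The sum is an information *rate* (bits/s); the
headline value is bits per spike (rate divided by $F$), the unit in which
place-cell information content is conventionally reported. Both are returned.
SI is a scaled Kullback–Leibler divergence, hence nonnegative, zero exactly
for spatially uniform firing, and undefined for a silent unit (an error, not
a zero).

**Place field.** The set of 4-connected (edge-sharing) pixels with rate at or
above 10% of the unit's peak that contains the peak pixel, accepted only when
it spans at least 8 pixels; suprathreshold blobs that do not contain the peak
are discarded. Field size is pixel count × 4 cm². The relative threshold
makes field size invariant to rescaling the map. All boundary rules here and
below are inclusive as stated: ≥ 10% of peak, ≥ 8 pixels, ≥ 3 Hz, ≥ 7 cm,
≥ 250 μs.

**Center of mass.** Rate-weighted mean of pixel-center coordinates. The
default scope is field-restricted when a field exists (robust to background
pixels and matching the idea of "the place field's COM"), falling back to the
full valid map otherwise; the scope used is recorded with each value. The COM
shift between trials is the Euclidean distance between the two COMs computed
on the common valid mask, with the displacement kept as a 2-D COM vector.

**Similarity.** Pearson correlation of the two smoothed maps' rates over the
common valid pixels; undefined (NA with a reason code) when a map is constant
on the mask or fewer than 3 pixels remain. Smoothed maps are the default
input; raw maps can be passed explicitly.

**Unit screening.** Units with a clear refractory gap in their
autocorrelogram are putative pyramidal cells when the peak-to-trough spike
width is ≥ 250 μs, putative interneurons when narrower, and rejected
otherwise (or when no waveform metadata exists). The package takes the
width and gap as metadata; it does not compute autocorrelograms from raw
trains.

## Unit dynamics across trials

A unit is *active* in a trial when its peak rate is ≥ 3 Hz, *inactive*
otherwise; this boundary separates a low-information sub-population in real
recordings. Across each transition (T1→T2, T2→T3) the four classes —
active/active = **active**, inactive/active = **emerging**, active/inactive =
**vanishing**, inactive/inactive = **inactive** — are exhaustive and
disjoint, and each transition is classified independently (a unit may emerge
at T2 and vanish at T3). Active units are further split by COM shift into
**stable** (< 7 cm) and **unstable** (≥ 7 cm).

The **vector index** compares the field's COM displacement with the object's
20-cm displacement: it is the magnitude of the *vector* difference
$\lVert \vec{m} - \Delta\vec{c}\rVert$, not a difference of lengths. Only
this reading makes a null index equivalent to the field moving along the same
vector as the object — a length difference of zero would also be produced by
a 20-cm COM move in any direction. The index is translation-invariant and
obeys the triangle bounds
$\bigl|\,\lVert\vec m\rVert - \lVert\Delta\vec c\rVert\,\bigr| \le
\text{VI} \le \lVert\vec m\rVert + \lVert\Delta\vec c\rVert$.
`object_vector_analysis()` correlates the index with the T2 distance to the
moving object, separately for stable and unstable units.

## Behavior

Object visits are maximal runs of frames with the nose inside an object's
circular zone. The 6.5-cm zone diameter is treated as derived — object base
diameter (4.5 cm) plus twice the 1-cm snout-proximity threshold — and is
recomputed from the layout so non-default objects scale correctly.
Overlapping zones are rejected as ambiguous. No minimum episode duration is
imposed by default (one frame suffices), configurable via
`min_episode_frames`.

Two sample-trial ratio conventions exist in the literature and they are
genuinely different quantities: the quotient form $R/(L+R) \in [0,1]$ and the
discrimination form $(R-L)/(L+R) \in [-1,1]$. Published group means for this
index are sometimes negative, which only the discrimination form can produce,
so that form is the headline here and both are returned. The choice-trial
**OPM ratio** is $(\text{moved}-\text{stable})/(\text{moved}+\text{stable})$,
positive when the displaced object is preferred, and antisymmetric under
swapping the two roles.

Percent time moving thresholds instantaneous frame-to-frame speed at 2 cm/s,
a standard rodent immobility cutoff; the threshold is a parameter because no
single value is canonical.

## Statistical scheme

Every two-group comparison passes through a normality gate: Shapiro–Wilk on
each sample at α = 0.05 (the gate level is configurable); if both samples
pass, a two-sample Student's t-test with mean ± s.e.m. descriptives,
otherwise a nonparametric test with median ± IQR descriptives. The
nonparametric branch is a configuration choice between the two-sample
Kolmogorov–Smirnov test (default for large continuous metric sets) and the
Mann–Whitney U test (preferable at small n); the test actually used is
recorded in every result. Class frequencies between groups are compared with
Pearson's chi-square *without* continuity correction, so the statistic equals
the textbook $\sum (O-E)^2/E$; zero expected counts are an error with advice
to merge classes. No multiple-testing correction is applied, matching common
practice in this literature; the pipeline log reports how many tests were
run so readers can judge. The gate's empirical type-I error at n = 30 per
group is checked by simulation in the test suite (2000 null repetitions;
nominal 0.05).

## The synthetic-session generator

The generator exists so that every downstream stage has a testable ground
truth. What it emulates, and how:

* **Locomotion** — a persistent random walk: slowly diffusing heading,
  Ornstein–Uhlenbeck-like speed relaxation, reflective walls with a steering
  term that turns the heading toward the arena center inside a 3-cm wall
  margin, and a two-state move/pause process (per-frame switch probabilities
  0.01 and 0.02, i.e. about two thirds of time moving, in the range reported
  for mice in such arenas). `mean_speed` (default 5 cm/s) targets the
  *overall* mean speed including pauses; the moving-state speed is scaled up
  by the expected moving fraction. Trajectories are sampled at 30 Hz, and a
  900-s walk covers every quadrant (each holds well above 5% of samples).
  No published locomotion statistics beyond percent time moving exist for
  this paradigm, so these are realism choices, not calibrated claims.
* **Dwell bias near objects** is available (`object_bias_gain` slows the
  walk inside object zones) but off by default, so behavior and spiking
  analyses stay independently testable.
* **Tuning** — circular Gaussian bumps,
  $\lambda(p) = b + (a-b)\,e^{-d^2/2\sigma^2}$. Active units draw peaks from
  3 Hz + a lognormal (median ≈ 6 Hz above the boundary) and σ from 3–5.5 cm;
  inactive units draw sub-3-Hz peaks, reproducing the active/inactive
  bimodality. Baselines are a small fraction of peak (at most 5%, capped at
  0.3 Hz): out-of-field rates of real pyramidal cells are far below the 10%
  field threshold, and a baseline near that threshold would make the
  detected field leak across the background, leaving the tuning center
  ill-defined as ground truth. Centers keep a `max(4, 1.5σ)` cm wall margin
  for the same reason: a wall-clipped Gaussian has a genuinely displaced
  centroid. Real CA1 data *does* contain wall and boundary fields — passing
  recovery tests on this generator therefore says nothing about estimator
  behavior for truncated fields.
* **Spiking** — inhomogeneous-Poisson thinning of a homogeneous process at
  the tuning's maximum rate, with positions looked up at the nearest frame.
  Time-rescaling of simulated trains is verified against unit-rate
  exponential intervals in the tests. No burstiness, theta modulation, phase
  precession, or refractoriness is modeled.
* **Across-trial dynamics** — each unit samples a class per transition
  (stable, unstable, emerging, vanishing, inactive) from configurable
  probability vectors; defaults echo published cohort compositions (~59%
  active with ~20% emerging on T1→T2; ~67% active with few emerging on
  T2→T3). T2→T3 probabilities are renormalized over the classes consistent
  with the unit's activity state at the end of T2. Unstable units displace
  their tuning center by 8–14 cm; on T2→T3 the default rule mirrors the
  object-vector observation — units whose T2 center lies within 12 cm of the
  moving object follow the object's displacement vector, farther units move
  against it (±1 cm jitter) — so a positive vector-index/T2-distance
  correlation in unstable units is recoverable ground truth.
* **Condition effect** — the CPP perturbation multiplies σ by 1.8, attenuates
  the above-baseline peak by 0.8, and pulls tuning centers 40% of the way to
  the arena center. These defaults were set once from the qualitative
  published pattern (a roughly threefold field-*area* difference implies
  roughly 1.8-fold in σ; COM-to-center medians of ≈ 4 vs ≈ 7 cm imply a pull
  near 0.4) and are not fitted to anything. SAL is the identity by
  construction.
* **Reproducibility** — one named RNG substream per component (trajectory,
  unit assignment, spiking), all derived from the session seed; changing the
  number of units does not perturb the trajectories, and the same seed
  reproduces the dataset byte-for-byte through the CSV writers.

## Problem sizes and numerical choices

The recovery analyses in the tests and the acceptance script use cohorts of
25 units (900-s T1) for tuning-center and rank recovery, 200 units for
class-frequency recovery against exact binomial 99% intervals, 80 units for
the object-vector correlation, and 2000 repetitions for the gate
calibration; these sizes put binomial/correlation sampling error comfortably
inside the tested bands while keeping a full run around a minute. Ties are
resolved deterministically everywhere: spike-to-frame ties go to the earlier
frame, peak-rate ties to the first pixel in column-major order, and
equidistant objects are reported as a shared-distance tie. Degenerate inputs
are distinguished deliberately: an all-zero map has *no field* (`NULL`) but
a silent unit's SI is an *error*; a map with no valid pixels is an error
rather than an all-zero map; a constant map's similarity is NA with a reason
code.

## A worked example

```{r example, eval = FALSE}
ses <- generate_opm_session(n_units = 25, seed = 1)
rep <- analyze_session(ses)
head(rep$unit_trial)
subset(rep$cohort, transition == "T1_T2")
rep$behavior$opm_ratio
```

## Limitations

The generator's trajectories have no thigmotaxis beyond wall avoidance, its
units have single circular fields with no directional or speed tuning, and
its CPP effect is a smooth parametric caricature. The analysis side computes
no sparsity/coherence, no multi-field inventories beyond the peak-containing
field, and no autocorrelograms from raw spike trains (the unit screen takes
waveform metadata as input). Group-level values published from real tetrode
recordings are not reproduction targets for synthetic cohorts; what the test
suite establishes is that the estimators recover known ground truth under
the generator's assumptions and that every formula agrees with independent
brute-force oracles.
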