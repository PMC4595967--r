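---
title: "Methods: location-specific firing and lap-by-lap co-fluctuation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: location-specific firing and lap-by-lap co-fluctuation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cofluct)
```

This vignette documents the statistical model behind `cofluct`, the meaning
and defaults of every tunable parameter, the design decisions taken where
the procedure admits more than one reasonable reading, what the synthetic
generator does and does not emulate, and the package's numerical
conventions. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. From tracking to running epochs

Input tracking is a ~33-Hz series of (x, y, head direction) samples. The
track is described as a piecewise-linear path; each sample is projected to
its nearest point on the path and expressed as an arc length `s` in
`[0, L]` (default L = 300 cm). The two *trajectories* are the two directed
traversals; on the return direction positions are reported as `L − s`, so
the `pos` coordinate always increases in the running direction and the two
directions are analyzed independently throughout.

**Lap rule.** A lap is one complete food-well-to-food-well traversal. The
start is the *last* sample inside the departure well zone (within
`well_margin_cm = 10` of a track end) and the end is the *first* sample
inside the opposite zone. Turn-arounds that fail to reach the far well are
discarded entirely. This rule is a design decision: with reward delivered
only after a full end-to-end run, partial excursions are not task laps, and
anchoring the boundaries at the zone edges makes the lap duration match the
time in which spikes can carry spatial information.

**Speed and mask.** Speed is the forward-differenced arc-length distance
over the sample interval; the last sample copies its predecessor (the data
define speed only between sample pairs, so some convention is required and
forward differences keep speed aligned with the interval a spike falls in).
A sample is *running* only if it is (i) inside a lap, (ii) outside the
10-cm well zones — a position criterion, deliberately independent of speed,
because reward consumption at the wells produces slow but position-stable
samples — and (iii) not inside a stopping interval, i.e. a maximal run of
samples below `speed_floor_cms = 6` spanning at least `stop_min_s = 0.5`.
Brief decelerations shorter than 0.5 s are retained. Every downstream rate
estimate uses running samples only, and only spikes whose enclosing sample
is running.

## 2. Rate curves and spatial tuning statistics

Each trajectory is divided into `bin_cm = 2` cm bins (`N = ceil(L/2)`,
half-open `[2k, 2k+2)`, final bin closed). Occupancy `t_i` accumulates the
sample periods of running samples per bin; spike positions are linearly
interpolated between the two enclosing tracking samples (spike timing is
much finer than 33-Hz tracking) and binned identically. The raw rate is
`x_i = counts_i / t_i`; unvisited bins get rate 0 and are excluded from the
occupancy distribution. Curves are smoothed with a Gaussian kernel of
`smooth_sigma_bins = 2`, truncated at ±4σ and renormalized at the track
ends — the ends are physical boundaries, so neither reflection nor
wrap-around is meaningful. Per-lap curves are computed the same way within
a single lap.

Spatial information content and rate are the Skaggs estimators

    SIc = Σ_i p_i (x_i / r) log2(x_i / r)   [bits/spike]
    SIr = SIc · r                           [bits/s]

with `p_i = t_i / Σ t_i`, `r = Σ p_i x_i`, and `x log x → 0` at `x = 0`.
Whether these are evaluated on raw or smoothed curves is genuinely open;
the package evaluates them on the smoothed curve for consistency with the
smoothed rate-map convention, and exposes `use = "raw"` as a switch.
Spatial stability is the mean Pearson correlation between the smoothed
curves of all unordered lap pairs over occupied bins; lap pairs where
either curve has zero variance are skipped (Pearson is undefined there)
and counted.

Cells are *active* on a trajectory above `active_hz = 0.5` Hz of overall
running-epoch rate. CA1 cells above `interneuron_hz = 5` Hz are putative
interneurons and excluded; high-rate V1 cells are retained, since V1 rate
distributions do not separate into distinct clusters the way CA1
pyramidal/interneuron rates do.

## 3. The circular-shuffle null and the SMI

SIc and SIr depend on firing rate, so their values are not comparable
between populations with different rates. The spatial modulation index
removes that dependence by z-scoring each cell against its own chance
distribution: within each lap `[T1, T2]`, all spikes are shifted by a
single random interval `R ~ U(0, T2 − T1)` drawn independently per lap,

    P → T1 + ((P + R − T1) mod (T2 − T1)),

which preserves the lap's spike count and (up to one wrap point) its
inter-spike intervals while decoupling spikes from position. With
`n_shuffles = 100` shuffled SIc values of mean `m` and SD `s`, the index is
`SMI = (a − m)/s`; a cell is *location-responsive* when `SMI > 2.325`. The
cutoff is kept as the constant 2.325 — the 99th percentile of the chance
level as conventionally printed — rather than recomputed from
`qnorm(0.99) ≈ 2.3263`; the two differ by under 0.1% and keeping the
constant makes classifications reproducible to the letter. Cells whose
null SD is zero (e.g. near-empty trains) get a missing SMI and are not
responsive. Each cell's shuffle stream is seeded from
`(master_seed, cell_id, trajectory)` via a small string hash, so results
are reproducible and independent of cell ordering.

## 4. Firing fields

On the smoothed curve, the baseline is its 30th percentile
(`baseline_pct = 30`); the baseline-subtracted, zero-clipped curve is
scanned for local maxima exceeding both `peak_min_hz = 1` Hz and
`peak_baseline_frac = 0.2` of the baseline (for near-zero baselines the
1-Hz floor governs). Boundaries extend outward to the first bin at or
below `boundary_frac = 0.1` of the *subtracted* peak — interpreting "10% of
the peak" on the subtracted scale is a design decision; on the raw scale
the criterion can be unsatisfiable whenever the baseline exceeds 10% of the
peak. Fields separated by less than `merge_gap_cm = 4` merge as interval
unions keeping the larger peak, iterated to a fixpoint (interval-union
merging is order-independent, so the fixpoint is unique). Two local maxima
sharing one above-threshold region are one field. Detection runs on active
CA1 cells and on location-responsive V1 cells.

Field *distributions* are histograms of field-peak positions in the same
2-cm bins, smoothed with the same σ = 2 kernel, normalized by total field
count; their V1↔CA1 cross-correlogram is a sliding-lag Pearson correlation
over the overlapping support.

**Bidirectionality.** For a cell responsive on both directions, the
direction-2 curve is flipped into direction-1's physical coordinate and the
two curves are cross-correlated at 2-cm lags. The global correlogram peak
must lie within ±`bidir_window_cm = 50` and reach Pearson
`p < bidir_alpha = 0.00098` (0.05 Bonferroni-corrected for the 51 lags
tested). Sign convention: after flipping, a positive lag means the
direction-2 feature lies beyond the shared landmark along direction-1's
running direction, i.e. the cell fires *before* the landmark on both
runs — prospective; negative is retrospective. A cell constructed to fire
`d` cm before a landmark on both directions peaks at `+2d`. The global
peak is searched over the full lag range so that an out-of-window peak is
rejected rather than shadowed by a secondary in-window maximum.

## 5. Temporal cross-correlograms

For spike trains P (M spikes) and Q (N spikes) restricted to running
epochs, the count at lag ΔT is
`C(ΔT) = Σ_i #{Q ∈ [P_i + ΔT − B/2, P_i + ΔT + B/2]}` with
`B = xcorr_bin_ms = 10` ms, normalized by the expectation under independent
homogeneous Poisson trains of the same counts over the included time T:

    m = M · N · B / T,    C̃(ΔT) = (C − m) / √m.

A formulation of the normalizer sometimes printed as `m = M·N/B` is
dimensionally inconsistent when B is the bin width in seconds; `M·N·B/T` is
the unique reading that equals the expected Poisson coincidence count, and
the literal form remains available via `normalizer = "printed"` for
comparison. The correlogram spans ±500 ms; the significance peak is
searched within ±`xcorr_peak_window_ms = 200` ms and a pair is *highly
significant* above `xcorr_sig_threshold = 8`. Counting windows are closed
on both ends, which makes `C̃_PQ(ΔT) = C̃_QP(−ΔT)` exact. Q spikes are
counted wherever they fall relative to an included P spike (no edge
correction; the bias is second-order for 10-ms windows). The population
direction bias is an exact two-sided binomial test on the signs of the
nonzero peak times.

## 6. Pair classification and Δrate/ΔCOM co-fluctuation

Pairs of trajectory-active cells are classified per trajectory:

* **overlapping** — both location-responsive, some field pair overlaps by
  at least `overlap_min_frac = 0.5`, and the spike cross-correlogram has a
  peak ≥ 8 within ±200 ms (this second condition screens out pairs whose
  spikes mostly fall outside the shared field). Probed intervals: the
  overlapped field pair with the maximum sum of peak rates.
* **non_overlapping** — both responsive, no field pair overlaps by ≥ 50%.
  Probed: each cell's dominant (highest-peak) field.
* **non_responsive** — exactly one cell responsive; probed in its dominant
  field, while the other cell is probed in a copy of that field shifted by
  a seeded random distance yielding an overlap uniform in [50%, 100%]
  (shifts that would leave the track flip sign).

The overlap *denominator* is the shorter field's length — the strictest
symmetric reading of "overlapped by at least 50%" — and is configurable
(`overlap_denom = "longer"`). Responsive pairs that overlap spatially but
fail the correlogram criterion match neither the overlapping nor the
non-overlapping definition; they are returned as `unclassified` and
excluded from group summaries.

Within its probed interval each cell contributes, per lap, a firing rate
(in-interval spikes over in-interval running time) and a spike COM (mean
interpolated spike position). Δrate and ΔCOM are the deviations from the
across-lap means; Δ series therefore sum to zero over included laps.
Zero-spike laps are a real rate observation (rate 0) but have no defined
COM, so they enter Δrate and are dropped pairwise for ΔCOM. Pair
correlations are Pearson with two-sided p, computed only with at least
`min_laps = 10` paired laps (below that the p-value is unreliable; the
choice of 10 is a package convention).

**Behavioral residualization.** Per lap the covariates are the mean running
speed through the cell's probed interval and Δhdir, the lap's circular-mean
head direction minus the circular mean over laps, wrapped to (−180°, 180°].
Although head direction is circular, Δhdir is treated linearly in the
regression — deviations concentrate well within ±30°, where the linear
approximation is adequate. The modified series is the OLS residual of
`Δ ~ speed + Δhdir` (with intercept — the standard OLS practice, and the
intercept is what keeps residuals mean-zero); it has exactly zero sample
correlation with both covariates, so any co-fluctuation surviving it cannot
be a linear speed/heading artifact. Collinear covariates drop the aliased
term with a warning.

**COM shift.** For cells with ≥ 25 laps, the per-lap COM change is taken
relative to the cell's stabilized COM (mean over laps 21–25), averaged over
cells per lap, and summarized by the least-squares slope over laps 1–10 —
run on raw and on behavior-residualized COM series.

## 7. The synthetic generator: what it emulates, and what not

`simulate_session()` produces tracking and spikes with the statistical
structure the analysis assumes, plus full ground truth (lap boundaries,
per-lap gains and jitters, modulation coefficients, seed; identical seeds
give byte-identical sessions):

* **Kinematics** — alternating end-to-end runs on a four-corner C-shaped
  300-cm path at 33 Hz; 2-s food-well pauses; per-lap target speed
  `N(35, 3²)` cm/s with within-lap Ornstein–Uhlenbeck noise (SD 5 cm/s,
  τ = 1 s); optional scripted mid-track stops; head direction = movement
  heading + N(0, 3°) noise. Mean speed 35 cm/s and the 300-cm/33-Hz
  geometry are the study conditions; the speed-noise scales are chosen once
  as typical of rat track running.
* **Spiking** — inhomogeneous Poisson by Bernoulli thinning on the tracking
  grid (optionally refined, e.g. `refine = 30` gives ~1-ms resolution for
  cross-correlogram work — sub-sample timing matters only there). The rate
  is `clip0((baseline + gain_l · Σ_f peak_f · N(pos; center_f + jitter_l,
  width_f)) · (1 + c_speed (v − v̄)/v̄ + c_hdir Δhdir/30°))`. The 30° scale
  makes head-direction coefficients order-1 over the realistic Δhdir range.
* **Lap-wise latent structure** — per-lap multiplicative gain
  `max(0, 1 + gain_sd · z)` and additive COM jitter `jitter_sd · w`, with
  `(z, w)` latents correlated between designated pair members at the
  configured ρ. Defaults `gain_sd = 0.7`, `jitter_sd_cm = 3` reflect the
  large excess (super-Poisson) trial-to-trial variability place-field
  traversal rates are known to show; a cell may belong to at most one
  latent pair so that injected correlations remain interpretable.
  Probabilities `λ·Δt` are capped at 0.95 with a warning (error above 20%
  of in-lap samples, advising a finer grid).

The generator deliberately does **not** emulate theta rhythmicity or phase
precession, bursting, visual-scene structure, electrode drift, sorting
errors, or 2-D behavior. Passing tests therefore show that the estimators
recover the structure they target under clean Poisson assumptions — not
that real recordings satisfy those assumptions.

## 8. Numerical conventions and validation problem sizes

* Bin assignment `floor(pos/2)+1`, clamped; ties at bin edges go right
  (half-open bins), track end closed.
* Pearson correlations, their p-values, the exact binomial test and OLS come
  from `stats` (`cor`, `cor.test`, `binom.test`, `lm`); equation-form
  Pearson (population-SD normalization with the 1/N factor) equals `cor`
  exactly.
* Shuffle and simulator RNG draws run in isolated streams (the caller's
  RNG state is saved and restored); per-cell sub-seeds hash the cell id so
  cell order is irrelevant.
* Degenerate inputs are flagged, not silently dropped: zero-rate cells give
  missing SIc/SIr, zero null SD gives missing SMI, constant series give
  missing correlations, empty trains give a flagged empty correlogram.

The validation suite uses problem sizes chosen to give stable statistics at
desk scale: 200 null cells × 100 shuffles for SMI calibration; 50 pairs per
ρ at 50 laps with 20-Hz fields for gain-correlation recovery; 30 pairs per
class for the group contrast; 40 pairs per scenario for confound removal;
200 single-field cells for detector recovery. Oracle comparisons (Skaggs
summation, sliding Pearson, binomial tail sums) hold to 1e-12; the
independent shuffle-oracle match holds to 1e-10.

## 9. Known limitations

* The lap rule and the ≥ 10-lap minimum are package conventions where the
  underlying procedure is underdetermined; both are configurable.
* SIc/SIr on smoothed curves (the default) are slightly biased downward
  relative to raw curves; the SMI largely cancels this, since actual and
  shuffled values share the smoothing.
* The non-responsive probe interval is random by construction, so
  non-responsive group statistics carry extra seed-dependent variance.
* Field boundaries are bin-quantized (2 cm); peak positions are reported at
  bin centers, so localization error is bounded below by ±1 cm.
* The Δhdir regression is linear; sessions with large heading excursions
  (> ~45°) would need a circular regression instead.
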