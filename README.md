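# cofluct

Lap-by-lap co-fluctuation analysis of location-specific neural firing on
linear tracks.

## The problem

When a rat runs back and forth on a track, hippocampal CA1 place cells —
and, less obviously, many primary visual cortex (V1) neurons — fire at
specific track locations. Beyond the *average* spatial tuning, the precise
firing rate and firing location of a cell inside its field fluctuate from
lap to lap. If a V1 cell and a CA1 cell with overlapping firing fields
fluctuate *together*, that trial-by-trial "noise correlation" is evidence of
a functional coupling between the two regions that mean rate maps cannot
reveal.

`cofluct` implements the full analysis chain needed to make that inference
from tetrode recordings (position tracking at ~33 Hz plus per-cell spike
times), together with a ground-truth simulator so that every stage can be
validated without any recording:

1. **Behavior** — projection of (x, y) tracking onto a piecewise-linear
   track path, lap segmentation between food-well zones, running speed, and
   the active-running mask (speed < 6 cm/s for ≥ 0.5 s and the final ~10 cm
   at each track end are excluded).
2. **Rate maps** — occupancy-normalized firing rate curves in 2-cm bins,
   Gaussian-smoothed (σ = 2 bins), per lap and lap-averaged.
3. **Spatial tuning statistics** — Skaggs spatial information content
   (bits/spike) and rate (bits/s),

   `SIc = Σ_i p_i (x_i / r) log2(x_i / r)`,  `SIr = SIc · r`,

   and spatial stability (mean Pearson correlation between all lap pairs'
   rate curves).
4. **Spatial modulation index (SMI)** — each cell's SIc is z-scored against
   a null built by circularly shifting its spikes within each lap by an
   independent random interval (100 shuffles); this preserves rate and
   spike-pattern statistics while destroying spatial correlates. Cells with
   SMI > 2.325 (99th percentile of chance) are *location-responsive*.
5. **Firing fields** — peaks of the baseline-subtracted rate curve
   (baseline = 30th percentile; peaks > max(1 Hz, 20% of baseline);
   boundaries at 10% of peak; fields closer than 4 cm merged), field
   distributions along the track and their V1↔CA1 spatial cross-correlogram,
   and prospective/retrospective bidirectional firing classification from
   the cross-correlogram of a cell's two running-direction curves
   (±50 cm window, per-lag α = 0.00098 = 0.05/51).
6. **Temporal coupling** — Poisson-normalized spike-count cross-correlograms
   `C̃ = (C − m)/√m` with `m = M·N·B/T` (B = 10 ms), a peak threshold of 8
   within ±200 ms, and the population sign-bias binomial test on peak times.
7. **Co-fluctuation (the headline analysis)** — cell pairs are classified as
   overlapping (≥ 50% field overlap plus a significant spike-correlogram
   peak), non-overlapping, or non-responsive; within the probed fields the
   per-lap firing rate and spike center of mass (COM) give Δrate and ΔCOM
   series whose pairwise Pearson correlation measures the co-fluctuation.
   Lap speed and head-direction deviation are regressed out (OLS) to test
   whether behavior explains the coupling, and COM backward shift over early
   laps is quantified against its stabilized value (laps 21–25).

## Worked example

Simulate a short session — two V1 and two CA1 cells, one V1–CA1 pair given
overlapping fields and a shared lap-wise gain (latent correlation 0.8) — and
run the pipeline:

```r
library(cofluct)
cells  <- rbind(synth_cells(2, region = "V1",  baseline_hz = 2,   prefix = "v"),
                synth_cells(2, region = "CA1", baseline_hz = 0.2, prefix = "c"))
fields <- data.frame(cell_id = c("v_1", "c_1"), trajectory_id = "traj1",
                     center_cm = c(100, 104), width_cm = 8, peak_hz = c(18, 16))
pairs  <- data.frame(cell_a = "v_1", cell_b = "c_1", rho_gain = 0.8, rho_com = 0.5)
cfg <- synthetic_config(cells, fields, pairs, n_laps = 14, refine = 2L)
sim <- simulate_session(cfg, seed = 42)
res <- run_pipeline(sim$session, run_config(master_seed = 42, min_laps = 8))
```

The per-cell metrics on trajectory 1 (printed by the code above):

```
 cell_id region overall_rate_hz sic_bits_per_spike stability   smi location_responsive
     v_1     V1            3.57               0.61      0.58 13.67                TRUE
     v_2     V1            1.74               0.05     -0.02 -1.25               FALSE
     c_1    CA1            1.30               2.05      0.79 12.37                TRUE
     c_2    CA1            0.24               0.54      0.01    NA               FALSE
```

The two field-bearing cells are location-responsive (SMI ≫ 2.325) with high
spatial stability; the baseline-only V1 cell is not, and the 0.24-Hz CA1
cell is inactive (SMI not computed). The pair table:

```
 cell_a cell_b          class overlap_frac n_laps r_drate p_drate r_drate_mod
    v_1    c_1    overlapping        0.857     14   0.569   0.034       0.665
    v_2    c_1 non_responsive        0.748     14  -0.131   0.655      -0.120
```

The injected overlapping pair shows a significant lap-by-lap Δrate
correlation (r = 0.57, p = 0.03) that survives regressing out speed and head
direction (r = 0.67), while the control pairing of the same place cell with
a non-responsive V1 cell does not. `write_results(res, dir)` writes
`metrics.csv`, `fields.csv`, `bidir.csv`, `xcorr_pairs.csv`, `pairs.csv`,
`comshift.csv`, `laps.csv` and `summary.json`.

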