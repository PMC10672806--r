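# motility3d

Quantitative analysis of 3D cell trajectories from time-lapse (e.g.
two-photon intravital) imaging, built for comparing how the same cell type
moves in different tissue environments. The motivating use case is T cell
motility: naive T cells patrolling a lymph node move fast and persistently,
while effector T cells in inflamed lung tend to reverse direction, stay
confined, and consequently survey far less tissue. `motility3d` turns raw
track tables (cell id, imaging field, tissue, time, x/y/z) into per-cell
motility metrics and runs the statistical comparison layer across tissues
and imaging fields.

## What it computes

For a track of positions (x_i, y_i, z_i) at times t_i, with step distances
d_{i,i+1} = ||p_{i+1} − p_i||:

- **Cell-based speed** s_cell = Σ d_{i,i+1} / (t_n − t_1) — mean speed along
  the path (µm/min).
- **Displacement speed** s_disp = d_{1,n} / (t_n − t_1) — how fast the cell
  gets away from where it started.
- **Meandering ratio** M = d_{1,n} / Σ d_{i,i+1} ∈ [0, 1], with the exact
  identity M · s_cell = s_disp.
- **Turning angles** θ = arccos(v₁·v₂ / |v₁||v₂|) between consecutive
  displacement vectors; angles with associated speed < 1 µm/min are excluded
  (near-stationary cells produce artifactual angles). A mode near 160–180°
  flags "back and forth" reversing motion.
- **Speed persistence likelihood** per 1 µm/min speed bin:
  P(A_i|B_i)/P(A_i) = (m·m_ab)/(m_a·m_b) over consecutive step-speed pairs —
  the fold increase in the chance of staying at a speed given the cell was
  just moving at it.
- **MSD exponent**: slope of log (d_{1,k})² against log (t_k − t_1), capped
  at 10.5 min of elapsed time; ≈ 1 Brownian, 1–2 superdiffusive (Lévy-like,
  2 = ballistic), < 1 subdiffusive.
- **Confinement**: dwells of > 150 s inside a 5 µm ball (confined ratio =
  confined time / track time), and the mean time to first exit a 5 µm ball
  around each position (confined time, minutes).
- **Patrolled-volume rate**: 2.5 µm voxels of a 400 µm cube whose centers
  pass within 5 µm of the cell (including along interpolated segments),
  times voxel volume, per second of tracking (µm³/s) — the single number
  that integrates speed, turning, and confinement into search capacity.

Around the metrics: time-step normalization to 90 s with *phase-complete
subsampling* (a 45 s series becomes two 90 s tracks, {t0,t2,…} and
{t1,t3,…}, so no data are discarded), pairwise Mann–Whitney and
Kolmogorov–Smirnov tables with Bonferroni correction, one-way ANOVA of frame
(imaging-field) heterogeneity within and between tissues, and a greedy
outlier-frame reduction that removes the frames driving within-tissue
variance. A seedable generator of 3D walker populations (ballistic,
Brownian, persistent, confined, reversing) with a tissue → frame → cell
hierarchy provides ground truth for every stage.

## Worked example

```r
library(motility3d)

ts  <- generate_cohort(study_cohort_spec(scale = 0.1), seed = 42)
rs  <- resample_tracks(ts, resample_spec(target_dt = 90, tolerance = 10))
res <- compute_all(rs)
med <- summarize_medians(res$cell_metrics)
med[, c("tissue", "n_cells", "median_cell_speed", "median_meandering_ratio",
        "median_msd_slope", "median_volume_rate")]
#>     tissue n_cells median_cell_speed median_meandering_ratio median_msd_slope
#> 1       LN     880              5.69                   0.416            1.388
#> 2 lung_flu      35              5.93                   0.202            0.784
#> 3 lung_lps      18              2.25                   0.188            0.876
#> 4    villi      69              6.73                   0.575            1.247
#>   median_volume_rate
#> 1               7.65
#> 2               5.44
#> 3               1.42
#> 4               9.53

pairwise_ranksum(split(res$cell_metrics$cell_speed, res$cell_metrics$tissue))
#> <pairwise_matrix> Mann-Whitney rank sum, 6 comparisons, bonferroni correction
#>                LN lung_flu lung_lps    villi
#> LN       1.00e+00    1.000 1.59e-03 3.43e-05
#> lung_flu 1.00e+00    1.000 2.10e-02 1.00e+00
#> lung_lps 1.59e-03    0.021 1.00e+00 1.92e-05
#> villi    3.43e-05    1.000 1.92e-05 1.00e+00
```

Reading the output: the lymph-node-like and villi-like tissues move fast
(medians ~6 µm/min), straight (meandering 0.4–0.6) and superdiffusively (MSD
slope > 1), so they patrol 7.7–9.5 µm³/s. The reversing influenza-lung-like
walkers keep a near-normal speed but displace poorly (slope < 1), and the
confined LPS-lung-like mixture is slow, confined and patrols the least
(1.4 µm³/s). The rank-sum table shows which tissue pairs differ in
cell-based speed after Bonferroni correction.

## Analysis workflow

The `analysis/` scripts run the complete study-scale workflow over the
default synthetic cohort, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # build the cohort, write results/tracks.csv
Rscript analysis/02_metrics.R    # 90 s normalization + per-cell metrics
Rscript analysis/03_compare.R    # pairwise tables, ANOVA, frame reduction
```

The methods vignette (`vignettes/motility-analysis.Rmd`) documents the
model, every tunable parameter, and the design decisions.

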