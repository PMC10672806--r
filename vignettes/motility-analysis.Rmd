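---
title: "Methods: 3D cell-track motility metrics and group comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D cell-track motility metrics and group comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motility3d)
```

## The problem

Immune cells — T cells in particular — patrol tissue by crawling through it,
and the efficiency of that search depends on *how* they move: how fast, how
straight, how often they turn back, how long they linger. Intravital
two-photon imaging yields 3D tracks (a handful to a few dozen positions per
cell, tens of seconds apart), grouped into imaging fields ("frames") and
tissues/conditions. Comparing motility across tissues requires (i) metrics
that are robust to short, coarsely sampled tracks, (ii) a common sampling
interval, because nearly every motility statistic is sampling-rate
dependent, and (iii) a statistical layer that respects the frame structure,
since cells from one field share a micro-environment and fields can be
outliers.

`motility3d` implements that pipeline. All positions are micrometres, times
seconds; every speed is reported in µm/min (× 60 at reporting time).

## Time-step normalization

All metrics are computed at a nominal 90 s step (`resample_spec(90, 10)`).
Series acquired faster are *phase-split*: for a native step d with
k = round(90/d) ≥ 2, k subsampled tracks are emitted, one per phase offset,
each greedily selecting the remaining sample closest to (last time + 90 s)
and accepting it when within the tolerance (default 10 s). A 45 s series
thus becomes {t0,t2,t4,…} and {t1,t3,t5,…}: every observation is used
exactly once, and no position is ever interpolated or fabricated. Tracks
already within tolerance of 90 s pass through unchanged; phases left with
fewer than 2 points are dropped and counted.

Two consequences are worth knowing. Phase tracks are treated as independent
tracks downstream (they are reported with a `_p<k>` cell-id suffix); this
doubles the apparent cell count of fast-sampled tissues, which matters for
test sample sizes but not for medians, since both phases sample the same
cell population. And with tolerance 10 s, series whose native step divides
90 poorly (e.g. 60 s) are rejected rather than approximated at 120 s; the
tolerance is a parameter if that trade-off is wrong for a data set.

`timestep_summary()` reports realized per-tissue step means and sds after
normalization; the sd is the population (divide-by-n) sd over pooled steps,
a deliberate convention since the pooled steps are the full population of
realized intervals, not a sample from a larger one.

## Per-cell metrics

*Speeds and meandering.* Cell-based speed is path length over elapsed time;
displacement speed uses only the first and last positions; the meandering
ratio is their quotient, so `meandering_ratio * cell_speed ==
displacement_speed` holds to machine precision and is asserted in the test
suite. Zero elapsed time or zero path length yield `NA` markers — undefined
metrics are never imputed and are excluded pairwise downstream.

*Turning angles.* The angle between consecutive displacement vectors, in
[0°, 180°]. Angles need an associated speed both for the < 1 µm/min
exclusion and for the speed–angle profile; the package uses the **mean of
the incoming and outgoing step speeds**. The alternatives (incoming only,
outgoing only, either-below-threshold) are defensible; the symmetric mean
was chosen because the angle belongs equally to both steps, and the
threshold is exposed as `min_speed`. Angles at zero-length steps are
undefined and counted, not silently dropped. The angle histogram uses
9° bins by default; the speed–angle profile reports per-bin mean associated
speed, its population sd, and sd/8 (the half-error-bar convention used when
plotting, which keeps error bars legible at large n; the full sd is also
returned).

*Speed persistence.* Consecutive same-cell step-speed pairs (s_before,
s_after) are pooled within a group and binned at 1 µm/min. The likelihood
ratio (m·m_ab)/(m_a·m_b) estimates P(A_i|B_i)/P(A_i): 1 under independence,
large when cells persist at a speed. The denominator count m is the **total
number of pooled pairs** — the only reading under which m_a/m, m_b/m and
m_ab/m are probabilities. The top bin is open-ended at `max_bin`
(default 12 µm/min); bins with m_a·m_b = 0 are undefined.

*MSD exponent.* The regression uses displacements **from the first track
position** (not time-averaged overlapping displacements): log (d_{1,k})²
against log (t_k − t_1), over 0 < t_k − t_1 ≤ 10.5 min. The cap equalizes
the fitted time range across tissues with different track durations. Zero
displacements are excluded (log 0); at least 3 usable points are required,
otherwise the slope is `NA` and the cell is excluded from slope statistics.
The slope is invariant to log base, rotation, and translation (tested).
Single-track slopes are noisy — classification is meaningful at the
population (median) level, which is how it is used.

*Confinement.* The confined **ratio** uses an anchor scan: dwell inside a
5 µm ball around the anchor; when the cell first steps out, the dwell (anchor
to last inside position) counts as confined if it exceeds 150 s — the
*whole* dwell, not just the excess, since the dwell time itself is the
quantity of interest — and the anchor restarts at the exit point. The
confined **time** is the mean, over all positions, of the time to first exit
a 5 µm ball around that position; anchors whose ball is never exited
contribute the censored time to track end (the final position contributes
0). Censoring inflates the estimate for short tracks of slow cells; dropping
never-exiting anchors instead would bias it down and discard exactly the
most-confined cells, so censoring was chosen and the behaviour is documented
here rather than hidden.

*Patrolled volume.* The enclosing 400 µm cube is divided into 2.5 µm voxels;
a voxel is patrolled when its center lies within 5 µm of any observed
position or of any point along the straight segments joining successive
positions, sampled every voxel/2 = 1.25 µm — below the voxel size, so no
cube within reach can be skipped between samples (verified against an
exhaustive brute-force grid scan, exact count equality, in the tests). The
track is translated so its bounding box is centered in the domain; the voxel
grid is registered to the domain origin, so the marked count has a mild
grid-phase sensitivity (sub-voxel translations of a track can change the
count by a few voxels), which is irrelevant at the ~500 µm³ scale of real
tracks but visible in single-point fixtures. Volume divided by tracked time
gives µm³/s.

## Group statistics

Pairwise tables use the two-sided unpaired Mann–Whitney U test (groups are
disjoint sets of cells, so a paired test is not meaningful), exact for small
untied samples and normal-approximated with continuity correction otherwise,
with Bonferroni correction: raw p × number of unordered pairs in the table
(6 for four tissues), capped at 1. The Kolmogorov–Smirnov variant compares
full distributions and is used for the patrolled-volume rate, where two
tissues can share a median while differing in shape.

Frame heterogeneity uses classical one-way ANOVA (equal-variance F test):
intra-tissue with frames as groups and cells as observations, inter-tissue
with tissues as groups. Frames with fewer than 2 usable values are dropped;
zero within-group variance is a degenerate-input error rather than F = ∞.

The outlier-frame reduction is a greedy procedure the data define only
implicitly: at each step, remove the frame whose exclusion maximally
*increases* the intra-tissue ANOVA p-value, stopping when p ≥ 1e-4, when 55%
of the tissue's frames have been removed, or when no removal raises p. Ties
break toward the lexicographically smaller frame id, making the procedure
deterministic. The trajectory of (removed frame, p before, p after) is
returned so the monotone-p invariant can be audited. The stop rule is
configurable; the defaults bracket the behaviour expected of cohorts where
one tissue is far more heterogeneous than the rest.

## The synthetic cohort generator

Real validation data for this pipeline are two-photon track sets, which are
large, binary, and study-specific; the package instead ships seedable
walker generators with known ground truth. Step lengths are speed × Δt with
per-step speeds from a normal distribution left-clipped at zero, optionally
around a per-cell mean (cell-level heterogeneity). Headings:

- *ballistic* — fixed direction, constant per-cell speed (meandering 1, MSD
  slope exactly 2);
- *brownian* — i.i.d. isotropic directions (turning-angle density sin θ/2,
  median MSD slope ≈ 1);
- *persistent* — von Mises–Fisher perturbation of the previous heading with
  concentration κ (superdiffusive; vMF chosen because it is the canonical
  rotationally symmetric distribution on the sphere with a single
  concentration parameter and an exact 3D sampler);
- *back_and_forth* — reversal with probability p_rev plus vMF jitter about
  the (possibly negated) heading, jitter given in degrees and converted as
  κ = 1/σ² (radians) — produces the near-160° turning-angle mode of
  reversing cells;
- *confined* — isotropic proposals rejected beyond a tether radius from the
  start (subdiffusive at matched duration).

`generate_cohort()` adds the tissue → frame → cell hierarchy with a per-frame
speed offset drawn once per frame (sd `frame_speed_sd`), which is what the
intra-tissue ANOVA and the outlier reduction machinery are exercised
against. Everything is reproducible: same spec + seed → bit-identical
tracks.

`study_cohort_spec()` fixes the default study conditions: four tissues with
frame structure 40×110 (LN-like, persistent κ = 2.5, 45 s sampling with
1.5 s jitter), 10×42 (villi-like, persistent κ = 2, 46.5 s sampling, 4 s
jitter), 5×71 (influenza-lung-like, reversing, p_rev = 0.6, 20° jitter, 90 s
sampling), and 3×64 (LPS-lung-like, a 60/40 confined/Brownian mixture, 90 s
sampling); track lengths uniform on 10–40 points for the fast-sampled
tissues (5–20 per phase after splitting) and 5–30 at 90 s; speed means
6.5/7/5.5/4–5 µm/min with cell-level sds of 1.5–3 µm/min and frame-offset
sds of 1.2/1.0/0.9/0.15 µm/min. These values were chosen once as a
realistic, stylized rendering of the phenotypes such studies report (fast
persistent lymphoid tissues sampled faster than 90 s; a reversing infected
lung; a confined inflamed lung; strong frame heterogeneity concentrated in
the largest tissue). The generator emulates the *statistical* structure of
two-photon track data — it does not model tissue architecture, chemokine
fields, cell–cell contact, or tracking errors (misassignments, gaps), so
green tests demonstrate the correctness of the computations and the
qualitative phenotype contrasts, not agreement with any particular
biological measurement.

## Numerical choices and degenerate inputs

- Undefined metrics are `NA` markers, excluded pairwise; never zeros.
- `acos` arguments are clamped to [−1, 1] before the angle is taken.
- The persistence ratio uses double arithmetic for m·m_ab (counts at 10⁵
  pairs overflow 32-bit integers).
- Tracks shorter than each metric's minimum (2 points for speeds, 3 for
  angles and MSD) are excluded per metric, not at load; loading enforces
  only ≥ 2 points, strictly increasing times, and finite coordinates.
- The MSD fit is an explicit least-squares slope (no intercept reporting);
  ties in the outlier reduction and phase ordering are broken
  deterministically, so reruns are byte-identical.
- Problem sizes in the tests are chosen for tight sampling error at small
  cost: 500–1000 tracks for property checks, 10⁵ angle/pair samples for
  distributional laws, 2000 null simulations for the ANOVA type-I rate; the
  analysis scripts and acceptance run use the full 5367-track cohort.

## Known limitations

- Phase-split tracks are not independent samples of *cells* (two phases per
  cell); inferential sample sizes for fast-sampled tissues are accordingly
  optimistic. Keep this in mind when reading the pairwise tables for
  tissues that required splitting.
- The patrolled-volume count inherits the voxel grid phase (above).
- The greedy frame reduction is a heuristic: it reproduces the intended
  effect (removing the frames responsible for within-tissue variance) but
  is not guaranteed to find the minimal outlier set, and with a very
  heterogeneous tissue it can hit the removal cap before the p threshold
  (flagged `reached = FALSE` in the report).
- Confined-time censoring makes that metric duration-dependent for cells
  that never leave their ball; compare tissues at matched track-duration
  distributions (the 10.5 min MSD cap has no analogue here).
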