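---
title: "Methods: quantifying polar protein dynamics in gliding rod cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying polar protein dynamics in gliding rod cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions, and numerical choices
behind `rodpol`. It is the place to look when a default looks arbitrary:
each one was chosen once, for the reasons given here, and is exercised by
the test suite.

## The measurement problem

Gliding rod-shaped bacteria (the motivating organism is *Myxococcus
xanthus*) move along their long axis and reverse direction every few
minutes. Polarly localized motility regulators form fluorescent clusters
that relocate from one pole to the other around each reversal. Three
quantities characterize such data:

1. **Where** the protein sits along the cell: the axial profile, reduced
   to 15 equal-length positional segments, and the population histogram of
   cluster occurrence per segment.
2. **When** the cell reverses: scored from centroid tracks.
3. **When** the cluster switches poles: scored from pole-intensity time
   series, and correlated with the reversals through the delay
   cross-correlation Rxy.

## The synthetic scene model

Real acquisitions of this kind are not publicly deposited, so the
package's ground truth comes from a generative model
(`scene_config()` / `generate_movie()`), built to emulate a widefield
time-lapse at 0.1 µm/px with 30 s frames over 20 min.

**Geometry and motion.** Cells are spherocylinders (rectangle capped by
half-disks), by default 4 µm × 0.7 µm, placed in disjoint horizontal
lanes — the analysis targets isolated cells, so cell–cell contact is out
of scope by construction. Each cell glides along its axis at constant
speed (default 2 µm/min, a typical gliding speed for this organism) and
reverses either on a fixed frame schedule or as a memoryless (Poisson)
process with a configurable mean interval (default 8 min). A reversal is
modeled as an instantaneous sign flip of the velocity: at 30 s sampling,
sub-frame reversal kinetics are unresolvable, so a point event is the
appropriate idealization.

**Fluorescence.** The cytoplasm carries a diffuse level (180 au over a
100 au camera offset); each pole can carry a Gaussian cluster
(sd 1.5 px) centred at the pole apex — polar clusters hug the extreme
cell tip, which is also what places them in the terminal axial segments.
Cluster amplitudes are configured per pole role, default 800 au at the
leading and 300 au at the lagging pole, or per cell (an `n_cells × 2`
matrix), which is how unipolar/bipolar snapshot populations are built.
The cluster relocates to the new leading pole `switch_lag_frames` after
each reversal (positive lag = switch after reversal; 0–1 frames matches
switching tightly coupled to reversals at this sampling).

**Optics and noise.** The field is blurred with an isotropic Gaussian PSF
of sd 1.5 px — the diffraction-limited appearance at this pixel size
without modeling the optical train. Per-pixel shot noise
(`rpois(I·s)/s`, default scale 1) and Gaussian read noise (default sd
10 au) follow; images are clipped to the 16-bit range and the clipped
fraction is reported.

**Photobleaching.** All cellular fluorescence decays by 2 % per frame.
This is both realistic (acquisitions of this type are designed around
bleaching) and load-bearing for the switching score: the score looks for
the *maximum* fluorescence at the new leading pole, and on an idealized
bleach-free plateau that maximum is a coin flip among noise — with a slow
decay it lands at cluster arrival, as it does on real traces.

**What the generator does not emulate:** cell growth and division,
curvature, cell–cell mechanics and group motility, focus drift,
illumination inhomogeneity, or background structure. Passing tests on
these scenes therefore demonstrate the correctness of the *quantification
procedures* under controlled conditions, not robustness to every artifact
of real microscopy.

## Segmentation and the axial profile

Frames are thresholded, components labeled, and a centerline extracted
per cell by Zhang–Suen thinning, the longest geodesic path through the
skeleton (BFS, ties broken lexicographically), and extension to the mask
boundary along the end tangents. Pole tips are the extended endpoints,
ordered lexicographically so axis orientation is deterministic.

Two thresholding methods are offered. `"otsu"` is the textbook default
for an isolated snapshot. For movie frames, where cells occupy ~1 % of
the field, Otsu's between-class criterion can land inside the background
noise and merge distant cells; the pipeline therefore defaults to
`"robust"`: background median + 4×MAD. When the background is noise-free
(MAD ≈ 0, as in idealized renders) the robust method falls back to the
midpoint between the background plateau and the cell-body level (95th
percentile of above-background pixels, insensitive to bright polar
spots).

The profile value at each centerline point is the mean intensity over the
mask cross-section perpendicular to the local axis (band average — more
noise-robust than a single-pixel line sample), after subtracting the
per-frame background (median of non-cell pixels) and flooring at zero.
Cell boundaries are then defined on the profile itself: the profile is
restricted to the contiguous region above half its central median (the
decision uses a 5-sample running mean so a single noisy sample cannot
truncate a cell), and a further fixed 3 px — twice the PSF sd — is
trimmed from each end. The above-threshold mask overhangs the physical
poles by the blur skirt; the trim places the profile ends at the poles,
so apex-hugging clusters fall in segments 1 and 15.

**Splicing.** The restricted profile is treated as piecewise constant
between sample midpoints and integrated exactly over 15 equal arc-length
intervals; samples straddling a boundary contribute fractionally. Total
integrated intensity is conserved to floating-point precision
(property-tested at 1e-6 relative). Segment values are means; a maximum
could be argued for cluster detection, but the mean is what the
intensity-conservation invariant and the histogram substrate need, and it
is less noise-sensitive.

**Cluster calls and patterns.** One global minimal-intensity threshold is
applied to all segment values of a dataset — never re-tuned per cell or
condition. It can be given in au or derived once from the pooled
segment-value distribution (`"quantile:q"` or `"otsu"`). Terminal
segments {1, 15} define "polar"; a cell is diffuse/unipolar/bipolar by
its terminal flags, and bipolar cells are split symmetric vs asymmetric
at a brighter/dimmer ratio of 1.5 (the literature depicts asymmetry
qualitatively; 1.5 is a conservative reading of "visibly unequal").

**A diffraction-limit caveat.** At 4 µm / 0.1 µm/px, one segment is
~2.7 px wide while a diffraction-limited cluster has an effective sd of
~2.1 px after the PSF: around 40 % of a polar cluster's in-segment mass
spills into the neighboring segment. Near-threshold datasets will
therefore show occupancy at segments 2 and 14; classification is
unaffected (it reads only the terminal segments), but "clusters appear
*only* in terminal segments" holds at high confidence only when the
cluster-to-diffuse contrast is strong. The reference snapshot population
used by the tests (100 cells, 40 bipolar / 60 unipolar, amplitude 600 au
on diffuse 150 au, longer-exposure noise with `poisson_scale = 2` — a
still frame integrates more photons than a 30 s time-lapse frame — and a
calibrated global threshold of 172 au) sits in that regime.

## Tracking and reversal scoring

Linking is greedy nearest-neighbor with gap closing (`max_step` 15 px per
frame of separation, `max_gap` 1 frame), deterministic under ties. This
is adequate for isolated cells in lanes; it is not a multi-hypothesis
tracker and makes no attempt to resolve crossings.

The traveled-distance statistic is computed over the first full 10-min
window of each track, in both readings: cumulated path length (sum of
frame-to-frame centroid distances) and net start-to-end displacement.
Both are always reported because the two readings answer different
questions (total motor activity vs productive displacement) and the
field's usage is ambiguous; net displacement is the default reported
metric.

Reversals: each frame-to-frame displacement is projected on the cell body
axis (axis sign aligned frame to frame); displacements below `min_move`
(1 px per interval — sub-pixel centroid jitter at 30 s sampling must not
flip the direction sign) carry no direction. The movement direction is
established at the first supra-threshold interval, and a reversal is
stamped on the first *frame* whose preceding interval moves the opposite
way. Consequently a velocity flip at frame f is scored at f + 1 — "as
soon as movement was detected in the opposite direction" — and
truth-comparison uses a ±1-frame tolerance.

## Pole series, switching, and Rxy

Pole intensities are disk means (radius 3.5 px = half the cell width)
clipped to the cell mask, background-subtracted. The disk is centred on
the brightest mask pixel near the extracted tip rather than the tip
itself: extracted tip coordinates wobble by ~1 px between frames, and on
the steep flank of a cluster that wobble would otherwise dominate the
measurement noise. Physical pole identity is maintained across frames by
matching tips to the previous frame; role labels (initial leading /
initial lagging) are assigned from the first supra-threshold movement
direction and stay fixed — roles, not poles, swap at reversals.

Switching is scored per reversal: the new leading pole is the pole
opposite the pre-reversal movement direction (roles alternate), and the
switch frame is the argmax of that pole's intensity within the
inter-reversal interval starting at the scored reversal; exact ties take
the first frame and are flagged low-confidence.

**Rxy.** Both event series are binarized on the frame grid (duplicate
events collapse). The cross-correlation at delay m is

    Rxy(m) = Σ_t [x(t) − x̄][y(t − m) − ȳ] / (N σx σy),

with full-series means and population SDs — the standard
cross-correlogram normalization (identical to `stats::ccf`, against which
the implementation is verified). This form guarantees |Rxy| ≤ 1 at every
delay and Rxy = 1 at zero delay for identical non-constant series, the
two analytic properties the statistic must satisfy. An overlap-length
normalization was considered and rejected: it is unbiased at large delays
but can exceed 1 when the overlap is short, violating the coefficient's
range. At the delays of interest here (|m| ≤ 4 over N = 40) the two
differ by under 10 %.

Sign convention: positive m means the switch occurs m frames *after* the
reversal, so a population with `switch_lag_frames = k` produces an
aggregate Rxy peaking at m = k (property-tested for k ∈ {0, 1, 2}).
Constant series (cells without events) have undefined correlation and are
returned as `NA` with a warning — never as 0 — and are dropped from the
aggregate, whose `n_cells` records the cells that contributed, mirroring
the practice of analyzing reversing cells. Aggregation is
per-cell-curves-then-average (a pooled mode can be built from the same
primitives); significance is flagged when the mean curve exceeds 0.4 at
some delay within 0–1 min (delays 0, 30, 60 s at 30 s frames).

## Orchestration and reproducibility

`run_pipeline()` chains simulate (or read) → segment → profile/classify →
track → reversals/distances → pole series/switching → Rxy, writes every
tabular intermediate as UTF-8 CSV with unit-suffixed column names
(`_px`, `_au`, `_s`), and emits a YAML manifest with the configuration,
seed, package version, collected warnings (ties, clipping, skipped short
tracks — so silent data loss is impossible) and per-stage timings. The
scene seed fully determines the movie, and a rerun with the same
configuration reproduces every CSV byte for byte; the manifest suffices
to reproduce a run.

## Problem sizes and numerical tolerances

The test suite exercises: 15-segment splicing against an independent
cumulative-integral oracle (1e-9) and intensity conservation (1e-6
relative); Rxy against a double-loop oracle, exhaustively over all
non-constant binary series of length 5 (and length 4 in the end-to-end
suite) plus random longer series (1e-12), and against `stats::ccf`; a
200-cell truth-only Poisson check of the reversal process (3 SE); 100-cell
snapshot populations for histogram exactness (noiseless) and ≥95 %
classification accuracy (noisy, SNR ≈ 8); 6-cell fixed-schedule movies
for reversal/switch timing; and a 30-cell full-pipeline simulation for the
0–1 min Rxy readout. These sizes give stable statistics at interactive
runtimes; all stochastic tests run under fixed seeds.

## Known limitations

* Straight cells only: the centerline handles mild curvature, but the
  generator produces straight rods and none of the validation covers
  strongly curved or dividing cells.
* The greedy linker will swap identities if cells pass within `max_step`
  of each other; the generator's lane layout avoids this by design.
* Switch timing inherits the plateau-argmax ambiguity: with weak
  bleaching or very noisy pole measurements the scored switch frame can
  slip a few frames late, which smears (but rarely destroys) the Rxy peak.
* The cluster-occurrence histogram is diffraction-limited as discussed
  above; terminal-segment exclusivity should not be over-interpreted on
  real data near the detection threshold.
* Absolute intensities are arbitrary units; nothing calibrates au to
  photon counts or molecule numbers.
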