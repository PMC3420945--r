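# rodpol

Quantification of dynamic polar protein localization in gliding,
rod-shaped bacteria from time-lapse fluorescence microscopy.

Bacteria such as *Myxococcus xanthus* glide along their long axis and
periodically reverse direction. Motility regulators (small GTPases and
their partners) form fluorescent clusters at the cell poles and relocate
from pole to pole when the cell reverses. Asking whether those
fluorescence switches are *coupled* to the mechanical reversals — and with
what time delay — requires a chain of quantification steps that this
package implements end to end:

* **Axial profiling** — segment each rod, extract its centerline, sample
  background-subtracted intensity along the cell axis, restrict the
  profile to the cell boundaries, and splice it into **15 equal-length
  segments**. Cluster occurrence per segment over a population of cells
  gives the classic polar-localization histogram, and per-cell terminal
  segments classify cells as diffuse, unipolar, or bipolar
  (symmetric/asymmetric).
* **Motility tracking** — link per-frame centroids into tracks
  (nearest-neighbor, gap-closing), report the distance traveled in a
  10-minute reference window (both cumulated path length and net
  displacement), and score **reversals** at the first frame where movement
  is detected in the opposite direction along the body axis.
* **Pole dynamics** — measure fluorescence in a disk at each pole through
  time, keep the two physical poles in correspondence, and score a
  **pole-to-pole switch** at the frame where fluorescence reaches its
  maximum at the new leading pole after each reversal.
* **Rxy cross-correlation** — binarize switching events x(t) and reversal
  events y(t) on the frame grid and compute the normalized
  cross-correlation coefficient as a function of the delay m (in frames):

  ```
  Rxy(m) = sum_t [x(t) - x̄][y(t - m) - ȳ] / (N · σx · σy)
  ```

  the standard cross-correlogram normalization, so that Rxy = 1 for
  perfectly correlated series and |Rxy| ≤ 1 at every delay. Positive m
  means the fluorescence switch follows the reversal by m frames. Mean
  curves over ~30 cells with Rxy > 0.4 at a 0–1 min delay indicate
  reversal-coupled switching.

Because no public time-lapse data accompany this kind of experiment, the
package ships a **synthetic scene generator**: spherocylindrical cells
with diffuse cytoplasmic fluorescence plus Gaussian polar clusters, gliding
at constant speed in disjoint lanes, reversing on a fixed schedule or as a
Poisson process, switching cluster polarity with a programmable lag,
photobleaching slowly, imaged at 0.1 µm/px with a Gaussian PSF under
Poisson + Gaussian camera noise — together with exact per-frame ground
truth, so every stage of the pipeline is testable.

## Worked example

Simulate 10 reversing cells (30 s frames, 20 min movie, mean reversal
interval 8 min, cluster switching one frame after each reversal) and run
the full pipeline:

```r
library(rodpol)

sc <- scene_config(n_cells = 10, n_frames = 40, seed = 7,
                   reversal_process = list(type = "poisson",
                                           mean_interval_min = 8),
                   switch_lag_frames = 1)
run <- run_pipeline(pipeline_config(scene = sc, out_dir = "demo-run"))
run
#> <rodpol_run> 40 frames, 11 tracks, 27 reversals, 27 switches
#>   aggregate Rxy over 10 cells: peak 0.686 at +0 frames; significant: TRUE

glance(run$rxy)
#> # A tibble: 1 × 6
#>   n_cells peak_rxy peak_delay_frames peak_delay_s significant threshold
#>     <int>    <dbl>             <int>        <dbl> <lgl>           <dbl>
#> 1      10    0.686                 0            0 TRUE              0.4

head(run$distances, 3)
#> # A tibble: 3 × 4
#>   track_id path_length_px net_displacement_px n_frames_used
#>      <int>          <dbl>               <dbl>         <int>
#> 1        1           200.             200.               21
#> 2        2           207.               0.128            21
#> 3        3           200.             200.               21
```

The mean Rxy curve peaks at 0.69 at zero delay — the programmed
switching (0–30 s after each reversal) is recovered as significant
(> 0.4) coupling in the 0–1 min window. The traveled-distance table shows
both readings of single-cell motility: track 2 reversed mid-window, so its
cumulated path (207 px ≈ 20.7 µm in 10 min) is large while its net
displacement is near zero.

All intermediates (masks, profiles, 15-segment tables, the occurrence
histogram, tracks, reversal and switch events, per-cell and aggregate Rxy
curves) are written as CSV into `demo-run/`, along with a YAML manifest
recording the configuration, seed, warnings and per-stage timings. Rerunning
with the same configuration reproduces every CSV byte for byte.

`autoplot()` methods display the main result types
(`autoplot(run$rxy)`, `autoplot(run$histogram)`), and `tidy()` /
`glance()` return plain tibbles for downstream analysis.

## Package layout

| Area | Functions |
| --- | --- |
| Synthetic scenes | `scene_config()`, `generate_movie()`, `render_cell()`, `write_stack()`/`read_stack()`, `write_truth()`/`read_truth()` |
| Cell quantification | `segment_cells()`, `axial_profile()`, `splice_segments()`, `detect_clusters()`, `build_histogram()`, `classify_pattern()` |
| Tracking | `link_tracks()`, `traveled_distance()`, `score_reversals()` |
| Pole dynamics | `pole_series()`, `score_switching()`, `binarize_events()`, `cross_correlation()`, `aggregate_rxy()` |
| Orchestration | `pipeline_config()`, `run_pipeline()`, `validate_against_truth()` |

See the methods vignette (`vignettes/rodpol-methods.Rmd`) for the model
assumptions, parameter choices, and known limitations.
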