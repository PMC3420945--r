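# Shared fixtures, generated once per test session and cached. All fixtures
# are built in code from the synthetic-scene module; nothing is stored on
# disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# 6 reversing cells, 20 min movie, fixed reversal schedule, switching lag 1,
# default (realistic) noise.
fixture_movie <- function() {
  fixture("movie", function() {
    cfg <- scene_config(n_cells = 6, n_frames = 40, seed = 42,
                        reversal_process = list(type = "fixed",
                                                frames = c(10, 25)),
                        switch_lag_frames = 1)
    generate_movie(cfg)
  })
}

# Noise-free twin of fixture_movie (same geometry/schedule).
fixture_noiseless <- function() {
  fixture("noiseless", function() {
    cfg <- scene_config(n_cells = 6, n_frames = 40, seed = 42,
                        reversal_process = list(type = "fixed",
                                                frames = c(10, 25)),
                        switch_lag_frames = 1,
                        noise = list(poisson_scale = 0, gaussian_sd = 0))
    generate_movie(cfg)
  })
}

# Segment every frame of a movie and link tracks; returns list with masks,
# tracks, reversals.
analyse_movie <- function(mv, min_move = 1) {
  segf <- lapply(seq_along(mv$frames), function(f) {
    m <- segment_cells(mv$frames[[f]], method = "robust", min_area = 100)
    dplyr::mutate(m, frame = f - 1L,
                  background_au = attr(m, "background_au"), .before = 1)
  })
  det <- dplyr::select(dplyr::bind_rows(segf), -"cell_id")
  tracks <- link_tracks(det)
  reversals <- score_reversals(tracks, min_move = min_move)
  list(masks = det, tracks = tracks, reversals = reversals)
}

fixture_analysis <- function() {
  fixture("analysis", function() analyse_movie(fixture_movie()))
}

fixture_noiseless_analysis <- function() {
  fixture("noiseless_analysis", function() analyse_movie(fixture_noiseless()))
}

# Map each track to the nearest ground-truth cell (by centroid distance at
# the first common frame).
match_tracks_to_truth <- function(tracks, truth) {
  ids <- unique(tracks$track_id)
  vapply(ids, function(id) {
    d <- tracks[tracks$track_id == id, ][1, ]
    tr <- truth[truth$frame == d$frame, ]
    tr$cell_id[which.min((tr$x - d$x)^2 + (tr$y - d$y)^2)]
  }, integer(1)) |> stats::setNames(ids)
}

# 100-cell snapshot population: 40 symmetric-bipolar and 60 unipolar cells
# with equal cluster amplitude, static, 2 frames. Snapshots integrate more
# photons than 30 s time-lapse frames, hence the larger poisson_scale.
snapshot_config <- function(noise = list(poisson_scale = 2, gaussian_sd = 7),
                            seed = 7) {
  amp <- rbind(matrix(c(600, 600), 40, 2, byrow = TRUE),
               matrix(c(600, 0), 60, 2, byrow = TRUE))
  scene_config(n_cells = 100, n_frames = 2,
               polar_cluster_amplitudes = amp,
               diffuse_level = 150, bleach_per_frame = 0,
               reversal_process = list(type = "none"),
               noise = noise, seed = seed)
}

# Per-cell 15-segment values for frame 0 of a movie (cluster threshold in
# au is the dataset-calibrated global value used throughout the tests).
snapshot_segments <- function(mv) {
  m <- segment_cells(mv$frames[[1]], method = "robust", min_area = 100)
  profs <- lapply(seq_len(nrow(m)), function(i) {
    p <- axial_profile(mv$frames[[1]], m[i, ],
                       background = attr(m, "background_au"))
    dplyr::mutate(p, frame = 0L, .after = "cell_id")
  })
  list(masks = m, segments = splice_segments(dplyr::bind_rows(profs)))
}

fixture_snapshot <- function() {
  fixture("snapshot", function() {
    mv <- generate_movie(snapshot_config())
    c(list(movie = mv), snapshot_segments(mv))
  })
}

fixture_snapshot_noiseless <- function() {
  fixture("snapshot_noiseless", function() {
    mv <- generate_movie(snapshot_config(
      noise = list(poisson_scale = 0, gaussian_sd = 0)))
    c(list(movie = mv), snapshot_segments(mv))
  })
}

# Global cluster-intensity threshold (au) calibrated once for the snapshot
# scene family: between the diffuse segment level (~150 au) and the
# polar-spot terminal segment level (>220 au) at amplitude 600.
SNAPSHOT_CLUSTER_THRESHOLD <- 172

# True pattern implied by the generator amplitudes of a snapshot cell.
snapshot_truth_pattern <- function(truth0) {
  ifelse(truth0$intensity_lagging_au > 0 & truth0$intensity_leading_au > 0,
         "bipolar_symmetric",
         ifelse(truth0$intensity_lagging_au > 0 |
                  truth0$intensity_leading_au > 0, "unipolar", "diffuse"))
}
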