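# End-to-end orchestration: synthetic scene (or input stack) -> segmentation
# -> profiling/classification -> tracking -> pole dynamics -> Rxy, with all
# intermediates written as CSV plus a machine-readable manifest.

#' Pipeline configuration
#'
#' Exactly one of `scene` (a [scene_config()], simulated at run time) or
#' `input_path` (an existing multi-frame TIFF) must be given.
#'
#' @param scene a [scene_config()], or `NULL`.
#' @param input_path path to a multi-frame TIFF, or `NULL`.
#' @param out_dir output directory (created if needed).
#' @param frame_interval seconds per frame (for `input_path` movies; scenes
#'   carry their own).
#' @param segmentation list: `method`, `level`, `min_area`, `max_area`
#'   (see [segment_cells()]).
#' @param cluster_rule global cluster threshold rule (see
#'   [detect_clusters()]).
#' @param sym_cutoff bipolar symmetry cutoff (see [classify_pattern()]).
#' @param snapshot_frame frame (0-based) used for the per-cell snapshot
#'   histogram and pattern classification.
#' @param tracking list: `max_step`, `max_gap`, `min_move`, `window_min`.
#' @param dynamics list: `r_pole`, `m_range`, `rxy_threshold`, `window_s`.
#' @param seed overrides the scene seed when not `NULL`.
#' @param write_movie also write the rendered movie as `movie.tif`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = NULL, input_path = NULL, out_dir,
                            frame_interval = 30,
                            segmentation = list(),
                            cluster_rule = "otsu",
                            sym_cutoff = 1.5,
                            snapshot_frame = 0,
                            tracking = list(),
                            dynamics = list(),
                            seed = NULL,
                            write_movie = FALSE) {
  if (is.null(scene) == is.null(input_path))
    stop_rodpol("exactly one of `scene` and `input_path` must be given")
  if (!is.null(input_path) && !file.exists(input_path))
    stop_rodpol("input_path does not exist: ", input_path)
  seg <- utils::modifyList(
    list(method = "robust", level = NULL, min_area = 100, max_area = Inf),
    segmentation)
  trk <- utils::modifyList(
    list(max_step = 15, max_gap = 1, min_move = 1, window_min = 10),
    tracking)
  dyn <- utils::modifyList(
    list(r_pole = 3.5, m_range = -4:4, rxy_threshold = 0.4, window_s = 60),
    dynamics)
  if (!is.null(scene)) {
    stopifnot(inherits(scene, "scene_config"))
    if (!is.null(seed)) scene$seed <- as.integer(seed)
    frame_interval <- scene$frame_interval
  }
  structure(list(scene = scene, input_path = input_path, out_dir = out_dir,
                 frame_interval = frame_interval, segmentation = seg,
                 cluster_rule = cluster_rule, sym_cutoff = sym_cutoff,
                 snapshot_frame = snapshot_frame, tracking = trk,
                 dynamics = dyn, write_movie = isTRUE(write_movie)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_rodpol(sprintf("pipeline stage '%s' failed: %s", name,
                        conditionMessage(e))))
}

#' Run the full quantification pipeline
#'
#' Simulates (or reads) a movie, segments every frame, builds the snapshot
#' 15-segment histogram and pattern table, links tracks, scores reversals
#' and traveled distances, extracts pole-intensity series, scores
#' switching, and computes per-cell and aggregate Rxy curves. Every tabular
#' intermediate is written as a UTF-8 CSV with a header into `out_dir`,
#' along with a YAML manifest (configuration, package version, collected
#' warnings, per-stage timings). Reruns with the same configuration and
#' seed reproduce all CSVs bit-identically.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list of class `rodpol_run` with all result tables,
#'   the manifest, and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warn_log <- character(0)
  timings <- list()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      stage(name, expr),
      warning = function(w) {
        warn_log <<- c(warn_log, paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        warn_log <<- c(warn_log, paste0(name, ": ",
                                        trimws(conditionMessage(m))))
        invokeRestart("muffleMessage")
      })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # --- acquire -------------------------------------------------------------
  movie <- NULL
  if (!is.null(config$scene)) {
    movie <- timed("simulate", generate_movie(config$scene))
    frames <- movie$frames
    if (movie$clip_fraction > 0)
      warn_log <- c(warn_log, sprintf("simulate: %.3g%% of pixels clipped",
                                      100 * movie$clip_fraction))
    readr::write_csv(movie$truth, file.path(config$out_dir, "truth.csv"))
    if (nrow(movie$events))
      readr::write_csv(movie$events, file.path(config$out_dir, "truth_events.csv"))
    if (config$write_movie)
      write_stack(frames, file.path(config$out_dir, "movie.tif"))
  } else {
    frames <- timed("read", read_stack(config$input_path))
  }
  nf <- length(frames)

  # --- segmentation --------------------------------------------------------
  seg <- config$segmentation
  seg_out <- timed("segment", {
    per_frame <- lapply(seq_len(nf) - 1L, function(f) {
      m <- segment_cells(frames[[f + 1]], method = seg$method,
                         level = seg$level, min_area = seg$min_area,
                         max_area = seg$max_area,
                         k_mad = seg$k_mad %||% 4)
      bgv <- attr(m, "background_au")
      if (nrow(m)) m <- dplyr::mutate(m, frame = f, background_au = bgv,
                                      .before = 1)
      else m <- dplyr::mutate(m, frame = integer(0),
                              background_au = double(0), .before = 1)
      m
    })
    dplyr::bind_rows(per_frame)
  })
  if (nrow(seg_out) == 0) stop_rodpol("pipeline stage 'segment' failed: no cells found in any frame")
  masks_csv <- dplyr::select(seg_out, -"axis", -"pixels")
  readr::write_csv(masks_csv, file.path(config$out_dir, "masks.csv"))

  # --- snapshot profiling / histogram / classification ---------------------
  snap_f <- config$snapshot_frame
  snap <- seg_out[seg_out$frame == snap_f, , drop = FALSE]
  quant <- timed("profile", {
    img <- frames[[snap_f + 1]]
    profs <- lapply(seq_len(nrow(snap)), function(i) {
      p <- axial_profile(img, snap[i, ], background = snap$background_au[i])
      dplyr::mutate(p, frame = snap_f, .after = "cell_id")
    })
    profiles <- dplyr::bind_rows(profs)
    segments <- splice_segments(profiles)
    calls <- detect_clusters(segments, rule = config$cluster_rule)
    hist <- build_histogram(calls)
    patterns <- classify_pattern(calls, sym_cutoff = config$sym_cutoff)
    list(profiles = profiles, segments = segments, calls = calls,
         histogram = hist, patterns = patterns)
  })
  readr::write_csv(quant$profiles, file.path(config$out_dir, "profiles.csv"))
  readr::write_csv(
    tidyr::pivot_wider(quant$segments, names_from = "segment",
                       values_from = "value_au", names_prefix = "seg_"),
    file.path(config$out_dir, "segments.csv"))
  readr::write_csv(tibble::as_tibble(quant$histogram),
                   file.path(config$out_dir, "histogram.csv"))
  readr::write_csv(quant$patterns, file.path(config$out_dir, "patterns.csv"))

  # --- tracking ------------------------------------------------------------
  trk <- config$tracking
  tracks <- timed("track", {
    det <- dplyr::select(seg_out, -"cell_id")
    link_tracks(det, max_step = trk$max_step, max_gap = trk$max_gap)
  })
  tracks_csv <- dplyr::select(tracks, "track_id", "frame", "x", "y",
                              "axis_x", "axis_y", "area_px")
  readr::write_csv(tracks_csv, file.path(config$out_dir, "tracks.csv"))

  reversals <- timed("reversals",
                     score_reversals(tracks, min_move = trk$min_move))
  rev_long <- reversal_events(reversals)
  readr::write_csv(dplyr::select(reversals, -"reversal_frames"),
                   file.path(config$out_dir, "reversal_summary.csv"))
  readr::write_csv(rev_long, file.path(config$out_dir, "reversal_events.csv"))

  distances <- timed("distance",
                     traveled_distance(tracks,
                                       frame_interval = config$frame_interval,
                                       window_min = trk$window_min))
  readr::write_csv(distances, file.path(config$out_dir, "distances.csv"))

  # --- pole dynamics and Rxy ----------------------------------------------
  dyn <- config$dynamics
  dynres <- timed("dynamics", {
    ids <- unique(tracks$track_id)
    series_list <- list(); switches_list <- list(); curves <- list()
    for (id in ids) {
      tm <- tracks[tracks$track_id == id, , drop = FALSE]
      if (nrow(tm) < 2) next
      ps <- pole_series(tm, frames, r_pole = dyn$r_pole,
                        background = tm$background_au,
                        min_move = trk$min_move)
      series_list[[as.character(id)]] <- ps
      rv <- reversals$reversal_frames[[match(id, reversals$track_id)]]
      sw <- score_switching(ps, rv)
      switches_list[[as.character(id)]] <- sw
      if (length(rv) >= 1 && nrow(sw) >= 1) {
        x <- binarize_events(sw$switch_frame, nf)
        y <- binarize_events(rv, nf)
        curves[[as.character(id)]] <- cross_correlation(
          x, y, m_range = dyn$m_range,
          frame_interval = config$frame_interval)
      }
    }
    series <- dplyr::bind_rows(series_list)
    switches <- dplyr::bind_rows(switches_list)
    agg <- if (length(curves))
      aggregate_rxy(curves, threshold = dyn$rxy_threshold,
                    window_s = dyn$window_s) else NULL
    percell <- dplyr::bind_rows(lapply(names(curves), function(id)
      dplyr::mutate(tibble::as_tibble(curves[[id]]),
                    cell_id = as.integer(id), .before = 1)))
    list(series = series, switches = switches, curves = curves,
         percell = percell, aggregate = agg)
  })
  if (nrow(dynres$series))
    readr::write_csv(dynres$series, file.path(config$out_dir, "pole_series.csv"))
  if (nrow(dynres$switches))
    readr::write_csv(dynres$switches, file.path(config$out_dir, "switch_events.csv"))
  if (!is.null(dynres$percell) && nrow(dynres$percell))
    readr::write_csv(dynres$percell, file.path(config$out_dir, "rxy_percell.csv"))
  if (!is.null(dynres$aggregate))
    readr::write_csv(tibble::as_tibble(dynres$aggregate),
                     file.path(config$out_dir, "rxy_aggregate.csv"))

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    package = "rodpol",
    version = as.character(utils::packageVersion("rodpol")),
    seed = if (!is.null(config$scene)) config$scene$seed else NA,
    frame_interval_s = config$frame_interval,
    n_frames = nf,
    n_tracks = length(unique(tracks$track_id)),
    n_reversal_events = nrow(rev_long),
    n_switch_events = nrow(dynres$switches),
    rxy_n_cells = if (!is.null(dynres$aggregate))
      attr(dynres$aggregate, "n_cells") else 0L,
    rxy_significant = if (!is.null(dynres$aggregate))
      attr(dynres$aggregate, "significant") else NA,
    config = config_to_list(config),
    warnings = as.list(warn_log),
    timings_s = timings)
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  invisible(structure(
    list(config = config, movie = movie, masks = seg_out,
         profiles = quant$profiles, segments = quant$segments,
         calls = quant$calls, histogram = quant$histogram,
         patterns = quant$patterns, tracks = tracks,
         reversals = reversals, distances = distances,
         pole_series = dynres$series, switches = dynres$switches,
         rxy_percell = dynres$curves, rxy = dynres$aggregate,
         manifest = manifest, out_dir = config$out_dir),
    class = "rodpol_run"))
}

config_to_list <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$scene)) {
    sc <- unclass(cfg$scene)
    sc$polar_cluster_amplitudes <- as.vector(sc$polar_cluster_amplitudes)
    cfg$scene <- sc
  }
  cfg$dynamics$m_range <- as.integer(cfg$dynamics$m_range)
  cfg
}

#' @export
print.rodpol_run <- function(x, ...) {
  cat(sprintf("<rodpol_run> %d frames, %d tracks, %d reversals, %d switches\n",
              x$manifest$n_frames, x$manifest$n_tracks,
              x$manifest$n_reversal_events, x$manifest$n_switch_events))
  if (!is.null(x$rxy))
    cat(sprintf("  aggregate Rxy over %d cells: peak %.3f at %+d frames; significant: %s\n",
                attr(x$rxy, "n_cells"), max(x$rxy$rxy, na.rm = TRUE),
                x$rxy$delay_frames[which.max(x$rxy$rxy)],
                attr(x$rxy, "significant")))
  invisible(x)
}

# ---- validation against ground truth -------------------------------------

#' Compare a pipeline run with synthetic ground truth
#'
#' Matches tracks to ground-truth cells by centroid proximity and reports:
#' reversal detection precision and recall at a +/-1 frame tolerance, the
#' distribution of switching-time errors (scored switch frame minus true
#' switch frame), the pattern classification confusion table for the
#' snapshot frame, and the histogram terminal-bin error.
#'
#' @param run a `rodpol_run` from a synthetic scene (or any object with
#'   `tracks`, `reversals`, `switches`, `patterns`, `histogram`).
#' @param truth,events ground-truth tables (default: taken from the run's
#'   own movie).
#' @return list of tibbles: `track_map`, `reversal_metrics`, `switch_lag`,
#'   `confusion`, `histogram_error`.
#' @export
validate_against_truth <- function(run, truth = NULL, events = NULL) {
  truth <- truth %||% run$movie$truth
  events <- events %||% run$movie$events
  if (is.null(truth)) stop_rodpol("no ground truth available")

  # map tracks to truth cells by mean centroid distance over common frames
  map <- run$tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_map(function(d, key) {
      j <- dplyr::inner_join(d, truth, by = "frame",
                             suffix = c("", "_true"),
                             relationship = "many-to-many")
      best <- j |>
        dplyr::group_by(.data$cell_id) |>
        dplyr::summarise(
          d = mean(sqrt((.data$x - .data$x_true)^2 +
                          (.data$y - .data$y_true)^2)),
          .groups = "drop") |>
        dplyr::slice_min(.data$d, n = 1, with_ties = FALSE)
      tibble::tibble(track_id = key$track_id, cell_id = best$cell_id,
                     mean_dist_px = best$d)
    }) |>
    dplyr::bind_rows()

  tol_match <- function(scored, true, tol = 1) {
    used <- logical(length(true)); tp <- 0L
    for (s in scored) {
      j <- which(!used & abs(true - s) <= tol)
      if (length(j)) { used[j[1]] <- TRUE; tp <- tp + 1L }
    }
    tp
  }

  rev_true <- events[events$event == "reversal", , drop = FALSE]
  sw_true <- events[events$event == "switch", , drop = FALSE]
  tp <- 0L; n_scored <- 0L; n_true <- 0L
  lag_err <- numeric(0)
  for (i in seq_len(nrow(map))) {
    tid <- map$track_id[i]; cid <- map$cell_id[i]
    scored <- run$reversals$reversal_frames[[match(tid, run$reversals$track_id)]]
    true_fr <- rev_true$frame[rev_true$cell_id == cid]
    tp <- tp + tol_match(scored, true_fr)
    n_scored <- n_scored + length(scored)
    n_true <- n_true + length(true_fr)
    sw_scored <- run$switches$switch_frame[run$switches$track_id == tid]
    true_sw <- sw_true$frame[sw_true$cell_id == cid]
    for (s in sw_scored) {
      if (length(true_sw))
        lag_err <- c(lag_err, s - true_sw[which.min(abs(true_sw - s))])
    }
  }
  reversal_metrics <- tibble::tibble(
    n_true = n_true, n_scored = n_scored, true_positives = tp,
    precision = ifelse(n_scored > 0, tp / n_scored, NA_real_),
    recall = ifelse(n_true > 0, tp / n_true, NA_real_))

  switch_lag <- tibble::tibble(error_frames = lag_err)

  confusion <- NULL
  if (!is.null(run$patterns) && nrow(run$patterns)) {
    snap_f <- run$config$snapshot_frame
    truth_snap <- truth[truth$frame == snap_f, , drop = FALSE]
    true_pat <- truth_pattern(truth_snap, run$config$sym_cutoff)
    snap_masks <- run$masks[run$masks$frame == snap_f, , drop = FALSE]
    mmap <- vapply(seq_len(nrow(snap_masks)), function(i) {
      dd <- sqrt((truth_snap$x - snap_masks$x[i])^2 +
                   (truth_snap$y - snap_masks$y[i])^2)
      truth_snap$cell_id[which.min(dd)]
    }, integer(1))
    obs <- run$patterns
    obs$true_cell <- mmap[match(obs$cell_id, snap_masks$cell_id)]
    obs$true_pattern <- true_pat$pattern[match(obs$true_cell, true_pat$cell_id)]
    confusion <- obs |>
      dplyr::count(.data$true_pattern, .data$pattern, name = "n")
  }

  histogram_error <- NULL
  if (!is.null(run$histogram) && !is.null(confusion)) {
    snap_f <- run$config$snapshot_frame
    truth_snap <- truth[truth$frame == snap_f, , drop = FALSE]
    true_pat <- truth_pattern(truth_snap, run$config$sym_cutoff)
    exp_bip <- sum(grepl("^bipolar", true_pat$pattern))
    exp_uni <- sum(true_pat$pattern == "unipolar")
    h <- run$histogram
    n_seg <- max(h$segment)
    obs_terminal <- sum(h$count[h$segment %in% c(1, n_seg)])
    exp_terminal <- 2 * exp_bip + exp_uni
    histogram_error <- tibble::tibble(
      expected_terminal_count = exp_terminal,
      observed_terminal_count = obs_terminal,
      error = obs_terminal - exp_terminal)
  }

  list(track_map = map, reversal_metrics = reversal_metrics,
       switch_lag = switch_lag, confusion = confusion,
       histogram_error = histogram_error)
}

# True localization pattern implied by the generator's amplitudes.
truth_pattern <- function(truth_snap, sym_cutoff = 1.5) {
  a1 <- truth_snap$intensity_leading_au
  a2 <- truth_snap$intensity_lagging_au
  pattern <- ifelse(a1 == 0 & a2 == 0, "diffuse",
             ifelse(a1 == 0 | a2 == 0, "unipolar",
             ifelse(pmax(a1, a2) / pmin(a1, a2) > sym_cutoff,
                    "bipolar_asymmetric", "bipolar_symmetric")))
  tibble::tibble(cell_id = truth_snap$cell_id, pattern = pattern)
}
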