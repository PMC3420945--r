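# Centroid linking, the 10-min traveled-distance statistic, and reversal
# scoring.

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbor frame-to-frame linking. Candidate links farther
#' than `max_step` px per elapsed frame are rejected; a track may bridge up
#' to `max_gap` missing frames. Deterministic: candidate links are taken in
#' order of increasing distance, ties broken by smallest track id and then
#' lexicographic detection position. Unlinked detections start new tracks.
#'
#' @param detections tibble with columns `frame` (0-based), `x`, `y` (px);
#'   extra columns are carried through.
#' @param max_step maximum linking distance, px per frame of separation.
#' @param max_gap maximum number of consecutive missing frames bridged.
#' @return the input tibble with a `track_id` column, sorted by track then
#'   frame.
#' @export
link_tracks <- function(detections, max_step = 15, max_gap = 1) {
  if (nrow(detections) == 0)
    return(dplyr::mutate(detections, track_id = integer(0)))
  det <- dplyr::arrange(detections, .data$frame, .data$x, .data$y)
  det$track_id <- NA_integer_
  frames <- sort(unique(det$frame))
  # active track state: id, last frame, last x, last y
  state <- data.frame(id = integer(0), frame = numeric(0),
                      x = numeric(0), y = numeric(0))
  next_id <- 1L
  for (f in frames) {
    di <- which(det$frame == f)
    cand <- state[f - state$frame <= max_gap + 1 & state$frame < f, , drop = FALSE]
    if (nrow(cand) && length(di)) {
      pairs <- expand.grid(s = seq_len(nrow(cand)), d = seq_along(di))
      gapf <- f - cand$frame[pairs$s]
      dd <- sqrt((cand$x[pairs$s] - det$x[di[pairs$d]])^2 +
                   (cand$y[pairs$s] - det$y[di[pairs$d]])^2)
      ok <- dd <= max_step * gapf
      pairs <- pairs[ok, , drop = FALSE]; dd <- dd[ok]
      ord <- order(dd, cand$id[pairs$s], det$x[di[pairs$d]], det$y[di[pairs$d]])
      used_s <- logical(nrow(cand)); used_d <- logical(length(di))
      for (k in ord) {
        s <- pairs$s[k]; d <- pairs$d[k]
        if (used_s[s] || used_d[d]) next
        used_s[s] <- TRUE; used_d[d] <- TRUE
        det$track_id[di[d]] <- cand$id[s]
        j <- match(cand$id[s], state$id)
        state$frame[j] <- f; state$x[j] <- det$x[di[d]]; state$y[j] <- det$y[di[d]]
      }
    }
    new_d <- di[is.na(det$track_id[di])]
    for (d in new_d) {
      det$track_id[d] <- next_id
      state <- rbind(state, data.frame(id = next_id, frame = f,
                                       x = det$x[d], y = det$y[d]))
      next_id <- next_id + 1L
    }
  }
  dplyr::arrange(det, .data$track_id, .data$frame)
}

#' Traveled distance over a reference window
#'
#' For each track spanning at least `window_min` minutes from its start,
#' computes over that first full window both the cumulated path length
#' (sum of frame-to-frame centroid distances) and the net start-to-end
#' displacement. Shorter tracks are skipped with a message.
#'
#' @param tracks tibble from [link_tracks()] (columns `track_id`, `frame`,
#'   `x`, `y`).
#' @param frame_interval seconds between frames.
#' @param window_min reference window, minutes.
#' @return tibble `track_id`, `path_length_px`, `net_displacement_px`,
#'   `n_frames_used`.
#' @export
traveled_distance <- function(tracks, frame_interval = 30, window_min = 10) {
  n_int <- window_min * 60 / frame_interval
  out <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_map(function(d, key) {
      d <- dplyr::arrange(d, .data$frame)
      f0 <- d$frame[1]
      span <- max(d$frame) - f0
      if (span < n_int) {
        message(sprintf("track %s spans %.1f min < %g min window; skipped",
                        key$track_id, span * frame_interval / 60, window_min))
        return(NULL)
      }
      d <- d[d$frame <= f0 + n_int, , drop = FALSE]
      dx <- diff(d$x); dy <- diff(d$y)
      tibble::tibble(
        track_id = key$track_id,
        path_length_px = sum(sqrt(dx^2 + dy^2)),
        net_displacement_px = sqrt((d$x[nrow(d)] - d$x[1])^2 +
                                     (d$y[nrow(d)] - d$y[1])^2),
        n_frames_used = nrow(d))
    }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0)
    out <- tibble::tibble(track_id = integer(0), path_length_px = double(0),
                          net_displacement_px = double(0),
                          n_frames_used = integer(0))
  out
}

#' Score reversals along a track
#'
#' Projects each frame-to-frame displacement onto the cell body axis; the
#' signed direction of an interval is the sign of the projection where its
#' magnitude reaches `min_move` px (intervals below the noise floor carry no
#' direction). Movement direction is established at the first
#' supra-threshold interval; a reversal is scored at the first frame whose
#' interval shows the opposite direction, as soon as opposite movement is
#' detected.
#'
#' @param tracks tibble from [link_tracks()] with per-frame axis unit
#'   vectors `axis_x`, `axis_y` (from segmentation). Axis sign is aligned
#'   across frames internally.
#' @param min_move noise floor, px per interval.
#' @return tibble, one row per track: `track_id`, `n_reversals`, `motile`,
#'   and list-column `reversal_frames` (frame indices).
#' @export
score_reversals <- function(tracks, min_move = 1) {
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_map(function(d, key) {
      d <- dplyr::arrange(d, .data$frame)
      n <- nrow(d)
      if (n < 2)
        return(tibble::tibble(track_id = key$track_id, n_reversals = 0L,
                              motile = FALSE, reversal_frames = list(integer(0))))
      ax <- cbind(d$axis_x, d$axis_y)
      if (any(!is.finite(ax))) ax[!is.finite(ax)] <- 0
      for (i in 2:n) {   # align axis sign with the previous frame
        if (sum(ax[i, ] * ax[i - 1, ]) < 0) ax[i, ] <- -ax[i, ]
      }
      disp <- cbind(diff(d$x), diff(d$y))
      proj <- rowSums(disp * ax[-n, , drop = FALSE])
      dir <- ifelse(abs(proj) >= min_move, sign(proj), 0)
      established <- 0
      rev_fr <- integer(0)
      for (i in seq_along(dir)) {
        if (dir[i] == 0) next
        if (established == 0) { established <- dir[i]; next }
        if (dir[i] == -established) {
          rev_fr <- c(rev_fr, d$frame[i + 1])
          established <- dir[i]
        }
      }
      tibble::tibble(track_id = key$track_id,
                     n_reversals = length(rev_fr),
                     motile = any(dir != 0),
                     reversal_frames = list(as.integer(rev_fr)))
    }) |>
    dplyr::bind_rows()
}

#' Long-format reversal events
#'
#' @param reversals tibble from [score_reversals()].
#' @return tibble `track_id`, `frame`, one row per reversal event.
#' @export
reversal_events <- function(reversals) {
  reversals |>
    dplyr::select("track_id", "reversal_frames") |>
    tidyr::unnest_longer("reversal_frames", values_to = "frame") |>
    dplyr::filter(!is.na(.data$frame))
}
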