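# Pole-intensity time series, pole-to-pole switching scoring, event
# binarization and the Rxy delay cross-correlation.

#' Pole-intensity time series for one tracked cell
#'
#' For each frame of a track, measures the mean background-subtracted
#' intensity in a disk of radius `r_pole` at each pole tip, clipped to the
#' cell mask. The two physical poles are kept in correspondence across
#' frames by geometric continuity (each frame's tips are matched to the
#' previous frame's), and labelled by their initial role: the initial
#' leading pole is the pole that points in the direction of the first
#' supra-threshold movement. Roles (not poles) swap at each reversal.
#'
#' @param track_masks tibble: the rows of per-frame [segment_cells()] output
#'   belonging to one track, with columns `frame`, `x`, `y`, tip
#'   coordinates, and list-columns `pixels`; plus `background_au` column or
#'   a single background value via `background`.
#' @param frames list of frame images (full movie; indexed by `frame + 1`).
#' @param r_pole disk radius, px (default: half the median mask width
#'   proxy, 3.5 px at 0.1 um/px).
#' @param background background level in au (per-frame vector or scalar).
#' @param min_move noise floor used to find the first real movement, px.
#' @return tibble of class `pole_series`: `track_id`, `frame`,
#'   `initial_leading_au`, `initial_lagging_au`; attribute `leading_tip`
#'   ("tip1"/"tip2") records which physical pole was initially leading.
#' @export
pole_series <- function(track_masks, frames, r_pole = 3.5,
                        background = 0, min_move = 1) {
  d <- dplyr::arrange(track_masks, .data$frame)
  n <- nrow(d)
  if (n < 2) stop_rodpol("pole series needs at least 2 frames")
  bg <- rep(background, length.out = n)
  # tip correspondence by continuity: tips1/tips2 follow physical poles
  tips1 <- matrix(NA_real_, n, 2); tips2 <- matrix(NA_real_, n, 2)
  tips1[1, ] <- c(d$tip1_x[1], d$tip1_y[1])
  tips2[1, ] <- c(d$tip2_x[1], d$tip2_y[1])
  for (i in 2:n) {
    a <- c(d$tip1_x[i], d$tip1_y[i]); b <- c(d$tip2_x[i], d$tip2_y[i])
    straight <- sum((a - tips1[i - 1, ])^2) + sum((b - tips2[i - 1, ])^2)
    crossed <- sum((b - tips1[i - 1, ])^2) + sum((a - tips2[i - 1, ])^2)
    if (crossed < straight) { tips1[i, ] <- b; tips2[i, ] <- a }
    else { tips1[i, ] <- a; tips2[i, ] <- b }
  }
  meas <- function(i, tip) {
    img <- frames[[d$frame[i] + 1]]
    px <- d$pixels[[i]]
    # sparse mask: only pixels near the tip matter
    keep <- abs(px[, 2] - 1 - tip[1]) <= 3 * r_pole + 2 &
      abs(px[, 1] - 1 - tip[2]) <= 3 * r_pole + 2
    mask <- matrix(FALSE, nrow(img), ncol(img))
    mask[px[keep, , drop = FALSE]] <- TRUE
    # centre the disk on the brightest mask pixel near the tip: the scored
    # quantity is the cluster intensity, and the extracted tip coordinate
    # wobbles by ~1 px frame to frame, which a fixed disk would turn into
    # measurement noise on the steep cluster profile
    r0 <- max(1L, floor(tip[2] - r_pole) + 1L)
    r1 <- min(nrow(img), ceiling(tip[2] + r_pole) + 1L)
    c0 <- max(1L, floor(tip[1] - r_pole) + 1L)
    c1 <- min(ncol(img), ceiling(tip[1] + r_pole) + 1L)
    sub <- img[r0:r1, c0:c1, drop = FALSE]
    msk <- mask[r0:r1, c0:c1, drop = FALSE]
    centre <- tip
    if (any(msk)) {
      sub[!msk] <- -Inf
      j <- which(sub == max(sub), arr.ind = TRUE)[1, ]
      centre <- c(c0 + j[2] - 2, r0 + j[1] - 2)  # back to 0-based x, y
    }
    v <- disk_mean(img, centre[1], centre[2], r_pole, mask)
    max(v - bg[i], 0)
  }
  i1 <- vapply(seq_len(n), function(i) meas(i, tips1[i, ]), numeric(1))
  i2 <- vapply(seq_len(n), function(i) meas(i, tips2[i, ]), numeric(1))
  # initial leading pole: points along the first supra-threshold displacement
  disp <- cbind(diff(d$x), diff(d$y))
  mags <- sqrt(rowSums(disp^2))
  k <- which(mags >= min_move)[1]
  leading_tip <- "tip1"
  if (!is.na(k)) {
    v <- disp[k, ]
    if (sum((tips2[1, ] - c(d$x[1], d$y[1])) * v) >
        sum((tips1[1, ] - c(d$x[1], d$y[1])) * v))
      leading_tip <- "tip2"
  }
  lead <- if (leading_tip == "tip1") i1 else i2
  lagg <- if (leading_tip == "tip1") i2 else i1
  out <- tibble::tibble(track_id = d$track_id %||% NA_integer_,
                        frame = d$frame,
                        initial_leading_au = lead,
                        initial_lagging_au = lagg)
  structure(out, leading_tip = leading_tip,
            class = c("pole_series", class(out)))
}

#' Score pole-to-pole switching events
#'
#' For each scored reversal, the new leading pole is the pole opposite to
#' the pre-reversal movement direction; the switching event is scored at the
#' frame where that pole's fluorescence reaches its maximum within the
#' inter-reversal interval starting at the reversal. Exact ties take the
#' first frame and are flagged low-confidence.
#'
#' @param series a [pole_series()] tibble.
#' @param reversal_frames integer vector of scored reversal frames for the
#'   same cell (strictly increasing).
#' @return tibble `track_id`, `reversal_frame`, `switch_frame`, `pole`
#'   ("initial_leading"/"initial_lagging"), `low_confidence`. Empty when
#'   there are no reversals.
#' @export
score_switching <- function(series, reversal_frames) {
  reversal_frames <- sort(unique(as.integer(reversal_frames)))
  empty <- tibble::tibble(track_id = integer(0), reversal_frame = integer(0),
                          switch_frame = integer(0), pole = character(0),
                          low_confidence = logical(0))
  if (length(reversal_frames) == 0) return(empty)
  d <- dplyr::arrange(series, .data$frame)
  ends <- c(reversal_frames[-1], max(d$frame) + 1L)
  rows <- vector("list", length(reversal_frames))
  for (i in seq_along(reversal_frames)) {
    # roles alternate: after the 1st reversal the new leading pole is the
    # initial lagging pole, after the 2nd the initial leading pole, ...
    pole <- if (i %% 2 == 1) "initial_lagging" else "initial_leading"
    col <- paste0(pole, "_au")
    win <- d[d$frame >= reversal_frames[i] & d$frame < ends[i], , drop = FALSE]
    if (nrow(win) == 0) next
    v <- win[[col]]
    jmax <- which(v == max(v))
    rows[[i]] <- tibble::tibble(
      track_id = win$track_id[1], reversal_frame = reversal_frames[i],
      switch_frame = win$frame[jmax[1]], pole = pole,
      low_confidence = length(jmax) > 1)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty else out
}

#' Binarize event frames onto the frame grid
#'
#' @param event_frames integer frame indices (0-based); duplicates collapse
#'   to a single event.
#' @param n_frames length of the movie.
#' @return integer 0/1 vector of length `n_frames`.
#' @export
binarize_events <- function(event_frames, n_frames) {
  event_frames <- as.integer(event_frames)
  if (length(event_frames) &&
      (any(event_frames < 0) || any(event_frames >= n_frames)))
    stop_rodpol("event frame outside [0, n_frames)")
  v <- integer(n_frames)
  v[unique(event_frames) + 1L] <- 1L
  v
}

#' Normalized cross-correlation of two event series
#'
#' Computes the cross-correlation coefficient Rxy between a fluorescence
#' pole-inversion series x(t) and a reversal series y(t) as a function of
#' the delay m (in frames): both series are centred on their full-series
#' means, and for each delay the products `x(t) * y(t - m)` are summed over
#' the overlapping window and normalized by the series length times the
#' product of the full-series (population) standard deviations — the
#' standard cross-correlogram normalization (as in [stats::ccf()]), which
#' guarantees `|Rxy| <= 1` for every delay. A positive delay means the
#' fluorescence switch occurs m frames after the reversal. Two identical
#' non-constant series give Rxy = 1 at m = 0, the theoretical
#' perfect-correlation value.
#'
#' @param x,y equal-length numeric/integer vectors (typically 0/1 event
#'   indicators from [binarize_events()]).
#' @param m_range integer vector of delays, frames (signed).
#' @param frame_interval seconds per frame (for the `delay_s` column).
#' @return tibble of class `rxy_curve`: `delay_frames`, `delay_s`, `rxy`.
#'   If either series is constant the correlation is undefined: `rxy` is
#'   `NA` and a warning is raised (never silently 0).
#' @export
cross_correlation <- function(x, y, m_range = -4:4, frame_interval = 30) {
  if (length(x) != length(y) || length(x) == 0)
    stop_rodpol("x and y must be non-empty and of equal length")
  N <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(sum(xc^2) / N); sy <- sqrt(sum(yc^2) / N)
  m_range <- as.integer(m_range)
  if (sx == 0 || sy == 0) {
    warning("constant event series: Rxy undefined, returning NA")
    rxy <- rep(NA_real_, length(m_range))
  } else {
    rxy <- vapply(m_range, function(m) {
      if (abs(m) >= N) return(NA_real_)
      if (m >= 0) {
        t <- (m + 1):N
        sum(xc[t] * yc[t - m]) / (N * sx * sy)
      } else {
        t <- 1:(N + m)
        sum(xc[t] * yc[t - m]) / (N * sx * sy)
      }
    }, numeric(1))
  }
  structure(tibble::tibble(delay_frames = m_range,
                           delay_s = m_range * frame_interval,
                           rxy = rxy),
            n_cells = 1L, frame_interval = frame_interval,
            class = c("rxy_curve", "tbl_df", "tbl", "data.frame"))
}

#' Aggregate per-cell Rxy curves
#'
#' Averages per-cell Rxy curves over cells (all on the same delay grid) and
#' flags significance: the population shows reversal-coupled switching when
#' the mean Rxy exceeds `threshold` at some delay within `[0, window_s]`
#' (0-1 min at 30 s frames, i.e. delays 0, 30 and 60 s).
#'
#' @param curves list of [cross_correlation()] results, or one tibble with a
#'   `cell_id` column. Curves that are all-`NA` (cells without events) are
#'   dropped from the average.
#' @param threshold significance cutoff on the mean Rxy (default 0.4).
#' @param window_s delay window for the significance readout, seconds.
#' @return tibble of class `rxy_curve`: `delay_frames`, `delay_s`, `rxy`
#'   (mean), `n_cells` (cells contributing per delay); attributes `n_cells`,
#'   `significant`, `threshold`, `window_s`.
#' @export
aggregate_rxy <- function(curves, threshold = 0.4, window_s = 60) {
  if (inherits(curves, "data.frame")) {
    if (!"cell_id" %in% names(curves))
      stop_rodpol("a single tibble of curves needs a cell_id column")
    curves <- split(curves, curves$cell_id)
  }
  if (length(curves) == 0) stop_rodpol("no curves to aggregate")
  grid <- curves[[1]]$delay_frames
  for (cu in curves)
    if (!identical(as.integer(cu$delay_frames), as.integer(grid)))
      stop_rodpol("per-cell curves are on different delay grids")
  fi <- attr(curves[[1]], "frame_interval") %||%
    (if (length(grid) > 1) diff(curves[[1]]$delay_s[1:2]) / diff(grid[1:2]) else 30)
  mat <- vapply(curves, function(cu) as.numeric(cu$rxy), numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  usable <- colSums(is.na(mat)) < nrow(mat)
  if (!any(usable)) stop_rodpol("all per-cell curves are undefined")
  mat <- mat[, usable, drop = FALSE]
  mean_rxy <- rowMeans(mat, na.rm = TRUE)
  n_per <- rowSums(!is.na(mat))
  delay_s <- grid * fi
  in_win <- delay_s >= 0 & delay_s <= window_s
  sig <- any(mean_rxy[in_win] > threshold, na.rm = TRUE)
  structure(tibble::tibble(delay_frames = as.integer(grid),
                           delay_s = delay_s, rxy = mean_rxy,
                           n_cells = n_per),
            n_cells = ncol(mat), significant = sig, threshold = threshold,
            window_s = window_s, frame_interval = fi,
            class = c("rxy_curve", "tbl_df", "tbl", "data.frame"))
}
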