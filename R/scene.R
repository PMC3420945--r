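# Synthetic time-lapse scenes of gliding, reversing rod cells with
# programmable polar fluorescence dynamics, plus exact ground truth.

#' Configuration for a synthetic time-lapse scene
#'
#' Describes a movie of rod-shaped cells gliding along their long axis,
#' reversing direction at programmable times, and relocating a polar
#' fluorescent cluster to the new leading pole a programmable number of
#' frames after each reversal. The defaults emulate a typical widefield
#' acquisition of *Myxococcus xanthus*-like cells: 0.1 um/px, 30 s frames,
#' 20 min movies, ~4 x 0.7 um cells gliding at ~2 um/min, reversing on
#' average every 8 min.
#'
#' @param n_cells number of cells. Cells are laid out in disjoint horizontal
#'   lanes so they never touch (isolated-cell analysis).
#' @param n_frames number of frames (>= 2).
#' @param frame_interval frame interval in seconds.
#' @param pixel_size um per pixel.
#' @param image_shape integer c(height, width) in px, or `NULL` to size the
#'   image automatically from `n_cells` and the motion range.
#' @param cell_length_um,cell_width_um cell geometry in um.
#' @param speed_um_per_min gliding speed in um/min.
#' @param reversal_process either `list(type = "fixed", frames = c(...))`
#'   (0-based frame indices at which velocity flips, same schedule for every
#'   cell) or `list(type = "poisson", mean_interval_min = m)` (memoryless
#'   reversals with the given mean interval, drawn per cell).
#' @param switch_lag_frames signed integer lag, in frames, between a reversal
#'   and the relocation of the polar cluster to the new leading pole
#'   (positive: cluster switches after the reversal). Scalar or one value per
#'   cell.
#' @param polar_cluster_amplitudes peak amplitudes (au, above the diffuse
#'   cytoplasmic level, before blur) of the Gaussian cluster at the leading
#'   and lagging pole: `c(leading, lagging)`, or an `n_cells x 2` matrix for
#'   per-cell patterns (e.g. a unipolar cell has lagging amplitude 0).
#' @param diffuse_level diffuse cytoplasmic intensity (au).
#' @param camera_offset constant camera baseline added to every pixel (au).
#' @param bleach_per_frame fractional photobleaching per frame applied to all
#'   cellular fluorescence (not the camera offset). A small decay makes the
#'   "maximum fluorescence at the new leading pole" switching criterion
#'   well-posed: after the cluster arrives, intensity peaks and then fades,
#'   as in real acquisitions.
#' @param noise `list(poisson_scale, gaussian_sd)`. If `poisson_scale > 0`
#'   each pixel is replaced by `rpois(intensity * scale) / scale` (shot
#'   noise); Gaussian read noise of the given sd (au) is then added. Either
#'   can be 0 to disable.
#' @param spot_sd,psf_sd Gaussian cluster footprint sd and point-spread
#'   blur sd, in px.
#' @param seed integer; fully determines the movie and its ground truth.
#'
#' @return an object of class `scene_config` (a validated list).
#' @export
scene_config <- function(n_cells = 20,
                         n_frames = 40,
                         frame_interval = 30,
                         pixel_size = 0.1,
                         image_shape = NULL,
                         cell_length_um = 4,
                         cell_width_um = 0.7,
                         speed_um_per_min = 2,
                         reversal_process = list(type = "poisson", mean_interval_min = 8),
                         switch_lag_frames = 1,
                         polar_cluster_amplitudes = c(800, 300),
                         diffuse_level = 180,
                         camera_offset = 100,
                         bleach_per_frame = 0.02,
                         noise = list(poisson_scale = 1, gaussian_sd = 10),
                         spot_sd = 1.5,
                         psf_sd = 1.5,
                         seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
              frame_interval = frame_interval, pixel_size = pixel_size,
              image_shape = image_shape, cell_length_um = cell_length_um,
              cell_width_um = cell_width_um, speed_um_per_min = speed_um_per_min,
              reversal_process = reversal_process,
              switch_lag_frames = switch_lag_frames,
              polar_cluster_amplitudes = polar_cluster_amplitudes,
              diffuse_level = diffuse_level, camera_offset = camera_offset,
              bleach_per_frame = bleach_per_frame, noise = noise,
              spot_sd = spot_sd, psf_sd = psf_sd, seed = as.integer(seed))
  validate_scene_config(cfg)
}

validate_scene_config <- function(cfg) {
  geom <- c(cfg$pixel_size, cfg$cell_length_um, cfg$cell_width_um,
            cfg$frame_interval, cfg$spot_sd, cfg$psf_sd)
  if (any(!is.finite(geom)) || any(geom <= 0))
    stop_rodpol("all geometric quantities must be strictly positive")
  if (cfg$n_cells < 1) stop_rodpol("n_cells must be >= 1")
  if (cfg$n_frames < 2) stop_rodpol("n_frames must be >= 2")
  if (cfg$speed_um_per_min < 0) stop_rodpol("speed must be nonnegative")
  if (cfg$cell_width_um >= cfg$cell_length_um)
    stop_rodpol("cell width must be smaller than cell length")
  amp <- cfg$polar_cluster_amplitudes
  if (is.matrix(amp)) {
    if (nrow(amp) != cfg$n_cells || ncol(amp) != 2)
      stop_rodpol("amplitude matrix must be n_cells x 2")
  } else if (length(amp) != 2) {
    stop_rodpol("polar_cluster_amplitudes must be length 2 or an n_cells x 2 matrix")
  }
  if (any(amp < 0)) stop_rodpol("cluster amplitudes must be nonnegative")
  if (!length(cfg$switch_lag_frames) %in% c(1L, cfg$n_cells))
    stop_rodpol("switch_lag_frames must be scalar or one value per cell")
  rp <- cfg$reversal_process
  if (!is.list(rp) || is.null(rp$type) ||
      !rp$type %in% c("fixed", "poisson", "none"))
    stop_rodpol("reversal_process$type must be 'fixed', 'poisson' or 'none'")
  if (rp$type == "fixed" && is.null(rp$frames))
    stop_rodpol("fixed reversal_process needs $frames")
  if (rp$type == "poisson" &&
      (is.null(rp$mean_interval_min) || rp$mean_interval_min <= 0))
    stop_rodpol("poisson reversal_process needs a positive $mean_interval_min")
  structure(cfg, class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(
    "<scene_config> %d cells, %d frames @ %gs (%.1f min), %g um/px, seed %d\n",
    x$n_cells, x$n_frames, x$frame_interval,
    x$n_frames * x$frame_interval / 60, x$pixel_size, x$seed))
  invisible(x)
}

# Geometry of the scene in pixels, plus the auto image shape.
scene_geometry <- function(cfg) {
  len_px <- cfg$cell_length_um / cfg$pixel_size
  wid_px <- cfg$cell_width_um / cfg$pixel_size
  step_px <- cfg$speed_um_per_min / 60 * cfg$frame_interval / cfg$pixel_size
  lane_h <- ceiling(wid_px) + 9
  shape <- cfg$image_shape
  if (is.null(shape)) {
    height <- 2L * 20L + cfg$n_cells * lane_h
    # worst case: monotone drift over the whole movie plus jitter and margin
    half_w <- ceiling(step_px * (cfg$n_frames - 1) + 30 + 1.5 * len_px + 10)
    shape <- c(height, 2L * half_w)
  }
  list(len_px = len_px, wid_px = wid_px, step_px = step_px,
       lane_h = lane_h, shape = as.integer(shape))
}

# Draw reversal frames (0-based) for one cell.
draw_reversals <- function(rp, n_frames, frame_interval) {
  if (rp$type == "none") return(integer(0))
  if (rp$type == "fixed") {
    fr <- sort(unique(as.integer(rp$frames)))
  } else {
    t_min <- 0
    total_min <- n_frames * frame_interval / 60
    ev <- c()
    repeat {
      t_min <- t_min + stats::rexp(1, rate = 1 / rp$mean_interval_min)
      if (t_min >= total_min) break
      ev <- c(ev, t_min)
    }
    fr <- sort(unique(as.integer(ceiling(ev * 60 / frame_interval))))
  }
  fr[fr >= 1 & fr <= n_frames - 2]
}

#' Generate a synthetic movie with ground truth
#'
#' Renders `n_frames` images of gliding, reversing rod cells (see
#' [scene_config()]) and returns them together with exact per-frame ground
#' truth. Identical `config` (including its seed) produces bit-identical
#' output.
#'
#' @param config a [scene_config()].
#' @param render render pixel frames (`TRUE`); with `FALSE` only the ground
#'   truth and event tables are produced (`frames` is `NULL`), which is
#'   useful for statistical checks on the event processes at large n.
#' @return a list of class `rodpol_movie` with elements
#'   \describe{
#'     \item{frames}{list of `n_frames` numeric matrices (au, clipped to
#'       the 16-bit range).}
#'     \item{truth}{tibble, one row per cell per frame: `cell_id`, `frame`
#'       (0-based), centroid `x`, `y` (0-based px), `orientation` (radians),
#'       `velocity_sign`, `polarity_sign` (+1: cluster at the +x pole),
#'       `intensity_leading_au`, `intensity_lagging_au` (true cluster
#'       amplitudes after bleaching).}
#'     \item{events}{tibble `cell_id`, `event` ("reversal"/"switch"),
#'       `frame`.}
#'     \item{config}{the input configuration.}
#'     \item{clip_fraction}{fraction of pixels clipped at the 16-bit limits.}
#'   }
#' @export
generate_movie <- function(config, render = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  geo <- scene_geometry(config)
  H <- geo$shape[1]; W <- geo$shape[2]
  n <- config$n_cells; nf <- config$n_frames

  if (2 * 20 + n * geo$lane_h > H)
    stop_rodpol(sprintf("image height %d cannot fit %d cell lanes", H, n))

  amp <- config$polar_cluster_amplitudes
  if (!is.matrix(amp)) amp <- matrix(rep(amp, each = n), n, 2)
  lag <- rep(config$switch_lag_frames, length.out = n)

  withr::with_seed(config$seed, {
    cells <- vector("list", n)
    for (i in seq_len(n)) {
      y <- 20 + (i - 0.5) * geo$lane_h
      x0 <- W / 2 + stats::runif(1, -30, 30)
      dir0 <- sample(c(-1, 1), 1)
      rev_fr <- draw_reversals(config$reversal_process, nf, config$frame_interval)
      sw_fr <- sort(unique(pmin(pmax(rev_fr + lag[i], 0L), nf - 1L)))
      fr <- 0:(nf - 1)
      n_rev_before <- vapply(fr, function(f) sum(rev_fr <= f), integer(1))
      n_sw_before <- vapply(fr, function(f) sum(sw_fr <= f), integer(1))
      v_sign <- dir0 * (-1)^n_rev_before
      p_sign <- dir0 * (-1)^n_sw_before
      x <- x0 + c(0, cumsum(v_sign[-nf] * geo$step_px))
      lo <- geo$len_px; hi <- W - 1 - geo$len_px
      if (any(x < lo | x > hi))
        stop_rodpol(sprintf(
          "cell %d leaves the usable field (x range %.0f..%.0f px); enlarge image_shape or slow the cells",
          i, min(x), max(x)))
      bleach <- (1 - config$bleach_per_frame)^fr
      cells[[i]] <- tibble::tibble(
        cell_id = i, frame = fr, x = x, y = y, orientation = 0,
        velocity_sign = as.integer(v_sign), polarity_sign = as.integer(p_sign),
        intensity_leading_au = amp[i, 1] * bleach,
        intensity_lagging_au = amp[i, 2] * bleach)
      attr(cells[[i]], "rev_fr") <- rev_fr
      attr(cells[[i]], "sw_fr") <- sw_fr
    }

    events <- dplyr::bind_rows(lapply(cells, function(tr) {
      dplyr::bind_rows(
        tibble::tibble(cell_id = tr$cell_id[1], event = "reversal",
                       frame = as.integer(attr(tr, "rev_fr"))),
        tibble::tibble(cell_id = tr$cell_id[1], event = "switch",
                       frame = as.integer(attr(tr, "sw_fr"))))
    }))
    truth <- dplyr::bind_rows(lapply(cells, function(tr) {
      attr(tr, "rev_fr") <- NULL; attr(tr, "sw_fr") <- NULL; tr
    }))

    frames <- if (render) vector("list", nf) else NULL
    n_clip <- 0
    if (render) for (f in seq_len(nf) - 1L) {
      canvas <- matrix(0, H, W)
      for (i in seq_len(n)) {
        tr <- cells[[i]]
        row <- f + 1L
        bleach <- (1 - config$bleach_per_frame)^f
        # cluster sits at the pole designated by polarity_sign
        a_plus <- if (tr$polarity_sign[row] > 0) amp[i, 1] else amp[i, 2]
        a_minus <- if (tr$polarity_sign[row] > 0) amp[i, 2] else amp[i, 1]
        canvas <- add_cell_field(
          canvas, center = c(tr$x[row], tr$y[row]), angle = 0,
          length_px = geo$len_px, width_px = geo$wid_px,
          diffuse = config$diffuse_level * bleach,
          spot_plus = a_plus * bleach, spot_minus = a_minus * bleach,
          spot_sd = config$spot_sd)
      }
      img <- blur_psf(canvas, config$psf_sd) + config$camera_offset
      ps <- config$noise$poisson_scale %||% 0
      gs <- config$noise$gaussian_sd %||% 0
      if (ps > 0)
        img <- matrix(stats::rpois(length(img), pmax(img, 0) * ps) / ps, H, W)
      if (gs > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, gs), H, W)
      n_clip <- n_clip + sum(img < 0 | img > 65535)
      frames[[f + 1L]] <- pmin(pmax(img, 0), 65535)
    }
  })

  structure(list(frames = frames, truth = truth, events = events,
                 config = config,
                 clip_fraction = n_clip / (as.numeric(H) * W * nf)),
            class = "rodpol_movie")
}

#' @export
print.rodpol_movie <- function(x, ...) {
  if (is.null(x$frames)) {
    cat(sprintf("<rodpol_movie> truth only (%d frames), %d cells, %d events\n",
                x$config$n_frames, x$config$n_cells, nrow(x$events)))
  } else {
    cat(sprintf("<rodpol_movie> %d frames %dx%d px, %d cells, %d events\n",
                length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
                x$config$n_cells, nrow(x$events)))
  }
  invisible(x)
}

# Add one cell's (unblurred) fluorescence field into a canvas, in place.
# spot_plus / spot_minus are the Gaussian peak amplitudes at the poles in
# the +x / -x axis direction (after rotating by `angle`).
add_cell_field <- function(canvas, center, angle, length_px, width_px,
                           diffuse, spot_plus, spot_minus, spot_sd) {
  H <- nrow(canvas); W <- ncol(canvas)
  half <- length_px / 2
  u <- c(cos(angle), sin(angle))
  # cluster centres sit at the pole apexes: polar clusters hug the extreme
  # cell tip, so they fall in the terminal axial segments of the profile
  pole_off <- half
  p_plus <- center + pole_off * u
  p_minus <- center - pole_off * u
  pad <- ceiling(half + 4 * spot_sd + 2)
  c0 <- max(1L, floor(center[1] - pad) + 1L)
  c1 <- min(W, ceiling(center[1] + pad) + 1L)
  r0 <- max(1L, floor(center[2] - pad) + 1L)
  r1 <- min(H, ceiling(center[2] + pad) + 1L)
  if (c0 > c1 || r0 > r1) return(canvas)
  rows <- r0:r1; cols <- c0:c1
  yy <- matrix(rows - 1, length(rows), length(cols))
  xx <- matrix(cols - 1, length(rows), length(cols), byrow = TRUE)
  e1 <- center + (half - width_px / 2) * u
  e2 <- center - (half - width_px / 2) * u
  d <- dist_to_segment(as.vector(xx), as.vector(yy), e1, e2)
  cover <- pmin(1, pmax(0, width_px / 2 + 0.5 - d))
  field <- diffuse * cover
  if (spot_plus > 0)
    field <- field + spot_plus *
      exp(-((as.vector(xx) - p_plus[1])^2 + (as.vector(yy) - p_plus[2])^2) /
            (2 * spot_sd^2))
  if (spot_minus > 0)
    field <- field + spot_minus *
      exp(-((as.vector(xx) - p_minus[1])^2 + (as.vector(yy) - p_minus[2])^2) /
            (2 * spot_sd^2))
  canvas[rows, cols] <- canvas[rows, cols] +
    matrix(field, length(rows), length(cols))
  canvas
}

#' Render a single rod cell
#'
#' Renders the fluorescence field of one spherocylindrical cell: a rod
#' footprint (rectangle capped by half-disks) filled with a diffuse level,
#' plus Gaussian clusters centred at the two pole apexes, blurred with the
#' point-spread function.
#'
#' @param image_shape c(height, width) px.
#' @param center centroid c(x, y), 0-based px.
#' @param angle body-axis angle, radians.
#' @param length_px,width_px cell geometry, px.
#' @param diffuse_level diffuse intensity (au).
#' @param spot_amplitudes c(amplitude at the +axis pole, at the -axis pole).
#' @param spot_sd,psf_sd cluster footprint sd and PSF sd, px.
#' @param blur apply the PSF (set `FALSE` for the raw field).
#' @return numeric matrix `image_shape`.
#' @export
render_cell <- function(image_shape, center, angle = 0, length_px, width_px,
                        diffuse_level = 150, spot_amplitudes = c(0, 0),
                        spot_sd = 1.5, psf_sd = 1.5, blur = TRUE) {
  if (width_px >= length_px) stop_rodpol("cell width must be below length")
  half <- length_px / 2
  if (center[1] < half || center[1] > image_shape[2] - 1 - half ||
      center[2] < half || center[2] > image_shape[1] - 1 - half)
    stop_rodpol("cell geometry does not fit inside the image")
  canvas <- matrix(0, image_shape[1], image_shape[2])
  canvas <- add_cell_field(canvas, center, angle, length_px, width_px,
                           diffuse_level, spot_amplitudes[1],
                           spot_amplitudes[2], spot_sd)
  if (blur) blur_psf(canvas, psf_sd) else canvas
}

#' Write / read a 16-bit multi-frame TIFF stack
#'
#' Intensities are rounded to integers and clipped to `[0, 65535]`; reading
#' back reproduces the stored integers exactly.
#'
#' @param frames list of numeric matrices (or a `rodpol_movie`).
#' @param path output file.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns a
#'   list of numeric matrices.
#' @export
write_stack <- function(frames, path) {
  if (inherits(frames, "rodpol_movie")) frames <- frames$frames
  if (length(frames) == 0) stop_rodpol("empty frame list")
  scaled <- lapply(frames, function(m) {
    i <- round(pmin(pmax(m, 0), 65535))
    pmin((i + 0.5) / 65535, 1)   # +0.5: the writer floors to grey levels
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  lapply(imgs, function(m) matrix(as.numeric(m), nrow(m), ncol(m)))
}

#' Write / read ground-truth tables
#'
#' Per-frame truth and event tables round-trip exactly through CSV.
#'
#' @param truth,events tibbles as produced by [generate_movie()].
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  if (is.null(truth) || nrow(truth) == 0)
    stop_rodpol("refusing to write an empty truth table")
  readr::write_csv(truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    cell_id = readr::col_integer(), frame = readr::col_integer(),
    x = readr::col_double(), y = readr::col_double(),
    orientation = readr::col_double(),
    velocity_sign = readr::col_integer(), polarity_sign = readr::col_integer(),
    intensity_leading_au = readr::col_double(),
    intensity_lagging_au = readr::col_double()))
}

#' @rdname write_truth
#' @export
write_events <- function(events, path) {
  if (is.null(events) || nrow(events) == 0)
    stop_rodpol("refusing to write an empty events table")
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_events <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    cell_id = readr::col_integer(), event = readr::col_character(),
    frame = readr::col_integer()))
}
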