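# Per-frame segmentation, axial intensity profiling, 15-segment splicing,
# threshold-based cluster detection, occurrence histograms and
# unipolar/bipolar pattern classification.

# ---- skeleton / centerline ------------------------------------------------

# Zhang-Suen thinning of a logical matrix (TRUE = foreground). Deterministic.
thin_mask <- function(mask) {
  m <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(x, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- shift(m, -1, 0); p3 <- shift(m, -1, 1); p4 <- shift(m, 0, 1)
      p5 <- shift(m, 1, 1); p6 <- shift(m, 1, 0); p7 <- shift(m, 1, -1)
      p8 <- shift(m, 0, -1); p9 <- shift(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seq9 <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, nr, nc)
      for (k in 1:8) a <- a + (!seq9[[k]] & seq9[[k + 1]])
      if (pass == 1) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)]
}

# BFS over 8-connected skeleton pixels. Returns for each pixel the hop
# distance from `start` (index into coords) and the BFS parent.
skel_bfs <- function(coords, start) {
  n <- nrow(coords)
  key <- paste(coords[, 1], coords[, 2])
  idx <- stats::setNames(seq_len(n), key)
  offs <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  dist <- rep(NA_integer_, n); parent <- rep(NA_integer_, n)
  dist[start] <- 0L
  queue <- start; head <- 1L
  while (head <= length(queue)) {
    cur <- queue[head]; head <- head + 1L
    nb <- cbind(coords[cur, 1] + offs[, 1], coords[cur, 2] + offs[, 2])
    j <- idx[paste(nb[, 1], nb[, 2])]
    j <- j[!is.na(j)]
    j <- j[is.na(dist[j])]
    if (length(j)) {
      dist[j] <- dist[cur] + 1L
      parent[j] <- cur
      queue <- c(queue, j)
    }
  }
  list(dist = dist, parent = parent)
}

# Longest geodesic path through a skeleton; coords is an n x 2 matrix of
# (row, col). Ties broken by lexicographic (row, col) order of endpoints.
longest_path <- function(coords) {
  ord <- order(coords[, 1], coords[, 2])
  coords <- coords[ord, , drop = FALSE]
  b1 <- skel_bfs(coords, 1L)
  reach <- which(!is.na(b1$dist))
  far1 <- reach[b1$dist[reach] == max(b1$dist[reach])][1]
  b2 <- skel_bfs(coords, far1)
  reach <- which(!is.na(b2$dist))
  far2 <- reach[b2$dist[reach] == max(b2$dist[reach])][1]
  path <- far2
  while (!is.na(b2$parent[path[1]])) path <- c(b2$parent[path[1]], path)
  coords[path, , drop = FALSE]
}

# Extend a centerline to the mask boundary along its end tangents; returns
# continuous (x, y) coordinates, tip to tip.
extend_centerline <- function(path_rc, mask) {
  xy <- cbind(path_rc[, 2] - 1, path_rc[, 1] - 1)  # 0-based x, y
  inside <- function(p) {
    r <- round(p[2]) + 1; c <- round(p[1]) + 1
    r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) && mask[r, c]
  }
  extend_one <- function(end, ref) {
    v <- end - ref
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) return(NULL)
    v <- v / nv
    pts <- NULL
    for (k in seq_len(80)) {
      q <- end + v * 0.25 * k
      if (!inside(q)) break
      pts <- rbind(pts, q)
    }
    pts
  }
  n <- nrow(xy)
  k <- min(5, n - 1)
  head_ext <- extend_one(xy[1, ], xy[1 + k, ])
  tail_ext <- extend_one(xy[n, ], xy[n - k, ])
  out <- xy
  if (!is.null(head_ext))
    out <- rbind(head_ext[nrow(head_ext):1, , drop = FALSE], out)
  if (!is.null(tail_ext)) out <- rbind(out, tail_ext)
  out
}

# ---- segmentation ---------------------------------------------------------

#' Segment rod cells in a fluorescence frame
#'
#' Thresholds the frame (Otsu by default, or an absolute level), labels
#' connected components, filters by area, and extracts a centerline per
#' cell by skeletonizing the mask, taking its longest geodesic path and
#' extending it to the boundary along the end tangents. Pole tips are the
#' two extended endpoints, ordered so the lexicographically smaller (x,
#' then y) tip comes first.
#'
#' @param image numeric matrix (au).
#' @param method `"otsu"` (histogram bimodality), `"robust"` (background
#'   median + `k_mad` times the MAD — stable when cells cover only a small
#'   image fraction, as in sparse time-lapse fields), or `"absolute"`.
#' @param level threshold in au when `method = "absolute"`.
#' @param k_mad MAD multiplier for `method = "robust"`.
#' @param min_area,max_area component area limits in px.
#' @return tibble with one row per cell: `cell_id`, `area_px`, centroid
#'   `x`/`y` (0-based px), `tip1_x`/`tip1_y`/`tip2_x`/`tip2_y`,
#'   `axis_x`/`axis_y` (unit vector tip1 -> tip2), and list-columns `axis`
#'   (ordered centerline points, n x 2 matrix of x, y) and `pixels`
#'   (n x 2 matrix of row, col, 1-based). Attribute `threshold_au` records
#'   the level used; attribute `background_au` the median intensity of the
#'   non-cell pixels. Cells are ordered by centroid (x, then y). An image
#'   with no acceptable component yields an empty tibble, not an error.
#' @export
segment_cells <- function(image, method = c("otsu", "robust", "absolute"),
                          level = NULL, min_area = 50, max_area = Inf,
                          k_mad = 4) {
  method <- match.arg(method)
  if (method == "absolute") {
    if (is.null(level)) stop_rodpol("method 'absolute' needs a level")
    th <- level
  } else if (method == "robust") {
    md <- stats::median(image); s <- stats::mad(image)
    if (s > 1e-6 * max(md, 1)) {
      th <- md + k_mad * s
    } else if (max(image) - md < 1e-6) {
      return(empty_masks(background = md))
    } else {
      # noise-free background (MAD 0): halfway between the background
      # plateau and the cell-body level (95th percentile of above-
      # background pixels, robust to bright polar spots)
      body <- stats::quantile(image[image > md + 1e-9], 0.95, names = FALSE)
      th <- md + 0.5 * (body - md)
    }
    if (th >= max(image)) return(empty_masks(background = md,
                                             threshold = th))
  } else {
    rng <- range(image)
    if (diff(rng) < 1e-12) {
      # constant image: nothing to segment
      return(empty_masks(background = rng[1]))
    }
    v <- (image - rng[1]) / diff(rng)
    th <- rng[1] + diff(rng) *
      EBImage::otsu(EBImage::Image(v), range = c(0, 1), levels = 256)
  }
  mask <- image > th
  bg <- stats::median(image[!mask])
  if (!any(mask)) return(empty_masks(background = bg, threshold = th))
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  n_lab <- max(lab)
  rows <- list()
  for (k in seq_len(n_lab)) {
    px <- which(lab == k, arr.ind = TRUE)
    area <- nrow(px)
    if (area < min_area || area > max_area) next
    if (area < 3) next
    # work in a cropped window around the component
    r0 <- min(px[, 1]) - 1L; c0 <- min(px[, 2]) - 1L
    sub <- matrix(FALSE, max(px[, 1]) - r0 + 2L, max(px[, 2]) - c0 + 2L)
    sub[cbind(px[, 1] - r0, px[, 2] - c0)] <- TRUE
    cm <- thin_mask(sub)
    coords <- which(cm, arr.ind = TRUE)
    if (nrow(coords) < 2) next
    path <- longest_path(coords)
    axis_xy <- extend_centerline(path, sub)
    if (nrow(axis_xy) < 3) next
    axis_xy[, 1] <- axis_xy[, 1] + c0 - 1L   # back to full-image 0-based x, y
    axis_xy[, 2] <- axis_xy[, 2] + r0 - 1L
    t1 <- axis_xy[1, ]; t2 <- axis_xy[nrow(axis_xy), ]
    if (t1[1] > t2[1] || (t1[1] == t2[1] && t1[2] > t2[2])) {
      axis_xy <- axis_xy[nrow(axis_xy):1, , drop = FALSE]
      tmp <- t1; t1 <- t2; t2 <- tmp
    }
    u <- t2 - t1; u <- u / sqrt(sum(u^2))
    rows[[length(rows) + 1]] <- tibble::tibble(
      area_px = area,
      x = mean(px[, 2] - 1), y = mean(px[, 1] - 1),
      tip1_x = t1[1], tip1_y = t1[2], tip2_x = t2[1], tip2_y = t2[2],
      axis_x = u[1], axis_y = u[2],
      axis = list(axis_xy), pixels = list(px))
  }
  if (!length(rows)) return(empty_masks(background = bg, threshold = th))
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$x, out$y), ]
  out <- dplyr::bind_cols(tibble::tibble(cell_id = seq_len(nrow(out))), out)
  attr(out, "threshold_au") <- th
  attr(out, "background_au") <- bg
  out
}

empty_masks <- function(background = NA_real_, threshold = NA_real_) {
  out <- tibble::tibble(
    cell_id = integer(0), area_px = integer(0), x = double(0), y = double(0),
    tip1_x = double(0), tip1_y = double(0), tip2_x = double(0),
    tip2_y = double(0), axis_x = double(0), axis_y = double(0),
    axis = list(), pixels = list())
  attr(out, "threshold_au") <- threshold
  attr(out, "background_au") <- background
  out
}

# ---- axial profile --------------------------------------------------------

#' Axial fluorescence profile of one cell
#'
#' Samples the background-subtracted intensity along the centerline: at each
#' centerline point, the profile value is the mean intensity over the mask
#' cross-section perpendicular to the local axis (band average, robust to
#' noise). Positions are arc length along the centerline in px.
#'
#' @param image numeric matrix (au).
#' @param mask one row of a [segment_cells()] tibble.
#' @param background background level in au, subtracted and floored at 0.
#'   Defaults to the per-frame non-cell median recorded by [segment_cells()].
#' @param step arc-length sampling step along the axis (px).
#' @param cross_step sampling step across the cell (px).
#' @param boundary_frac cell boundaries are defined by thresholding the
#'   axial profile at this fraction of its central (interquartile) median;
#'   the restricted profile between the outermost crossings (of a lightly
#'   smoothed copy, so single noisy samples cannot truncate the cell) is
#'   returned with positions re-zeroed. Set to 0 to disable.
#' @param tip_trim_px fixed arc length additionally removed from each end
#'   after thresholding, in px. The above-threshold mask overhangs the
#'   physical poles by the point-spread blur skirt; trimming twice the PSF
#'   sd (3 px at the default 1.5 px PSF) places the profile ends at the
#'   poles themselves, so polar clusters fall in the terminal segments.
#' @return tibble `cell_id`, `position_px` (strictly increasing, starting at
#'   0), `intensity_au` (>= 0).
#' @export
axial_profile <- function(image, mask, background = NULL, step = 0.5,
                          cross_step = 0.5, boundary_frac = 0.5,
                          tip_trim_px = 3) {
  axis_xy <- mask$axis[[1]]
  if (is.null(axis_xy) || nrow(axis_xy) < 3)
    stop_rodpol(sprintf("cell %s: degenerate axis (< 3 points)",
                        mask$cell_id[1]))
  bg <- background %||% attr(mask, "background_au") %||% 0
  px <- mask$pixels[[1]]
  rmin <- min(px[, 1]); rmax <- max(px[, 1])
  cmin <- min(px[, 2]); cmax <- max(px[, 2])
  local <- matrix(FALSE, nrow(image), ncol(image))
  local[px] <- TRUE
  half_w <- max(rmax - rmin, cmax - cmin, 4) / 2  # generous cross half-width

  # uniform arc-length resampling of the centerline polyline
  n <- nrow(axis_xy)
  seglen <- sqrt(rowSums((axis_xy[-1, , drop = FALSE] -
                            axis_xy[-n, , drop = FALSE])^2))
  keep <- c(TRUE, seglen > 1e-9)
  axis_xy <- axis_xy[keep, , drop = FALSE]
  n <- nrow(axis_xy)
  if (n < 3) stop_rodpol(sprintf("cell %s: degenerate axis (< 3 points)",
                                 mask$cell_id[1]))
  seglen <- sqrt(rowSums((axis_xy[-1, , drop = FALSE] -
                            axis_xy[-n, , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  L <- cum[n]
  pos <- seq(0, L, by = step)
  ax <- stats::approx(cum, axis_xy[, 1], xout = pos)$y
  ay <- stats::approx(cum, axis_xy[, 2], xout = pos)$y

  m <- length(pos)
  vals <- numeric(m)
  offs <- seq(-half_w, half_w, by = cross_step)
  imgsub <- pmax(image - bg, 0)
  for (i in seq_len(m)) {
    a <- max(1, i - 1); b <- min(m, i + 1)
    tg <- c(ax[b] - ax[a], ay[b] - ay[a])
    tg <- tg / sqrt(sum(tg^2))
    nrm <- c(-tg[2], tg[1])
    sx <- ax[i] + offs * nrm[1]
    sy <- ay[i] + offs * nrm[2]
    rr <- round(sy) + 1; cc <- round(sx) + 1
    ok <- rr >= 1 & rr <= nrow(image) & cc >= 1 & cc <= ncol(image)
    ok[ok] <- local[cbind(rr[ok], cc[ok])]
    if (!any(ok)) { vals[i] <- NA_real_; next }
    vals[i] <- mean(bilinear(imgsub, sx[ok], sy[ok]))
  }
  ok <- !is.na(vals)
  pos <- pos[ok]; vals <- vals[ok]

  if (boundary_frac > 0 && length(vals) > 8) {
    central <- vals[pos >= stats::quantile(pos, 0.25) &
                      pos <= stats::quantile(pos, 0.75)]
    level <- boundary_frac * stats::median(central)
    # smooth (5-sample running mean) only for the boundary decision
    k <- 5
    vsm <- as.numeric(stats::filter(vals, rep(1 / k, k), sides = 2))
    vsm[is.na(vsm)] <- vals[is.na(vsm)]
    above <- vsm >= level
    # maximal contiguous run containing the profile midpoint
    mid <- which.min(abs(pos - stats::median(pos)))
    if (above[mid]) {
      lo <- mid; while (lo > 1 && above[lo - 1]) lo <- lo - 1
      hi <- mid; while (hi < length(above) && above[hi + 1]) hi <- hi + 1
      pos <- pos[lo:hi]; vals <- vals[lo:hi]
      pos <- pos - pos[1]
    }
  }
  if (tip_trim_px > 0 && diff(range(pos)) > 2 * tip_trim_px + 4) {
    keep <- pos >= min(pos) + tip_trim_px & pos <= max(pos) - tip_trim_px
    pos <- pos[keep]; vals <- vals[keep]
    pos <- pos - pos[1]
  }
  tibble::tibble(cell_id = mask$cell_id[1], position_px = pos,
                 intensity_au = vals)
}

# ---- 15-segment splicing --------------------------------------------------

#' Splice an axial profile into equal-length segments
#'
#' Divides the profile's arc length into `n_segments` equal intervals and
#' computes the length-weighted mean intensity in each, treating the profile
#' as piecewise constant between sample midpoints; samples straddling a
#' segment boundary contribute fractionally. Total integrated intensity is
#' conserved exactly.
#'
#' @param profile tibble from [axial_profile()] (may contain several cells /
#'   frames; spliced per group).
#' @param n_segments number of segments (15, the standard choice for these
#'   occurrence histograms).
#' @return tibble `cell_id` (and `frame` if present), `segment` (1-based,
#'   tip1 -> tip2), `value_au`.
#' @export
splice_segments <- function(profile, n_segments = 15) {
  grp <- intersect(c("cell_id", "frame"), names(profile))
  profile |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(d, key) {
      splice_one(d$position_px, d$intensity_au, n_segments)
    }) |>
    dplyr::ungroup()
}

splice_one <- function(pos, val, n_segments) {
  if (length(pos) < 2 || diff(range(pos)) <= 0)
    stop_rodpol("profile arc length must be positive")
  o <- order(pos)
  pos <- pos[o]; val <- val[o]
  n <- length(pos)
  mids <- (pos[-1] + pos[-n]) / 2
  edges <- c(pos[1], mids, pos[n])
  L0 <- pos[1]; L1 <- pos[n]
  bounds <- seq(L0, L1, length.out = n_segments + 1)
  seg_len <- (L1 - L0) / n_segments
  out <- numeric(n_segments)
  for (j in seq_len(n_segments)) {
    ov <- pmax(0, pmin(edges[-1], bounds[j + 1]) - pmax(edges[-(n + 1)], bounds[j]))
    out[j] <- sum(ov * val) / seg_len
  }
  tibble::tibble(segment = seq_len(n_segments), value_au = out)
}

# ---- cluster detection ----------------------------------------------------

#' Detect fluorescent clusters per segment
#'
#' Applies one global minimal-intensity threshold to segment values across
#' the whole dataset: the same threshold for every cell and condition. The
#' threshold may be given in absolute au, or derived once from the pooled
#' segment-value distribution by a rule and then applied globally.
#'
#' @param segments tibble from [splice_segments()] (any number of cells).
#' @param rule a number (absolute au), `"quantile:q"` (pooled quantile, e.g.
#'   `"quantile:0.8"`), or `"otsu"` (Otsu's threshold on the pooled values).
#' @return the input with logical `cluster` and `threshold_au` columns.
#' @export
detect_clusters <- function(segments, rule = "otsu") {
  if (nrow(segments) == 0) stop_rodpol("empty segment table")
  v <- segments$value_au
  if (is.numeric(rule)) {
    th <- rule
  } else if (grepl("^quantile:", rule)) {
    q <- as.numeric(sub("^quantile:", "", rule))
    if (is.na(q) || q < 0 || q > 1) stop_rodpol("bad quantile rule: ", rule)
    th <- stats::quantile(v, q, names = FALSE)
  } else if (identical(rule, "otsu")) {
    rng <- range(v)
    if (diff(rng) < 1e-12) stop_rodpol("segment values are constant; cannot derive a threshold")
    th <- rng[1] + diff(rng) *
      EBImage::otsu(EBImage::Image(matrix((v - rng[1]) / diff(rng))),
                    range = c(0, 1), levels = 256)
  } else stop_rodpol("unknown cluster threshold rule: ", rule)
  dplyr::mutate(segments, cluster = .data$value_au >= th, threshold_au = th)
}

# ---- histogram ------------------------------------------------------------

#' Cluster-occurrence histogram over cell positions
#'
#' Counts, for each of the 15 axial segments, how many cells carry a
#' detected cluster there — the classic polar-occurrence histogram built
#' from one snapshot per cell.
#'
#' @param calls tibble from [detect_clusters()]; one frame per cell (mixing
#'   frames for a cell is an error).
#' @return tibble of class `localization_histogram`: `segment`, `count`,
#'   `frequency`; attribute `n_cells`.
#' @export
build_histogram <- function(calls) {
  if (nrow(calls) == 0) stop_rodpol("no cluster calls")
  if ("frame" %in% names(calls)) {
    nfr <- calls |> dplyr::group_by(.data$cell_id) |>
      dplyr::summarise(k = dplyr::n_distinct(.data$frame))
    if (any(nfr$k > 1))
      stop_rodpol("histogram needs a single snapshot per cell; cell(s) ",
                  paste(nfr$cell_id[nfr$k > 1], collapse = ", "),
                  " have several frames")
  }
  n_cells <- dplyr::n_distinct(calls$cell_id)
  out <- calls |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(count = sum(.data$cluster), .groups = "drop") |>
    dplyr::mutate(frequency = .data$count / n_cells)
  structure(out, n_cells = n_cells,
            class = c("localization_histogram", class(out)))
}

# ---- pattern classification ----------------------------------------------

#' Classify polar localization patterns
#'
#' Uses the terminal segments (1 and 15) as "polar": a cell is `diffuse` if
#' neither terminal segment carries a cluster, `unipolar` if exactly one
#' does, and bipolar if both do — split into `bipolar_symmetric` and
#' `bipolar_asymmetric` by the brighter/dimmer terminal-segment intensity
#' ratio against `sym_cutoff`.
#'
#' @param calls tibble from [detect_clusters()].
#' @param sym_cutoff asymmetry ratio above which a bipolar cell is called
#'   asymmetric (default 1.5).
#' @return tibble `cell_id` (and `frame` if present), `pattern`,
#'   `asymmetry_ratio` (>= 1; `NA` for diffuse and unipolar cells).
#' @export
classify_pattern <- function(calls, sym_cutoff = 1.5) {
  n_seg <- max(calls$segment)
  grp <- intersect(c("cell_id", "frame"), names(calls))
  calls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(d, key) {
      t1 <- d$cluster[d$segment == 1]
      t2 <- d$cluster[d$segment == n_seg]
      v1 <- d$value_au[d$segment == 1]
      v2 <- d$value_au[d$segment == n_seg]
      if (!t1 && !t2) return(tibble::tibble(pattern = "diffuse",
                                            asymmetry_ratio = NA_real_))
      if (xor(t1, t2)) return(tibble::tibble(pattern = "unipolar",
                                             asymmetry_ratio = NA_real_))
      ratio <- max(v1, v2) / max(min(v1, v2), .Machine$double.eps)
      tibble::tibble(
        pattern = if (ratio > sym_cutoff) "bipolar_asymmetric" else "bipolar_symmetric",
        asymmetry_ratio = ratio)
    }) |>
    dplyr::ungroup()
}
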