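# Segmentation, axial profiling, 15-segment splicing, cluster detection,
# histograms and pattern classification.

test_that("a blank frame yields an empty mask table, not an error", {
  expect_equal(nrow(segment_cells(matrix(100, 50, 50))), 0)
  expect_equal(nrow(segment_cells(matrix(100, 50, 50), method = "robust")), 0)
})

test_that("a single rendered cell is segmented with the right footprint", {
  l <- 40; w <- 7
  img <- render_cell(c(81, 121), center = c(60, 40), length_px = l,
                     width_px = w, diffuse_level = 180,
                     spot_amplitudes = c(0, 0)) + 100
  m <- segment_cells(img, method = "robust", min_area = 100)
  expect_equal(nrow(m), 1)
  area_true <- w * (l - w) + pi * (w / 2)^2
  expect_lt(abs(m$area_px - area_true) / area_true, 0.10)
  expect_lt(abs(m$x - 60), 1)
  expect_lt(abs(m$y - 40), 1)
})

test_that("two disjoint cells give two masks with centroids near truth", {
  cfg <- scene_config(n_cells = 2, n_frames = 2, seed = 77,
                      reversal_process = list(type = "none"))
  mv <- generate_movie(cfg)
  m <- segment_cells(mv$frames[[1]], method = "robust", min_area = 100)
  expect_equal(nrow(m), 2)
  tr <- mv$truth[mv$truth$frame == 0, ]
  for (i in 1:2) {
    dmin <- min(sqrt((tr$x - m$x[i])^2 + (tr$y - m$y[i])^2))
    expect_lt(dmin, 1)
  }
})

test_that("a uniform cell has a flat central profile", {
  img <- render_cell(c(81, 121), center = c(60, 40), length_px = 40,
                     width_px = 7, diffuse_level = 300,
                     spot_amplitudes = c(0, 0)) + 100
  m <- segment_cells(img, method = "robust", min_area = 100)
  p <- axial_profile(img, m[1, ], background = attr(m, "background_au"))
  L <- max(p$position_px)
  central <- p$intensity_au[p$position_px >= 0.1 * L & p$position_px <= 0.9 * L]
  expect_true(all(abs(central - mean(central)) / mean(central) < 0.02))
  expect_true(all(p$intensity_au >= 0))
  expect_true(all(diff(p$position_px) > 0))
})

test_that("a single polar cluster peaks at the matching profile end", {
  img <- render_cell(c(81, 121), center = c(60, 40), length_px = 40,
                     width_px = 7, diffuse_level = 180,
                     spot_amplitudes = c(400, 0)) + 100
  m <- segment_cells(img, method = "robust", min_area = 100)
  p <- axial_profile(img, m[1, ], background = attr(m, "background_au"))
  L <- max(p$position_px)
  peak <- p$position_px[which.max(p$intensity_au)]
  # the cluster sits at the +x pole apex = the far end of the profile
  expect_lt(L - peak, 2)
})

test_that("degenerate axes are rejected", {
  m <- tibble::tibble(cell_id = 1L, axis = list(matrix(c(0, 0), 1, 2)),
                      pixels = list(cbind(1L, 1L)))
  expect_error(axial_profile(matrix(0, 5, 5), m), "degenerate")
})

test_that("splicing a constant profile gives 15 equal segments", {
  prof <- tibble::tibble(cell_id = 1L, position_px = seq(0, 29),
                         intensity_au = 7)
  seg <- splice_segments(prof)
  expect_equal(nrow(seg), 15)
  expect_equal(seg$segment, 1:15)
  expect_equal(seg$value_au, rep(7, 15))
})

test_that("splicing always yields exactly 15 segments", {
  withr::with_seed(5, {
    for (n in c(17, 31, 80, 200)) {
      prof <- tibble::tibble(cell_id = 1L,
                             position_px = sort(runif(n, 0, 50)),
                             intensity_au = runif(n, 0, 500))
      expect_equal(nrow(splice_segments(prof)), 15)
    }
  })
})

test_that("segment values match the fine-grid quadrature oracle", {
  withr::with_seed(11, {
    pos <- sort(runif(31, 0, 42))
    val <- runif(31, 0, 300)
  })
  seg <- splice_segments(tibble::tibble(cell_id = 1L, position_px = pos,
                                        intensity_au = val))
  expect_equal(seg$value_au, splice_oracle(pos, val), tolerance = 1e-9)
})

test_that("splicing conserves integrated intensity", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      n <- sample(20:120, 1)
      pos <- sort(runif(n, 0, 60))
      val <- runif(n, 0, 800)
      seg <- splice_segments(tibble::tibble(cell_id = 1L, position_px = pos,
                                            intensity_au = val))
      edges <- c(pos[1], (pos[-1] + pos[-n]) / 2, pos[n])
      total_profile <- sum(diff(edges) * val)
      total_segments <- sum(seg$value_au) * diff(range(pos)) / 15
      expect_lt(abs(total_segments - total_profile) /
                  max(total_profile, 1e-12), 1e-6)
    }
  })
})

test_that("mirroring a profile reverses its segment values", {
  withr::with_seed(17, {
    pos <- sort(runif(40, 0, 35))
    val <- runif(40, 0, 400)
  })
  fwd <- splice_segments(tibble::tibble(cell_id = 1L, position_px = pos,
                                        intensity_au = val))
  mir <- splice_segments(tibble::tibble(
    cell_id = 1L, position_px = sort(max(pos) + min(pos) - pos),
    intensity_au = rev(val)))
  expect_equal(mir$value_au, rev(fwd$value_au), tolerance = 1e-9)
})

test_that("cluster detection applies one global threshold", {
  seg <- tidyr::expand_grid(cell_id = 1:3, segment = 1:15)
  seg$value_au <- c(rep(10, 15), rep(10, 15), rep(10, 15))
  seg$value_au[c(1, 30, 35)] <- c(200, 150, 180)
  calls <- detect_clusters(seg, rule = 100)
  expect_equal(which(calls$cluster), c(1, 30, 35))
  expect_true(all(calls$threshold_au == 100))
  expect_equal(calls$cluster, calls$value_au >= calls$threshold_au)
  # degenerate threshold 0: everything is a cluster
  expect_true(all(detect_clusters(seg, rule = 0)$cluster))
  # all below threshold: a diffuse cell
  expect_false(any(detect_clusters(seg, rule = 1e6)$cluster))
  # quantile rule resolves to one global absolute value
  q <- detect_clusters(seg, rule = "quantile:0.9")
  expect_equal(unique(q$threshold_au),
               unname(stats::quantile(seg$value_au, 0.9)))
  expect_error(detect_clusters(seg[0, ], rule = "otsu"), "empty")
  expect_error(detect_clusters(seg, rule = "quantile:2"), "quantile")
})

test_that("histograms count cells with clusters per segment", {
  calls <- tidyr::expand_grid(cell_id = 1:100, segment = 1:15)
  calls$frame <- 0L
  calls$value_au <- 0
  calls$cluster <- calls$segment == 1
  h <- build_histogram(calls)
  expect_s3_class(h, "localization_histogram")
  expect_equal(nrow(h), 15)
  expect_equal(h$count, c(100L, rep(0L, 14)))
  expect_equal(attr(h, "n_cells"), 100)
  expect_true(all(h$count <= 100))
  expect_true(all(h$frequency >= 0 & h$frequency <= 1))
  # one snapshot per cell: mixed frames are an error
  calls$frame[calls$cell_id == 7] <- rep(c(0L, 1L), length.out = 15)
  expect_error(build_histogram(calls), "7")
})

test_that("patterns are classified from terminal segments and asymmetry", {
  mk <- function(v1, v15, f1, f15) {
    d <- tibble::tibble(cell_id = 1L, segment = 1:15, value_au = 10,
                        cluster = FALSE)
    d$value_au[c(1, 15)] <- c(v1, v15)
    d$cluster[c(1, 15)] <- c(f1, f15)
    d
  }
  expect_equal(classify_pattern(mk(200, 10, TRUE, FALSE))$pattern, "unipolar")
  expect_equal(classify_pattern(mk(10, 200, FALSE, TRUE))$pattern, "unipolar")
  expect_equal(classify_pattern(mk(10, 10, FALSE, FALSE))$pattern, "diffuse")
  sym <- classify_pattern(mk(200, 200, TRUE, TRUE))
  expect_equal(sym$pattern, "bipolar_symmetric")
  expect_equal(sym$asymmetry_ratio, 1)
  asym <- classify_pattern(mk(300, 100, TRUE, TRUE), sym_cutoff = 1.5)
  expect_equal(asym$pattern, "bipolar_asymmetric")
  expect_equal(asym$asymmetry_ratio, 3)
})

test_that("noiseless snapshot population is recovered exactly", {
  fx <- fixture_snapshot_noiseless()
  calls <- detect_clusters(fx$segments, rule = SNAPSHOT_CLUSTER_THRESHOLD)
  h <- build_histogram(calls)
  truth0 <- fx$movie$truth[fx$movie$truth$frame == 0, ]
  # expected terminal-bin counts from the generator's truth: a cluster at
  # the +x pole falls in segment 15, at the -x pole in segment 1
  exp15 <- sum(ifelse(truth0$polarity_sign > 0, truth0$intensity_leading_au,
                      truth0$intensity_lagging_au) > 0)
  exp1 <- sum(ifelse(truth0$polarity_sign > 0, truth0$intensity_lagging_au,
                     truth0$intensity_leading_au) > 0)
  expect_equal(h$count[h$segment == 1], exp1)
  expect_equal(h$count[h$segment == 15], exp15)
  # bipolar count = cells flagged at both poles, recovered exactly
  expect_equal(h$count[h$segment == 1] + h$count[h$segment == 15] -
                 nrow(truth0), 40)
})

test_that("noisy snapshot classification reaches 95% accuracy at SNR >= 5", {
  fx <- fixture_snapshot()
  cfgn <- fx$movie$config$noise
  # SNR: blurred cluster peak over the pixel noise sd at that intensity
  peak <- 600 * 1.5^2 / (1.5^2 + 1.5^2)
  at_spot <- 100 + 150 + peak
  noise_sd <- sqrt(at_spot / cfgn$poisson_scale + cfgn$gaussian_sd^2)
  expect_gte(peak / noise_sd, 5)

  calls <- detect_clusters(fx$segments, rule = SNAPSHOT_CLUSTER_THRESHOLD)
  pat <- classify_pattern(calls)
  truth0 <- fx$movie$truth[fx$movie$truth$frame == 0, ]
  cid <- vapply(seq_len(nrow(fx$masks)), function(i)
    truth0$cell_id[which.min((truth0$x - fx$masks$x[i])^2 +
                               (truth0$y - fx$masks$y[i])^2)], integer(1))
  want <- snapshot_truth_pattern(truth0)[cid]
  got <- pat$pattern[match(fx$masks$cell_id, pat$cell_id)]
  expect_gte(mean(got == want), 0.95)

  # clusters are called only in the terminal segments for >= 95% of cells
  only_term <- calls |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(ok = all(segment[cluster] %in% c(1, 15)) && any(cluster))
  expect_gte(mean(only_term$ok), 0.95)

  # terminal-bin frequencies sit inside the binomial 95% CI of the
  # generating fractions (40% bipolar + half of the unipolar per pole)
  h <- build_histogram(calls)
  n <- attr(h, "n_cells")
  for (s in c(1, 15)) {
    pole_side <- if (s == 15) truth0$polarity_sign > 0 else
      truth0$polarity_sign < 0
    exp_frac <- (40 + sum(pole_side &
                            snapshot_truth_pattern(truth0) == "unipolar")) / 100
    ci <- exp_frac + c(-1, 1) * 1.96 * sqrt(exp_frac * (1 - exp_frac) / n)
    expect_gte(h$frequency[h$segment == s], ci[1])
    expect_lte(h$frequency[h$segment == s], ci[2])
  }
})
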