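# Pole-intensity series, switching scoring, event binarization, and the
# Rxy delay cross-correlation.

test_that("pole series track both poles of a symmetric cell", {
  cfg <- scene_config(n_cells = 2, n_frames = 8, seed = 15,
                      polar_cluster_amplitudes = c(500, 500),
                      bleach_per_frame = 0,
                      noise = list(poisson_scale = 0, gaussian_sd = 0),
                      reversal_process = list(type = "none"))
  mv <- generate_movie(cfg)
  an <- analyse_movie(mv)
  for (id in unique(an$tracks$track_id)) {
    tm <- an$tracks[an$tracks$track_id == id, ]
    ps <- pole_series(tm, mv$frames, background = tm$background_au)
    expect_equal(nrow(ps), nrow(tm))
    asym <- abs(ps$initial_leading_au - ps$initial_lagging_au) /
      pmax(ps$initial_leading_au, ps$initial_lagging_au)
    expect_true(all(asym < 0.05))
  }
})

test_that("switching is scored when the new leading pole peaks", {
  # noiseless movie, switching lag 1: scored switch = true reversal + 1
  mv <- fixture_noiseless()
  an <- fixture_noiseless_analysis()
  for (id in unique(an$tracks$track_id)) {
    tm <- an$tracks[an$tracks$track_id == id, ]
    ps <- pole_series(tm, mv$frames, background = tm$background_au)
    rv <- an$reversals$reversal_frames[[match(id, an$reversals$track_id)]]
    sw <- score_switching(ps, rv)
    expect_equal(sw$switch_frame, c(11L, 26L))
    expect_equal(nrow(sw), length(rv))  # one switch per interval
    expect_equal(sw$pole, c("initial_lagging", "initial_leading"))
  }
})

test_that("intensity at the new leading pole rises after the true switch", {
  mv <- fixture_movie()
  an <- fixture_analysis()
  tm <- an$tracks[an$tracks$track_id == 1, ]
  ps <- pole_series(tm, mv$frames, background = tm$background_au)
  # the cluster moves to the initial lagging pole at frame 11 (lag 1)
  before <- mean(ps$initial_lagging_au[ps$frame %in% 5:10])
  after <- mean(ps$initial_lagging_au[ps$frame %in% 12:20])
  # the relocated cluster is brighter, though bleaching tempers the jump
  expect_gt(after, 1.2 * before)
  expect_gt(which.max(ps$initial_lagging_au), which(ps$frame == 11) - 1)
})

test_that("tied pole intensities resolve to the interval start, flagged", {
  ps <- structure(tibble::tibble(track_id = 1L, frame = 0:19,
                                 initial_leading_au = 5,
                                 initial_lagging_au = 5),
                  leading_tip = "tip1",
                  class = c("pole_series", "tbl_df", "tbl", "data.frame"))
  sw <- score_switching(ps, c(4L, 12L))
  expect_equal(sw$switch_frame, c(4L, 12L))
  expect_true(all(sw$low_confidence))
  expect_equal(nrow(score_switching(ps, integer(0))), 0)
})

test_that("event binarization builds exact indicator vectors", {
  expect_equal(binarize_events(integer(0), 5), rep(0L, 5))
  v <- binarize_events(c(3, 3), 6)
  expect_equal(which(v == 1) - 1L, 3L)
  expect_equal(sum(binarize_events(c(0, 2, 5), 6)), 3L)
  expect_error(binarize_events(6, 6), "outside")
  expect_error(binarize_events(-1, 6), "outside")
})

test_that("identical series give the theoretical perfect correlation of 1", {
  x <- binarize_events(c(5, 18, 31), 40)
  cc <- cross_correlation(x, x, m_range = -2:2)
  expect_equal(cc$rxy[cc$delay_frames == 0], 1, tolerance = 1e-12)
  expect_true(all(abs(cc$rxy) <= 1 + 1e-12))
})

test_that("the vectorized Rxy equals the brute-force oracle", {
  # exhaustive over all non-constant binary pairs of length 5
  grid <- expand.grid(rep(list(0:1), 5))
  vecs <- lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
  vecs <- Filter(function(v) stats::var(v) > 0, vecs)
  for (x in vecs) for (y in vecs) {
    cc <- cross_correlation(x, y, m_range = -3:3)
    for (j in seq_len(nrow(cc))) {
      expect_equal(cc$rxy[j], brute_rxy(x, y, cc$delay_frames[j]),
                   tolerance = 1e-12)
    }
  }
  # random longer vectors, including non-binary ones
  withr::with_seed(8, {
    for (rep in 1:20) {
      x <- stats::rbinom(40, 1, 0.2)
      y <- stats::rnorm(40)
      cc <- cross_correlation(x, y, m_range = -5:5)
      for (j in seq_len(nrow(cc)))
        expect_equal(cc$rxy[j], brute_rxy(x, y, cc$delay_frames[j]),
                     tolerance = 1e-12)
      expect_true(all(abs(cc$rxy) <= 1 + 1e-12, na.rm = TRUE))
    }
  })
})

test_that("Rxy agrees with the reference cross-correlogram", {
  withr::with_seed(2, {
    x <- stats::rbinom(40, 1, 0.2); y <- stats::rbinom(40, 1, 0.3)
  })
  cc <- cross_correlation(x, y, m_range = -5:5)
  cf <- stats::ccf(x, y, lag.max = 5, plot = FALSE)
  expect_equal(cc$rxy, as.numeric(cf$acf), tolerance = 1e-12)
})

test_that("a delayed copy peaks at its delay", {
  y <- binarize_events(c(4, 17, 30), 40)       # reversals
  x <- binarize_events(c(4, 17, 30) + 1, 40)   # switches one frame later
  cc <- cross_correlation(x, y, m_range = -3:3)
  expect_equal(cc$delay_frames[which.max(cc$rxy)], 1L)
})

test_that("Rxy on swapped series mirrors the delay axis", {
  withr::with_seed(4, {
    x <- stats::rbinom(30, 1, 0.2); y <- stats::rbinom(30, 1, 0.2)
  })
  a <- cross_correlation(x, y, m_range = -4:4)
  b <- cross_correlation(y, x, m_range = -4:4)
  expect_equal(a$rxy, rev(b$rxy), tolerance = 1e-12)
})

test_that("independent event series average to zero correlation", {
  withr::with_seed(123, {
    vals <- replicate(1000, {
      x <- stats::rbinom(40, 1, 0.1)
      y <- stats::rbinom(40, 1, 0.1)
      if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
      cross_correlation(x, y, m_range = 0)$rxy
    })
  })
  vals <- vals[!is.na(vals)]
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se + 1e-3)
})

test_that("constant series are flagged undefined, not zero", {
  expect_warning(cc <- cross_correlation(rep(0L, 10), binarize_events(3, 10)),
                 "undefined")
  expect_true(all(is.na(cc$rxy)))
})

test_that("aggregation averages curves and flags significance", {
  x <- binarize_events(c(5, 18, 31), 40)
  cc <- cross_correlation(x, x, m_range = -2:2)
  agg <- aggregate_rxy(list(cc, cc, cc))
  expect_equal(agg$rxy, cc$rxy)
  expect_equal(attr(agg, "n_cells"), 3)
  expect_true(attr(agg, "significant"))
  g <- glance(agg)
  expect_equal(g$peak_delay_frames, 0L)
  expect_true(g$significant)

  off <- cross_correlation(x, x, m_range = -1:3)
  expect_error(aggregate_rxy(list(cc, off)), "grids")
})

test_that("programmed switching lags are recovered as the Rxy peak", {
  for (k in 0:2) {
    cfg <- scene_config(n_cells = 30, n_frames = 40, seed = 300 + k,
                        switch_lag_frames = k)
    mv <- generate_movie(cfg, render = FALSE)
    curves <- list()
    for (i in unique(mv$truth$cell_id)) {
      ev <- mv$events[mv$events$cell_id == i, ]
      rv <- ev$frame[ev$event == "reversal"]
      sw <- ev$frame[ev$event == "switch"]
      if (length(rv) == 0) next
      curves[[as.character(i)]] <- cross_correlation(
        binarize_events(sw, 40), binarize_events(rv, 40), m_range = -4:4)
    }
    agg <- aggregate_rxy(curves)
    expect_equal(agg$delay_frames[which.max(agg$rxy)], k)
  }
})

test_that("uncorrelated switching does not cross the significance cutoff", {
  withr::with_seed(77, {
    curves <- lapply(1:30, function(i) {
      rv <- sort(sample(0:39, 3))
      sw <- sort(sample(0:39, 3))
      cross_correlation(binarize_events(sw, 40), binarize_events(rv, 40),
                        m_range = -4:4)
    })
  })
  agg <- aggregate_rxy(curves, threshold = 0.4, window_s = 60)
  expect_false(attr(agg, "significant"))
})

test_that("tidiers return plain tibbles with the expected shape", {
  x <- binarize_events(c(2, 9), 20)
  cc <- cross_correlation(x, x, m_range = -2:2)
  td <- tidy(cc)
  expect_false(inherits(td, "rxy_curve"))
  expect_named(td, c("delay_frames", "delay_s", "rxy"))
  g <- glance(cc)
  expect_equal(g$peak_rxy, 1)
})
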