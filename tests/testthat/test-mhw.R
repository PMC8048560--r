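test_that("climatology handles degenerate and noise-free series", {
  dates <- seq(as.Date("2000-01-01"), as.Date("2004-12-31"), by = "day")
  const <- tibble::tibble(date = dates, sst = 10)
  clim <- compute_climatology(const, smooth_width = 31)
  expect_equal(clim$seas_mean, rep(10, 366))
  expect_equal(clim$thresh90, rep(10, 366))

  # a pure function of day-of-year has zero spread within each doy, so the
  # threshold collapses onto the mean when the pooling window shrinks to 0
  doy <- doy366(dates)
  sinus <- tibble::tibble(date = dates, sst = 8 + 4 * sin(2 * pi * doy / 366))
  clim0 <- compute_climatology(sinus, window_halfwidth = 0, smooth_width = 1)
  keep <- setdiff(1:366, 60) # leap day is interpolated, not pooled
  expect_equal(clim0$thresh90[keep], clim0$seas_mean[keep], tolerance = 1e-12)
})

test_that("pooled percentile matches an independent brute-force pass", {
  set.seed(11)
  dates <- seq(as.Date("1985-01-01"), as.Date("2014-12-31"), by = "day")
  series <- tibble::tibble(date = dates, sst = rnorm(length(dates), 8, 1))
  clim <- compute_climatology(series, window_halfwidth = 5, smooth_width = 1)
  doy <- doy366(dates)
  for (d in c(1, 45, 180, 300, 366)) {
    win <- ((d - 5):(d + 5) - 1) %% 366 + 1
    pooled <- series$sst[doy %in% win]
    expect_equal(clim$seas_mean[d], mean(pooled), tolerance = 1e-12)
    expect_equal(clim$thresh90[d],
                 unname(quantile(pooled, 0.9, type = 7)),
                 tolerance = 1e-12)
  }
  # N(8, 1) pooled 90th percentile ~ 8 + 1.2816
  expect_equal(mean(clim$thresh90), 8 + qnorm(0.9), tolerance = 0.05)
  expect_true(all(clim$thresh90 >= clim$seas_mean))
})

test_that("climatology rejects bad baselines and gappy data", {
  dates <- seq(as.Date("2000-01-01"), as.Date("2009-12-31"), by = "day")
  series <- tibble::tibble(date = dates, sst = 10)
  expect_error(compute_climatology(series, baseline = c(1990, 2005)),
               "outside the data span")
  gappy <- series
  gappy$sst[seq_len(floor(0.3 * nrow(gappy)))] <- NA
  expect_error(compute_climatology(gappy), "30.0%")
  expect_error(compute_climatology(series, smooth_width = 30), "odd")
})

test_that("event detection matches direct construction", {
  clim <- flat_clim(seas = 10, thresh = 11)
  # one 10-day exceedance at +2 above the seasonal mean
  pat <- c(rep(FALSE, 20), rep(TRUE, 10), rep(FALSE, 20))
  ev <- detect_events(series_from_pattern(pat), clim, min_duration = 5,
                      max_gap = 2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration, 10L)
  expect_equal(ev$mean_intensity, 2)
  expect_equal(ev$max_intensity, 2)
  expect_equal(ev$cumulative_intensity, 20)
  expect_equal(ev$cumulative_intensity, ev$mean_intensity * ev$duration,
               tolerance = 1e-9)

  # never exceeding -> empty
  cold <- tibble::tibble(date = as.Date("2000-01-01") + 0:99, sst = 10)
  expect_equal(nrow(detect_events(cold, clim)), 0L)

  # two 6-day runs separated by a 2-day dip: merged at max_gap 2, not at 1
  pat2 <- c(rep(TRUE, 6), rep(FALSE, 2), rep(TRUE, 6), rep(FALSE, 10))
  s2 <- series_from_pattern(pat2)
  merged <- detect_events(s2, clim, min_duration = 5, max_gap = 2)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$duration, 14L)
  split_ev <- detect_events(s2, clim, min_duration = 5, max_gap = 1)
  expect_equal(nrow(split_ev), 2L)
  expect_equal(split_ev$duration, c(6L, 6L))
  # gap days are included in the merged event's intensity statistics
  expect_equal(merged$mean_intensity, (12 * 2 + 2 * (-1)) / 14)
})

test_that("missing SST is treated as below threshold with a warning", {
  clim <- flat_clim()
  pat <- c(rep(FALSE, 5), rep(TRUE, 12), rep(FALSE, 5))
  s <- series_from_pattern(pat)
  s$sst[10] <- NA
  expect_warning(ev <- detect_events(s, clim), "missing")
  # NA splits the 12-day run into 4- and 7-day runs; only the 7 qualifies
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration, 7L)
})

test_that("detection matches the run-enumeration oracle with monotonicity", {
  clim <- flat_clim()
  set.seed(21)
  for (rep in 1:25) {
    pat <- runif(sample(40:120, 1)) < 0.45
    s <- series_from_pattern(pat)
    n_prev_md <- NULL
    for (md in c(1, 3, 5)) {
      n_prev_gap <- NULL
      for (gap in 0:3) {
        got <- detect_events(s, clim, min_duration = md, max_gap = gap)
        want <- oracle_mhw_events(pat, md, gap)
        expect_equal(nrow(got), nrow(want))
        if (nrow(want) > 0) {
          expect_equal(as.integer(got$start - s$date[1] + 1), want[, 1])
          expect_equal(as.integer(got$end - s$date[1] + 1), want[, 2])
        }
        # raising max_gap never increases the number of events
        if (!is.null(n_prev_gap)) expect_lte(nrow(got), n_prev_gap)
        n_prev_gap <- nrow(got)
      }
      got_md <- detect_events(s, clim, min_duration = md, max_gap = 0)
      # lowering min_duration never decreases the number of events
      if (!is.null(n_prev_md)) expect_lte(nrow(got_md), n_prev_md)
      n_prev_md <- nrow(got_md)
    }
  }
})

test_that("event days partition: no overlap between merged events", {
  clim <- flat_clim()
  set.seed(31)
  for (rep in 1:10) {
    pat <- runif(90) < 0.5
    ev <- detect_events(series_from_pattern(pat), clim,
                        min_duration = 3, max_gap = 2)
    if (nrow(ev) > 1) {
      expect_true(all(ev$start[-1] > ev$end[-nrow(ev)]))
    }
    all_days <- do.call(c, lapply(ev$days, function(d) d$date))
    expect_equal(anyDuplicated(all_days), 0L)
  }
})

test_that("grid summary counts event days intersecting the period", {
  clim <- flat_clim()
  # 30-day event straddling the period start by 10 days
  pat <- c(rep(FALSE, 10), rep(TRUE, 30), rep(FALSE, 10))
  s <- series_from_pattern(pat, start = as.Date("2013-12-12"))
  ev <- detect_events(s, clim)
  expect_equal(ev$duration, 30L)
  period <- as.Date(c("2014-01-01", "2014-12-31"))
  gs <- summarize_grid(list(cellA = ev), period)
  expect_equal(gs$total_hw_days, 20L)
  expect_equal(gs$mean_event_intensity, 2)

  # event fully inside the period reports its own duration and intensity
  s2 <- series_from_pattern(c(rep(FALSE, 5), rep(TRUE, 30), rep(FALSE, 5)),
                            start = as.Date("2014-03-01"))
  ev2 <- detect_events(s2, clim)
  gs2 <- summarize_grid(list(cellA = ev2), period)
  expect_equal(gs2$total_hw_days, 30L)

  # cell with no events
  empty <- detect_events(tibble::tibble(
    date = as.Date("2014-01-01") + 0:30, sst = 5), clim)
  gs3 <- summarize_grid(list(cellA = empty), period)
  expect_equal(gs3$total_hw_days, 0L)
  expect_true(is.na(gs3$mean_event_intensity))
})

test_that("climatology is stable under recomputation from its own mean", {
  dates <- seq(as.Date("2000-01-01"), as.Date("2009-12-31"), by = "day")
  doy <- doy366(dates)
  base <- tibble::tibble(date = dates, sst = 8 + 4 * sin(2 * pi * doy / 366))
  clim <- compute_climatology(base, window_halfwidth = 5, smooth_width = 31)
  rebuilt <- tibble::tibble(date = dates, sst = clim$seas_mean[doy])
  clim2 <- compute_climatology(rebuilt, window_halfwidth = 0,
                               smooth_width = 1)
  # zero spread: threshold equals mean; curve reproduced exactly away from
  # the interpolated leap day, and up to local curvature at index 60
  expect_equal(clim2$thresh90, clim2$seas_mean, tolerance = 1e-10)
  keep <- setdiff(1:366, 60)
  expect_equal(clim2$seas_mean[keep], clim$seas_mean[keep],
               tolerance = 1e-10)
  expect_equal(clim2$seas_mean[60], clim$seas_mean[60], tolerance = 1e-3)
})
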