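#' Day-of-year index on a fixed 366-day calendar
#'
#' Maps calendar dates to indices 1..366 with 29 February always at index 60,
#' so that the same index refers to the same calendar day in leap and
#' non-leap years.
#'
#' @param dates a `Date` vector.
#' @return integer vector in 1..366.
#' @export
doy366 <- function(dates) {
  stopifnot(inherits(dates, "Date"))
  yd <- as.POSIXlt(dates)$yday + 1L
  yr <- as.POSIXlt(dates)$year + 1900L
  leap <- (yr %% 4 == 0 & yr %% 100 != 0) | (yr %% 400 == 0)
  ifelse(leap, yd, ifelse(yd >= 60L, yd + 1L, yd))
}

validate_sst_series <- function(series) {
  stop_if_not_cols(series, c("date", "sst"), "SST series")
  if (!inherits(series$date, "Date")) {
    stop("`date` must be of class Date", call. = FALSE)
  }
  d <- diff(as.integer(series$date))
  if (length(d) > 0 && any(d != 1L)) {
    stop("SST series dates must be contiguous daily values (step 1 day)",
         call. = FALSE)
  }
  if (any(is.infinite(series$sst), na.rm = TRUE)) {
    stop("SST values must be finite or NA", call. = FALSE)
  }
  invisible(series)
}

#' Day-of-year SST climatology with a percentile threshold
#'
#' Builds the seasonal baseline used for marine-heatwave detection: for each
#' day of year, temperatures from all baseline years falling within
#' `window_halfwidth` days of that day are pooled; their mean gives the
#' climatological mean and their empirical 90th percentile the event
#' threshold. Both curves are then smoothed with a centered moving average
#' that wraps across the year boundary. 29 February is interpolated from the
#' adjacent days so that leap years do not create a sample-size artifact.
#'
#' @param series a data frame with columns `date` (Date, contiguous daily)
#'   and `sst` (deg C, `NA` allowed).
#' @param baseline integer vector `c(first_year, last_year)`; default the full
#'   span of the series.
#' @param window_halfwidth half-width in days of the pooling window around
#'   each day of year (default 5, i.e. an 11-day window).
#' @param smooth_width width in days of the centered moving-average smoother
#'   applied to both curves (default 31; must be odd; 1 disables smoothing).
#' @param prob percentile defining the threshold (default 0.9). Empirical
#'   quantiles use the linear-interpolation (type 7) convention.
#' @return a tibble of class `sst_climatology` with columns `doy` (1..366),
#'   `seas_mean` and `thresh90` (deg C), and attributes `baseline`,
#'   `window_halfwidth`, `smooth_width`.
#' @examples
#' sst <- gen_sst(sst_scenario(seed = 1))
#' clim <- compute_climatology(sst$series)
#' @export
compute_climatology <- function(series, baseline = NULL,
                                window_halfwidth = 5L, smooth_width = 31L,
                                prob = 0.9) {
  validate_sst_series(series)
  stopifnot(window_halfwidth >= 0, smooth_width >= 1)
  if (smooth_width %% 2 == 0) {
    stop("`smooth_width` must be odd (centered moving average)", call. = FALSE)
  }
  years <- as.POSIXlt(series$date)$year + 1900L
  if (is.null(baseline)) baseline <- range(years)
  if (baseline[1] < min(years) || baseline[2] > max(years)) {
    stop("baseline ", baseline[1], ":", baseline[2],
         " lies outside the data span ", min(years), ":", max(years),
         call. = FALSE)
  }
  in_base <- years >= baseline[1] & years <= baseline[2]
  if (length(unique(years[in_base])) < 3) {
    stop("climatology requires a baseline spanning at least 3 years",
         call. = FALSE)
  }
  base_sst <- series$sst[in_base]
  gap_frac <- mean(is.na(base_sst))
  if (gap_frac > 0.25) {
    stop(sprintf(
      "%.1f%% of baseline SST values are missing (limit 25%%)",
      100 * gap_frac), call. = FALSE)
  }
  base_doy <- doy366(series$date[in_base])
  ok <- !is.na(base_sst)
  by_doy <- split(base_sst[ok], factor(base_doy[ok], levels = 1:366))

  pool_stats <- function(d) {
    win <- ((d - window_halfwidth):(d + window_halfwidth) - 1L) %% 366L + 1L
    v <- unlist(by_doy[win], use.names = FALSE)
    if (length(v) == 0) return(c(NA_real_, NA_real_))
    c(mean(v), unname(quantile(v, prob, type = 7)))
  }
  raw <- vapply(1:366, pool_stats, numeric(2))
  seas <- raw[1, ]
  thr <- raw[2, ]
  # leap-day interpolation: index 60 from its neighbours
  seas[60] <- mean(seas[c(59, 61)])
  thr[60] <- mean(thr[c(59, 61)])

  circ_ma <- function(x, w) {
    if (w <= 1) return(x)
    as.numeric(stats::filter(x, rep(1 / w, w), sides = 2, circular = TRUE))
  }
  out <- tibble::tibble(
    doy = 1:366,
    seas_mean = circ_ma(seas, smooth_width),
    thresh90 = circ_ma(thr, smooth_width)
  )
  attr(out, "baseline") <- as.integer(baseline)
  attr(out, "window_halfwidth") <- as.integer(window_halfwidth)
  attr(out, "smooth_width") <- as.integer(smooth_width)
  class(out) <- c("sst_climatology", class(out))
  out
}

#' Detect marine-heatwave events in a daily SST series
#'
#' An event is a run of at least `min_duration` consecutive days with SST
#' strictly above the day-of-year threshold. Two qualifying runs separated by
#' at most `max_gap` below-threshold days are merged into a single event
#' whose intensity statistics include the gap days. Intensities are
#' anomalies relative to the climatological mean. Missing SST values are
#' treated as below threshold (with a warning), which is conservative.
#'
#' @param series a data frame with columns `date`, `sst`.
#' @param clim a climatology from [compute_climatology()] (columns `doy`,
#'   `seas_mean`, `thresh90`).
#' @param min_duration minimum event length in days (default 5).
#' @param max_gap maximum below-threshold gap merged across (default 2).
#' @return a tibble of class `mhw_events`, one row per event, with columns
#'   `event_no`, `start`, `end`, `duration` (days), `mean_intensity`,
#'   `max_intensity` (deg C), `cumulative_intensity` (deg C days,
#'   `mean_intensity * duration`), and a list-column `days` holding a tibble
#'   `(date, anomaly)` for each event day.
#' @export
detect_events <- function(series, clim, min_duration = 5L, max_gap = 2L) {
  validate_sst_series(series)
  stop_if_not_cols(clim, c("doy", "seas_mean", "thresh90"), "climatology")
  stopifnot(min_duration >= 1, max_gap >= 0)
  idx <- match(doy366(series$date), clim$doy)
  if (anyNA(idx)) stop("climatology does not cover all days of year",
                       call. = FALSE)
  thr <- clim$thresh90[idx]
  seas <- clim$seas_mean[idx]
  if (anyNA(thr)) stop("climatology threshold contains NA", call. = FALSE)
  miss <- is.na(series$sst)
  if (any(miss)) {
    warning(sum(miss), " missing SST day(s) treated as below threshold")
  }
  exceeds <- !miss & series$sst > thr

  empty <- tibble::tibble(
    event_no = integer(), start = as.Date(character()),
    end = as.Date(character()), duration = integer(),
    mean_intensity = numeric(), max_intensity = numeric(),
    cumulative_intensity = numeric(), days = list()
  )
  r <- rle(exceeds)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- which(r$values & r$lengths >= min_duration)
  if (length(qual) == 0) {
    class(empty) <- c("mhw_events", class(empty))
    return(empty)
  }
  # merge qualifying runs across short gaps, left to right
  ivals <- cbind(starts[qual], ends[qual])
  merged <- list(ivals[1, ])
  if (nrow(ivals) > 1) {
    for (i in 2:nrow(ivals)) {
      prev <- merged[[length(merged)]]
      gap <- ivals[i, 1] - prev[2] - 1L
      if (gap <= max_gap) {
        merged[[length(merged)]] <- c(prev[1], ivals[i, 2])
      } else {
        merged[[length(merged) + 1L]] <- ivals[i, ]
      }
    }
  }
  anom <- series$sst - seas
  rows <- lapply(seq_along(merged), function(k) {
    i0 <- merged[[k]][1]; i1 <- merged[[k]][2]
    a <- anom[i0:i1]
    dur <- i1 - i0 + 1L
    mi <- mean(a, na.rm = TRUE)
    tibble::tibble(
      event_no = k,
      start = series$date[i0], end = series$date[i1],
      duration = dur,
      mean_intensity = mi,
      max_intensity = max(a, na.rm = TRUE),
      cumulative_intensity = mi * dur,
      days = list(tibble::tibble(date = series$date[i0:i1], anomaly = a))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mhw_events", class(out))
  out
}

#' Summarize heatwave exposure per grid cell over a period
#'
#' Counts event days intersecting the summary period and averages the daily
#' anomaly over those days, per cell — the cumulative-heatwave-days and
#' mean-intensity maps of a heatwave episode.
#'
#' @param events_by_cell either a named list mapping cell id to an
#'   [detect_events()] result, or a single events tibble with a `cell_id`
#'   column.
#' @param period a length-2 `Date` vector `c(start, end)` (calendar bounds,
#'   inclusive).
#' @return a tibble with columns `cell_id`, `total_hw_days`,
#'   `mean_event_intensity` (`NA` where no event days fall in the period).
#' @export
summarize_grid <- function(events_by_cell, period) {
  stopifnot(length(period) == 2, inherits(period, "Date"),
            period[1] <= period[2])
  if (is.data.frame(events_by_cell)) {
    stop_if_not_cols(events_by_cell, "cell_id", "events table")
    events_by_cell <- split(events_by_cell,
                            events_by_cell$cell_id)
  }
  if (is.null(names(events_by_cell)) || any(names(events_by_cell) == "")) {
    stop("`events_by_cell` must be named by cell id", call. = FALSE)
  }
  rows <- lapply(names(events_by_cell), function(cid) {
    ev <- events_by_cell[[cid]]
    if (nrow(ev) == 0) {
      return(tibble::tibble(cell_id = cid, total_hw_days = 0L,
                            mean_event_intensity = NA_real_))
    }
    days <- dplyr::bind_rows(ev$days)
    days <- days[days$date >= period[1] & days$date <= period[2], ]
    n <- nrow(days)
    tibble::tibble(
      cell_id = cid,
      total_hw_days = n,
      mean_event_intensity = if (n > 0) mean(days$anomaly, na.rm = TRUE)
                             else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}
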