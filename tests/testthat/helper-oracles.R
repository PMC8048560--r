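# Independent brute-force oracles used to validate the pipeline
# implementations. These deliberately share no code with the package:
# day-scan loops, per-bin loops, direct formulas.

# --- heatwave run enumeration -------------------------------------------
# exceeds: logical vector; returns matrix with columns start, end (indices)
oracle_mhw_events <- function(exceeds, min_duration, max_gap) {
  runs <- list()
  i <- 1L
  n <- length(exceeds)
  while (i <= n) {
    if (isTRUE(exceeds[i])) {
      j <- i
      while (j < n && isTRUE(exceeds[j + 1L])) j <- j + 1L
      if (j - i + 1L >= min_duration) runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(runs) == 0) return(matrix(integer(0), ncol = 2))
  merged <- list(runs[[1]])
  for (k in seq_along(runs)[-1]) {
    prev <- merged[[length(merged)]]
    if (runs[[k]][1] - prev[2] - 1L <= max_gap) {
      merged[[length(merged)]] <- c(prev[1], runs[[k]][2])
    } else {
      merged[[length(merged) + 1L]] <- runs[[k]]
    }
  }
  do.call(rbind, merged)
}

# constant-threshold climatology covering every day of year
flat_clim <- function(seas = 10, thresh = 11) {
  structure(tibble::tibble(doy = 1:366, seas_mean = seas, thresh90 = thresh),
            class = c("sst_climatology", "tbl_df", "tbl", "data.frame"))
}

# daily series from an exceedance pattern: sst = seas + 2 where exceeding,
# seas - 1 otherwise (threshold = seas + 1)
series_from_pattern <- function(exceeds, start = as.Date("2000-01-01"),
                                seas = 10) {
  tibble::tibble(date = start + seq_along(exceeds) - 1L,
                 sst = ifelse(exceeds, seas + 2, seas - 1))
}

# --- per-bin acoustic pipeline ------------------------------------------
# Recomputes bin -> classify -> integrate with plain loops. Returns a list
# with `class` (matrix over sample cells) and `nasc` (data frame keyed by
# dist_cell/depth_cell).
oracle_acoustics <- function(eg, pings_per_cell = 5, meters_per_cell = 5,
                             floor_db = -80, lo = 8, hi = 30,
                             horiz_km = 0.5, vert_m = 5) {
  nb <- nrow(eg$sv120); np <- ncol(eg$sv120)
  h <- eg$bin_height
  tops <- eg$depth_top + (seq_len(nb) - 1) * h
  valid <- matrix(FALSE, nb, np)
  for (p in 1:np) {
    for (b in 1:nb) {
      valid[b, p] <- tops[b] >= 4 && (tops[b] + h) <= eg$bottom_m[p] - 1
    }
  }
  nb_per <- as.integer(round(meters_per_cell / h))
  n_dc <- ceiling(nb / nb_per)
  n_pc <- ceiling(np / pings_per_cell)
  ping_cells <- lapply(1:n_pc, function(pc) {
    ps <- ((pc - 1) * pings_per_cell + 1):min(pc * pings_per_cell, np)
    ps
  })
  # drop trailing partial ping cell with < half the pings
  if (n_pc > 1 && length(ping_cells[[n_pc]]) < pings_per_cell / 2) {
    ping_cells <- ping_cells[-n_pc]
    n_pc <- n_pc - 1
  }
  cls <- matrix(NA_character_, n_dc, n_pc)
  for (dc in 1:n_dc) {
    bs <- ((dc - 1) * nb_per + 1):min(dc * nb_per, nb)
    for (pc in 1:n_pc) {
      ps <- ping_cells[[pc]]
      acc38 <- c(); acc120 <- c()
      for (b in bs) for (p in ps) {
        if (valid[b, p]) {
          if (!is.na(eg$sv38[b, p])) acc38 <- c(acc38, eg$sv38[b, p])
          if (!is.na(eg$sv120[b, p])) acc120 <- c(acc120, eg$sv120[b, p])
        }
      }
      m38 <- if (length(acc38)) 10 * log10(mean(10^(acc38 / 10))) else NA
      m120 <- if (length(acc120)) 10 * log10(mean(10^(acc120 / 10))) else NA
      if (is.na(m38) && is.na(m120)) {
        cls[dc, pc] <- "masked"
        next
      }
      f38 <- if (is.na(m38)) NA else max(m38, floor_db)
      f120 <- if (is.na(m120)) NA else max(m120, floor_db)
      if (!is.na(f38) && !is.na(f120) && f38 <= floor_db &&
          f120 <= floor_db) {
        cls[dc, pc] <- "below_threshold"
      } else if (!is.na(f38) && !is.na(f120) &&
                 (f120 - f38) >= lo && (f120 - f38) <= hi) {
        cls[dc, pc] <- "macrozooplankton"
      } else {
        cls[dc, pc] <- "other"
      }
    }
  }
  # per-ping sample-cell lookup
  pc_of_ping <- rep(NA_integer_, np)
  for (pc in seq_along(ping_cells)) pc_of_ping[ping_cells[[pc]]] <- pc
  # export cells
  exp_dc <- floor(tops / vert_m) + 1
  exp_pc <- floor(eg$distance_km / horiz_km) + 1
  out <- list()
  for (ec in sort(unique(exp_pc))) {
    ps <- which(exp_pc == ec & !is.na(pc_of_ping))
    if (length(ps) == 0) next
    for (dc in sort(unique(exp_dc))) {
      bs <- which(exp_dc == dc)
      any_valid <- FALSE
      sums <- numeric(length(ps))
      for (k in seq_along(ps)) {
        p <- ps[k]
        for (b in bs) {
          if (valid[b, p]) any_valid <- TRUE
          sdc <- (b - 1) %/% nb_per + 1
          if (valid[b, p] && !is.na(eg$sv120[b, p]) &&
              cls[sdc, pc_of_ping[p]] == "macrozooplankton") {
            sums[k] <- sums[k] + 10^(eg$sv120[b, p] / 10) * h
          }
        }
      }
      out[[length(out) + 1]] <- data.frame(
        dist_cell = ec, depth_cell = dc,
        NASC = if (any_valid) 4 * pi * 1852^2 * mean(sums) else NA_real_)
    }
  }
  list(class = cls, nasc = do.call(rbind, out))
}

# random small echogram for oracle-equivalence testing
random_echogram <- function(seed, max_pings = 50, max_bins = 40) {
  set.seed(seed)
  np <- sample(6:max_pings, 1)
  nb <- sample(8:max_bins, 1)
  sv120 <- matrix(runif(nb * np, -95, -55), nb, np)
  sv38 <- matrix(runif(nb * np, -95, -55), nb, np)
  drop <- runif(nb * np) < 0.05
  sv120[drop] <- NA
  sv38[matrix(runif(nb * np) < 0.05, nb, np)] <- NA
  bottom <- runif(np, 0.75, 1) * nb
  echogram(sv38 = sv38, sv120 = sv120,
           distance_km = cumsum(runif(np, 0.005, 0.02)),
           bottom_m = bottom, bin_height = 1,
           region = "R", year = 2000L)
}
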