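# Echo-integration constant: m^2 nmi^-2 per (m^-1 * m), 4*pi*1852^2.
NASC_CONST <- 4 * pi * 1852^2

#' Construct a two-frequency echogram
#'
#' Container for co-registered 38 and 120 kHz volume backscattering strength
#' (Sv, dB re 1 m-1) grids. Depth bins are surface-referenced and half-open
#' `[top, top + bin_height)`.
#'
#' @param sv38,sv120 numeric matrices, rows = depth bins (shallow first),
#'   columns = pings. `NA` marks no-data samples.
#' @param distance_km along-track distance per ping (non-decreasing).
#' @param bottom_m bottom depth per ping (m).
#' @param bin_height depth bin height (m).
#' @param depth_top depth of the top of the first bin (m, default 0).
#' @param region,year optional labels carried into downstream indices.
#' @return an object of class `echogram`.
#' @export
echogram <- function(sv38, sv120, distance_km, bottom_m, bin_height,
                     depth_top = 0, region = NA_character_,
                     year = NA_integer_) {
  stopifnot(is.matrix(sv38), is.matrix(sv120))
  if (!all(dim(sv38) == dim(sv120))) {
    stop("38 and 120 kHz grids must have identical dimensions",
         call. = FALSE)
  }
  np <- ncol(sv38)
  stopifnot(length(distance_km) == np, length(bottom_m) == np,
            bin_height > 0)
  if (any(diff(distance_km) < 0)) {
    stop("`distance_km` must be non-decreasing", call. = FALSE)
  }
  if (any(is.infinite(sv38), na.rm = TRUE) ||
      any(is.infinite(sv120), na.rm = TRUE)) {
    stop("Sv must be finite or NA", call. = FALSE)
  }
  structure(
    list(sv38 = sv38, sv120 = sv120, distance_km = distance_km,
         bottom_m = bottom_m, bin_height = bin_height,
         depth_top = depth_top, region = region, year = year),
    class = "echogram")
}

#' @export
print.echogram <- function(x, ...) {
  cat(sprintf(
    "<echogram> %d depth bins x %d pings, bin height %g m, %.2f km track\n",
    nrow(x$sv38), ncol(x$sv38), x$bin_height,
    diff(range(x$distance_km))))
  invisible(x)
}

# depths of bin tops, and validity mask of bins within
# [surface_excl below surface, bottom_excl above bottom]
echogram_bin_tops <- function(eg) {
  eg$depth_top + (seq_len(nrow(eg$sv38)) - 1L) * eg$bin_height
}

echogram_valid_mask <- function(eg, surface_excl = 4, bottom_excl = 1) {
  tops <- echogram_bin_tops(eg)
  bots <- tops + eg$bin_height
  ok_top <- tops >= surface_excl
  # bin must lie fully above (bottom - bottom_excl), per ping
  outer(bots, eg$bottom_m - bottom_excl, `<=`) & ok_top
}

#' Average an echogram into classification sample cells
#'
#' Mean Sv per cell of `pings_per_cell` pings by `meters_per_cell` of depth,
#' per frequency. Averaging is done in the linear domain
#' (`sv = 10^(Sv/10)`) and converted back to dB; the dB difference between
#' frequencies is then taken between the cell means. Cell means below the
#' floor are raised to the floor before differencing, and bins outside the
#' valid water column (default 4 m below the surface to 1 m above the
#' bottom) are excluded. Trailing along-track cells with at least half the
#' nominal ping count are kept.
#'
#' @param eg an [echogram()].
#' @param pings_per_cell,meters_per_cell cell size (defaults 5 pings, 5 m).
#' @param floor_db minimum threshold in dB (default -80).
#' @param surface_excl,bottom_excl exclusion margins in m (defaults 4 and 1).
#' @return a tibble of class `sample_grid` with one row per cell: `dcell`,
#'   `pcell` (depth/ping cell indices), `depth_top`, `depth_bottom`,
#'   `ping_start`, `ping_end`, `sv38_db`, `sv120_db` (floored cell means),
#'   `dSv`, `masked`, `both_floored`, plus attributes describing the grid
#'   geometry (used by [compute_nasc()]).
#' @export
bin_samples <- function(eg, pings_per_cell = 5L, meters_per_cell = 5,
                        floor_db = -80, surface_excl = 4, bottom_excl = 1) {
  stopifnot(inherits(eg, "echogram"))
  nb_per <- meters_per_cell / eg$bin_height
  if (abs(nb_per - round(nb_per)) > 1e-9) {
    stop("bin height must divide the cell height", call. = FALSE)
  }
  nb_per <- as.integer(round(nb_per))
  nb <- nrow(eg$sv38); np <- ncol(eg$sv38)
  dcell_of_bin <- (seq_len(nb) - 1L) %/% nb_per + 1L
  pcell_of_ping <- (seq_len(np) - 1L) %/% pings_per_cell + 1L
  # drop a trailing partial ping cell with < half the nominal pings
  last <- max(pcell_of_ping)
  n_last <- sum(pcell_of_ping == last)
  if (last > 1 && n_last < pings_per_cell / 2) {
    pcell_of_ping[pcell_of_ping == last] <- NA_integer_
  }
  valid <- echogram_valid_mask(eg, surface_excl, bottom_excl)
  tops <- echogram_bin_tops(eg)

  cell_mean_db <- function(sv_db, dc, pc) {
    sel_b <- dcell_of_bin == dc
    sel_p <- !is.na(pcell_of_ping) & pcell_of_ping == pc
    v <- sv_db[sel_b, sel_p, drop = FALSE]
    ok <- valid[sel_b, sel_p, drop = FALSE] & !is.na(v)
    if (!any(ok)) return(NA_real_)
    10 * log10(mean(10^(v[ok] / 10)))
  }
  grid <- expand.grid(dcell = unique(dcell_of_bin),
                      pcell = sort(unique(stats::na.omit(pcell_of_ping))))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    dc <- grid$dcell[i]; pc <- grid$pcell[i]
    m38 <- cell_mean_db(eg$sv38, dc, pc)
    m120 <- cell_mean_db(eg$sv120, dc, pc)
    masked <- is.na(m38) && is.na(m120)
    f38 <- if (is.na(m38)) NA_real_ else max(m38, floor_db)
    f120 <- if (is.na(m120)) NA_real_ else max(m120, floor_db)
    both_fl <- !masked && !is.na(f38) && !is.na(f120) &&
      f38 <= floor_db && f120 <= floor_db
    pings <- which(!is.na(pcell_of_ping) & pcell_of_ping == pc)
    bsel <- which(dcell_of_bin == dc)
    tibble::tibble(
      dcell = dc, pcell = pc,
      depth_top = tops[bsel[1]],
      depth_bottom = tops[bsel[length(bsel)]] + eg$bin_height,
      ping_start = pings[1], ping_end = pings[length(pings)],
      sv38_db = f38, sv120_db = f120,
      dSv = if (masked || is.na(f38) || is.na(f120)) NA_real_
            else f120 - f38,
      masked = masked, both_floored = both_fl)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "geometry") <- list(
    dcell_of_bin = dcell_of_bin, pcell_of_ping = pcell_of_ping,
    pings_per_cell = as.integer(pings_per_cell),
    meters_per_cell = meters_per_cell, floor_db = floor_db,
    surface_excl = surface_excl, bottom_excl = bottom_excl)
  class(out) <- c("sample_grid", class(out))
  out
}

#' Classify sample cells by the 120-38 kHz dB difference
#'
#' Cells whose dB difference `dSv = Sv120 - Sv38` lies in `[lo, hi]`
#' (default `[8, 30]` dB) are classified `macrozooplankton` — fluid-like
#' scatterers such as euphausiids backscatter relatively more at 120 kHz.
#' Swim-bladdered fish give `dSv` near or below 0 and fall in `other`.
#' Cells at the floor at both frequencies are `below_threshold`; cells with
#' no valid bins remain `masked`.
#'
#' @param grid a [bin_samples()] result.
#' @param lo,hi classification band in dB (defaults 8 and 30).
#' @return the grid with an added `class` factor column
#'   (`macrozooplankton`, `other`, `below_threshold`, `masked`).
#' @export
classify <- function(grid, lo = 8, hi = 30) {
  stopifnot(inherits(grid, "sample_grid"), lo < hi)
  cls <- dplyr::case_when(
    grid$masked ~ "masked",
    grid$both_floored ~ "below_threshold",
    !is.na(grid$dSv) & grid$dSv >= lo & grid$dSv <= hi ~ "macrozooplankton",
    TRUE ~ "other")
  out <- dplyr::mutate(grid, class = factor(
    cls, levels = c("macrozooplankton", "other", "below_threshold",
                    "masked")))
  attr(out, "geometry") <- attr(grid, "geometry")
  class(out) <- unique(c("sample_grid", class(out)))
  out
}

#' Echo-integrate macrozooplankton backscatter into NASC export cells
#'
#' For each export cell (`horiz_km` of track by `vert_m` of depth) the
#' nautical area scattering coefficient is computed from the 120 kHz data
#' restricted to macrozooplankton-classified sample cells:
#' `NASC = 4 pi 1852^2 * mean over pings of sum(sv * dz)` over the cell's
#' depth range, in m2 nmi-2. Non-macrozooplankton backscatter contributes
#' zero; export cells whose bins are entirely outside the valid domain are
#' `NA`.
#'
#' @param eg the [echogram()] the grid was built from.
#' @param cls a classified grid from [classify()].
#' @param horiz_km,vert_m export cell size (defaults 0.5 km and 5 m).
#' @return a tibble with one row per export cell: `dist_cell`, `depth_cell`,
#'   `dist_start_km`, `depth_top`, `depth_bottom`, `n_pings`, `NASC`,
#'   `region`, `year`.
#' @export
compute_nasc <- function(eg, cls, horiz_km = 0.5, vert_m = 5) {
  stopifnot(inherits(eg, "echogram"), inherits(cls, "sample_grid"))
  if (!"class" %in% names(cls)) {
    stop("`cls` must be a classified grid (run classify())", call. = FALSE)
  }
  geom <- attr(cls, "geometry")
  nb <- nrow(eg$sv120); np <- ncol(eg$sv120)
  dcell_of_bin <- geom$dcell_of_bin
  pcell_of_ping <- geom$pcell_of_ping
  valid <- echogram_valid_mask(eg, geom$surface_excl, geom$bottom_excl)
  # macrozooplankton membership per (sample dcell, pcell)
  key <- paste(cls$dcell, cls$pcell)
  is_zoo <- setNames(cls$class == "macrozooplankton", key)
  sv_lin <- 10^(eg$sv120 / 10)
  contrib <- matrix(0, nb, np)
  for (p in seq_len(np)) {
    pc <- pcell_of_ping[p]
    if (is.na(pc)) next
    zoo_b <- is_zoo[paste(dcell_of_bin, pc)]
    ok <- !is.na(zoo_b) & zoo_b & valid[, p] & !is.na(sv_lin[, p])
    contrib[ok, p] <- sv_lin[ok, p] * eg$bin_height
  }
  tops <- echogram_bin_tops(eg)
  exp_dcell <- floor(tops / vert_m) + 1L
  exp_pcell <- floor(eg$distance_km / horiz_km) + 1L
  rows <- list()
  for (ec in sort(unique(exp_pcell))) {
    psel <- which(exp_pcell == ec & !is.na(pcell_of_ping))
    if (length(psel) == 0) next
    for (dc in sort(unique(exp_dcell))) {
      bsel <- which(exp_dcell == dc)
      any_valid <- any(valid[bsel, psel, drop = FALSE])
      col_int <- colSums(contrib[bsel, psel, drop = FALSE])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        dist_cell = ec, depth_cell = dc,
        dist_start_km = (ec - 1L) * horiz_km,
        depth_top = (dc - 1L) * vert_m,
        depth_bottom = dc * vert_m,
        n_pings = length(psel),
        NASC = if (any_valid) NASC_CONST * mean(col_int) else NA_real_,
        region = eg$region, year = eg$year)
    }
  }
  dplyr::bind_rows(rows)
}

#' Regional macrozooplankton index
#'
#' Arithmetic mean NASC over export cells per region and year.
#'
#' @param cells a table of export cells from [compute_nasc()] (possibly
#'   several surveys bound together).
#' @param by grouping columns (default `c("region", "year")`).
#' @return a tibble with the grouping columns, `regional_mean` and
#'   `n_cells`. Groups with no unmasked cells are omitted with a warning.
#' @export
regional_index <- function(cells, by = c("region", "year")) {
  stop_if_not_cols(cells, c(by, "NASC"), "NASC cells")
  out <- cells %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) %>%
    dplyr::summarise(
      regional_mean = mean(.data$NASC, na.rm = TRUE),
      n_cells = sum(!is.na(.data$NASC)), .groups = "drop")
  empty <- out$n_cells == 0
  if (any(empty)) {
    warning(sum(empty), " region-year group(s) had no unmasked cells; ",
            "omitted")
    out <- out[!empty, ]
  }
  out
}
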