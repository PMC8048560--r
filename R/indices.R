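#' Standardize a series to zero mean and unit SD within groups
#'
#' The anomaly transform used for predator density and abundance indices:
#' within each group, `z = (x - mean) / SD` with the sample SD (n - 1).
#' Degenerate groups (fewer than 2 values, or zero SD) are flagged and
#' their `z` left missing rather than fabricated.
#'
#' @param df a data frame.
#' @param value name of the value column (default `"value"`).
#' @param by character vector of grouping columns (default
#'   `c("season", "region")`).
#' @return `df` with added columns `z` and `degenerate` (logical).
#' @export
standardize <- function(df, value = "value", by = c("season", "region")) {
  stop_if_not_cols(df, c(value, by), "table")
  df %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) %>%
    dplyr::mutate(
      .n = sum(!is.na(.data[[value]])),
      .sd = sd(.data[[value]], na.rm = TRUE),
      degenerate = .data$.n < 2 | is.na(.data$.sd) | .data$.sd == 0,
      z = dplyr::if_else(
        .data$degenerate, NA_real_,
        (.data[[value]] - mean(.data[[value]], na.rm = TRUE)) /
          .data$.sd)) %>%
    dplyr::ungroup() %>%
    dplyr::select(-".n", -".sd")
}

#' Flag unusually extreme standardized values
#'
#' @param z numeric vector of standardized values (or a data frame with a
#'   `z` column).
#' @param threshold flag values strictly greater than this many SD
#'   (default 2).
#' @return logical vector (or the data frame with an added `extreme`
#'   column). `NA` z-values are not flagged.
#' @export
flag_extremes <- function(z, threshold = 2) {
  if (is.data.frame(z)) {
    stop_if_not_cols(z, "z", "table")
    z$extreme <- flag_extremes(z$z, threshold)
    return(z)
  }
  !is.na(z) & z > threshold
}

#' Encounter rate per unit survey effort
#'
#' `count / effort` — also the calf index when `count` is calves and
#' `effort` the adult count. Pooling segments must be done by summing
#' counts and effort before dividing (the rate of pooled effort, not the
#' mean of rates).
#'
#' @param count non-negative counts.
#' @param effort positive effort (km surveyed, adults counted, ...).
#' @return the rate(s).
#' @export
encounter_rate <- function(count, effort) {
  if (any(effort <= 0, na.rm = TRUE)) {
    stop("effort must be positive", call. = FALSE)
  }
  if (any(count < 0, na.rm = TRUE)) {
    stop("count must be non-negative", call. = FALSE)
  }
  count / effort
}

#' Percent decline from a first to a second value
#'
#' `100 * (first - second) / first`: positive when the series declined.
#'
#' @param first reference (earlier) value, > 0.
#' @param second later value.
#' @return percent change relative to `first`.
#' @export
percent_change <- function(first, second) {
  if (any(first <= 0, na.rm = TRUE)) {
    stop("`first` must be positive", call. = FALSE)
  }
  100 * (first - second) / first
}

#' Mean and SD of station-level biomass by group
#'
#' Region and season labels are input metadata (e.g. Inner Shelf = shore to
#' 50 km; Middle Shelf = 50 km to the 1000 m isobath; Oceanic beyond);
#' no bathymetric classification is recomputed here.
#'
#' @param samples data frame of station-level values.
#' @param value name of the biomass column (default `"biomass"`).
#' @param by grouping columns (default
#'   `c("region", "season", "year", "species")`).
#' @param regions optional controlled vocabulary for the `region` column;
#'   unknown labels raise an error.
#' @return a tibble with the grouping columns, `mean_biomass`, `sd_biomass`
#'   (0 with `single_station = TRUE` when n = 1), and `n`.
#' @export
seasonal_biomass_summary <- function(samples, value = "biomass",
                                     by = c("region", "season", "year",
                                            "species"),
                                     regions = NULL) {
  stop_if_not_cols(samples, c(value, by), "samples")
  if (!is.null(regions) && "region" %in% by) {
    bad <- setdiff(unique(samples$region), regions)
    if (length(bad) > 0) {
      stop("unknown region label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  samples %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) %>%
    dplyr::summarise(
      mean_biomass = mean(.data[[value]]),
      n = dplyr::n(),
      sd_biomass = dplyr::if_else(dplyr::n() > 1,
                                  sd(.data[[value]]), 0),
      single_station = dplyr::n() == 1,
      .groups = "drop")
}
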