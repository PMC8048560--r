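#' Frequency of occurrence of prey species in diet samples
#'
#' Availability index: the proportion of diet samples, per year and feeding
#' guild, in which a prey species occurs.
#'
#' @param samples a long data frame with columns `sample_id`, `year`,
#'   `guild`, `species`, `present` (logical or 0/1). Each `sample_id` is one
#'   diet sample; a species absent from a sample may appear with
#'   `present = FALSE` or simply be omitted.
#' @param species optional character vector fixing the species set (so that
#'   species never observed in a year still get `F = 0`). Default: all
#'   species occurring in `samples`.
#' @return a tibble with columns `year`, `guild`, `species`, `F` (frequency
#'   of occurrence in `[0, 1]`) and `n_samples`.
#' @examples
#' diets <- gen_diet(diet_scenario(seed = 1))
#' frequency_of_occurrence(diets$samples)
#' @export
frequency_of_occurrence <- function(samples, species = NULL) {
  stop_if_not_cols(samples, c("sample_id", "year", "guild", "species",
                              "present"), "diet samples")
  samples <- dplyr::mutate(samples, present = as.logical(.data$present))
  if (is.null(species)) {
    species <- sort(unique(samples$species[samples$present]))
  }
  sizes <- samples %>%
    dplyr::distinct(.data$year, .data$guild, .data$sample_id) %>%
    dplyr::count(.data$year, .data$guild, name = "n_samples")
  counts <- samples %>%
    dplyr::filter(.data$present, .data$species %in% !!species) %>%
    dplyr::distinct(.data$year, .data$guild, .data$species,
                    .data$sample_id) %>%
    dplyr::count(.data$year, .data$guild, .data$species, name = "n_present")
  grid <- tidyr::expand_grid(
    dplyr::distinct(sizes, .data$year, .data$guild), species = species)
  grid %>%
    dplyr::left_join(counts, by = c("year", "guild", "species")) %>%
    dplyr::left_join(sizes, by = c("year", "guild")) %>%
    dplyr::mutate(n_present = dplyr::coalesce(.data$n_present, 0L),
                  F = .data$n_present / .data$n_samples) %>%
    dplyr::select("year", "guild", "species", "F", "n_samples") %>%
    dplyr::arrange(.data$year, .data$guild, .data$species)
}

#' Variance ratio of a multispecies time series
#'
#' `VR = var(sum across species) / sum(per-species variances)`, the community
#' synchrony statistic: `VR = 1` for uncorrelated species, `> 1` for
#' synchronous (positively covarying) species and `< 1` for compensatory
#' dynamics. Sample variances (n - 1) are used in both numerator and
#' denominator; the convention cancels in the ratio.
#'
#' @param series a numeric matrix or data frame, rows = time points (years),
#'   columns = species (at least 2 columns, 2 rows).
#' @return the variance ratio, or `NA` when every per-species variance is
#'   zero (the statistic is undefined; no stability is fabricated).
#' @export
variance_ratio <- function(series) {
  m <- as.matrix(series)
  if (!is.numeric(m)) stop("`series` must be numeric", call. = FALSE)
  if (ncol(m) < 2) stop("variance ratio needs at least 2 species",
                        call. = FALSE)
  if (nrow(m) < 2) stop("variance ratio needs at least 2 time points",
                        call. = FALSE)
  if (anyNA(m)) stop("`series` contains NA; supply complete windows",
                     call. = FALSE)
  denom <- sum(apply(m, 2, var))
  if (denom == 0) return(NA_real_)
  var(rowSums(m)) / denom
}

#' Rolling portfolio effects from prey frequency series
#'
#' Computes the variance ratio in centered rolling windows of the per-species
#' frequency-of-occurrence series for each guild, and reports the portfolio
#' effect `PE = 1 - VR`. Lower PE means greater synchrony across species and
#' lower buffering by the forage community; `PE = 0` is the uncorrelated
#' baseline and `PE = 1 - k` the fully synchronized limit for `k` species.
#'
#' @param freq a frequency table from [frequency_of_occurrence()] (columns
#'   `year`, `guild`, `species`, `F`).
#' @param window_len window length in years (odd, default 3).
#' @param species optional species subset; default all species in `freq`.
#' @return a tibble with columns `center_year`, `guild`, `n_window_years`,
#'   `VR`, `PE`. Windows whose years are incomplete for any species are
#'   skipped; windows where all species are constant give `NA` (undefined).
#' @export
rolling_portfolio_effect <- function(freq, window_len = 3L, species = NULL) {
  stop_if_not_cols(freq, c("year", "guild", "species", "F"),
                   "frequency table")
  stopifnot(window_len >= 2)
  if (window_len %% 2 == 0) {
    stop("`window_len` must be odd for a centered window", call. = FALSE)
  }
  if (is.null(species)) species <- sort(unique(freq$species))
  half <- (window_len - 1L) %/% 2L
  out <- freq %>%
    dplyr::filter(.data$species %in% !!species) %>%
    dplyr::group_by(.data$guild) %>%
    dplyr::group_modify(function(g, key) {
      wide <- tidyr::pivot_wider(g[, c("year", "species", "F")],
                                 names_from = "species", values_from = "F")
      wide <- wide[order(wide$year), ]
      centers <- wide$year[(wide$year - half) %in% wide$year &
                           (wide$year + half) %in% wide$year]
      rows <- lapply(centers, function(cy) {
        yrs <- (cy - half):(cy + half)
        w <- wide[match(yrs, wide$year), species, drop = FALSE]
        if (anyNA(match(yrs, wide$year)) || anyNA(w)) return(NULL)
        vr <- variance_ratio(w)
        tibble::tibble(center_year = cy, n_window_years = window_len,
                       VR = vr, PE = 1 - vr)
      })
      dplyr::bind_rows(rows)
    }) %>%
    dplyr::ungroup()
  out
}

#' Pearson correlation between two year-indexed guild series
#'
#' @param series_a,series_b data frames with columns `year` and `value`
#'   (or named numeric vectors with years as names). Only shared years are
#'   used; at least 3 are required.
#' @return a tibble with `r`, `p` (two-sided, t transform), `n`.
#' @export
guild_correlation <- function(series_a, series_b) {
  as_yv <- function(s, nm) {
    if (is.data.frame(s)) {
      stop_if_not_cols(s, c("year", "value"), nm)
      setNames(s$value, s$year)
    } else if (!is.null(names(s))) {
      s
    } else {
      stop(nm, " must be a data frame (year, value) or a named vector",
           call. = FALSE)
    }
  }
  a <- as_yv(series_a, "series_a")
  b <- as_yv(series_b, "series_b")
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3) stop("need at least 3 shared years", call. = FALSE)
  x <- a[shared]; y <- b[shared]
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance in one of the series", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value,
                 n = length(shared))
}
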