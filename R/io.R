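# CSV readers for the long-form input dialects, and a provenance-stamped
# writer used by the pipeline. All inputs and outputs are plain text.

#' Read a long-form daily SST table
#'
#' Expected columns: `date,sst` with optional `cell_id,lat,lon`. Multi-cell
#' files hold one contiguous daily series per `cell_id`.
#'
#' @param path CSV path.
#' @return a tibble with `date` parsed as `Date`.
#' @export
read_sst_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  stop_if_not_cols(df, c("date", "sst"), path)
  df$date <- as.Date(df$date)
  df
}

#' Read a long-form diet-sample table
#'
#' Expected columns: `sample_id,year,guild,species,present`.
#'
#' @param path CSV path.
#' @return a tibble.
#' @export
read_diet_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  stop_if_not_cols(df, c("sample_id", "year", "guild", "species",
                         "present"), path)
  df$present <- as.logical(df$present)
  df
}

#' Read a long-form two-frequency echogram export
#'
#' Expected columns: `ping,distance_km,depth_m,sv38_db,sv120_db,bottom_m`,
#' one row per ping x depth bin, `depth_m` being the bin top. Bin height is
#' inferred from the depth spacing (must be uniform).
#'
#' @param path CSV path.
#' @param region,year optional labels attached to the echogram.
#' @return an [echogram()].
#' @export
read_echogram_csv <- function(path, region = NA_character_,
                              year = NA_integer_) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  stop_if_not_cols(df, c("ping", "distance_km", "depth_m", "sv38_db",
                         "sv120_db", "bottom_m"), path)
  depths <- sort(unique(df$depth_m))
  if (length(depths) < 2) stop("echogram needs >= 2 depth bins",
                               call. = FALSE)
  dh <- diff(depths)
  if (max(dh) - min(dh) > 1e-9) {
    stop("depth bins must be uniform", call. = FALSE)
  }
  pings <- sort(unique(df$ping))
  shape <- function(col) {
    m <- matrix(NA_real_, length(depths), length(pings))
    m[cbind(match(df$depth_m, depths), match(df$ping, pings))] <- df[[col]]
    m
  }
  per_ping <- df[match(pings, df$ping), ]
  echogram(sv38 = shape("sv38_db"), sv120 = shape("sv120_db"),
           distance_km = per_ping$distance_km,
           bottom_m = per_ping$bottom_m, bin_height = dh[1],
           depth_top = depths[1], region = region, year = year)
}

#' Read annual length-frequency and CPUE tables
#'
#' @param path CSV path with columns `year,length_mm` (lengths) or
#'   `year,cpue` (CPUE).
#' @return a tibble.
#' @export
read_lengths_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  stop_if_not_cols(df, c("year", "length_mm"), path)
  df
}

#' @rdname read_lengths_csv
#' @export
read_cpue_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  stop_if_not_cols(df, c("year", "cpue"), path)
  df
}

#' Read a fish-energetics record table
#'
#' Expected columns: `species,year,month,site,fork_length_mm,wet_g,dry_g,
#' cn_ratio` with optional `ed_dry_kj_g`.
#'
#' @param path CSV path.
#' @return a tibble.
#' @export
read_energy_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  stop_if_not_cols(df, c("species", "year", "month", "site", "wet_g",
                         "dry_g", "cn_ratio"), path)
  df
}

#' Write a stage output CSV with a provenance header
#'
#' Prepends a comment line `# pelagicsync <version>, <stage>,
#' params=<hash>` so every table records which stage and parameter set
#' produced it. Numeric columns are printed at fixed 1e-6 precision for
#' byte-stable reruns.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param stage stage label.
#' @param params list of parameters hashed into the header.
#' @return `path`, invisibly.
#' @export
write_stage_csv <- function(df, path, stage, params = list()) {
  ver <- as.character(utils::packageVersion("pelagicsync"))
  phash <- digest_params(params)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, 6))
  writeLines(sprintf("# pelagicsync v%s, %s, params=%s", ver, stage,
                     phash), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

# md5 of the serialized parameter list (written to a temp file;
# tools::md5sum has no connection interface)
digest_params <- function(params) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(params), collapse = ""), tf)
  unname(tools::md5sum(tf))
}

#' Flatten an echogram to the long CSV layout
#'
#' Inverse of [read_echogram_csv()]: one row per ping x depth bin with
#' columns `ping,distance_km,depth_m,sv38_db,sv120_db,bottom_m`.
#'
#' @param eg an [echogram()].
#' @return a tibble.
#' @export
echogram_to_long <- function(eg) {
  stopifnot(inherits(eg, "echogram"))
  nb <- nrow(eg$sv120)
  np <- ncol(eg$sv120)
  out <- tidyr::expand_grid(ping = seq_len(np), bin = seq_len(nb))
  out$distance_km <- eg$distance_km[out$ping]
  out$depth_m <- eg$depth_top + (out$bin - 1) * eg$bin_height
  out$sv38_db <- eg$sv38[cbind(out$bin, out$ping)]
  out$sv120_db <- eg$sv120[cbind(out$bin, out$ping)]
  out$bottom_m <- eg$bottom_m[out$ping]
  out$bin <- NULL
  out
}
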