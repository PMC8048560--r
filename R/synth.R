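# Seeded generators emulating the statistical structure of each input
# stream: seasonal + AR(1) SST with injected warm events, correlated
# Bernoulli diet-presence records, layered two-frequency echograms,
# lognormal mixture lengths, and hierarchical energetics records. Each
# generator is a pure function of its scenario (seed included) and returns
# the data together with the ground truth needed to score recovery tests.

#' Scenario for the synthetic SST generator
#'
#' Defaults describe a multi-decadal subarctic coastal series with a strong
#' seasonal cycle, red (AR(1)) daily noise, and a 2014-2016 warm boxcar
#' emulating a persistent marine heatwave.
#'
#' @param seed integer seed.
#' @param years `c(first, last)` calendar years (default `c(1982, 2018)`).
#' @param mean_sst long-term mean (deg C).
#' @param amplitude seasonal semi-amplitude (deg C).
#' @param phase seasonal phase (radians).
#' @param ar1_phi lag-1 autocorrelation of the noise.
#' @param noise_sd marginal SD of the AR(1) noise (deg C).
#' @param events list of injected warm events, each
#'   `list(start = "YYYY-MM-DD", duration = days, amplitude = deg C)`.
#' @return a scenario list for [gen_sst()].
#' @export
sst_scenario <- function(seed = 1L, years = c(1982L, 2018L), mean_sst = 8,
                         amplitude = 4, phase = -2, ar1_phi = 0.8,
                         noise_sd = 0.6,
                         events = list(list(start = "2014-01-15",
                                            duration = 1050,
                                            amplitude = 2.5))) {
  list(seed = as.integer(seed), years = years, mean_sst = mean_sst,
       amplitude = amplitude, phase = phase, ar1_phi = ar1_phi,
       noise_sd = noise_sd, events = events)
}

#' Generate a daily SST series with injected warm events
#'
#' `sst(t) = mean + A sin(2 pi doy / 365.25 + phase) + AR(1) noise +
#' event boxcars`.
#'
#' @param cfg a scenario from [sst_scenario()].
#' @return a list with `series` (tibble `date`, `sst`) and `truth` (tibble
#'   of injected events: `start`, `end`, `duration`, `amplitude`).
#' @export
gen_sst <- function(cfg) {
  if (diff(cfg$years) + 1 < 10) {
    stop("SST span must be >= 10 years for a stable climatology",
         call. = FALSE)
  }
  dates <- seq(as.Date(paste0(cfg$years[1], "-01-01")),
               as.Date(paste0(cfg$years[2], "-12-31")), by = "day")
  n <- length(dates)
  truth <- dplyr::bind_rows(lapply(cfg$events, function(ev) {
    s <- as.Date(ev$start)
    tibble::tibble(start = s, end = s + ev$duration - 1L,
                   duration = as.integer(ev$duration),
                   amplitude = ev$amplitude)
  }))
  if (nrow(truth) > 1) {
    o <- order(truth$start)
    if (any(truth$start[o][-1] <= truth$end[o][-nrow(truth)])) {
      stop("injected events overlap", call. = FALSE)
    }
  }
  # seasonality as a pure function of the 366-day calendar index, so the
  # day-of-year climatology can represent it without phase drift
  doy <- doy366(dates)
  seasonal <- cfg$mean_sst +
    cfg$amplitude * sin(2 * pi * doy / 366 + cfg$phase)
  noise <- with_local_seed(seed_offset(cfg$seed, "sst"), {
    if (cfg$noise_sd == 0) {
      rep(0, n)
    } else {
      innov_sd <- cfg$noise_sd * sqrt(1 - cfg$ar1_phi^2)
      as.numeric(stats::filter(rnorm(n, 0, innov_sd), cfg$ar1_phi,
                               method = "recursive"))
    }
  })
  boxcar <- rep(0, n)
  if (nrow(truth) > 0) {
    for (i in seq_len(nrow(truth))) {
      sel <- dates >= truth$start[i] & dates <= truth$end[i]
      boxcar[sel] <- boxcar[sel] + truth$amplitude[i]
    }
  }
  list(series = tibble::tibble(date = dates,
                               sst = seasonal + noise + boxcar),
       truth = truth)
}

#' Scenario for the synthetic diet-presence generator
#'
#' Defaults emulate a 26-year colony diet series: two feeding guilds, three
#' preferred prey species with distinct base frequencies, and a latent
#' year-level availability process whose cross-species correlation is set
#' by the synchrony parameter `rho`.
#'
#' @param seed integer seed.
#' @param years `c(first, last)` (default `c(1993, 2018)`).
#' @param species named numeric vector of base frequencies of occurrence.
#' @param rho synchrony in `[0, 1]`: the latent logit availability is
#'   `qlogis(base) + shock_sd * (rho * common + (1 - rho) * own)` with
#'   standard-normal year shocks.
#' @param shock_sd SD of the logit-scale year shocks.
#' @param samples_per_year diet samples per year and guild.
#' @param guilds guild labels.
#' @return a scenario list for [gen_diet()].
#' @export
diet_scenario <- function(seed = 1L, years = c(1993L, 2018L),
                          species = c(capelin = 0.5, sand_lance = 0.35,
                                      herring = 0.12),
                          rho = 0, shock_sd = 0.8,
                          samples_per_year = 150L,
                          guilds = c("diver", "surface")) {
  stopifnot(rho >= 0, rho <= 1, all(species > 0), all(species <= 1))
  list(seed = as.integer(seed), years = years, species = species,
       rho = rho, shock_sd = shock_sd,
       samples_per_year = as.integer(samples_per_year), guilds = guilds)
}

#' Generate Bernoulli diet-presence samples with controllable synchrony
#'
#' @param cfg a scenario from [diet_scenario()].
#' @return a list with `samples` (long tibble `sample_id`, `year`, `guild`,
#'   `species`, `present`) and `truth` (tibble of latent per-species
#'   occurrence probabilities `year`, `species`, `p`).
#' @export
gen_diet <- function(cfg) {
  yrs <- cfg$years[1]:cfg$years[2]
  sp <- names(cfg$species)
  with_local_seed(seed_offset(cfg$seed, "diet"), {
    common <- rnorm(length(yrs))
    own <- matrix(rnorm(length(yrs) * length(sp)), length(yrs), length(sp),
                  dimnames = list(NULL, sp))
    logit_p <- sweep(
      cfg$shock_sd * (cfg$rho * common + (1 - cfg$rho) * own),
      2, qlogis(cfg$species), `+`)
    p <- plogis(logit_p)
    truth <- tidyr::expand_grid(year = yrs, species = sp)
    truth$p <- p[cbind(match(truth$year, yrs), match(truth$species, sp))]
    rows <- list()
    for (g in cfg$guilds) {
      for (iy in seq_along(yrs)) {
        for (is in seq_along(sp)) {
          pres <- rbinom(cfg$samples_per_year, 1, p[iy, is]) == 1
          rows[[length(rows) + 1L]] <- tibble::tibble(
            sample_id = sprintf("%s-%d-%03d", g, yrs[iy],
                                seq_len(cfg$samples_per_year)),
            year = yrs[iy], guild = g, species = sp[is], present = pres)
        }
      }
    }
    list(samples = dplyr::bind_rows(rows), truth = truth)
  })
}

#' Scenario for the synthetic two-frequency echogram generator
#'
#' Defaults place a fluid-like macrozooplankton layer (`dSv` = 16 dB) above
#' a swim-bladdered fish layer (`dSv` = -2 dB) in otherwise empty water
#' below the detection floor, over a flat 60 m bottom.
#'
#' @param seed integer seed.
#' @param n_pings,ping_spacing_km track geometry (default 100 pings,
#'   0.05 km apart).
#' @param bin_height depth bin height (m, default 1).
#' @param bottom_m bottom depth per ping (scalar or vector, default 60).
#' @param background_db Sv of empty water (default -95, below the -80
#'   floor).
#' @param noise_sd Gaussian dB noise added independently per frequency.
#' @param layers list of layers, each `list(top, bottom, sv120, dsv,
#'   class)` with depths in m, `sv120` in dB and `class` a label stored in
#'   the truth.
#' @param region,year labels carried through.
#' @return a scenario list for [gen_echogram()].
#' @export
echogram_scenario <- function(seed = 1L, n_pings = 100L,
                              ping_spacing_km = 0.05, bin_height = 1,
                              bottom_m = 60, background_db = -95,
                              noise_sd = 1,
                              layers = list(
                                list(top = 10, bottom = 30, sv120 = -66,
                                     dsv = 16, class = "macrozooplankton"),
                                list(top = 35, bottom = 45, sv120 = -60,
                                     dsv = -2, class = "fish")),
                              region = "A", year = 2014L) {
  list(seed = as.integer(seed), n_pings = as.integer(n_pings),
       ping_spacing_km = ping_spacing_km, bin_height = bin_height,
       bottom_m = bottom_m, background_db = background_db,
       noise_sd = noise_sd, layers = layers, region = region,
       year = as.integer(year))
}

#' Generate a layered two-frequency echogram
#'
#' `Sv120 = layer value + noise`; `Sv38 = layer value - dSv + independent
#' noise`. The truth records, per layer, the expected column NASC of a
#' ping through the layer (`4 pi 1852^2 * sv * thickness`).
#'
#' @param cfg a scenario from [echogram_scenario()].
#' @return a list with `eg` (an [echogram()]) and `truth` (tibble `layer`,
#'   `class`, `top`, `bottom`, `sv120_db`, `dsv_db`, `column_nasc`).
#' @export
gen_echogram <- function(cfg) {
  bottom <- rep(cfg$bottom_m, length.out = cfg$n_pings)
  nb <- ceiling(max(bottom) / cfg$bin_height)
  tops <- (seq_len(nb) - 1) * cfg$bin_height
  clean120 <- matrix(cfg$background_db, nb, cfg$n_pings)
  dsv <- matrix(0, nb, cfg$n_pings)
  truth <- list()
  for (i in seq_along(cfg$layers)) {
    ly <- cfg$layers[[i]]
    if (ly$bottom > max(bottom)) {
      stop("layer ", i, " extends below the bottom", call. = FALSE)
    }
    sel <- tops >= ly$top & tops + cfg$bin_height <= ly$bottom
    clean120[sel, ] <- ly$sv120
    dsv[sel, ] <- ly$dsv
    truth[[i]] <- tibble::tibble(
      layer = i, class = ly$class, top = ly$top, bottom = ly$bottom,
      sv120_db = ly$sv120, dsv_db = ly$dsv,
      column_nasc = NASC_CONST * 10^(ly$sv120 / 10) * (ly$bottom - ly$top))
  }
  eg <- with_local_seed(seed_offset(cfg$seed, "echogram"), {
    sv120 <- clean120 + rnorm(nb * cfg$n_pings, 0, cfg$noise_sd)
    sv38 <- clean120 - dsv + rnorm(nb * cfg$n_pings, 0, cfg$noise_sd)
    echogram(sv38 = sv38, sv120 = sv120,
             distance_km = (seq_len(cfg$n_pings) - 1) *
               cfg$ping_spacing_km,
             bottom_m = bottom, bin_height = cfg$bin_height,
             region = cfg$region, year = cfg$year)
  })
  list(eg = eg, truth = dplyr::bind_rows(truth))
}

#' Scenario for the synthetic length-frequency generator
#'
#' Defaults emulate three size modes (roughly age-0, age-1, older) in a
#' multi-year diet-sampled length series.
#'
#' @param seed integer seed.
#' @param years `c(first, last)` (default `c(2012, 2016)`).
#' @param weights,meanlog,sdlog mixture parameters (recycled across
#'   years).
#' @param n_per_year lengths per year.
#' @param cpue named vector of CPUE by year, or a single value recycled.
#' @return a scenario list for [gen_lengths()].
#' @export
lengths_scenario <- function(seed = 1L, years = c(2012L, 2016L),
                             weights = c(0.6, 0.3, 0.1),
                             meanlog = log(c(65, 130, 190)),
                             sdlog = c(0.12, 0.10, 0.08),
                             n_per_year = 1000L, cpue = 100) {
  stopifnot(abs(sum(weights) - 1) < 1e-9, all(sdlog >= 0))
  list(seed = as.integer(seed), years = years, weights = weights,
       meanlog = meanlog, sdlog = sdlog,
       n_per_year = as.integer(n_per_year), cpue = cpue)
}

#' Generate annual lognormal-mixture length samples
#'
#' @param cfg a scenario from [lengths_scenario()].
#' @return a list with `lengths` (tibble `year`, `length_mm`), `cpue`
#'   (tibble `year`, `cpue`) and `truth` (mixture parameters and the true
#'   size-class proportions implied by them for a 100 mm boundary).
#' @export
gen_lengths <- function(cfg) {
  yrs <- cfg$years[1]:cfg$years[2]
  K <- length(cfg$weights)
  with_local_seed(seed_offset(cfg$seed, "lengths"), {
    rows <- lapply(yrs, function(y) {
      comp <- sample.int(K, cfg$n_per_year, replace = TRUE,
                         prob = cfg$weights)
      tibble::tibble(year = y,
                     length_mm = rlnorm(cfg$n_per_year,
                                        cfg$meanlog[comp],
                                        cfg$sdlog[comp]))
    })
    cpue_tbl <- tibble::tibble(
      year = yrs,
      cpue = if (length(cfg$cpue) == 1) rep(cfg$cpue, length(yrs))
             else unname(cfg$cpue[as.character(yrs)]))
    truth <- tibble::tibble(
      component = seq_len(K), weight = cfg$weights,
      meanlog = cfg$meanlog, sdlog = cfg$sdlog)
    list(lengths = dplyr::bind_rows(rows), cpue = cpue_tbl, truth = truth)
  })
}

#' Scenario for the synthetic energetics generator
#'
#' Defaults emulate a decade of juvenile-herring energetics sampling in two
#' months at a handful of nursery sites, with multiplicative year effects,
#' site-in-year random intercepts, and lognormal residuals on total energy.
#'
#' @param seed integer seed.
#' @param years `c(first, last)` (default `c(2007, 2016)`).
#' @param months sampling months.
#' @param base_log_te grand mean of log total energy (log kJ).
#' @param year_effects named numeric vector of log-scale year deviations;
#'   unnamed years get 0. Default: a 2015 trough and 2016 rebound.
#' @param month_effects named log-scale month deviations.
#' @param sites_per_year,n_per_site sampling design.
#' @param site_sd,resid_sd SD of site-in-year intercepts and residuals
#'   (log scale).
#' @return a scenario list for [gen_energetics()].
#' @export
energetics_scenario <- function(seed = 1L, years = c(2007L, 2016L),
                                months = c("Mar", "Nov"),
                                base_log_te = log(25),
                                year_effects = c("2015" = -0.5,
                                                 "2016" = 0.3),
                                month_effects = c(Mar = -0.2, Nov = 0.2),
                                sites_per_year = 4L, n_per_site = 15L,
                                site_sd = 0.15, resid_sd = 0.25) {
  stopifnot(site_sd >= 0, resid_sd >= 0)
  list(seed = as.integer(seed), years = years, months = months,
       base_log_te = base_log_te, year_effects = year_effects,
       month_effects = month_effects,
       sites_per_year = as.integer(sites_per_year),
       n_per_site = as.integer(n_per_site), site_sd = site_sd,
       resid_sd = resid_sd)
}

#' Generate hierarchical fish-energetics records
#'
#' Latent `log TE = base + year effect + month effect + site intercept +
#' residual`. Chemistry and masses are back-solved so that recomputing the
#' energy density from the generated C:N and dry/wet ratios reproduces the
#' stored density exactly, and `ED x wet mass` reproduces the latent total
#' energy.
#'
#' @param cfg a scenario from [energetics_scenario()].
#' @return a list with `records` (tibble `species`, `year`, `month`,
#'   `site`, `fork_length_mm`, `wet_g`, `dry_g`, `cn_ratio`, `ed_kj_g`,
#'   `total_energy_kj`) and `truth` (per year x month expected log TE and
#'   the design SDs).
#' @export
gen_energetics <- function(cfg) {
  yrs <- cfg$years[1]:cfg$years[2]
  yeff <- setNames(rep(0, length(yrs)), yrs)
  yeff[names(cfg$year_effects)] <- cfg$year_effects
  with_local_seed(seed_offset(cfg$seed, "energetics"), {
    rows <- list()
    for (y in yrs) {
      site_int <- rnorm(cfg$sites_per_year, 0, cfg$site_sd)
      for (s in seq_len(cfg$sites_per_year)) {
        for (m in cfg$months) {
          n <- cfg$n_per_site
          log_te <- cfg$base_log_te + yeff[as.character(y)] +
            cfg$month_effects[[m]] + site_int[s] +
            rnorm(n, 0, cfg$resid_sd)
          te <- exp(log_te)
          dry_wet <- runif(n, 0.18, 0.30)
          cn <- runif(n, 4, 7)
          ed <- herring_energy_density(cn, dry_wet)
          wet <- te / ed
          rows[[length(rows) + 1L]] <- tibble::tibble(
            species = "herring", year = y, month = m,
            site = paste0("site", s),
            fork_length_mm = runif(n, 60, 110),
            wet_g = wet, dry_g = wet * dry_wet, cn_ratio = cn,
            ed_kj_g = ed, total_energy_kj = te)
        }
      }
    }
    truth <- tidyr::expand_grid(year = yrs, month = cfg$months) %>%
      dplyr::mutate(
        expected_log_te = cfg$base_log_te +
          unname(yeff[as.character(.data$year)]) +
          unname(unlist(cfg$month_effects)[.data$month]),
        site_sd = cfg$site_sd, resid_sd = cfg$resid_sd)
    list(records = dplyr::bind_rows(rows), truth = truth)
  })
}
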