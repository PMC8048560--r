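#' Herring energy density from carbon:nitrogen chemistry
#'
#' Energy density (kJ per g wet mass) predicted from the carbon/nitrogen
#' atomic ratio and the dry/wet mass ratio:
#' `ED = 0.103 * CN + 32.6 * dry_wet - 2.902`. The C:N term tracks lipid
#' content, the dry/wet term water content.
#'
#' @param cn_atomic_ratio carbon/nitrogen atomic ratio (> 0).
#' @param dry_wet dry-to-wet mass ratio, in `(0, 1]`.
#' @return energy density in kJ g-1 (wet basis). Non-positive results are
#'   physically impossible and flagged with a warning (likely data errors);
#'   they are returned as computed so callers can locate the records.
#' @examples
#' herring_energy_density(5.0, 0.25) # 5.763
#' @export
herring_energy_density <- function(cn_atomic_ratio, dry_wet) {
  if (any(cn_atomic_ratio <= 0, na.rm = TRUE)) {
    stop("C:N atomic ratio must be positive", call. = FALSE)
  }
  if (any(dry_wet <= 0 | dry_wet > 1, na.rm = TRUE)) {
    stop("dry/wet ratio must lie in (0, 1]", call. = FALSE)
  }
  ed <- 0.103 * cn_atomic_ratio + 32.6 * dry_wet - 2.902
  bad <- !is.na(ed) & ed <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-positive energy density; ",
            "flagged as invalid")
  }
  ed
}

#' Whole-body total energy
#'
#' `TE = energy density x body mass`. The mass basis must be stated
#' explicitly — wet mass with a wet-basis density (herring C:N model) or dry
#' mass with a dry-basis density (calorimetry) — to prevent silent unit
#' mixing.
#'
#' @param ed energy density, kJ g-1 on the `basis` scale.
#' @param mass body mass in g on the same basis (> 0).
#' @param basis `"wet"` or `"dry"`; no default.
#' @return total energy in kJ, with the basis recorded as an attribute.
#' @export
total_energy <- function(ed, mass, basis) {
  if (missing(basis)) {
    stop("`basis` must be given explicitly (\"wet\" or \"dry\")",
         call. = FALSE)
  }
  basis <- match.arg(basis, c("wet", "dry"))
  if (any(ed <= 0, na.rm = TRUE)) stop("energy density must be positive",
                                       call. = FALSE)
  if (any(mass <= 0, na.rm = TRUE)) stop("mass must be positive",
                                         call. = FALSE)
  structure(ed * mass, basis = basis)
}

#' Apply the juvenile-herring fork-length filter
#'
#' Retains records with fork length inside `[lo, hi]` mm (defaults 55 and
#' 115, the juvenile window used for energetics modelling); out-of-range
#' records are reported, not silently dropped.
#'
#' @param records data frame with a `fork_length_mm` column.
#' @param lo,hi inclusive bounds in mm.
#' @return the filtered data frame.
#' @export
filter_herring_lengths <- function(records, lo = 55, hi = 115) {
  stop_if_not_cols(records, "fork_length_mm", "records")
  out <- records$fork_length_mm < lo | records$fork_length_mm > hi
  if (any(out)) {
    message(sum(out), " record(s) outside ", lo, "-", hi,
            " mm fork length removed")
  }
  records[!out, , drop = FALSE]
}

#' Derive per-fish total energy columns from raw records
#'
#' For `basis = "wet"` the energy density is computed from the C:N model
#' ([herring_energy_density()]) and multiplied by wet mass; for
#' `basis = "dry"` a calorimetric dry-basis density column
#' (`ed_dry_kj_g`) is multiplied by dry mass.
#'
#' @param records data frame with `wet_g`, `dry_g`, and either `cn_ratio`
#'   (wet basis) or `ed_dry_kj_g` (dry basis).
#' @param basis `"wet"` or `"dry"`.
#' @return `records` with added `ed_kj_g` and `total_energy_kj` columns and
#'   a logical `valid_energy` flag (FALSE where the derived density is
#'   non-positive).
#' @export
add_total_energy <- function(records, basis) {
  if (missing(basis)) stop("`basis` must be given explicitly", call. = FALSE)
  basis <- match.arg(basis, c("wet", "dry"))
  stop_if_not_cols(records, c("wet_g", "dry_g"), "records")
  if (any(records$wet_g <= 0 | records$dry_g <= 0, na.rm = TRUE)) {
    stop("masses must be positive", call. = FALSE)
  }
  if (any(records$dry_g > records$wet_g, na.rm = TRUE)) {
    stop("dry mass cannot exceed wet mass", call. = FALSE)
  }
  if (basis == "wet") {
    stop_if_not_cols(records, "cn_ratio", "records")
    ed <- withCallingHandlers(
      herring_energy_density(records$cn_ratio,
                             records$dry_g / records$wet_g),
      warning = function(w) invokeRestart("muffleWarning"))
    mass <- records$wet_g
  } else {
    stop_if_not_cols(records, "ed_dry_kj_g", "records")
    ed <- records$ed_dry_kj_g
    mass <- records$dry_g
  }
  records$ed_kj_g <- ed
  records$valid_energy <- !is.na(ed) & ed > 0
  records$total_energy_kj <- ifelse(records$valid_energy,
                                    ed * mass, NA_real_)
  attr(records, "energy_basis") <- basis
  records
}

#' Compare a quantity among years by one-way ANOVA with Tukey HSD
#'
#' @param records data frame with columns `year` and the response column.
#' @param response name of the response column (default
#'   `"total_energy_kj"`).
#' @param log_response log-transform the response before modelling
#'   (default FALSE).
#' @param alpha familywise level for the compact letter display
#'   (default 0.05).
#' @return a list with `anova` (tibble: `F`, `df1`, `df2`, `p`, `r2`),
#'   `tukey` (pairwise comparisons), and `letters` (tibble `year`,
#'   `letter`; years sharing a letter are not significantly different).
#' @export
annual_group_comparison <- function(records, response = "total_energy_kj",
                                    log_response = FALSE, alpha = 0.05) {
  stop_if_not_cols(records, c("year", response), "records")
  y <- records[[response]]
  keep <- !is.na(y)
  df <- data.frame(y = y[keep], year = factor(records$year[keep]))
  counts <- table(df$year)
  singletons <- names(counts)[counts < 2]
  if (length(singletons) > 0) {
    warning("year(s) with a single record dropped: ",
            paste(singletons, collapse = ", "))
    df <- df[!df$year %in% singletons, , drop = FALSE]
    df$year <- droplevels(df$year)
  }
  if (nlevels(df$year) < 2) {
    stop("need at least 2 years with >= 2 records each", call. = FALSE)
  }
  if (log_response) df$y <- log(df$y)
  fit <- aov(y ~ year, data = df)
  s <- summary(fit)[[1]]
  ss <- s[["Sum Sq"]]
  anova_tbl <- tibble::tibble(
    F = s[["F value"]][1], df1 = s[["Df"]][1], df2 = s[["Df"]][2],
    p = s[["Pr(>F)"]][1], r2 = ss[1] / sum(ss))
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$year
  letters_tbl <- tukey_letters(rownames(tk), tk[, "p adj"],
                               levels(df$year), alpha)
  list(anova = anova_tbl,
       tukey = tibble::as_tibble(tk, rownames = "contrast"),
       letters = letters_tbl)
}

# Compact letter display from pairwise adjusted p-values
# (insert-and-absorb): groups sharing a letter are not significantly
# different at `alpha`.
tukey_letters <- function(contrasts, p_adj, groups, alpha = 0.05) {
  pair <- strsplit(contrasts, "-", fixed = TRUE)
  sig <- vapply(seq_along(pair), function(i) p_adj[i] < alpha, logical(1))
  sets <- list(groups)
  for (i in which(sig)) {
    a <- pair[[i]][1]; b <- pair[[i]][2]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb sets contained in another; drop duplicates
    keep <- rep(TRUE, length(new_sets))
    for (j in seq_along(new_sets)) {
      for (k in seq_along(new_sets)) {
        if (j != k && keep[j] &&
            all(new_sets[[j]] %in% new_sets[[k]]) &&
            (length(new_sets[[j]]) < length(new_sets[[k]]) || j > k)) {
          keep[j] <- FALSE
        }
      }
    }
    sets <- new_sets[keep]
  }
  lab <- vapply(groups, function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = "")
  }, character(1))
  tibble::tibble(year = groups, letter = unname(lab))
}

#' Annual total-energy estimates from a mixed-effects model
#'
#' Fits, for one sampling month, `log(TE) ~ year` (categorical) with a
#' random intercept for site nested in year, by REML, and reports the
#' back-transformed least-squares mean (geometric-scale estimate) per year
#' with a normal-theory 95% interval exponentiated from the log scale.
#' When the site variance is estimated as singular the model is refit
#' without the random term and flagged.
#'
#' @param records data frame with `year`, `site`, `total_energy_kj` and
#'   (unless `month` is NULL) `month`.
#' @param month month to subset on, or NULL to use all rows.
#' @param conf confidence level (default 0.95).
#' @return a tibble with `year`, `month`, `n`, `ls_mean_total_energy`
#'   (kJ), `ci_lo`, `ci_hi`, `r2_marginal`, `r2_conditional`, and attribute
#'   `random_dropped` (TRUE when the singular random term was removed).
#' @export
annual_energy_model <- function(records, month = NULL, conf = 0.95) {
  stop_if_not_cols(records, c("year", "site", "total_energy_kj"),
                   "records")
  if (!is.null(month)) {
    stop_if_not_cols(records, "month", "records")
    records <- records[records$month == month, , drop = FALSE]
  }
  records <- records[!is.na(records$total_energy_kj), , drop = FALSE]
  if (any(records$total_energy_kj <= 0)) {
    stop("total energy must be positive for log modelling", call. = FALSE)
  }
  df <- data.frame(
    logte = log(records$total_energy_kj),
    year = factor(records$year),
    site_in_year = factor(paste(records$year, records$site, sep = ":")))
  if (nlevels(df$year) < 2) stop("need at least 2 years", call. = FALSE)

  random_dropped <- FALSE
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(logte ~ year + (1 | site_in_year), data = df))),
    error = function(e) NULL)
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
    random_dropped <- TRUE
    fit <- stats::lm(logte ~ year, data = df)
  }
  emm <- summary(emmeans::emmeans(fit, "year"), level = conf,
                 infer = c(TRUE, FALSE))
  n_by_year <- table(df$year)

  if (inherits(fit, "merMod")) {
    var_f <- var(as.vector(
      model.matrix(fit) %*% lme4::fixef(fit))) * (nrow(df) - 1) / nrow(df)
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_re <- sum(vc$vcov[vc$grp != "Residual"])
    var_res <- vc$vcov[vc$grp == "Residual"]
  } else {
    var_f <- var(stats::fitted(fit)) * (nrow(df) - 1) / nrow(df)
    var_re <- 0
    var_res <- summary(fit)$sigma^2
  }
  tot <- var_f + var_re + var_res
  r2m <- var_f / tot
  r2c <- (var_f + var_re) / tot

  out <- tibble::tibble(
    year = as.character(emm$year),
    month = if (is.null(month)) NA_character_ else as.character(month),
    n = as.integer(n_by_year[as.character(emm$year)]),
    ls_mean_total_energy = exp(emm$emmean),
    ci_lo = exp(emm$lower.CL),
    ci_hi = exp(emm$upper.CL),
    r2_marginal = r2m,
    r2_conditional = r2c)
  attr(out, "random_dropped") <- random_dropped
  out
}

#' Two-sample comparison of mean length (or any mean)
#'
#' Welch's t-test by default; the pooled-variance test is available via
#' `pooled = TRUE`.
#'
#' @param group_a,group_b numeric vectors (n >= 2 each).
#' @return a tibble with `t`, `df`, `p`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`.
#' @export
mean_comparison_ttest <- function(group_a, group_b, pooled = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    stop("both groups have zero variance", call. = FALSE)
  }
  tt <- t.test(group_a, group_b, var.equal = pooled)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value,
                 mean_a = mean(group_a), sd_a = sd(group_a),
                 mean_b = mean(group_b), sd_b = sd(group_b))
}
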