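#' Fit a lognormal mixture to length-frequency data by EM
#'
#' Decomposes a unimodal-to-multimodal length distribution into `K`
#' lognormal components, i.e. a Gaussian mixture on log-lengths fitted by
#' expectation-maximization. The E-step computes responsibilities from
#' normal densities in log space; the M-step uses weighted moment updates
#' (maximum-likelihood, population variance convention). The best of
#' `n_starts` random initializations (quantile seeding with jitter) is
#' returned, components ordered by increasing `meanlog`.
#'
#' @param lengths numeric vector of lengths (mm), all positive.
#' @param K number of components.
#' @param n_starts random restarts (default 10); ties in log-likelihood are
#'   broken by the lowest start index.
#' @param tol convergence tolerance on the log-likelihood change
#'   (default 1e-8).
#' @param max_iter maximum EM iterations per start (default 500).
#' @param seed integer seed; the fit is a deterministic function of
#'   `(lengths, K, n_starts, seed)`.
#' @param sigma_floor lower bound on component `sdlog`; a start whose
#'   component collapses below it is discarded and restarted (default 1e-3).
#' @param min_per_comp guard requiring `length(lengths) >= K * min_per_comp`
#'   (default 10).
#' @return an object of class `lognormal_mixture_fit`: a list with `K`,
#'   `weights`, `meanlog`, `sdlog`, `loglik`, `bic`, `n_iter`, `converged`,
#'   `seed`, `n` and the per-iteration `loglik_trace` of the winning start.
#' @examples
#' x <- gen_lengths(lengths_scenario(seed = 1))
#' fit <- fit_lognormal_mixture(x$lengths$length_mm[x$lengths$year == 2012],
#'                              K = 2, seed = 1)
#' @export
fit_lognormal_mixture <- function(lengths, K, n_starts = 10L, tol = 1e-8,
                                  max_iter = 500L, seed = 1L,
                                  sigma_floor = 1e-3, min_per_comp = 10L) {
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("all lengths must be positive and finite", call. = FALSE)
  }
  stopifnot(K >= 1, n_starts >= 1)
  n <- length(lengths)
  if (n < K * min_per_comp) {
    stop("need at least ", K * min_per_comp, " observations for K = ", K,
         call. = FALSE)
  }
  x <- log(lengths)

  finish <- function(w, mu, sg, ll, iter, conv, trace, sd_used) {
    ord <- order(mu)
    structure(list(
      K = K, weights = w[ord], meanlog = mu[ord], sdlog = sg[ord],
      loglik = ll, bic = -2 * ll + (3 * K - 1) * log(n),
      n_iter = iter, converged = conv, seed = as.integer(seed), n = n,
      loglik_trace = trace, start_used = sd_used),
      class = "lognormal_mixture_fit")
  }

  if (K == 1) {
    mu <- mean(x)
    sg <- sqrt(mean((x - mu)^2))
    if (sg < sigma_floor) sg <- sigma_floor
    ll <- sum(dnorm(x, mu, sg, log = TRUE))
    return(finish(1, mu, sg, ll, 0L, TRUE, ll, 0L))
  }

  run_em <- function(mu, sg, w) {
    trace <- numeric(0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      logd <- vapply(seq_len(K), function(k) {
        log(w[k]) + dnorm(x, mu[k], sg[k], log = TRUE)
      }, numeric(n))
      m <- apply(logd, 1, max)
      lse <- m + log(rowSums(exp(logd - m)))
      ll <- sum(lse)
      trace <- c(trace, ll)
      r <- exp(logd - lse)
      nk <- colSums(r)
      w <- nk / n
      mu <- colSums(r * x) / nk
      sg <- sqrt(colSums(r * (outer(x, mu, `-`))^2) / nk)
      if (any(!is.finite(sg)) || any(sg < sigma_floor)) {
        return(list(collapsed = TRUE))
      }
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
        return(list(collapsed = FALSE, w = w, mu = mu, sg = sg, ll = ll,
                    iter = it, converged = TRUE, trace = trace))
      }
      ll_old <- ll
    }
    list(collapsed = FALSE, w = w, mu = mu, sg = sg, ll = ll_old,
         iter = max_iter, converged = FALSE, trace = trace)
  }

  best <- NULL
  failed_seeds <- integer(0)
  for (s in seq_len(n_starts)) {
    fit_s <- with_local_seed(as.integer(seed) + s - 1L, {
      q <- quantile(x, (seq_len(K) - 0.5) / K, type = 7)
      mu0 <- as.numeric(q) + rnorm(K, 0, 0.1 * sd(x))
      sg0 <- rep(max(sd(x) / K, sigma_floor * 2), K)
      run_em(mu0, sg0, rep(1 / K, K))
    })
    if (fit_s$collapsed) {
      failed_seeds <- c(failed_seeds, as.integer(seed) + s - 1L)
      next
    }
    if (is.null(best) || fit_s$ll > best$ll) {
      best <- fit_s
      best$start <- s
    }
  }
  if (is.null(best)) {
    stop("all ", n_starts, " EM starts collapsed (sdlog < ", sigma_floor,
         "); start seeds: ", paste(failed_seeds, collapse = ", "),
         call. = FALSE)
  }
  finish(best$w, best$mu, best$sg, best$ll, best$iter, best$converged,
         best$trace, best$start)
}

#' @export
print.lognormal_mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<lognormal mixture> K = %d, n = %d, loglik = %.3f, BIC = %.3f (%s)\n",
    x$K, x$n, x$loglik, x$bic,
    if (x$converged) paste0("converged in ", x$n_iter, " iterations")
    else "not converged"))
  print(tibble::tibble(component = seq_len(x$K), weight = x$weights,
                       meanlog = x$meanlog, sdlog = x$sdlog,
                       median_mm = exp(x$meanlog)))
  invisible(x)
}

#' Size-class proportions from a fitted mixture
#'
#' Integrates the mixture density over size-class intervals defined by the
#' cut points; classes partition `(0, Inf)`, so proportions sum to 1. With
#' the default single boundary at 100 mm, class 1 is the `< 100 mm` group
#' that typically corresponds to age-0 fish in summer.
#'
#' @param fit a [fit_lognormal_mixture()] result.
#' @param boundaries increasing cut points in mm (default 100).
#' @return a tibble with `size_class` (1 = smallest) and `proportion`.
#' @export
component_proportions <- function(fit, boundaries = 100) {
  stopifnot(inherits(fit, "lognormal_mixture_fit"))
  if (is.unsorted(boundaries, strictly = TRUE) || any(boundaries <= 0)) {
    stop("`boundaries` must be positive and strictly increasing",
         call. = FALSE)
  }
  cuts <- c(0, boundaries, Inf)
  props <- vapply(seq_len(length(cuts) - 1L), function(j) {
    sum(fit$weights *
          (plnorm(cuts[j + 1], fit$meanlog, fit$sdlog) -
             plnorm(cuts[j], fit$meanlog, fit$sdlog)))
  }, numeric(1))
  tibble::tibble(size_class = seq_along(props), proportion = props)
}

#' Fit mixtures to annual length-frequency data
#'
#' Per-year wrapper around [fit_lognormal_mixture()] with a fallback: when a
#' `K`-component fit collapses (too few fish in a mode), `K - 1` is tried,
#' down to 1, with a message recording the reduction.
#'
#' @param lengths_df data frame with columns `year`, `length_mm`.
#' @param K target number of components (default 3).
#' @param boundaries size-class cut points in mm passed to
#'   [component_proportions()] (default 100).
#' @param ... further arguments to [fit_lognormal_mixture()].
#' @return a list with `fits` (named by year) and `proportions` (tibble
#'   `year`, `size_class`, `proportion`, `K_used`).
#' @export
fit_mixtures_by_year <- function(lengths_df, K = 3L, boundaries = 100,
                                 ...) {
  stop_if_not_cols(lengths_df, c("year", "length_mm"), "length table")
  years <- sort(unique(lengths_df$year))
  fits <- list()
  props <- list()
  for (y in years) {
    xs <- lengths_df$length_mm[lengths_df$year == y]
    fit <- NULL
    for (k in rev(seq_len(K))) {
      fit <- tryCatch(fit_lognormal_mixture(xs, K = k, ...),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        if (k < K) message("year ", y, ": reduced K from ", K, " to ", k)
        break
      }
    }
    if (is.null(fit)) {
      warning("year ", y, ": no mixture fit possible; skipped")
      next
    }
    fits[[as.character(y)]] <- fit
    props[[as.character(y)]] <- dplyr::mutate(
      component_proportions(fit, boundaries), year = y, K_used = fit$K)
  }
  list(fits = fits,
       proportions = dplyr::bind_rows(props) %>%
         dplyr::select("year", "size_class", "proportion", "K_used"))
}

#' Scale size-class proportions by annual CPUE
#'
#' @param props a tibble with `year`, `size_class`, `proportion` (e.g. from
#'   [fit_mixtures_by_year()]).
#' @param cpue_by_year a tibble with `year`, `cpue`.
#' @return a tibble with `year`, `size_class`, `proportion`, `cpue`,
#'   `cpue_scaled = proportion * cpue`. Years missing CPUE are omitted with
#'   a warning.
#' @export
size_class_cpue <- function(props, cpue_by_year) {
  stop_if_not_cols(props, c("year", "size_class", "proportion"),
                   "proportions")
  stop_if_not_cols(cpue_by_year, c("year", "cpue"), "CPUE table")
  missing_years <- setdiff(unique(props$year), cpue_by_year$year)
  if (length(missing_years) > 0) {
    warning("no CPUE for year(s) ", paste(missing_years, collapse = ", "),
            "; omitted")
  }
  props %>%
    dplyr::inner_join(cpue_by_year, by = "year") %>%
    dplyr::mutate(cpue_scaled = .data$proportion * .data$cpue) %>%
    dplyr::arrange(.data$year, .data$size_class)
}
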