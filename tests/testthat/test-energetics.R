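test_that("energy density formula is exact and linear", {
  expect_equal(herring_energy_density(5.0, 0.25), 5.763, tolerance = 1e-12)
  # linearity: finite differences recover the coefficients
  ed0 <- herring_energy_density(5, 0.25)
  expect_equal((herring_energy_density(5, 0.25 + 1e-6) - ed0) / 1e-6,
               32.6, tolerance = 1e-6)
  expect_equal((herring_energy_density(5 + 1e-6, 0.25) - ed0) / 1e-6,
               0.103, tolerance = 1e-6)
  # the intercept limit is physically impossible and flagged
  expect_warning(ed <- herring_energy_density(1e-9, 1e-9), "non-positive")
  expect_equal(ed, -2.902, tolerance = 1e-6)
  expect_error(herring_energy_density(-1, 0.25), "positive")
  expect_error(herring_energy_density(5, 1.5), "\\(0, 1\\]")
})

test_that("total energy requires an explicit mass basis", {
  te <- total_energy(5.763, 10, basis = "wet")
  expect_equal(as.numeric(te), 57.63, tolerance = 1e-12)
  expect_equal(attr(te, "basis"), "wet")
  expect_error(total_energy(5.763, 10), "basis")
  expect_error(total_energy(5.763, 0, basis = "wet"), "positive")
  expect_error(total_energy(-1, 10, basis = "dry"), "positive")
  # scale equivariance
  expect_equal(as.numeric(total_energy(4, 20, basis = "dry")),
               2 * as.numeric(total_energy(4, 10, basis = "dry")))
})

test_that("generated chemistry round-trips through the energy formulas", {
  g <- gen_energetics(energetics_scenario(seed = 23))
  rec <- add_total_energy(
    dplyr::select(g$records, -"total_energy_kj", -"ed_kj_g"),
    basis = "wet")
  expect_equal(rec$ed_kj_g,
               herring_energy_density(g$records$cn_ratio,
                                      g$records$dry_g / g$records$wet_g),
               tolerance = 1e-12)
  expect_equal(rec$total_energy_kj, g$records$total_energy_kj,
               tolerance = 1e-12)
  expect_error(add_total_energy(g$records, basis = "dry"), "ed_dry_kj_g")
})

test_that("ANOVA comparison separates clearly different years", {
  set.seed(24)
  d <- tibble::tibble(
    year = rep(2013:2014, each = 30),
    total_energy_kj = c(rnorm(30, 50, 2), rnorm(30, 40, 2))) # 5 SD apart
  res <- annual_group_comparison(d)
  expect_lt(res$anova$p, 0.001)
  expect_true(res$letters$letter[1] != res$letters$letter[2])
  expect_gt(res$anova$r2, 0.5)

  one <- d[d$year == 2013, ]
  expect_error(annual_group_comparison(one), "at least 2 years")
  with_single <- dplyr::bind_rows(
    d, tibble::tibble(year = 2015, total_energy_kj = 45))
  expect_warning(annual_group_comparison(with_single), "single record")
})

test_that("indistinguishable years share a Tukey letter", {
  set.seed(25)
  d <- tibble::tibble(year = rep(2010:2012, each = 25),
                      total_energy_kj = rnorm(75, 50, 5))
  res <- annual_group_comparison(d)
  expect_true(all(res$letters$letter == res$letters$letter[1]))
})

test_that("mixed model reproduces injected year means when noise is zero", {
  yrs <- rep(2010:2012, each = 20)
  sites <- rep(rep(c("s1", "s2"), each = 10), 3)
  mu <- c("2010" = log(20), "2011" = log(28), "2012" = log(16))
  d <- tibble::tibble(year = yrs, site = sites,
                      total_energy_kj = exp(mu[as.character(yrs)]))
  est <- annual_energy_model(d)
  expect_equal(log(est$ls_mean_total_energy), unname(mu),
               tolerance = 1e-8)
})

test_that("LS means equal geometric means in a balanced zero-site design", {
  set.seed(26)
  yrs <- rep(2010:2012, each = 30)
  sites <- rep(rep(c("s1", "s2", "s3"), each = 10), 3)
  te <- exp(log(25) + rep(c(0, 0.3, -0.2), each = 30) + rnorm(90, 0, 0.2))
  d <- tibble::tibble(year = yrs, site = sites, total_energy_kj = te)
  est <- annual_energy_model(d)
  geo <- as.numeric(exp(tapply(log(te), yrs, mean)))
  expect_equal(est$ls_mean_total_energy, geo, tolerance = 1e-6)
  # back-transform consistency: the interval is symmetric on the log scale
  expect_equal(log(est$ci_lo * est$ci_hi) / 2,
               log(est$ls_mean_total_energy), tolerance = 1e-8)
})

test_that("LS means are invariant to site relabelling", {
  g <- gen_energetics(energetics_scenario(seed = 27))
  rec <- g$records
  est1 <- annual_energy_model(rec, month = "Nov")
  relab <- c(site1 = "zulu", site2 = "alpha", site3 = "mike",
             site4 = "echo")
  rec2 <- dplyr::mutate(rec, site = unname(relab[site]))
  est2 <- annual_energy_model(rec2, month = "Nov")
  expect_equal(est1$ls_mean_total_energy, est2$ls_mean_total_energy,
               tolerance = 1e-9)
  expect_true(all(est1$ci_lo <= est1$ls_mean_total_energy &
                    est1$ls_mean_total_energy <= est1$ci_hi))
  expect_true(all(est1$r2_marginal <= est1$r2_conditional))
})

test_that("Welch t-test wrapper behaves like the classical test", {
  a <- c(1, 2, 3, 4)
  expect_equal(mean_comparison_ttest(a, a)$t, 0)
  res_ab <- mean_comparison_ttest(a, a + 1)
  res_ba <- mean_comparison_ttest(a + 1, a)
  expect_equal(res_ab$t, -res_ba$t)
  expect_error(mean_comparison_ttest(c(1, 1), c(1, 1)), "zero variance")

  # the spawning-length regime: N(124, 27) vs N(147, 19), n = 300 each
  set.seed(28)
  ts <- replicate(20, {
    abs(mean_comparison_ttest(rnorm(300, 147, 19),
                              rnorm(300, 124, 27))$t)
  })
  expect_gt(mean(ts), 9)
  expect_lt(mean(ts), 16)
})

test_that("fork-length filter reports what it removes", {
  rec <- tibble::tibble(fork_length_mm = c(40, 60, 115, 150))
  expect_message(out <- filter_herring_lengths(rec), "2 record")
  expect_equal(out$fork_length_mm, c(60, 115))
})
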