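uniform_eg <- function(sv120, dsv, nb = 40, np = 10, bottom = 60,
                       spacing = 0.01) {
  echogram(sv38 = matrix(sv120 - dsv, nb, np),
           sv120 = matrix(sv120, nb, np),
           distance_km = (seq_len(np) - 1) * spacing,
           bottom_m = rep(bottom, np), bin_height = 1,
           region = "R", year = 2014L)
}

test_that("cell means average in the linear domain", {
  eg <- uniform_eg(-70, 0)
  grid <- bin_samples(eg)
  expect_equal(unique(round(grid$sv120_db, 10)), -70)

  # bins at -60 and -70 dB in equal measure: linear mean 5.5e-7 -> -62.6 dB
  eg2 <- uniform_eg(-70, 0, nb = 10, np = 5)
  eg2$sv120[6:10, ] <- c(-60, -60, -70, -70, NA) # cell spans depths 5..10 m
  g2 <- bin_samples(eg2)
  cell <- g2[g2$depth_top == 5, ]
  expect_equal(cell$sv120_db, 10 * log10((1e-6 + 1e-7) / 2),
               tolerance = 1e-9)

  # no-data bins are simply absent from the average
  eg3 <- uniform_eg(-60, 0, nb = 10, np = 5)
  eg3$sv120[6:9, ] <- NA
  g3 <- bin_samples(eg3)
  expect_equal(g3$sv120_db[g3$depth_top == 5], -60, tolerance = 1e-9)
})

test_that("dB-difference classification follows the [8, 30] dB band", {
  mk <- function(sv120, sv38) {
    eg <- uniform_eg(-70, 0, nb = 10, np = 5)
    eg$sv120[] <- sv120
    eg$sv38[] <- sv38
    cls <- classify(bin_samples(eg))
    as.character(unique(cls$class))
  }
  expect_equal(mk(-60, -75), "macrozooplankton") # dSv = 15
  expect_equal(mk(-60, -58), "other")            # dSv = -2
  expect_equal(mk(-90, -90), "below_threshold")  # both floored at -80
  expect_equal(mk(-52, -60), "macrozooplankton") # dSv = 8, inclusive
  expect_equal(mk(-30, -60), "macrozooplankton") # dSv = 30, inclusive
  expect_equal(mk(-29, -60), "other")            # dSv = 31
})

test_that("uniform-layer NASC matches the closed form 4*pi*1852^2*sv*H", {
  # 50 m of water at Sv120 = -70 dB, all classified macrozooplankton
  eg <- uniform_eg(-70, 16, nb = 55, np = 10, bottom = 60)
  cls <- classify(bin_samples(eg))
  cells <- compute_nasc(eg, cls, horiz_km = 1, vert_m = 5)
  # valid domain is 4..54 m; integrate the fully-covered 5..50 m column
  col <- cells[cells$depth_top >= 5 & cells$depth_bottom <= 50, ]
  expect_equal(sum(col$NASC), 4 * pi * 1852^2 * 1e-7 * 45,
               tolerance = 1e-6)
  # linearity: +10*log10(2) dB doubles sv and hence NASC
  eg2 <- uniform_eg(-70 + 10 * log10(2), 16, nb = 55, np = 10)
  cells2 <- compute_nasc(eg2, classify(bin_samples(eg2)),
                         horiz_km = 1, vert_m = 5)
  expect_equal(cells2$NASC, 2 * cells$NASC, tolerance = 1e-9)
  # no macrozooplankton cells -> NASC identically 0
  eg3 <- uniform_eg(-60, -2, nb = 55, np = 10)
  cells3 <- compute_nasc(eg3, classify(bin_samples(eg3)),
                         horiz_km = 1, vert_m = 5)
  expect_true(all(cells3$NASC == 0))
})

test_that("NASC is additive when export cells are split in depth", {
  set.seed(12)
  eg <- random_echogram(101, max_pings = 30, max_bins = 40)
  cls <- classify(bin_samples(eg))
  whole <- compute_nasc(eg, cls, horiz_km = 0.1, vert_m = 10)
  halves <- compute_nasc(eg, cls, horiz_km = 0.1, vert_m = 5)
  for (i in seq_len(nrow(whole))) {
    sub <- halves[halves$dist_cell == whole$dist_cell[i] &
                    halves$depth_top >= whole$depth_top[i] &
                    halves$depth_bottom <= whole$depth_bottom[i], ]
    if (!is.na(whole$NASC[i])) {
      expect_equal(sum(sub$NASC, na.rm = TRUE), whole$NASC[i],
                   tolerance = 1e-9)
    }
  }
})

test_that("raising the floor never increases macrozooplankton cells", {
  set.seed(13)
  for (s in 1:5) {
    eg <- random_echogram(200 + s, max_pings = 25, max_bins = 30)
    n_macro <- sapply(c(-80, -75, -70, -65), function(fl) {
      cls <- classify(bin_samples(eg, floor_db = fl))
      sum(cls$class == "macrozooplankton")
    })
    expect_true(all(diff(n_macro) <= 0))
  }
})

test_that("classification is independent of row order and idempotent", {
  eg <- random_echogram(301, max_pings = 20, max_bins = 20)
  grid <- bin_samples(eg)
  cls <- classify(grid)
  perm <- sample(nrow(grid))
  grid_p <- grid[perm, ]
  attr(grid_p, "geometry") <- attr(grid, "geometry")
  class(grid_p) <- class(grid)
  cls_p <- classify(grid_p)
  key <- function(d) paste(d$dcell, d$pcell)
  expect_equal(as.character(cls_p$class[order(key(cls_p))]),
               as.character(cls$class[order(key(cls))]))
  expect_equal(as.character(classify(cls)$class), as.character(cls$class))
})

test_that("pipeline equals the per-bin brute-force oracle", {
  for (s in 1:8) {
    eg <- random_echogram(400 + s)
    grid <- bin_samples(eg)
    cls <- classify(grid)
    want <- oracle_acoustics(eg, horiz_km = 0.1, vert_m = 5)
    expect_equal(as.character(cls$class),
                 want$class[cbind(cls$dcell, cls$pcell)])
    got <- compute_nasc(eg, cls, horiz_km = 0.1, vert_m = 5)
    got <- got[order(got$dist_cell, got$depth_cell), ]
    want_n <- want$nasc[order(want$nasc$dist_cell, want$nasc$depth_cell), ]
    expect_equal(got$dist_cell, want_n$dist_cell)
    expect_equal(got$NASC, want_n$NASC, tolerance = 1e-12)
  }
})

test_that("regional index averages cells and reports group sizes", {
  cells <- tibble::tibble(region = c("A", "A", "B"), year = 2014,
                          NASC = c(100, 300, NA))
  expect_warning(ri <- regional_index(cells), "no unmasked")
  expect_equal(nrow(ri), 1L)
  expect_equal(ri$regional_mean, 200)
  single <- tibble::tibble(region = "A", year = 2014, NASC = 42)
  expect_equal(regional_index(single)$regional_mean, 42)
})

test_that("synthetic survey recovers a density contrast between regions", {
  sc_a <- echogram_scenario(seed = 51, noise_sd = 0.5, region = "A",
                            layers = list(list(top = 10, bottom = 30,
                                               sv120 = -66, dsv = 16,
                                               class = "macrozooplankton")))
  sc_b <- sc_a
  sc_b$seed <- 52L
  sc_b$region <- "B"
  # 3x the linear scatterer density in region B
  sc_b$layers[[1]]$sv120 <- -66 + 10 * log10(3)
  run <- function(sc) {
    g <- gen_echogram(sc)
    cells <- compute_nasc(g$eg, classify(bin_samples(g$eg)))
    regional_index(cells)$regional_mean
  }
  ratio <- run(sc_b) / run(sc_a)
  expect_equal(ratio, 3, tolerance = 0.15)
})
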