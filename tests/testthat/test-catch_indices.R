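tl_toy <- tl_table(c(A = 2.77, B = 3.38, LO = 2, HI = 4))

test_that("mean trophic level is the catch-weighted mean with coverage", {
  expect_equal(mean_trophic_level(c(A = 50), tl_toy)$mtl, 2.77)
  expect_equal(mean_trophic_level(c(LO = 7, HI = 7), tl_toy)$mtl, 3)
  m <- mean_trophic_level(c(A = 100, B = 50), tl_toy)
  expect_equal(m$mtl, 446 / 150, tolerance = 1e-12)
  # unknown species drop out of both numerator and denominator
  m2 <- mean_trophic_level(c(A = 100, B = 50, ZZZ = 50), tl_toy)
  expect_equal(m2$mtl, 446 / 150, tolerance = 1e-12)
  expect_equal(m2$coverage, 150 / 200)
  expect_equal(m2$n_excluded, 1L)
  expect_error(mean_trophic_level(c(ZZZ = 10), tl_toy), "no usable catch")
  # invariant under uniform catch rescaling
  expect_equal(mean_trophic_level(c(A = 1e3, B = 5e2), tl_toy)$mtl, m$mtl)
})

test_that("FiB is zero at the reference year and matches its closed form", {
  expect_equal(fishing_in_balance(c(100, 100), c(3, 3))[2], 0)
  # exact cancellation: tenfold catch at one trophic level lower
  expect_equal(fishing_in_balance(c(100, 1000), c(3, 2))[2], 0,
               tolerance = 1e-12)
  expect_equal(fishing_in_balance(c(100, 200), c(3, 3))[2], log10(2),
               tolerance = 1e-12)
  expect_error(fishing_in_balance(c(100, 0), c(3, 3)), "positive")
  set.seed(5)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    Y <- runif(n, 1, 1e4)
    MTL <- runif(n, 2, 4.5)
    TE <- runif(1, 0.02, 0.9)
    fib <- fishing_in_balance(Y, MTL, ref = 1, TE = TE)
    closed <- log10(Y / Y[1]) + (MTL - MTL[1]) * log10(1 / TE)
    expect_equal(fib, closed, tolerance = 1e-12)
    expect_identical(fib[1], 0)
  }
})

test_that("rmtl_decompose reproduces the balanced-region formulas", {
  # before the breakpoint everything sits in region 1 unchanged
  s <- data.frame(year = 2000:2002, Y = c(100, 110, 121),
                  MTL = c(3, 3.05, 3.1))
  p <- rmtl_decompose(s, 2002)
  r1 <- p[p$region == 1, ]
  expect_equal(r1$Y_hat, s$Y)
  expect_equal(r1$MTL_hat, s$MTL)
  expect_true(all(p$Y_hat[p$region == 2] == 0))

  # balanced-region catch: 100 * 10^(3.0 - 3.1) with TE = 0.1
  s2 <- data.frame(year = 2000:2001, Y = c(100, 300), MTL = c(3.0, 3.1))
  p2 <- rmtl_decompose(s2, 2000)
  expect_equal(p2$Y_hat[p2$year == 2001 & p2$region == 1],
               100 * 10^(3.0 - 3.1), tolerance = 1e-12)
  # balanced-region MTL: 3.0 - log10(2) when catch doubles
  s3 <- data.frame(year = 2000:2001, Y = c(100, 200), MTL = c(3.0, 3.3))
  p3 <- rmtl_decompose(s3, 2000)
  m1 <- p3$MTL_hat[p3$year == 2001 & p3$region == 1]
  expect_equal(m1, 3.0 - log10(2), tolerance = 1e-12)
  # mass-weighted identity forces the expanded-region MTL
  y1 <- p3$Y_hat[p3$year == 2001 & p3$region == 1]
  y2 <- p3$Y_hat[p3$year == 2001 & p3$region == 2]
  m2 <- p3$MTL_hat[p3$year == 2001 & p3$region == 2]
  expect_equal(m1 * y1 + m2 * y2, 3.3 * 200, tolerance = 1e-6 * 3.3 * 200)
})

test_that("negative expanded-region residuals are floored and flagged", {
  # falling MTL with flat catch: balanced region-1 estimate exceeds totals
  s <- data.frame(year = 2000:2001, Y = c(100, 100), MTL = c(3.0, 2.8))
  p <- rmtl_decompose(s, 2000)
  row2 <- p[p$year == 2001 & p$region == 2, ]
  expect_equal(row2$Y_hat, 0)
  expect_match(p$flag[p$year == 2001][1], "assumption_violated")
  # partition still sums to the reported catch
  expect_equal(sum(p$Y_hat[p$year == 2001]), 100)
})

test_that("noise-free construction recovers the configured expanded MTL", {
  s <- make_expansion_series(mtl2 = 3.25, jump = 4)
  p <- rmtl_decompose(s, 2007)
  r2 <- p[p$region == 2 & p$Y_hat > 0 & !is.na(p$MTL_hat), ]
  expect_gt(nrow(r2), 0)
  expect_lt(max(abs(r2$MTL_hat - 3.25)), 1e-6)
})

test_that("quadrant gridding uses signed floors and spherical cell areas", {
  g <- grid_quadrants(data.frame(lat = -26.2, lon = -48.7, catch_t = 5))
  expect_equal(g$cells$cell_lat, -53L)
  expect_equal(g$cells$cell_lon, -98L)
  # two records in one cell -> one quadrant
  two <- data.frame(lat = c(-26.2, -26.4), lon = c(-48.7, -48.6),
                    catch_t = c(5, 7))
  g2 <- grid_quadrants(two)
  expect_equal(nrow(g2$cells), 1L)
  expect_equal(g2$cells$catch_t, 12)
  # independent spherical computation at 26.5 degrees S centre
  expect_equal(quadrant_area(-26.5),
               (111.32 * 0.5) * (111.32 * cos(26.5 * pi / 180) * 0.5),
               tolerance = 1e-12)
  # missing coordinates excluded and counted
  g3 <- grid_quadrants(data.frame(lat = c(-26.2, NA), lon = c(-48.7, -48),
                                  catch_t = c(5, 5)))
  expect_equal(g3$n_excluded, 1L)
})

test_that("biomass density sums catch over visited quadrants", {
  one <- data.frame(year = 2001, species_code = "SV", lat = -26.2,
                    lon = -48.7, catch_t = 40)
  b <- biomass_by_year(one)
  expect_equal(b$density_t_km2, 40 / quadrant_area(-26.25), tolerance = 1e-12)
  two <- one
  two$catch_t <- 80
  expect_equal(biomass_by_year(two)$density_t_km2, 2 * b$density_t_km2)
  # three-quadrant toy against a hand-built ledger
  toy <- data.frame(year = 2001, species_code = c("SV", "SV", "SL"),
                    lat = c(-26.2, -26.7, -27.2),
                    lon = c(-48.7, -48.7, -48.2),
                    catch_t = c(10, 20, 30))
  bt <- biomass_by_year(toy)
  area <- quadrant_area(-26.25) + quadrant_area(-26.75) + quadrant_area(-27.25)
  expect_equal(bt$biomass_t[bt$species_code == "SV"], 30)
  expect_equal(bt$density_t_km2[bt$species_code == "SV"], 30 / area,
               tolerance = 1e-12)
  expect_equal(bt$density_t_km2[bt$species_code == "SL"], 30 / area,
               tolerance = 1e-12)
})

test_that("effort indices are ratios to the fleet's reference year", {
  rec <- data.frame(
    year = c(2000, 2000, 2001, 2001, 2001),
    fleet = c("VIC", "VIC", "VIC", "VIC", "VRB"),
    days_at_sea = c(10, 10, 5, 5, 8),
    fishing_days = c(8, 8, 4, 4, 6),
    hauls = c(4, 4, 2, 2, 3))
  e <- effort_indices(rec, ref_year = 2000)
  vic0 <- e[e$fleet == "VIC" & e$year == 2000, ]
  expect_equal(unlist(vic0[, c("days_at_sea", "fishing_days", "hauls")]),
               c(days_at_sea = 1, fishing_days = 1, hauls = 1))
  vic1 <- e[e$fleet == "VIC" & e$year == 2001, ]
  expect_equal(vic1$days_at_sea, 0.5)
  expect_equal(vic1$fishing_days, 0.5)
  expect_equal(vic1$hauls, 0.5)
  # fleet absent in the reference year falls back to its first year
  vrb <- e[e$fleet == "VRB", ]
  expect_equal(vrb$ref_year, 2001)
  expect_equal(vrb$days_at_sea, 1)
  expect_match(vrb$flag, "absent_in_reference")
})
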