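test_that("seeded generation is bit-reproducible", {
  s <- cruise_spec(seed = 101, n_underway = 50, n_stations = 5)
  expect_identical(simulate_underway(s), simulate_underway(s))
  expect_identical(simulate_bottles(s), simulate_bottles(s))
  expect_identical(simulate_forcing(s, "southern"),
                   simulate_forcing(s, "southern"))
})

test_that("noise-free spring records sit at the under-ice state", {
  s <- cruise_spec(seed = 1, n_underway = 40, noise = 0)
  u <- simulate_underway(s, periods = "spring")
  north <- dplyr::filter(u, region == "northern")
  expect_true(all(abs(north$sst - -1.71) < 1e-9))
  expect_true(all(abs(north$sss - 32.1) < 1e-9))
  expect_true(all(abs(north$pco2 - 538) < 1e-9))
  # DIC backed out of TA and the 538 reference is chemically consistent
  dic <- dic_from_ta_pco2(2225, 538, -1.71, 32.1)
  expect_equal(pco2_from_ta_dic(2225, dic, -1.71, 32.1), 538,
               tolerance = 1e-6)
})

test_that("summer southern records classify mostly as Pacific summer water", {
  s <- cruise_spec(seed = 7, n_underway = 400)
  u <- simulate_underway(s, periods = "early_summer")
  south <- dplyr::filter(u, region == "southern")
  labs <- classify_water_mass(south$sst, south$sss)
  expect_gt(mean(labs %in% c("ACW", "BSW")), 0.8)
})

test_that("default forcing: monotone ice retreat and bounded ranges", {
  s <- cruise_spec(seed = 13)
  f <- simulate_forcing(s, "northern")
  expect_true(all(diff(f$ice_pct) <= 0))
  expect_true(all(f$ice_pct >= 0 & f$ice_pct <= 100))
  expect_true(all(f$u10_sq >= 25 & f$u10_sq <= 80))
  expect_true(all(f$xco2 > 390 & f$xco2 < 402))
  expect_equal(f$day, 120:270)
})

test_that("full ice cover attenuates flux to <= 10% of open water", {
  s <- cruise_spec(seed = 13)
  f <- simulate_forcing(s, "northern")
  early <- f[f$ice_pct > 90, ][1, ]
  cell <- tibble::tibble(day = early$day, lat_bin = 0L, lon_bin = 0L,
                         lat = 72, lon = -165, mean_sst = early$sst,
                         mean_sss = early$sss, mean_pco2 = 538, n_obs = 1L)
  iced <- co2_flux(cell, early)
  open <- co2_flux(cell, dplyr::mutate(early, ice_pct = 0))
  expect_lte(abs(iced$flux), 0.1 * abs(open$flux) + 1e-12)
})

test_that("noise-free closure: the pipeline returns the prescribed C:N", {
  s <- cruise_spec(seed = 1, noise = 0, true_cn = 6.6)
  out <- ncp_summary(normalize_bottles(simulate_bottles(s)))
  expect_equal(out$cn_uptake, c(6.6, 6.6), tolerance = 1e-10)
})

test_that("single-seed recovery at documented noise is close to truth", {
  s <- cruise_spec(seed = 42, true_cn = 12)
  out <- ncp_summary(normalize_bottles(simulate_bottles(s)))
  # per-seed station noise leaves the two-region mean within ~15%
  expect_equal(mean(out$cn_uptake), 12, tolerance = 0.15)
})

test_that("dilution without biology yields near-zero NCP", {
  s <- cruise_spec(seed = 5, noise = 0)
  stats0 <- s$stats
  # freeze summer nutrients at their diluted-conservative level: set the
  # summer targets so no drawdown is implied beyond dilution
  spr_s <- dplyr::filter(stats0, region == "southern", period == "spring",
                         layer == "surface")
  spr_n <- dplyr::filter(stats0, region == "northern", period == "spring",
                         layer == "surface")
  fix <- function(df, reg, spr) {
    i <- df$region == reg & df$period == "early_summer" & df$layer == "surface"
    s_sum <- df$s_mean[i]
    df$no3_mean[i] <- spr$no3_mean * s_sum / spr$s_mean
    df$po4_mean[i] <- spr$po4_mean * s_sum / spr$s_mean
    df
  }
  s$stats <- fix(fix(stats0, "southern", spr_s), "northern", spr_n)
  out <- ncp_summary(normalize_bottles(simulate_bottles(s)))
  expect_equal(out$ncp_n, c(0, 0), tolerance = 1e-9)
  expect_equal(out$ncp_dic, c(0, 0), tolerance = 1e-9)
})
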