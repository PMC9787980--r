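make_cell <- function(pco2 = 250, sst = 0, sss = 32) {
  tibble::tibble(day = 1L, lat_bin = 272L, lon_bin = -676L, lat = 68.1,
                 lon = -168.9, mean_sst = sst, mean_sss = sss,
                 mean_pco2 = pco2, n_obs = 1L)
}
make_forcing <- function(u10_sq = 49, ice = 0, psl = 1, xco2 = 400) {
  tibble::tibble(day = 1L, u10_sq = u10_sq, ice_pct = ice, psl = psl,
                 xco2 = xco2)
}

test_that("gas transfer velocity: zero wind, Schmidt scaling, ice cap", {
  expect_equal(gas_transfer_velocity(0, 0, 0), 0)
  # direct evaluation of 0.251 * u2 * (Sc/660)^-1/2 at 0 degC
  sc0 <- 2116.8
  expect_equal(gas_transfer_velocity(49, 0, 0),
               0.251 * 49 * (sc0 / 660)^-0.5)
  # >90% ice keeps a 10% open-water floor
  k_open <- gas_transfer_velocity(49, 0, 0)
  expect_equal(gas_transfer_velocity(49, 0, 100), 0.1 * k_open)
  expect_equal(gas_transfer_velocity(49, 0, 95), 0.1 * k_open)
  expect_equal(gas_transfer_velocity(49, 0, 50), 0.5 * k_open)
  expect_error(gas_transfer_velocity(-1, 0, 0), "non-negative")
  expect_error(gas_transfer_velocity(49, 0, 101), "ice_pct")
})

test_that("atmospheric pCO2 reflects the vapor-pressure correction", {
  expect_equal(pco2_air(0, 1, 0, 32), 0)
  expect_equal(pco2_air(400, 1, 0, 32), 400 * (1 - vapor_pressure(0, 32)))
  expect_lt(pco2_air(400, 1, 0, 32), 400)
})

test_that("flux sign convention and the frozen worked case", {
  f0 <- co2_flux(make_cell(pco2 = pco2_air(400, 1, 0, 32)), make_forcing())
  expect_equal(f0$flux, 0, tolerance = 1e-12)
  sink <- co2_flux(make_cell(pco2 = 300), make_forcing())
  expect_lt(sink$flux, 0)
  source_ <- co2_flux(make_cell(pco2 = 500), make_forcing())
  expect_gt(source_$flux, 0)
  # frozen composition of the pinned formulas: u2=49, T=0, S=32,
  # ice=50%, pco2_sea=250, xco2=400, psl=1
  worked <- co2_flux(make_cell(), make_forcing(ice = 50))
  expect_equal(worked$flux, -7.988979765, tolerance = 1e-8)
})

test_that("flux is linear in dpCO2 and in open-water fraction", {
  base <- co2_flux(make_cell(pco2 = 250), make_forcing())
  pa <- base$pco2_air
  f2 <- co2_flux(make_cell(pco2 = pa + 2 * (250 - pa)), make_forcing())
  expect_equal(f2$flux, 2 * base$flux, tolerance = 1e-12)
  f_ice <- sapply(c(0, 30, 60, 90), function(i)
    co2_flux(make_cell(), make_forcing(ice = i))$flux)
  expect_equal(f_ice, f_ice[1] * (1 - c(0, 30, 60, 90) / 100))
})

test_that("regional table separates a known ACW / non-ACW contrast", {
  withr::with_seed(21, {
    cells <- tibble::tibble(
      region = "southern", period = "early_summer",
      group = rep(c("ACW", "nonACW"), each = 20),
      flux = c(rnorm(20, -14, 2), rnorm(20, -22, 2)))
  })
  tab <- regional_flux_table(cells)
  expect_lt(tab$p_value, 0.001)
  expect_equal(tab$signif, "***")
  expect_false(tab$test_skipped)
  expect_equal(tab$n, 40L)
})

test_that("identical groups are rarely flagged and n=1 skips the test", {
  withr::with_seed(31, {
    flagged <- sapply(1:40, function(i) {
      cells <- tibble::tibble(region = "southern",
                              group = rep(c("ACW", "nonACW"), each = 15),
                              flux = rnorm(30, -15, 4))
      regional_flux_table(cells)$p_value < 0.05
    })
  })
  expect_gte(mean(!flagged), 0.9)
  one <- tibble::tibble(region = "southern",
                        group = c("ACW", rep("nonACW", 5)),
                        flux = rnorm(6, -15))
  tab1 <- regional_flux_table(one)
  expect_true(tab1$test_skipped)
  expect_true(is.na(tab1$p_value))
  expect_false(is.na(tab1$mean_acw))
})
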