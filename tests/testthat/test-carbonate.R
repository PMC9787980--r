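test_that("solver matches the independent reference grid to within 1 uatm", {
  grid <- readr::read_csv(test_path("ref_carbonate_grid.csv"),
                          show_col_types = FALSE)
  got <- pco2_from_ta_dic(grid$ta, grid$dic, grid$temperature, grid$salinity)
  expect_equal(nrow(grid), 125)
  expect_lt(max(abs(got - grid$pco2_ref)), 1)
})

test_that("pCO2 is monotone increasing in DIC and decreasing in TA", {
  dic <- seq(1900, 2150, by = 50)
  p_dic <- pco2_from_ta_dic(2200, dic, 0, 32)
  expect_true(all(diff(p_dic) > 0))
  ta <- seq(2150, 2400, by = 50)
  p_ta <- pco2_from_ta_dic(ta, 2100, 0, 32)
  expect_true(all(diff(p_ta) < 0))
})

test_that("TA/DIC <-> TA/pCO2 round trip closes to 0.01 umol/kg", {
  cases <- expand.grid(ta = c(2150, 2250), dic = c(1950, 2100),
                       t = c(-1.5, 8), s = c(30, 33))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      p <- pco2_from_ta_dic(ta, dic, t, s)
      back <- dic_from_ta_pco2(ta, p, t, s)
      expect_lt(abs(back - dic), 0.01)
    })
  }
  # inverse is monotone in pCO2
  d <- dic_from_ta_pco2(2200, c(200, 400, 600), 0, 32)
  expect_true(all(diff(d) > 0))
})

test_that("solver rejects unphysical inputs", {
  expect_error(pco2_from_ta_dic(-1, 2000, 0, 32), "positive")
  expect_error(pco2_from_ta_dic(2200, 0, 0, 32), "positive")
  expect_error(dic_from_ta_pco2(2200, 0, 0, 32), "positive")
  expect_error(pco2_from_ta_dic(2200, 2000, 50, 32), "temperature")
  expect_error(pco2_from_ta_dic(2200, 2000, 0, 45), "salinity")
})

test_that("CO2 solubility follows the Weiss evaluation and salting out", {
  # frozen from an independent evaluation of the volumetric Weiss polynomial
  expect_equal(co2_solubility(0, 32), 0.06566557292753147, tolerance = 1e-8)
  t <- seq(-1.5, 10, by = 0.5)
  expect_true(all(diff(co2_solubility(t, 32)) < 0))
  expect_gt(co2_solubility(5, 0.1), co2_solubility(5, 35))
})

test_that("vapor pressure is physically consistent", {
  # ~0.006 atm at freezing; pinned from the Buck evaluation with the
  # seawater reduction at S = 32
  expect_equal(vapor_pressure(0, 32), 0.005928517, tolerance = 1e-6)
  t <- seq(-1, 25, by = 1)
  expect_true(all(diff(vapor_pressure(t, 32)) > 0))
  # moist-air correction always lowers pCO2air below xco2 * psl
  expect_lt(pco2_air(400, 1, 0, 32), 400)
  expect_error(vapor_pressure(40, 32, psl = 0.005), "nonphysical")
})

test_that("density matches UNESCO check values and expected gradients", {
  expect_equal(sw_density(5, 35), 1027.67547, tolerance = 1e-7)
  expect_equal(sw_density(25, 35), 1023.34306, tolerance = 1e-7)
  expect_true(sw_density(0, 32) > 1020 && sw_density(0, 32) < 1030)
  expect_gt(sw_density(0, 33), sw_density(0, 32))
  expect_lt(sw_density(10, 32), sw_density(0, 32))
})
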