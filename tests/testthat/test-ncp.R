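test_that("nutrient-based NCP reproduces the regional worked examples", {
  expect_equal(round(ncp_nutrient(10.24, 25, 73), 2), 3.51)
  expect_equal(round(ncp_nutrient(9.92, 25, 49), 2), 5.06)
  expect_equal(ncp_nutrient(0, 25, 73), 0)
  expect_error(ncp_nutrient(10, 25, 0), "positive")
  # linearity in drawdown and mld, inverse in dt
  expect_equal(ncp_nutrient(20, 25, 73), 2 * ncp_nutrient(10, 25, 73))
  expect_equal(ncp_nutrient(10, 50, 73), 2 * ncp_nutrient(10, 25, 73))
  expect_equal(ncp_nutrient(10, 25, 146), ncp_nutrient(10, 25, 73) / 2)
})

test_that("Redfield conversion to carbon units", {
  expect_equal(redfield_convert(3.51, "N"), 3.51 * 106 / 16)
  # chained printed values round slightly differently; agree to 0.5%
  expect_equal(redfield_convert(3.51, "N"), 23.2, tolerance = 0.005)
  expect_equal(redfield_convert(0.41, "P"), 43.3, tolerance = 0.005)
  expect_equal(redfield_convert(0, "N"), 0)
})

test_that("CaCO3 term: zero cases and the dissolution worked example", {
  expect_equal(caco3_correction(0, 0), 0)
  # a pure nitrate-uptake alkalinity change cancels exactly
  rho <- 1025
  d_no3 <- 10.24
  expect_equal(caco3_correction(-d_no3 / (rho / 1000), d_no3, rho), 0)
  expect_equal(caco3_correction(-34, 10.24, 1025), -12.305)
})

test_that("DIC-based NCP combines drawdown, CaCO3 and flux corrections", {
  expect_equal(ncp_dic(0, dt = 73), 0)
  got <- ncp_dic(79, mld = 25, dt = 73, rho1 = 1025, rho2 = 1025,
                 mean_co2_flux = -10)
  expect_equal(got, 79 * 1.025 * 25 / 73 + 10)
  # uptake (negative flux) adds DIC, so subtracting it raises NCP
  expect_gt(ncp_dic(79, dt = 73, mean_co2_flux = -10),
            ncp_dic(79, dt = 73, mean_co2_flux = 0))
  # dissolution (negative CaCO3 term) hides drawdown, so correcting
  # raises NCP
  expect_gt(ncp_dic(79, dt = 73, caco3_term = -12.3),
            ncp_dic(79, dt = 73, caco3_term = 0))
  # exact product-difference form reduces to the mean-density form when
  # densities match
  expect_equal(ncp_dic(79, dt = 73, rho1 = 1025, rho2 = 1025,
                       ndic_t1 = 2079, ndic_t2 = 2000),
               ncp_dic(79, dt = 73, rho1 = 1025, rho2 = 1025))
})

test_that("uptake ratios reproduce the regional diagnostics", {
  r_s <- uptake_ratios(38.4, 3.51, 0.41)
  expect_equal(round(r_s$cn_uptake, 1), 10.9)
  r_n <- uptake_ratios(61.4, 5.06, 0.48)
  expect_equal(round(r_n$cn_uptake, 1), 12.1)
  expect_equal(uptake_ratios(6.625 * 3, 3)$cn_uptake, 6.625)
  expect_warning(r0 <- uptake_ratios(10, 0), "undefined")
  expect_true(is.na(r0$cn_uptake))
})

test_that("N2-fixation adjustment integrates the volumetric rate", {
  expect_equal(n2_fixation_adjustment(3.51, 3.60, 25), 3.60)
  expect_equal(n2_fixation_adjustment(0, 3.60, 25), 0.09)
  expect_equal(n2_fixation_adjustment(3.51, 0, 25), 3.51)
  expect_error(n2_fixation_adjustment(3.51, -1, 25), "non-negative")
})

test_that("ncp_summary recovers a prescribed drawdown table", {
  spec <- cruise_spec(seed = 3, noise = 0, true_cn = 10)
  out <- ncp_summary(normalize_bottles(simulate_bottles(spec)))
  expect_equal(nrow(out), 2)
  expect_equal(out$cn_uptake, c(10, 10), tolerance = 1e-10)
  expect_equal(out$cp_uptake, c(160, 160), tolerance = 1e-10)
  # CaCO3 diagnostic is ~0 when the generator adds no carbonate signal
  expect_equal(out$caco3_term, c(0, 0), tolerance = 1e-9)
})
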