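quiet_forcing <- function(days = 150:160, sst = 0, ta = 2205,
                          u10_sq = 0, ice = 0, ncp_n = 0) {
  n <- length(days)
  tibble::tibble(day = days, sst = rep_len(sst, n), sss = 32,
                 ta = rep_len(ta, n), u10_sq = rep_len(u10_sq, n),
                 ice_pct = rep_len(ice, n), psl = 1, xco2 = 400,
                 ncp_n = rep_len(ncp_n, n))
}

test_that("no forcing leaves DIC constant; SST alone moves pCO2", {
  sc <- box_scenario("southern", 6.6, t_start = 150, t_end = 160)
  run <- run_box_model(quiet_forcing(), sc, init_dic = 2068)
  expect_equal(diff(run$trajectory$dic), rep(0, 10))
  warm <- quiet_forcing(sst = seq(0, 5, length.out = 11))
  run_w <- run_box_model(warm, sc, init_dic = 2068)
  expect_equal(diff(run_w$trajectory$dic), rep(0, 10))
  expect_true(all(diff(run_w$trajectory$pco2) > 0))
})

test_that("biological and dilution step terms match closed-form values", {
  sc <- box_scenario("southern", 6.6, t_start = 150, t_end = 151)
  f <- quiet_forcing(150:151, ncp_n = 1)
  run <- run_box_model(f, sc, init_dic = 2068)
  rho <- sw_density(0, 32)
  expect_equal(run$terms$d_ncp, -6.6 / (25 * rho) * 1000)
  expect_equal(run$terms$d_ncp, -0.2576, tolerance = 2e-3)
  # 1% TA drop dilutes DIC by 1%
  f2 <- quiet_forcing(150:151, ta = c(2000, 1980))
  run2 <- run_box_model(f2, sc, init_dic = 2000)
  expect_equal(run2$terms$d_dil, -20)
})

test_that("DIC budget closes to 1e-9 umol/kg and uptake integrates flux", {
  spec <- cruise_spec(seed = 17)
  f <- make_box_forcing(spec, "northern")
  run <- run_box_model(f, box_scenario("northern", 12.1), init_dic = 2153)
  g <- glance(run)
  expect_lt(abs(g$budget_residual), 1e-9)
  tr <- tidy(run)
  expect_equal(dplyr::last(tr$cum_uptake), -sum(tr$flux))
  # pCO2 stays consistent with (TA, DIC) through the solver at every day
  i <- c(1, 25, nrow(tr))
  expect_equal(tr$pco2[i],
               pco2_from_ta_dic(tr$ta[i], tr$dic[i], tr$sst[i], tr$sss[i]),
               tolerance = 1e-8)
})

test_that("cumulative uptake is non-decreasing in the C:N ratio", {
  spec <- cruise_spec(seed = 23)
  f <- make_box_forcing(spec, "southern")
  ups <- sapply(c(6.6, 9, 10.9, 12.1), function(cn)
    cumulative_uptake(run_box_model(f, box_scenario("southern", cn),
                                    init_dic = 2068)))
  expect_true(all(diff(ups) > 0))
})

test_that("operator ordering within a daily step is negligible", {
  spec <- cruise_spec(seed = 29)
  f <- make_box_forcing(spec, "southern")
  sc <- box_scenario("southern", 10.9)
  a <- run_box_model(f, sc, init_dic = 2068, order = "flux_first")
  b <- run_box_model(f, sc, init_dic = 2068, order = "ncp_first")
  expect_lt(max(abs(a$trajectory$dic - b$trajectory$dic)), 0.5)
})

test_that("scenario comparison arithmetic and forcing guard", {
  cmp <- scenario_compare(751, 528)
  expect_equal(cmp$enhancement_pct, 42.2, tolerance = 0.01)
  expect_equal(cmp$flexibility_share_pct, 29.7, tolerance = 0.01)
  cmp2 <- scenario_compare(343, 185)
  expect_equal(cmp2$enhancement_pct, 85.4, tolerance = 0.01)
  expect_equal(cmp2$flexibility_share_pct, 46.1, tolerance = 0.01)
  expect_equal(scenario_compare(100, 100)$enhancement_pct, 0)
  expect_equal(scenario_compare(100, 100)$flexibility_share_pct, 0)

  spec <- cruise_spec(seed = 31)
  f1 <- make_box_forcing(spec, "southern")
  f2 <- make_box_forcing(spec, "northern")
  r1 <- run_box_model(f1, box_scenario("southern", 10.9), init_dic = 2068)
  r2 <- run_box_model(f2, box_scenario("northern", 6.6), init_dic = 2153)
  expect_error(compare_scenarios(r1, r2), "identical forcing")
})

test_that("missing forcing days abort with their listing", {
  sc <- box_scenario("southern", 6.6, t_start = 150, t_end = 160)
  f <- quiet_forcing()[-3, ]
  expect_error(run_box_model(f, sc, init_dic = 2068), "missing days: 152")
})
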