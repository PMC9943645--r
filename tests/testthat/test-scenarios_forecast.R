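test_that("scenario rainfall sampling respects support and mixture weights", {
  rain <- make_rainfall(15, seed = 3)
  set.seed(1)
  base <- sample_rainfall(rain, scenario_spec("baseline"), 500)
  expect_true(all(base %in% rain$values))

  all_dry <- sample_rainfall(rain, scenario_spec("climate_change", p_below = 1),
                             500)
  expect_true(all(all_dry < rain$mean))

  mix <- sample_rainfall(rain, scenario_spec("climate_change", p_below = 0.8),
                         10000)
  frac <- mean(mix < rain$mean)
  se <- sqrt(0.8 * 0.2 / 10000)
  # small slack: some above-subset values could coincide below the mean
  expect_lt(abs(frac - 0.8), 3 * se + 1e-6)

  const <- suppressWarnings(make_rainfall(5, sd = 0, seed = 1))
  expect_error(sample_rainfall(const, scenario_spec("baseline"), 5),
               "degenerate")
})

test_that("zero-horizon scenarios return the initial abundances", {
  fx <- fix_small_sim(seed = 51, n_species = 2, n_plots = 3, n_years = 8)
  init <- array(5, dim = c(3, 2, 3))
  res <- run_scenario(fx$truth, init, scenario_spec("baseline", horizon = 0,
                                                    n_runs = 3),
                      fx$topo, fx$sim$truth$std, fx$sim$data$rainfall,
                      data = fx$sim$data)
  expect_equal(unname(res$mean_adults), matrix(5, 3, 2))
})

test_that("severed interspecific coupling: dynamic equals no-dynamic exactly", {
  # no interspecific slopes anywhere: the ablation resamples a covariate
  # that never enters the rates, so equal seeds give identical trajectories
  truth <- lapply(1:2, function(i) {
    species_params(c(0.8, 0.3, -0.5, 0), c(1.5, 0.4, -0.8, 0),
                   tau = 0.2, gamma = 0.3, rho = 2,
                   name = sprintf("sp%02d", i))
  })
  topo <- default_topology(4)
  sim <- simulate_community(truth, topo, n_years = 8,
                            rainfall = make_rainfall(8, seed = 6), seed = 7)
  init <- array(8, dim = c(4, 2, 3))
  for (kind in c("baseline", "climate_change")) {
    dyn <- run_scenario(truth, init,
                        scenario_spec(kind, horizon = 15, n_runs = 5, seed = 9),
                        topo, sim$truth$std, sim$data$rainfall, data = sim$data)
    nod <- run_scenario(truth, init,
                        scenario_spec(kind, horizon = 15, n_runs = 5, seed = 9,
                                      dynamic_interspecific = FALSE),
                        topo, sim$truth$std, sim$data$rainfall, data = sim$data)
    expect_identical(dyn$mean_adults, nod$mean_adults)
  }
})

test_that("zero rain slopes make climate and baseline scenarios identical", {
  truth <- lapply(1:2, function(i) {
    species_params(c(0.8, 0, -0.5, 0.2), c(1.5, 0, -0.8, -0.2),
                   tau = 0.2, gamma = 0.3, rho = 2,
                   name = sprintf("sp%02d", i))
  })
  topo <- default_topology(4)
  sim <- simulate_community(truth, topo, n_years = 8,
                            rainfall = make_rainfall(8, seed = 8), seed = 9)
  init <- array(8, dim = c(4, 2, 3))
  a <- run_scenario(truth, init,
                    scenario_spec("baseline", horizon = 12, n_runs = 4, seed = 2),
                    topo, sim$truth$std, sim$data$rainfall)
  b <- run_scenario(truth, init,
                    scenario_spec("climate_change", horizon = 12, n_runs = 4,
                                  seed = 2),
                    topo, sim$truth$std, sim$data$rainfall)
  expect_identical(a$mean_adults, b$mean_adults)
})

test_that("scenario comparison arithmetic and design guards", {
  fx <- fix_small_sim(seed = 53, n_species = 2, n_plots = 3, n_years = 8)
  init <- array(6, dim = c(3, 2, 3))
  spec <- scenario_spec("baseline", horizon = 5, n_runs = 3, seed = 4)
  res <- run_scenario(fx$truth, init, spec, fx$topo, fx$sim$truth$std,
                      fx$sim$data$rainfall)
  same <- compare_scenarios(res, res)
  expect_true(all(same$delta == 0))

  shifted <- res
  shifted$mean_adults <- res$mean_adults + 1
  plus <- compare_scenarios(shifted, res)
  expect_true(all(abs(plus$delta - 1) < 1e-12))
  expect_equal(plus$summary$median, rep(1, 2), tolerance = 1e-12)

  small <- res
  small$mean_adults <- res$mean_adults[1:2, ]
  expect_error(compare_scenarios(small, res), "do not match")
})

test_that("forecast metrics: exact identities and the frozen 5-point example", {
  x <- c(3, 7, 1, 9, 4)
  ev <- evaluate_forecast(x, x)
  expect_identical(ev$mse, 0)
  expect_equal(ev$r, 1)

  ev <- evaluate_forecast(x + 2.5, x)
  expect_equal(ev$mse, 2.5^2)
  expect_equal(ev$r, 1)

  ev <- evaluate_forecast(c(2, 4, 3, 8, 7), c(1, 5, 2, 9, 6))
  expect_equal(ev$mse, 1, tolerance = 1e-12)
  expect_equal(ev$r, 0.950979330328515, tolerance = 1e-12)
  expect_equal(ev$r_ci, c(0.426833653901068, 0.996861704795850),
               tolerance = 1e-12)
  expect_equal(ev$n, 5)

  expect_true(is.na(evaluate_forecast(rep(2, 4), x[1:4])$r))
  expect_error(evaluate_forecast(1:2, 2:3), "3 paired points")
})

test_that("zero-step forecasts reproduce the observations exactly", {
  fx <- fix_small_sim(seed = 55, n_species = 2, n_plots = 4, n_years = 8)
  rep0 <- forecast_holdout(fx$sim$data, fx$truth, 2012, 2012, n_draws = 10,
                           seed = 2)
  sa <- rep0$cells[rep0$cells$stage %in% c("S", "A"), ]
  expect_equal(sa$predicted, sa$observed)
  m <- rep0$metrics[rep0$metrics$stage == "A", ]
  expect_equal(m$mse, 0)
  expect_equal(m$r, 1)
})

test_that("hold-out forecasts from the generating truth are calibrated", {
  fx <- fix_small_sim(seed = 57, n_species = 3, n_plots = 6, n_years = 10)
  rep <- forecast_holdout(fx$sim$data, fx$truth, 2007, 2016, n_draws = 300,
                          seed = 3)
  sa <- rep$cells[rep$cells$stage %in% c("S", "A"), ]
  coverage <- mean(sa$observed >= sa$q2.5 & sa$observed <= sa$q97.5)
  expect_gt(coverage, 0.85)
  expect_true(all(sa$q2.5 <= sa$q97.5))
  expect_equal(nrow(sa), 6 * 3 * 2)
})

test_that("forecasting from posterior draws produces a full report", {
  ref <- reference_fit()
  rep <- forecast_holdout(ref$fx$sim$data, ref$fit, 2007, 2021, n_draws = 150,
                          seed = 5)
  expect_s3_class(rep, "forecast_report")
  expect_equal(rep$n_draws, 150)
  m <- rep$metrics[rep$metrics$stage == "A", ]
  expect_gt(m$r, 0.5)
  expect_true(m$n == 10 * 3)
})
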