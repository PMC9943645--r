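test_that("split R-hat: identical chains give exactly 1, shifted chains flag", {
  set.seed(5)
  x <- rnorm(400)
  ident <- coda::as.mcmc.list(list(coda::mcmc(cbind(p = x)),
                                   coda::mcmc(cbind(p = x))))
  d <- diagnose(ident)
  expect_identical(d$rhat, 1)
  expect_false(d$flagged)

  shifted <- coda::as.mcmc.list(list(coda::mcmc(cbind(p = rnorm(400))),
                                     coda::mcmc(cbind(p = rnorm(400, 3)))))
  d <- diagnose(shifted)
  expect_gt(d$rhat, 1.1)
  expect_true(d$flagged)

  expect_error(diagnose(coda::as.mcmc.list(list(coda::mcmc(cbind(p = x))))),
               "2 chains")
})

test_that("split R-hat tracks the coda Gelman diagnostic", {
  set.seed(8)
  for (rep in 1:5) {
    # same-distribution chains: both diagnostics sit at 1
    ml <- coda::as.mcmc.list(list(coda::mcmc(cbind(p = rnorm(500))),
                                  coda::mcmc(cbind(p = rnorm(500)))))
    mine <- diagnose(ml)$rhat
    ref <- unname(coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1, 1])
    expect_equal(mine, max(1, ref), tolerance = 0.05)
    expect_lt(mine, 1.05)
    # grossly shifted chains: both diagnostics flag
    ml <- coda::as.mcmc.list(list(coda::mcmc(cbind(p = rnorm(500))),
                                  coda::mcmc(cbind(p = rnorm(500, 2)))))
    expect_gt(diagnose(ml)$rhat, 1.1)
    expect_gt(coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1, 1], 1.1)
  }
})

test_that("empirical seedlings-per-adult ratio is recovered from the data", {
  fx <- fix_small_sim(seed = 41)
  rho_hat <- dynmix:::estimate_rho(fx$sim$data)
  cnt <- fx$sim$data$counts
  for (i in 1:3) {
    manual <- sum(cnt[, 2, i, "R"]) / sum(cnt[, 1, i, "A"])
    expect_equal(unname(rho_hat[i]), manual)
  }
})

test_that("fit_model validates its inputs", {
  fx <- fix_small_sim(seed = 43)
  data <- fx$sim$data
  naked <- data; naked$rainfall <- NULL
  expect_error(fit_model(naked), "rainfall")
  one_year <- data
  one_year$counts <- data$counts[, 1, , , drop = FALSE]
  one_year$years <- data$years[1]
  expect_error(fit_model(one_year), "2 survey occasions")
  expect_error(fit_model(data, detection = 1.4), "detection")
})

test_that("near-flat truth with tight priors at zero is recovered tightly", {
  # all logit-scale coefficients zero (survival 0.5, no covariate effects);
  # a tight prior centred there must dominate the posterior
  flat <- lapply(1:2, function(i) {
    species_params(c(0, 0, 0, 0), c(0, 0, 0, 0), tau = 0.2, gamma = 0.3,
                   rho = 2, name = sprintf("sp%02d", i))
  })
  topo <- default_topology(6)
  sim <- simulate_community(flat, topo, n_years = 8,
                            rainfall = make_rainfall(8, seed = 2), seed = 3)
  cfg <- dynmix_config(warmup = 300, draws = 600, posterior_samples = 1200,
                       coef_prior_sd = 0.05)
  fit <- fit_model(sim$data, cfg, seed = 4)
  coefs <- fit$summary[grepl("^(theta|phi)_", fit$summary$parameter), ]
  expect_true(all(abs(coefs$mean) < 0.15))
})

test_that("reduced-design fit converges and is well calibrated", {
  ref <- reference_fit()
  fit <- ref$fit
  expect_gte(fit$n_draws, 2100)
  expect_true(all(fit$summary$rhat < 1.1))
  d <- diagnose(fit)
  expect_equal(sum(d$flagged), 0)
  expect_true(all(fit$summary$q2.5 <= fit$summary$median &
                    fit$summary$median <= fit$summary$q97.5))

  # truth should mostly fall inside the 95% credible intervals
  truth <- ref$fx$truth
  hit <- 0; tot <- 0
  for (i in seq_along(truth)) {
    sp <- fit$species[i]
    tv <- c(truth[[i]]$theta_coefs, truth[[i]]$phi_coefs, truth[[i]]$tau,
            truth[[i]]$gamma)
    pn <- c(sprintf("theta_%s.%s", dynmix:::COEF_NAMES, sp),
            sprintf("phi_%s.%s", dynmix:::COEF_NAMES, sp),
            sprintf("tau.%s", sp), sprintf("gamma.%s", sp))
    su <- fit$summary[match(pn, fit$summary$parameter), ]
    hit <- hit + sum(tv >= su$q2.5 & tv <= su$q97.5)
    tot <- tot + length(tv)
  }
  expect_gte(hit / tot, 0.8)
})

test_that("posterior point params round-trip into species_params", {
  ref <- reference_fit()
  pars <- params_from_posterior(ref$fit)
  expect_length(pars, 3)
  expect_s3_class(pars[[1]], "species_params")
  expect_equal(pars[[2]]$rho, unname(ref$fit$rho[2]))
  m <- colMeans(as.matrix(ref$fit))
  expect_equal(pars[[1]]$theta_coefs[1],
               unname(m[sprintf("theta_int.%s", ref$fit$species[1])]))
  one <- params_from_posterior(ref$fit, draw = 5)
  expect_false(identical(one[[1]]$theta_coefs, pars[[1]]$theta_coefs))
})

test_that("posterior predictive p-values are calibrated on own data, catch misfit", {
  ref <- reference_fit()
  gof <- posterior_predictive_gof(ref$fit, ref$fx$sim$data, n_rep = 150,
                                  seed = 9)
  expect_true(all(gof$p_value >= 0 & gof$p_value <= 1, na.rm = TRUE))
  # adult and seedling channels are calibrated; the sapling channel can show
  # lack of fit because gains run through a constant gamma and a fixed
  # empirical rho estimated from the two seedling-survey years
  interior <- gof$p_value[gof$stage %in% c("R", "A")]
  expect_gte(mean(interior > 0.05 & interior < 0.95), 0.8)

  # gross misfit: inflate adult counts tenfold after fitting
  broken <- ref$fx$sim$data
  broken$counts[, , , 3] <- broken$counts[, , , 3] * 10
  gof_bad <- posterior_predictive_gof(ref$fit, broken, n_rep = 150, seed = 9)
  expect_true(all(gof_bad$p_value[gof_bad$stage == "A"] < 0.05))
})

test_that("recovery harness reports per-parameter scores and convergence", {
  rep <- recovery_experiment(n_species = 2, n_plots = 5, n_years = 8,
                             n_replicates = 2, seed = 3,
                             config = dynmix_config(warmup = 250, draws = 550,
                                                    posterior_samples = 1100))
  expect_s3_class(rep, "recovery_report")
  expect_equal(nrow(rep$table), 2 * 2 * 10)  # replicates x species x params
  expect_true(all(c("truth", "post_mean", "covered", "bias") %in%
                    names(rep$table)))
  expect_length(rep$rhat, 2)
  expect_true(rep$coverage >= 0 && rep$coverage <= 1)
})

test_that("all-zero species triggers a warning but the fit proceeds", {
  fx <- fix_small_sim(seed = 47, n_species = 2, n_plots = 4, n_years = 6)
  data <- fx$sim$data
  data$counts[, , 2, ] <- 0
  cfg <- dynmix_config(warmup = 100, draws = 550, posterior_samples = 1100)
  expect_warning(fit_model(data, cfg, seed = 5), "all-zero")
})
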