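# Shared fixtures: small parameter sets, a reference standardization, and a
# cached reduced-design fit reused by the slower inference tests.

fix_std <- function() {
  standardization(rain_mean = 500, rain_sd = 120,
                  intra_mean = 10, intra_sd = 5,
                  inter_mean = 10, inter_sd = 5)
}

# single species with density-dependent adult survival and positive growth
# at low density: has an interior single-plot equilibrium
fix_solo_species <- function() {
  species_params(theta_coefs = c(1.2, 0, 0, 0),
                 phi_coefs = c(2.5, 0, -1.5, 0),
                 tau = 0.3, gamma = 0.4, rho = 2, name = "solo")
}

fix_small_sim <- function(seed = 3, n_species = 3, n_plots = 6, n_years = 12) {
  truth <- make_truth(n_species, 0.3, seed = seed)
  topo <- default_topology(n_plots)
  sim <- simulate_community(truth, topo, n_years = n_years,
                            rainfall = make_rainfall(n_years, seed = seed + 1),
                            seed = seed + 2)
  list(truth = truth, topo = topo, sim = sim)
}

# one reduced-design fit shared across inference tests (computed on demand)
.fit_cache <- new.env(parent = emptyenv())
reference_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    fx <- fix_small_sim(seed = 21, n_species = 3, n_plots = 10, n_years = 15)
    cfg <- dynmix_config(warmup = 1500, draws = 1500, posterior_samples = 3000)
    .fit_cache$fx <- fx
    .fit_cache$fit <- fit_model(fx$sim$data, cfg, seed = 22)
  }
  list(fit = .fit_cache$fit, fx = .fit_cache$fx)
}

rand_rates <- function(P, K) {
  list(theta = matrix(runif(P * K), P, K), phi = matrix(runif(P * K), P, K),
       tau = runif(K), gamma = runif(K), rho = runif(K, 0, 4))
}

rand_topology <- function(P, retention = NULL) {
  plots <- sprintf("q%02d", seq_len(P))
  pairs <- t(combn(plots, 2))
  keep <- runif(nrow(pairs)) < 0.4
  dispersal_topology(plots, if (any(keep)) pairs[keep, , drop = FALSE] else NULL,
                     retention = retention %||% runif(1, 0.5, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

logit <- function(p) log(p / (1 - p))
invlogit <- function(x) 1 / (1 + exp(-x))
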