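# Generator for multi-species stage-structured count data with known
# ground-truth parameters. The default design mirrors the Mediterranean
# shrub-community study the model family was developed for: 5 species, 18
# 5x5 m plots, 8 consecutive annual survey occasions, three stages
# (seedlings R, saplings S, adults A), rainfall- and density-driven survival,
# and seedling counts observed in only 2 of the survey years.

#' Draw ground-truth species parameters
#'
#' Intercepts are drawn so baseline survivals fall in \[0.3, 0.95\]; slopes
#' are Normal(0, `effect_scale`). Species 1 is forced to carry a positive
#' interspecific effect on sapling survival and a negative one on adult
#' survival, mirroring the facilitation/competition mix typical of shrub
#' neighbourhoods.
#'
#' @param n_species Number of species (>= 1).
#' @param effect_scale SD of the covariate slopes on the logit scale
#'   (0 gives slopes exactly zero).
#' @param seed RNG seed.
#' @return List of [species_params] of length `n_species`.
#' @export
make_truth <- function(n_species, effect_scale = 0.3, seed = 1L) {
  if (n_species < 1) stopf("n_species must be >= 1")
  if (effect_scale < 0) stopf("effect_scale must be non-negative")
  set.seed(seed)
  lapply(seq_len(n_species), function(i) {
    th <- c(logit(runif(1, 0.3, 0.95)), rnorm(3, 0, effect_scale))
    ph <- c(logit(runif(1, 0.3, 0.95)), rnorm(3, 0, effect_scale))
    if (i == 1L) {
      th[4] <- abs(th[4])   # facilitation of juveniles by neighbours
      ph[4] <- -abs(ph[4])  # competition on adults
    }
    species_params(theta_coefs = th, phi_coefs = ph,
                   tau = runif(1, 0.1, 0.4), gamma = runif(1, 0.1, 0.5),
                   rho = runif(1, 1, 4), name = sprintf("sp%02d", i))
  })
}

#' Draw an i.i.d. annual rainfall series
#'
#' @param n_years Series length.
#' @param mean,sd Normal draw parameters (natural scale; `sd = 0` gives a
#'   constant series).
#' @param seed RNG seed.
#' @param start_year First survey year.
#' @return A [rainfall_series] (its `below` field marks below-average years).
#' @export
make_rainfall <- function(n_years, mean = 500, sd = 120, seed = 1L,
                          start_year = 2007L) {
  if (sd < 0) stopf("sd must be non-negative")
  set.seed(seed)
  vals <- rnorm(n_years, mean, sd)
  suppressWarnings(rainfall_series(start_year + seq_len(n_years) - 1L, vals))
}

# Generator-wide density-standardization constants: chosen once from the
# initial-abundance scale, not refit to each realization.
generator_standardization <- function(rain, n_species, init_adults = 10) {
  standardization(rain_mean = rain$mean,
                  rain_sd = if (is.na(rain$sd)) 1 else rain$sd,
                  intra_mean = init_adults, intra_sd = init_adults / 2,
                  inter_mean = init_adults * max(1L, n_species - 1L),
                  inter_sd = (init_adults / 2) * max(1L, n_species - 1L))
}

#' Simulate a multi-species community and its observed counts
#'
#' Iterates the stochastic process kernel ([step_stochastic]) over the survey
#' window and emits both the observed counts (optionally thinned by binomial
#' detection) and the latent truth.
#'
#' @param params List of [species_params] (the ground truth).
#' @param topology A [dispersal_topology]; its plot list fixes the number of
#'   plots.
#' @param n_years Number of consecutive annual survey occasions.
#' @param rainfall A [rainfall_series] covering `n_years` (generated with
#'   [make_rainfall] when `NULL`).
#' @param init Per-plot, per-species initial abundances c(R, S, A).
#' @param detection_on When `TRUE`, counts are Binomial(N, p) thinned with
#'   each species' detection probabilities; otherwise counts equal latent
#'   abundances.
#' @param r_observed_years Which survey occasions carry seedling (R) counts;
#'   default the first two, emulating sparse recruitment data. Use
#'   `seq_len(n_years)` for complete seedling observation.
#' @param seed RNG seed.
#' @param std Optional [standardization]; defaults to generator-wide
#'   constants.
#' @param cap Total-abundance explosion guard.
#' @return List with `data` (a [count_dataset]) and `truth` (a
#'   `"latent_trajectory"`: array `N` of true abundances plus realized
#'   theta/phi).
#' @export
simulate_community <- function(params, topology, n_years = 8L, rainfall = NULL,
                               init = c(R = 10, S = 5, A = 10),
                               detection_on = FALSE,
                               r_observed_years = 1:2, seed = 1L,
                               std = NULL, cap = 1e7) {
  K <- length(params)
  P <- length(topology$plots)
  if (is.null(rainfall)) rainfall <- make_rainfall(n_years, seed = seed + 1L)
  if (length(rainfall$years) < n_years) stopf("rainfall does not cover n_years")
  if (any(init < 0)) stopf("init must be non-negative")
  if (is.null(std)) std <- generator_standardization(rainfall, K, init[["A"]])
  set.seed(seed)
  D <- build_dispersal_matrix(topology)
  N <- array(NA_real_, dim = c(P, n_years, K, 3L),
             dimnames = list(topology$plots, rainfall$years[seq_len(n_years)],
                             vapply(params, function(p) p$name %||% "sp", ""),
                             STAGES))
  theta_r <- phi_r <- array(NA_real_, dim = c(P, n_years - 1L, K))
  state <- aperm(array(init[STAGES], dim = c(3L, P, K)), c(2, 3, 1))
  N[, 1L, , ] <- state
  for (t in seq_len(n_years - 1L)) {
    rates <- community_rates(params, state, rainfall$values[t], std)
    theta_r[, t, ] <- rates$theta
    phi_r[, t, ] <- rates$phi
    state <- step_stochastic(state, rates, D)
    if (sum(state) > cap) {
      stopf("population exploded beyond cap %g at year %d; weaken rho or gamma",
            cap, t + 1L)
    }
    N[, t + 1L, , ] <- state
  }
  counts <- N
  if (detection_on) {
    for (i in seq_len(K)) for (s in 1:3) {
      p <- params[[i]]$detection[s]
      v <- N[, , i, s]
      counts[, , i, s] <- rbinom(length(v), as.integer(v), p)
    }
  }
  counts[, setdiff(seq_len(n_years), r_observed_years), , 1L] <- NA_real_
  data <- count_dataset(counts, rainfall = rainfall, topology = topology,
                        std = std)
  truth <- structure(list(N = N, theta = theta_r, phi = phi_r,
                          params = params, std = std),
                     class = "latent_trajectory")
  list(data = data, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a generated dataset (and its truth) to disk
#'
#' Emits counts.csv, rainfall.csv, topology.csv and truth.json under `dir`.
#'
#' @param sim Output of [simulate_community].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$data, file.path(dir, "counts.csv"))
  write_rainfall(sim$data$rainfall, file.path(dir, "rainfall.csv"))
  write_topology(sim$data$topology, file.path(dir, "topology.csv"))
  pars <- lapply(sim$truth$params, function(p) {
    list(name = p$name, theta_coefs = p$theta_coefs, phi_coefs = p$phi_coefs,
         tau = p$tau, gamma = p$gamma, rho = p$rho,
         detection = as.list(p$detection))
  })
  std <- sim$truth$std
  jsonlite::write_json(list(species = pars, standardization = unclass(std)),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Default plot topology of the emulated study design
#'
#' @param n_plots Number of plots (default 18).
#' @param retention Natal-plot seed retention.
#' @param layout `"line"` chains the plots; `"isolated"` declares no edges.
#' @return A [dispersal_topology].
#' @export
default_topology <- function(n_plots = 18L, retention = 0.9,
                             layout = c("line", "isolated")) {
  layout <- match.arg(layout)
  plots <- sprintf("p%02d", seq_len(n_plots))
  edges <- if (layout == "line" && n_plots > 1L) {
    cbind(plots[-n_plots], plots[-1L])
  } else NULL
  dispersal_topology(plots, edges, retention)
}
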