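# Climate-scenario projections (baseline resampling of the observed rainfall
# series vs. a drier future oversampling below-average years), the
# fully-dynamic vs. no-dynamic interspecific-density ablation, hold-out
# forecasting from posterior draws, and forecast-skill metrics.

#' Scenario specification
#'
#' @param kind `"baseline"` (resample all observed rainfall values) or
#'   `"climate_change"` (draw a below-average year with probability
#'   `p_below`).
#' @param p_below Probability of drawing from the below-average subset
#'   (ignored by the baseline scenario).
#' @param horizon Projection length in years.
#' @param n_runs Number of stochastic simulation runs.
#' @param dynamic_interspecific Propagate interspecific densities from the
#'   projected community (`TRUE`) or resample them from historical
#'   observations (`FALSE`, the "no-dynamic" ablation).
#' @param seed RNG seed.
#' @return An object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(kind = c("baseline", "climate_change"),
                          p_below = 0.8, horizon = 50L, n_runs = 100L,
                          dynamic_interspecific = TRUE, seed = 1L) {
  kind <- match.arg(kind)
  if (p_below < 0 || p_below > 1) stopf("p_below must lie in [0, 1]")
  if (horizon < 0 || n_runs < 1) stopf("horizon must be >= 0 and n_runs >= 1")
  structure(list(kind = kind, p_below = p_below, horizon = as.integer(horizon),
                 n_runs = as.integer(n_runs),
                 dynamic_interspecific = isTRUE(dynamic_interspecific),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Resample a rainfall sequence under a scenario
#'
#' Baseline draws uniformly with replacement from all observed values; the
#' climate-change scenario draws, at each step, from the below-average subset
#' with probability `p_below` and from the remaining values otherwise.
#' "Below average" is relative to the stored mean of the observed series.
#'
#' @param observed A [rainfall_series].
#' @param spec A [scenario_spec].
#' @param n Sequence length.
#' @return Numeric rainfall sequence of length `n` (natural scale).
#' @export
sample_rainfall <- function(observed, spec, n) {
  vals <- unname(observed$values)
  if (length(unique(vals)) < 2L) stopf("observed rainfall series is degenerate")
  if (spec$kind == "baseline") {
    return(vals[sample.int(length(vals), n, replace = TRUE)])
  }
  below <- vals[observed$below]
  above <- vals[!observed$below]
  if (length(below) == 0L) stopf("no below-average rainfall values to sample")
  use_below <- runif(n) < spec$p_below
  out <- numeric(n)
  out[use_below] <- below[sample.int(length(below), sum(use_below), replace = TRUE)]
  out[!use_below] <- above[sample.int(length(above), sum(!use_below), replace = TRUE)]
  out
}

# Historical natural-scale interspecific densities per plot/species/year from
# the observed adult counts.
historical_inter <- function(data) {
  P <- length(data$plots); T <- length(data$years); K <- length(data$species)
  A <- array(data$counts[, , , 3L], dim = c(P, T, K))
  tot <- apply(A, c(1, 2), sum)
  inter <- array(NA_real_, dim = c(P, T, K))
  for (i in seq_len(K)) inter[, , i] <- tot - A[, , i]
  inter
}

#' Run a climate/baseline scenario
#'
#' Projects the whole community stochastically `n_runs` times over
#' `horizon` steps under scenario-resampled rainfall, and averages adult
#' abundance over steps and runs. All stochastic drivers (rainfall sequences
#' and, for the no-dynamic ablation, the historical-density resampling
#' indices) are pre-drawn from the scenario seed, so runs with identical
#' community dynamics give identical trajectories across scenario variants.
#'
#' @param params List of [species_params] (truth or posterior means).
#' @param init `P x K x 3` starting abundances.
#' @param spec A [scenario_spec].
#' @param topology A [dispersal_topology].
#' @param std A [standardization].
#' @param observed_rainfall A [rainfall_series] to resample from.
#' @param data Historical [count_dataset]; required when
#'   `spec$dynamic_interspecific` is `FALSE`.
#' @param all_stages Keep per-stage means as well as adults.
#' @return An object of class `"scenario_result"` with `mean_adults`
#'   (`P x K` matrix averaged over steps and runs) and, optionally,
#'   `mean_stages` (`P x K x 3`).
#' @export
run_scenario <- function(params, init, spec, topology, std, observed_rainfall,
                         data = NULL, all_stages = FALSE) {
  P <- dim(init)[1]; K <- dim(init)[2]
  if (!spec$dynamic_interspecific && is.null(data)) {
    stopf("the no-dynamic ablation needs the historical dataset")
  }
  set.seed(spec$seed)
  rain_seqs <- replicate(spec$n_runs,
                         sample_rainfall(observed_rainfall, spec, spec$horizon),
                         simplify = FALSE)
  hist_idx <- NULL
  if (!is.null(data)) {
    T_obs <- length(data$years)
    hist_idx <- array(sample.int(T_obs, spec$n_runs * spec$horizon * P,
                                 replace = TRUE),
                      dim = c(spec$n_runs, spec$horizon, P))
    inter_hist <- historical_inter(data)
  }
  set.seed(spec$seed + 1000003L)
  acc <- array(0, dim = c(P, K, 3L))
  for (run in seq_len(spec$n_runs)) {
    override <- NULL
    if (!spec$dynamic_interspecific) {
      override <- array(NA_real_, dim = c(spec$horizon, P, K))
      for (t in seq_len(spec$horizon)) {
        override[t, , ] <- inter_hist[cbind(rep(seq_len(P), K),
                                            rep(hist_idx[run, t, ], K),
                                            rep(seq_len(K), each = P))]
      }
    }
    traj <- project_community(init, params, rain_seqs[[run]], spec$horizon,
                              topology, std, mode = "stochastic",
                              inter_override = override)
    if (spec$horizon > 0) {
      run_mean <- apply(traj[-1L, , , , drop = FALSE], c(2, 3, 4), mean)
    } else {
      run_mean <- array(traj[1L, , , ], dim = c(P, K, 3L))
    }
    acc <- acc + run_mean
  }
  acc <- acc / spec$n_runs
  dimnames(acc) <- list(topology$plots,
                        vapply(params, function(p) p$name %||% "sp", ""),
                        STAGES)
  structure(list(spec = spec,
                 mean_adults = matrix(acc[, , 3L], P, K,
                                      dimnames = dimnames(acc)[1:2]),
                 mean_stages = if (all_stages) acc else NULL),
            class = "scenario_result")
}

#' Contrast two scenario runs
#'
#' @param climate,baseline `"scenario_result"` objects from the same design.
#' @return Object of class `"scenario_comparison"`: per plot/species
#'   abundance difference (climate minus baseline) and per-species summary
#'   quantiles across plots.
#' @export
compare_scenarios <- function(climate, baseline) {
  a <- as.matrix(climate$mean_adults); b <- as.matrix(baseline$mean_adults)
  if (!identical(dim(a), dim(b))) stopf("scenario designs do not match")
  delta <- a - b
  qs <- t(apply(delta, 2, quantile, c(0.25, 0.5, 0.75)))
  structure(list(delta = delta,
                 summary = data.frame(species = colnames(delta),
                                      q25 = unname(qs[, 1]),
                                      median = unname(qs[, 2]),
                                      q75 = unname(qs[, 3]),
                                      mean = unname(colMeans(delta)),
                                      row.names = NULL)),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("Change in mean adult abundance (climate - baseline), across plots:\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Hold-out forecast from observed start-year abundances
#'
#' Projects every posterior draw (or replicate stochastic runs of fixed
#' parameters) from the observed stage-specific abundances in `start_year` to
#' `target_year` under the observed rainfall, and scores the posterior-mean
#' predictions against the observed target-year counts.
#'
#' @param data A [count_dataset] covering both years.
#' @param posterior A `"posterior_samples"` object (per-draw projection) or a
#'   plain list of [species_params] (fixed parameters, `n_draws` stochastic
#'   replicates).
#' @param start_year,target_year Observed survey years.
#' @param dynamic With `FALSE`, interspecific densities are resampled from
#'   the plot's historical observed values each step (the no-dynamic
#'   ablation).
#' @param pool_years Survey years forming the no-dynamic resampling pool
#'   (default: all observed years). For genuinely held-out evaluation the
#'   pool is the monitoring record and the target year lies beyond it.
#' @param n_draws Number of posterior draws / stochastic replicates.
#' @param seed RNG seed.
#' @return An object of class `"forecast_report"`: per-cell table (plot,
#'   species, stage, observed, predicted, q2.5, q97.5) and per-stage skill
#'   metrics from [evaluate_forecast].
#' @export
forecast_holdout <- function(data, posterior, start_year, target_year,
                             dynamic = TRUE, pool_years = NULL,
                             n_draws = 200L, seed = 1L) {
  if (!start_year %in% data$years || !target_year %in% data$years) {
    stopf("start and target years must be observed survey years")
  }
  n_steps <- target_year - start_year
  if (n_steps < 0) stopf("target_year must not precede start_year")
  P <- length(data$plots); K <- length(data$species)
  t0 <- match(start_year, data$years)
  init <- array(data$counts[, t0, , ], dim = c(P, K, 3L))
  init[is.na(init)] <- 0
  std <- if (inherits(posterior, "posterior_samples")) posterior$std else
    (data$std %||% default_standardization(data))
  rain <- unname(data$rainfall$values[as.character(seq(start_year,
                                                       length.out = max(n_steps, 1)))])
  from_fit <- inherits(posterior, "posterior_samples")
  n_avail <- if (from_fit) posterior$n_draws else Inf
  n_use <- min(n_draws, n_avail)
  set.seed(seed)
  draw_idx <- if (from_fit) sample.int(posterior$n_draws, n_use) else seq_len(n_use)
  inter_hist <- historical_inter(data)
  pool_idx <- if (is.null(pool_years)) seq_along(data$years) else
    match(intersect(pool_years, data$years), data$years)
  if (length(pool_idx) == 0L) stopf("pool_years share no years with the data")
  inter_hist <- inter_hist[, pool_idx, , drop = FALSE]
  T_obs <- length(pool_idx)
  preds <- array(NA_real_, dim = c(n_use, P, K, 3L))
  for (d in seq_len(n_use)) {
    pars <- if (from_fit) params_from_posterior(posterior, draw_idx[d]) else posterior
    override <- NULL
    if (!dynamic && n_steps > 0) {
      idx <- matrix(sample.int(T_obs, n_steps * P, replace = TRUE), n_steps, P)
      override <- array(NA_real_, dim = c(n_steps, P, K))
      for (t in seq_len(n_steps)) {
        override[t, , ] <- inter_hist[cbind(rep(seq_len(P), K), rep(idx[t, ], K),
                                            rep(seq_len(K), each = P))]
      }
    }
    traj <- project_community(init, pars, rain, n_steps, data$topology, std,
                              mode = "stochastic", inter_override = override)
    preds[d, , , ] <- traj[n_steps + 1L, , , ]
  }
  obs <- array(data$counts[, match(target_year, data$years), , ],
               dim = c(P, K, 3L))
  pm <- apply(preds, c(2, 3, 4), mean)
  lo <- apply(preds, c(2, 3, 4), quantile, 0.025)
  hi <- apply(preds, c(2, 3, 4), quantile, 0.975)
  cells <- expand.grid(plot = data$plots, species = data$species,
                       stage = STAGES, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  cells$observed <- as.vector(obs)
  cells$predicted <- as.vector(pm)
  cells$q2.5 <- as.vector(lo)
  cells$q97.5 <- as.vector(hi)
  metrics <- do.call(rbind, lapply(STAGES, function(s) {
    cc <- cells[cells$stage == s & !is.na(cells$observed), ]
    if (nrow(cc) < 3L) {
      return(data.frame(stage = s, mse = NA_real_, r = NA_real_,
                        r_lo = NA_real_, r_hi = NA_real_, n = nrow(cc)))
    }
    ev <- evaluate_forecast(cc$predicted, cc$observed)
    data.frame(stage = s, mse = ev$mse, r = ev$r, r_lo = ev$r_ci[1],
               r_hi = ev$r_ci[2], n = ev$n)
  }))
  structure(list(cells = cells, metrics = metrics, dynamic = dynamic,
                 start_year = start_year, target_year = target_year,
                 n_draws = n_use),
            class = "forecast_report")
}

#' @export
print.forecast_report <- function(x, ...) {
  cat(sprintf("Forecast %d -> %d (%s; %d draws)\n", x$start_year,
              x$target_year, if (x$dynamic) "fully dynamic" else "no-dynamic",
              x$n_draws))
  print(x$metrics, digits = 3)
  invisible(x)
}

#' Forecast skill: MSE and Pearson correlation with Fisher-z interval
#'
#' @param predicted,observed Paired numeric vectors (>= 3 points).
#' @return List with `mse`, `r`, `r_ci` (95% Fisher-z confidence interval)
#'   and `n`. `r` is `NA` when either vector has zero variance.
#' @export
evaluate_forecast <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stopf("length mismatch")
  ok <- !is.na(predicted) & !is.na(observed)
  predicted <- predicted[ok]; observed <- observed[ok]
  n <- length(predicted)
  if (n < 3L) stopf("need at least 3 paired points")
  mse <- mean((predicted - observed)^2)
  if (sd(predicted) == 0 || sd(observed) == 0) {
    return(list(mse = mse, r = NA_real_, r_ci = c(NA_real_, NA_real_), n = n))
  }
  r <- cor(predicted, observed)
  z <- atanh(r)
  half <- qnorm(0.975) / sqrt(n - 3)
  list(mse = mse, r = r, r_ci = tanh(c(z - half, z + half)), n = n)
}
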