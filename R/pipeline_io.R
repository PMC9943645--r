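# Readers/writers for the long-format count tables, rainfall series and plot
# topology, plus the run configuration. All files are UTF-8 CSV with a header
# row; counts are long format, one row per (plot, year, species, stage).

#' Plot adjacency and seed retention
#'
#' @param plots Character vector of plot identifiers.
#' @param edges Two-column matrix/data.frame of unordered adjacent plot pairs
#'   (may have zero rows: all plots isolated).
#' @param retention Fraction of seeds germinating in the natal plot, in
#'   (0, 1\].
#' @return An object of class `"dispersal_topology"`.
#' @export
dispersal_topology <- function(plots, edges = NULL, retention = 0.9) {
  plots <- as.character(plots)
  if (anyDuplicated(plots)) stopf("duplicate plot identifiers")
  if (retention <= 0 || retention > 1) stopf("retention must lie in (0, 1]")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stopf("edges must have two columns")
    edges <- matrix(as.character(edges), ncol = 2)
    if (any(edges[, 1] == edges[, 2])) stopf("self-edges are not allowed")
    unknown <- setdiff(unique(as.vector(edges)), plots)
    if (length(unknown)) stopf("unknown plot id in edges: %s",
                               paste(unknown, collapse = ", "))
  }
  structure(list(plots = plots, edges = edges, retention = retention),
            class = "dispersal_topology")
}

topology_adjacency <- function(topology) {
  P <- length(topology$plots)
  adj <- matrix(FALSE, P, P, dimnames = list(topology$plots, topology$plots))
  if (nrow(topology$edges)) {
    ia <- match(topology$edges[, 1], topology$plots)
    ib <- match(topology$edges[, 2], topology$plots)
    adj[cbind(ia, ib)] <- TRUE
    adj[cbind(ib, ia)] <- TRUE
  }
  adj
}

#' Stage-structured multi-species count dataset
#'
#' The central data container: a `P x T x K x 3` array of observed counts
#' (plots, survey years, species, stages R/S/A), with explicit `NA` for
#' unobserved cells (typically seedlings outside the few years they were
#' surveyed), plus the rainfall series, plot topology and the stored
#' covariate-standardization constants.
#'
#' @param counts `P x T x K x 3` integer array with dimnames
#'   (plot, year, species, stage).
#' @param rainfall Optional [rainfall_series] covering all survey years.
#' @param topology Optional [dispersal_topology] over the same plots.
#' @param std Optional [standardization]; computed from the data when `NULL`
#'   and a rainfall series is present.
#' @return An object of class `"count_dataset"`.
#' @export
count_dataset <- function(counts, rainfall = NULL, topology = NULL, std = NULL) {
  dn <- dimnames(counts)
  if (length(dim(counts)) != 4L || is.null(dn)) {
    stopf("counts must be a 4-d named array (plot x year x species x stage)")
  }
  x <- structure(list(counts = counts,
                      plots = dn[[1]], years = as.integer(dn[[2]]),
                      species = dn[[3]],
                      rainfall = rainfall, topology = topology, std = std),
                 class = "count_dataset")
  if (is.null(std) && !is.null(rainfall)) x$std <- default_standardization(x)
  validate_dataset(x)
  x
}

# Standardization constants computed once from the observed data: rainfall
# mean/SD from the series, density constants from the observed adult counts.
default_standardization <- function(data) {
  A <- data$counts[, , , 3L, drop = FALSE]
  K <- length(data$species)
  P <- length(data$plots); T <- length(data$years)
  A <- array(A, dim = c(P, T, K))
  inter <- sapply(seq_len(K), function(i) {
    apply(A, c(1, 2), sum) - A[, , i]
  })
  s_int <- sd(A, na.rm = TRUE); s_e <- sd(inter, na.rm = TRUE)
  standardization(rain_mean = data$rainfall$mean, rain_sd = data$rainfall$sd,
                  intra_mean = mean(A, na.rm = TRUE),
                  intra_sd = if (is.finite(s_int) && s_int > 0) s_int else 1,
                  inter_mean = mean(inter, na.rm = TRUE),
                  inter_sd = if (is.finite(s_e) && s_e > 0) s_e else 1)
}

validate_dataset <- function(x) {
  cnt <- x$counts
  bad <- !is.na(cnt) & (cnt < 0 | abs(cnt - round(cnt)) > 1e-8)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stopf("invalid count at plot %s, year %s, species %s, stage %s: %s",
          x$plots[idx[1]], x$years[idx[2]], x$species[idx[3]],
          STAGES[idx[4]], cnt[matrix(idx, 1)])
  }
  if (!identical(dimnames(cnt)[[4]], STAGES)) {
    stopf("stage dimension must be exactly (R, S, A)")
  }
  sa <- cnt[, , , 2:3, drop = FALSE]
  if (anyNA(sa)) {
    stopf("stages S and A must be observed for every (plot, year, species)")
  }
  if (length(x$years) > 1 && any(diff(x$years) != 1L)) {
    stopf("survey years must be consecutive integers")
  }
  if (!is.null(x$rainfall)) {
    miss <- setdiff(x$years, x$rainfall$years)
    if (length(miss)) stopf("rainfall missing for survey year(s): %s",
                            paste(miss, collapse = ", "))
  }
  if (!is.null(x$topology) && !setequal(x$topology$plots, x$plots)) {
    stopf("topology plots do not match dataset plots")
  }
  invisible(x)
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("Count dataset: %d plots x %d years (%d-%d) x %d species\n",
              length(x$plots), length(x$years), min(x$years), max(x$years),
              length(x$species)))
  r_years <- x$years[apply(!is.na(x$counts[, , , 1L, drop = FALSE]), 2, any)]
  cat("  seedling (R) counts observed in year(s):",
      if (length(r_years)) paste(r_years, collapse = ", ") else "none", "\n")
  cat("  rainfall:", if (is.null(x$rainfall)) "absent" else "attached",
      " topology:", if (is.null(x$topology)) "absent" else "attached", "\n")
  invisible(x)
}

#' Convert a count dataset to / from long format
#'
#' @param x A [count_dataset].
#' @param ... Unused.
#' @return Data frame with columns plot, year, species, stage, count
#'   (explicit `NA` rows mark unobserved cells).
#' @export
as.data.frame.count_dataset <- function(x, ...) {
  d <- expand.grid(plot = x$plots, year = x$years, species = x$species,
                   stage = STAGES, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$count <- as.vector(x$counts)
  d[order(d$plot, d$year, d$species, d$stage), , drop = FALSE]
}

#' Read a long-format count table
#'
#' @param path CSV with columns plot, year, species, stage, count; stage codes
#'   in R/S/A; unobserved cells appear as explicit NA rows.
#' @param rainfall,topology,std Optional components to attach (see
#'   [count_dataset]).
#' @return A validated [count_dataset].
#' @export
read_counts <- function(path, rainfall = NULL, topology = NULL, std = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot", "year", "species", "stage", "count")
  if (!all(need %in% names(d))) {
    stopf("counts file must have columns: %s", paste(need, collapse = ", "))
  }
  bad_stage <- setdiff(unique(d$stage), STAGES)
  if (length(bad_stage)) stopf("unknown stage code(s): %s",
                               paste(bad_stage, collapse = ", "))
  if (!is.numeric(d$count) && !all(is.na(d$count))) {
    stopf("count column must be numeric")
  }
  bad <- !is.na(d$count) & (!is_count(d$count))
  if (any(bad)) {
    stopf("negative or non-integer count in row %d (value %s)",
          which(bad)[1], d$count[which(bad)[1]])
  }
  key <- paste(d$plot, d$year, d$species, d$stage)
  if (anyDuplicated(key)) {
    stopf("duplicate row for (plot, year, species, stage): %s",
          key[anyDuplicated(key)])
  }
  plots <- sort(unique(as.character(d$plot)))
  years <- sort(unique(as.integer(d$year)))
  species <- sort(unique(as.character(d$species)))
  cnt <- array(NA_real_,
               dim = c(length(plots), length(years), length(species), 3L),
               dimnames = list(plots, years, species, STAGES))
  cnt[cbind(match(as.character(d$plot), plots),
            match(as.integer(d$year), years),
            match(as.character(d$species), species),
            match(d$stage, STAGES))] <- d$count
  count_dataset(cnt, rainfall = rainfall, topology = topology, std = std)
}

#' @rdname read_counts
#' @param data A [count_dataset] to write.
#' @export
write_counts <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Annual rainfall series
#'
#' Stores the observed series together with its mean and SD (the constants
#' later used for covariate standardization and for the below-average
#' climate-scenario threshold) and the per-year below-average indicator.
#'
#' @param years Integer survey years.
#' @param values Rainfall per year (natural scale, e.g. mm).
#' @return An object of class `"rainfall_series"`.
#' @export
rainfall_series <- function(years, values) {
  years <- as.integer(years)
  if (length(years) != length(values)) stopf("years and values differ in length")
  if (anyNA(values) || !is.numeric(values)) stopf("rainfall values must be numeric and complete")
  m <- mean(values); s <- sd(values)
  degenerate <- length(values) < 2 || s == 0
  if (degenerate) warnf("rainfall series has zero variance; standardization is impossible")
  structure(list(years = years, values = setNames(as.numeric(values), years),
                 mean = m, sd = if (degenerate) NA_real_ else s,
                 below = values < m, degenerate = degenerate),
            class = "rainfall_series")
}

#' Read an annual rainfall table
#'
#' @param path CSV with columns year, rainfall.
#' @param years Optional vector of years that must all be present.
#' @return A [rainfall_series].
#' @export
read_rainfall <- function(path, years = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "rainfall") %in% names(d))) {
    stopf("rainfall file must have columns year, rainfall")
  }
  if (!is.numeric(d$rainfall) || anyNA(d$rainfall)) {
    stopf("non-numeric or missing rainfall value")
  }
  if (!is.null(years)) {
    miss <- setdiff(years, d$year)
    if (length(miss)) stopf("rainfall missing for year(s): %s",
                            paste(miss, collapse = ", "))
  }
  d <- d[order(d$year), ]
  rainfall_series(d$year, d$rainfall)
}

#' @rdname read_rainfall
#' @param rain A [rainfall_series] to write.
#' @export
write_rainfall <- function(rain, path) {
  utils::write.csv(data.frame(year = rain$years, rainfall = unname(rain$values)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plot adjacency edge list
#'
#' @param path CSV with columns plot_a, plot_b (may be empty apart from the
#'   header: all plots isolated).
#' @param plots Full plot list (isolated plots never appear in the edge list).
#' @param retention Natal-plot seed retention fraction.
#' @return A [dispersal_topology].
#' @export
read_topology <- function(path, plots, retention = 0.9) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c("character", "character"))
  if (!all(c("plot_a", "plot_b") %in% names(d))) {
    stopf("topology file must have columns plot_a, plot_b")
  }
  dispersal_topology(plots, edges = d[, c("plot_a", "plot_b")],
                     retention = retention)
}

#' @rdname read_topology
#' @param topology A [dispersal_topology] to write.
#' @export
write_topology <- function(topology, path) {
  e <- topology$edges
  utils::write.csv(data.frame(plot_a = e[, 1], plot_b = e[, 2]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Gathers the MCMC, prior and scenario settings used across the pipeline.
#' Every pipeline stage derives its randomness from the single root `seed`.
#'
#' @param chains Number of MCMC chains (>= 2).
#' @param warmup Adaptation + burn-in iterations per chain.
#' @param draws Retained iterations per chain.
#' @param posterior_samples Total retained posterior sample target
#'   (`chains * draws` must reach it; default 2100).
#' @param coef_prior_sd Prior SD of the Normal(0, sd) priors on logit-scale
#'   coefficients.
#' @param p_below Climate-scenario probability of sampling a below-average
#'   rainfall year.
#' @param horizon Scenario projection length (years).
#' @param n_runs Scenario simulation runs.
#' @param retention Natal-plot seed retention.
#' @param seed Root RNG seed.
#' @param rhat_threshold Convergence flag threshold.
#' @param tol Numerical tolerance for equilibrium iteration.
#' @return An object of class `"dynmix_config"`.
#' @export
dynmix_config <- function(chains = 2L, warmup = 500L, draws = 1050L,
                          posterior_samples = 2100L, coef_prior_sd = 1.5,
                          p_below = 0.8, horizon = 50L, n_runs = 100L,
                          retention = 0.9, seed = 1L,
                          rhat_threshold = 1.1, tol = 1e-8) {
  if (chains < 2L) stopf("at least 2 chains are required")
  if (chains * draws < posterior_samples) {
    stopf("chains * draws (%d) below requested posterior sample count (%d)",
          chains * draws, posterior_samples)
  }
  if (p_below < 0 || p_below > 1) stopf("p_below must lie in [0, 1]")
  if (horizon < 1 || n_runs < 1) stopf("horizon and n_runs must be >= 1")
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws),
                 posterior_samples = as.integer(posterior_samples),
                 coef_prior_sd = coef_prior_sd, p_below = p_below,
                 horizon = as.integer(horizon), n_runs = as.integer(n_runs),
                 retention = retention, seed = as.integer(seed),
                 rhat_threshold = rhat_threshold, tol = tol),
            class = "dynmix_config")
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose keys match the arguments of [dynmix_config].
#' @return A validated `"dynmix_config"`, with attribute `"md5"` holding the
#'   config-file hash used to tag run logs.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  run <- if (!is.null(raw$run)) raw$run else
    raw[setdiff(names(raw), c("design", "paths"))]
  known <- names(formals(dynmix_config))
  unknown <- setdiff(names(run), known)
  if (length(unknown)) stopf("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  cfg <- do.call(dynmix_config, run)
  attr(cfg, "md5") <- unname(tools::md5sum(path))
  attr(cfg, "design") <- raw$design
  attr(cfg, "paths") <- raw$paths
  cfg
}
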