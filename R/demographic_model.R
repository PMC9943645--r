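# Process model: three-stage life cycle (seedlings R, saplings S, adults A)
# shared by the simulator, the likelihood and the projection engine.
#
# One annual step, per species and plot:
#   survivors_S ~ Binomial(S, theta)      sapling survival
#   movers      ~ Binomial(survivors_S, tau)   transition S -> A
#   gains       ~ Binomial(R, gamma)      seedlings recruiting to saplings
#   survivors_A ~ Binomial(A, phi)        adult survival
#   S' = survivors_S - movers + gains
#   A' = survivors_A + movers
#   R'_j ~ Poisson( sum_j' D[j, j'] * rho * A_{j'} )   seeds from start-of-step adults
#
# theta and phi are logit-linear in standardized rainfall and intra-/inter-
# specific adult densities; tau, gamma, rho are intercept-only per species.

#' Per-species demographic parameters
#'
#' @param theta_coefs Numeric length-4: intercept and slopes (rain, intra,
#'   inter) on the logit scale for sapling survival theta.
#' @param phi_coefs Numeric length-4: same structure for adult survival phi.
#' @param tau Sapling-to-adult transition probability in \[0, 1\].
#' @param gamma Per-seedling probability of recruiting to the sapling stage.
#' @param rho Per-capita seedlings produced per adult (>= 0).
#' @param detection Per-stage detection probability in (0, 1\]; default 1
#'   (complete counts of sessile plants in fixed plots).
#' @param name Optional species code.
#' @return An object of class `"species_params"`.
#' @export
species_params <- function(theta_coefs, phi_coefs, tau, gamma, rho,
                           detection = c(R = 1, S = 1, A = 1), name = NULL) {
  if (length(theta_coefs) != 4L || length(phi_coefs) != 4L) {
    stopf("coefficient vectors must have exactly 4 entries (intercept + 3 slopes)")
  }
  if (tau < 0 || tau > 1 || gamma < 0 || gamma > 1) {
    stopf("tau and gamma must lie in [0, 1]")
  }
  if (rho < 0) stopf("rho must be non-negative")
  detection <- rep_len(detection, 3L)
  if (any(detection <= 0 | detection > 1)) stopf("detection must lie in (0, 1]")
  names(detection) <- STAGES
  structure(list(theta_coefs = as.numeric(theta_coefs),
                 phi_coefs = as.numeric(phi_coefs),
                 tau = tau, gamma = gamma, rho = rho,
                 detection = detection, name = name),
            class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat("Species parameters", if (!is.null(x$name)) paste0("(", x$name, ")"), "\n")
  cat("  theta coefs:", format(x$theta_coefs, digits = 3), "\n")
  cat("  phi coefs:  ", format(x$phi_coefs, digits = 3), "\n")
  cat(sprintf("  tau = %.3f  gamma = %.3f  rho = %.3f\n", x$tau, x$gamma, x$rho))
  invisible(x)
}

#' Covariate frame for the survival models
#'
#' Bundles the natural-scale covariates entering a logit-linear survival model
#' together with the standardization constants used to scale them.
#'
#' @param rain Natural-scale rainfall value(s).
#' @param intra Adult abundance of the focal species in the plot (>= 0).
#' @param inter Summed adult abundance of all heterospecific modelled species.
#' @param std A [standardization] object.
#' @return An object of class `"covariate_frame"`.
#' @export
covariate_frame <- function(rain, intra, inter, std) {
  if (any(intra < 0) || any(inter < 0)) stopf("densities must be non-negative")
  structure(list(rain = rain, intra = intra, inter = inter, std = std),
            class = "covariate_frame")
}

#' Logit-linear survival probability
#'
#' Inverse-logit of `intercept + b_rain * rain_std + b_intra * intra_std +
#' b_inter * inter_std`, with covariates standardized by the constants stored
#' in the covariate frame.
#'
#' @param coefs Numeric length-4 coefficient vector (logit scale).
#' @param cov A [covariate_frame].
#' @return Survival probability in \[0, 1\] (vectorized over the frame).
#' @export
survival_prob <- function(coefs, cov) {
  if (length(coefs) != 4L) stopf("coefs must have exactly 4 entries")
  invlogit(coefs[1] +
             coefs[2] * std_rain(cov$rain, cov$std) +
             coefs[3] * std_intra(cov$intra, cov$std) +
             coefs[4] * std_inter(cov$inter, cov$std))
}

#' Summed heterospecific adult density
#'
#' @param adults Named or unnamed vector of adult abundances per species in a
#'   plot.
#' @param focal Index or name of the focal species.
#' @return Sum of adult abundances over all non-focal species.
#' @export
interspecific_density <- function(adults, focal) {
  if (is.character(focal)) focal <- match(focal, names(adults))
  if (is.na(focal) || focal < 1 || focal > length(adults)) {
    stopf("focal species not found")
  }
  sum(adults[-focal])
}

# Realized rates for the whole community at one time step.
# state: P x K x 3 array (plots x species x stages R,S,A); rain natural scale.
# Returns list(theta = P x K, phi = P x K, tau = K, gamma = K, rho = K).
community_rates <- function(params, state, rain, std) {
  K <- length(params)
  P <- dim(state)[1]
  adults <- state[, , 3L, drop = FALSE]
  dim(adults) <- c(P, K)
  tot <- rowSums(adults)
  theta <- phi <- matrix(NA_real_, P, K)
  r <- std_rain(rain, std)
  for (i in seq_len(K)) {
    intra <- std_intra(adults[, i], std)
    inter <- std_inter(tot - adults[, i], std)
    th <- params[[i]]$theta_coefs
    ph <- params[[i]]$phi_coefs
    theta[, i] <- invlogit(th[1] + th[2] * r + th[3] * intra + th[4] * inter)
    phi[, i] <- invlogit(ph[1] + ph[2] * r + ph[3] * intra + ph[4] * inter)
  }
  list(theta = theta, phi = phi,
       tau = vapply(params, `[[`, numeric(1), "tau"),
       gamma = vapply(params, `[[`, numeric(1), "gamma"),
       rho = vapply(params, `[[`, numeric(1), "rho"))
}

check_rates <- function(rates) {
  pr <- c(rates$theta, rates$phi, rates$tau, rates$gamma)
  if (any(!is.finite(pr)) || any(pr < 0) || any(pr > 1)) {
    stopf("probability rates must lie in [0, 1]")
  }
  if (any(rates$rho < 0)) stopf("rho must be non-negative")
  invisible(TRUE)
}

#' One stochastic step of the community process
#'
#' Applies the binomial survival/transition/gains kernels and Poisson seed
#' production with dispersal to a plot-by-species-by-stage abundance array.
#'
#' @param state Integer array `P x K x 3` (plots, species, stages R/S/A).
#' @param rates List with elements `theta`, `phi` (`P x K` matrices) and
#'   `tau`, `gamma`, `rho` (length-`K` vectors), e.g. from the internal rate
#'   calculator or built by hand.
#' @param dispersal `P x P` column-stochastic dispersal matrix (see
#'   [build_dispersal_matrix]); column j' gives the destination shares of
#'   seeds produced in plot j'.
#' @return Integer array of the same shape: the next state.
#' @export
step_stochastic <- function(state, rates, dispersal) {
  check_rates(rates)
  if (any(state < 0)) stopf("state must be non-negative")
  P <- dim(state)[1]; K <- dim(state)[2]
  R <- state[, , 1L]; S <- state[, , 2L]; A <- state[, , 3L]
  dim(R) <- dim(S) <- dim(A) <- c(P, K)
  tau <- matrix(rates$tau, P, K, byrow = TRUE)
  gam <- matrix(rates$gamma, P, K, byrow = TRUE)
  surv_s <- matrix(rbinom(P * K, as.vector(S), as.vector(rates$theta)), P, K)
  movers <- matrix(rbinom(P * K, as.vector(surv_s), as.vector(tau)), P, K)
  gains <- matrix(rbinom(P * K, as.vector(R), as.vector(gam)), P, K)
  surv_a <- matrix(rbinom(P * K, as.vector(A), as.vector(rates$phi)), P, K)
  seed_mu <- dispersal %*% (A * matrix(rates$rho, P, K, byrow = TRUE))
  out <- array(0L, dim = dim(state), dimnames = dimnames(state))
  out[, , 1L] <- matrix(rpois(P * K, as.vector(seed_mu)), P, K)
  out[, , 2L] <- surv_s - movers + gains
  out[, , 3L] <- surv_a + movers
  out
}

#' Mean-field (expected) step of the community process
#'
#' Replaces every sampling distribution in [step_stochastic] by its
#' expectation; identical algebra otherwise. Used for equilibria and
#' deterministic projection.
#'
#' @inheritParams step_stochastic
#' @param state Non-negative real array `P x K x 3`.
#' @return Real array of the same shape.
#' @export
expected_step <- function(state, rates, dispersal) {
  check_rates(rates)
  if (any(state < 0)) stopf("state must be non-negative")
  P <- dim(state)[1]; K <- dim(state)[2]
  R <- state[, , 1L]; S <- state[, , 2L]; A <- state[, , 3L]
  dim(R) <- dim(S) <- dim(A) <- c(P, K)
  tau <- matrix(rates$tau, P, K, byrow = TRUE)
  gam <- matrix(rates$gamma, P, K, byrow = TRUE)
  out <- array(0, dim = dim(state), dimnames = dimnames(state))
  out[, , 1L] <- dispersal %*% (A * matrix(rates$rho, P, K, byrow = TRUE))
  out[, , 2L] <- S * rates$theta * (1 - tau) + R * gam
  out[, , 3L] <- A * rates$phi + S * rates$theta * tau
  out
}
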