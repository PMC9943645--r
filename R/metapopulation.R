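# Stage-structured matrix population models per plot, coupled by dispersal of
# seeds into a (3P) x (3P) metapopulation matrix. Stage order (R, S, A).

#' Local 3x3 stage-structured projection matrix
#'
#' Builds the per-plot matrix population model over stages (R, S, A):
#' \preformatted{
#'   | 0        0             rho * retention |
#'   | gamma    theta*(1-tau) 0               |
#'   | 0        theta*tau     phi             |
#' }
#' The R-from-A entry carries only the locally retained seed share.
#'
#' @param theta,phi,tau,gamma Probabilities in \[0, 1\].
#' @param rho Per-capita seed production (>= 0).
#' @param retention Fraction of seeds germinating in the natal plot.
#' @return A 3x3 matrix with dimnames `c("R","S","A")`.
#' @export
build_local_matrix <- function(theta, phi, tau, gamma, rho, retention = 1) {
  pr <- c(theta, phi, tau, gamma)
  if (any(pr < 0) || any(pr > 1)) stopf("rates theta, phi, tau, gamma must lie in [0, 1]")
  if (rho < 0) stopf("rho must be non-negative")
  if (retention < 0 || retention > 1) stopf("retention must lie in [0, 1]")
  m <- matrix(0, 3, 3, dimnames = list(STAGES, STAGES))
  m["R", "A"] <- rho * retention
  m["S", "R"] <- gamma
  m["S", "S"] <- theta * (1 - tau)
  m["A", "S"] <- theta * tau
  m["A", "A"] <- phi
  m
}

#' Column-stochastic dispersal matrix from a plot topology
#'
#' `D[j, j'] ` is the fraction of seeds produced in plot j' that land in plot
#' j: the natal plot keeps `retention`, and the remainder is split equally
#' among its declared neighbours. Isolated plots retain everything.
#'
#' @param topology A [dispersal_topology].
#' @return `P x P` matrix with unit column sums.
#' @export
build_dispersal_matrix <- function(topology) {
  plots <- topology$plots
  P <- length(plots)
  D <- matrix(0, P, P, dimnames = list(plots, plots))
  adj <- topology_adjacency(topology)
  for (j in seq_len(P)) {
    nb <- which(adj[, j])
    if (length(nb) == 0L) {
      D[j, j] <- 1
    } else {
      D[j, j] <- topology$retention
      D[nb, j] <- (1 - topology$retention) / length(nb)
    }
  }
  D
}

#' Assemble the (3P) x (3P) metapopulation matrix for one species
#'
#' Stacks the per-plot local matrices block-diagonally (stage-within-plot
#' ordering) and fills the seedling-from-adult entries with `rho * D[j, j']`,
#' so that one matrix-vector product reproduces [expected_step] with frozen
#' rates.
#'
#' @param locals List of P local 3x3 matrices (their `R <- A` entry is
#'   overwritten from `rho` and `D`).
#' @param D `P x P` dispersal matrix.
#' @param rho Per-capita seed production of the species.
#' @return `(3P) x (3P)` matrix; state vectors are ordered
#'   (R_1, S_1, A_1, R_2, ...).
#' @export
assemble_metapop <- function(locals, D, rho) {
  P <- length(locals)
  if (!is.matrix(D) || nrow(D) != P || ncol(D) != P) {
    stopf("dispersal matrix must be %d x %d to match %d local matrices", P, P, P)
  }
  M <- matrix(0, 3 * P, 3 * P)
  for (j in seq_len(P)) {
    idx <- (j - 1L) * 3L + 1:3
    M[idx, idx] <- locals[[j]]
    for (jp in seq_len(P)) {
      M[(j - 1L) * 3L + 1L, (jp - 1L) * 3L + 3L] <- rho * D[j, jp]
    }
  }
  M
}

#' Dominant eigenvalue (spectral radius) by power iteration
#'
#' Power iteration on the shifted matrix `M + I` (the shift makes the
#' iteration converge on non-negative matrices with periodic structure, e.g.
#' pure reproduction-survival loops) from a deterministic all-ones start.
#' When the two leading eigenvalues are nearly tied (possible for reducible
#' matrices) the scalar iteration stalls and the routine escalates to block
#' orthogonal iteration with a Rayleigh-Ritz extraction, which separates
#' clustered leading eigenvalues.
#'
#' @param m Non-negative square matrix.
#' @param tol Convergence tolerance on the eigenvalue estimate.
#' @param max_iter Iteration cap of the scalar stage.
#' @return The spectral radius (a non-negative real).
#' @export
dominant_eigenvalue <- function(m, tol = 1e-12, max_iter = 20000L) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stopf("m must be a square matrix")
  if (any(m < 0)) stopf("m must be non-negative")
  n <- nrow(m)
  if (all(m == 0)) return(0)
  # nilpotent matrices (spectral radius exactly 0, e.g. pure transient
  # stage chains) make the iteration converge only polynomially: detect via
  # m^n == 0 and return 0 outright
  pw <- m
  for (i in seq_len(n - 1L)) {
    pw <- pw %*% m
    if (all(pw == 0)) return(0)
  }
  shift <- 1
  v <- rep(1, n)
  lam <- 0
  for (it in seq_len(max_iter)) {
    w <- as.vector(m %*% v) + shift * v
    nw <- sqrt(sum(w * w))
    if (nw == 0) return(0)  # ones vector annihilated: nilpotent direction
    w <- w / nw
    lam_new <- sum(w * (as.vector(m %*% w) + shift * w)) - shift
    if (it > 1 && abs(lam_new - lam) < tol) return(max(lam_new, 0))
    lam <- lam_new
    v <- w
  }
  block_power_eigenvalue(m, shift, tol, fallback = lam)
}

# Block orthogonal iteration for matrices whose leading eigenvalues are too
# close for the scalar power method. Deterministic start spanning the ones
# vector and the first unit vectors.
block_power_eigenvalue <- function(m, shift, tol, fallback,
                                   block = 4L, max_iter = 5000L) {
  n <- nrow(m)
  k <- min(n, block)
  Q <- qr.Q(qr(cbind(rep(1, n), diag(n)[, seq_len(k - 1), drop = FALSE])))
  B <- m + shift * diag(n)
  lam <- fallback
  for (it in seq_len(max_iter)) {
    Q <- qr.Q(qr(B %*% Q))
    H <- crossprod(Q, B %*% Q)
    lam_new <- max(Re(eigen(H, only.values = TRUE)$values)) - shift
    if (it > 1 && abs(lam_new - lam) < tol) return(max(lam_new, 0))
    lam <- lam_new
  }
  stopf("power iteration did not converge (last estimate change %.3e)",
        abs(lam_new - lam))
}

#' Joint community equilibrium of the mean-field map
#'
#' Iterates [expected_step] for all species together at a fixed rainfall
#' value, recomputing the density-dependent rates from the current adult
#' abundances at every iteration, until the state change falls below `tol`.
#' Non-convergent (e.g. cyclic) trajectories are not an error: the
#' time-averaged state over the last 100 iterations is returned with
#' `converged = FALSE`.
#'
#' @param params List of [species_params], one per species.
#' @param rain Fixed natural-scale rainfall value.
#' @param topology A [dispersal_topology].
#' @param std A [standardization] object.
#' @param init Optional starting `P x K x 3` array (default 10 adults, 5
#'   saplings, 10 seedlings everywhere).
#' @param tol Convergence tolerance on the max absolute state change.
#' @param max_iter Iteration cap.
#' @return List with `state` (`P x K x 3`), `converged`, `iterations`.
#' @export
find_equilibrium <- function(params, rain, topology, std, init = NULL,
                             tol = 1e-8, max_iter = 5000L) {
  if (tol <= 0) stopf("tol must be positive")
  P <- length(topology$plots)
  K <- length(params)
  D <- build_dispersal_matrix(topology)
  if (is.null(init)) {
    init <- array(rep(c(10, 5, 10), each = P * K), dim = c(P, K, 3))
  }
  state <- init
  tail_states <- vector("list", 100L)
  for (it in seq_len(max_iter)) {
    rates <- community_rates(params, state, rain, std)
    nxt <- expected_step(state, rates, D)
    delta <- max(abs(nxt - state))
    tail_states[[(it - 1L) %% 100L + 1L]] <- nxt
    state <- nxt
    if (delta < tol) {
      return(list(state = state, converged = TRUE, iterations = it))
    }
  }
  kept <- tail_states[!vapply(tail_states, is.null, logical(1))]
  avg <- Reduce(`+`, kept) / length(kept)
  list(state = avg, converged = FALSE, iterations = max_iter)
}

#' Project the community forward in time
#'
#' Rates are recomputed each step from the current adult densities and that
#' step's rainfall. Stochastic mode draws through [step_stochastic];
#' mean-field mode applies [expected_step].
#'
#' @param init `P x K x 3` starting abundances.
#' @param params List of [species_params].
#' @param rainfall Natural-scale rainfall sequence of length >= `n_steps`
#'   (value at position t drives the step t -> t+1).
#' @param n_steps Number of annual steps.
#' @param topology A [dispersal_topology].
#' @param std A [standardization] object.
#' @param mode `"stochastic"` or `"meanfield"`.
#' @param seed Optional RNG seed (stochastic mode).
#' @param cap Total-abundance explosion guard; exceeding it aborts with advice
#'   to weaken rho/gamma.
#' @param inter_override Optional `n_steps x P x K` array of natural-scale
#'   interspecific densities to use in place of the dynamically projected ones
#'   (the "no-dynamic" ablation); intraspecific densities stay dynamic.
#' @return `(n_steps + 1) x P x K x 3` trajectory array (first slice = init).
#' @export
project_community <- function(init, params, rainfall, n_steps, topology, std,
                              mode = c("stochastic", "meanfield"), seed = NULL,
                              cap = 1e7, inter_override = NULL) {
  mode <- match.arg(mode)
  if (length(rainfall) < n_steps) stopf("rainfall sequence shorter than n_steps")
  if (!is.null(seed)) set.seed(seed)
  P <- dim(init)[1]; K <- dim(init)[2]
  D <- build_dispersal_matrix(topology)
  traj <- array(NA_real_, dim = c(n_steps + 1L, P, K, 3L))
  traj[1L, , , ] <- init
  state <- init
  if (n_steps == 0L) return(traj)
  for (t in seq_len(n_steps)) {
    rates <- community_rates_override(params, state, rainfall[t], std,
                                      if (!is.null(inter_override)) inter_override[t, , , drop = FALSE])
    state <- if (mode == "stochastic") step_stochastic(state, rates, D)
             else expected_step(state, rates, D)
    if (sum(state) > cap) {
      stopf("population exploded beyond cap %g at step %d; weaken rho or gamma", cap, t)
    }
    traj[t + 1L, , , ] <- state
  }
  traj
}

# community_rates, but with the interspecific covariate optionally replaced by
# externally supplied (e.g. historically resampled) values.
community_rates_override <- function(params, state, rain, std, inter_values = NULL) {
  if (is.null(inter_values)) return(community_rates(params, state, rain, std))
  K <- length(params)
  P <- dim(state)[1]
  adults <- state[, , 3L, drop = FALSE]
  dim(adults) <- c(P, K)
  inter_values <- array(inter_values, dim = c(P, K))
  theta <- phi <- matrix(NA_real_, P, K)
  r <- std_rain(rain, std)
  for (i in seq_len(K)) {
    intra <- std_intra(adults[, i], std)
    inter <- std_inter(inter_values[, i], std)
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
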