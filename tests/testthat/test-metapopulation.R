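test_that("local matrix has the documented entries and zero pattern", {
  m <- build_local_matrix(theta = 0.5, phi = 0.9, tau = 0.2, gamma = 0.1,
                          rho = 2, retention = 1)
  expect_equal(unname(m),
               rbind(c(0, 0, 2), c(0.1, 0.4, 0), c(0, 0.1, 0.9)))
  expect_equal(unname(build_local_matrix(0, 0, 0, 0, 0)), matrix(0, 3, 3))

  set.seed(4)
  for (rep in 1:20) {
    m <- build_local_matrix(runif(1), runif(1), runif(1), runif(1),
                            runif(1, 0, 5), runif(1))
    expect_true(all(m[m != 0] >= 0))
    expect_equal(m[1, 1] + m[1, 2] + m[2, 3] + m[3, 1], 0)  # fixed zeros
    expect_true(all(m[c(2, 5, 6, 9)] <= 1))  # probability-derived entries
  }
  expect_error(build_local_matrix(1.2, 0.5, 0.5, 0.5, 1), "\\[0, 1\\]")
})

test_that("dispersal matrix splits the non-retained share equally", {
  tri <- dispersal_topology(c("a", "b", "c"),
                            rbind(c("a", "b"), c("b", "c"), c("a", "c")),
                            retention = 0.8)
  D <- build_dispersal_matrix(tri)
  expect_equal(unname(diag(D)), rep(0.8, 3))
  expect_equal(unname(D[2:3, 1]), c(0.1, 0.1))
  expect_equal(unname(colSums(D)), rep(1, 3))

  mixed <- dispersal_topology(c("a", "b", "c"), rbind(c("a", "b")),
                              retention = 0.6)
  D <- build_dispersal_matrix(mixed)
  expect_equal(unname(D[, 3]), c(0, 0, 1))  # isolated plot keeps everything

  set.seed(11)
  for (rep in 1:10) {
    D <- build_dispersal_matrix(rand_topology(sample(3:10, 1)))
    expect_true(all(abs(colSums(D) - 1) < 1e-12))
    expect_true(all(D >= 0))
  }
})

test_that("assembled metapopulation matrix reduces and composes correctly", {
  # P = 1, full retention: identical to the local matrix
  loc <- build_local_matrix(0.6, 0.85, 0.3, 0.2, 1.5, retention = 1)
  M <- assemble_metapop(list(loc), matrix(1, 1, 1), rho = 1.5)
  expect_equal(M, unname(loc))

  # P = 2 line, hand-assembled 6x6
  topo <- dispersal_topology(c("a", "b"), rbind(c("a", "b")), retention = 0.9)
  D <- build_dispersal_matrix(topo)
  rho <- 2
  l1 <- build_local_matrix(0.5, 0.8, 0.2, 0.1, rho, retention = 0.9)
  l2 <- build_local_matrix(0.4, 0.7, 0.3, 0.2, rho, retention = 0.9)
  M <- assemble_metapop(list(l1, l2), D, rho)
  expect_equal(M[1, 6], rho * 0.1)  # plot-1 seedlings from plot-2 adults
  expect_equal(M[4, 3], rho * 0.1)
  expect_equal(M[1, 3], rho * 0.9)
  expect_equal(M[2:3, 2:3], unname(l1[2:3, 2:3]))
  expect_equal(M[5:6, 5:6], unname(l2[2:3, 2:3]))
  expect_true(all(M[2:3, 4:6] == 0) && all(M[5:6, 1:3] == 0))

  expect_error(assemble_metapop(list(l1, l2), matrix(1, 3, 3), rho), "2 x 2")
})

test_that("one metapopulation multiplication equals the mean-field step", {
  set.seed(8)
  std <- fix_std()
  for (rep in 1:10) {
    P <- sample(2:6, 1); K <- sample(1:3, 1)
    topo <- rand_topology(P)
    D <- build_dispersal_matrix(topo)
    params <- make_truth(K, 0.4, seed = rep)
    st <- array(runif(P * K * 3, 0, 30), dim = c(P, K, 3))
    rates <- dynmix:::community_rates(params, st, 470, std)
    ex <- expected_step(st, rates, D)
    for (i in seq_len(K)) {
      locs <- lapply(seq_len(P), function(j) {
        build_local_matrix(rates$theta[j, i], rates$phi[j, i], rates$tau[i],
                           rates$gamma[i], rates$rho[i], retention = D[j, j])
      })
      M <- assemble_metapop(locs, D, rates$rho[i])
      x <- as.vector(rbind(st[, i, 1], st[, i, 2], st[, i, 3]))
      y <- as.vector(rbind(ex[, i, 1], ex[, i, 2], ex[, i, 3]))
      expect_lt(max(abs(M %*% x - y)), 1e-10)
    }
  }
})

test_that("dominant eigenvalue matches closed forms and dense solvers", {
  expect_equal(dominant_eigenvalue(rbind(c(0, 2), c(0.5, 0))), 1,
               tolerance = 1e-10)
  expect_equal(dominant_eigenvalue(diag(3)), 1, tolerance = 1e-12)
  expect_equal(dominant_eigenvalue(matrix(0, 2, 2)), 0)

  # characteristic-polynomial oracle for the documented local matrix
  m <- build_local_matrix(0.5, 0.9, 0.2, 0.1, 2, retention = 1)
  tr <- sum(diag(m))
  minors <- det(m[2:3, 2:3]) + det(m[c(1, 3), c(1, 3)]) + det(m[1:2, 1:2])
  roots <- polyroot(c(-det(m), minors, -tr, 1))
  lam_poly <- max(Re(roots[abs(Im(roots)) < 1e-9]))
  expect_equal(dominant_eigenvalue(m), lam_poly, tolerance = 1e-8)

  set.seed(14)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    A <- matrix(runif(n * n), n, n) * matrix(rbinom(n * n, 1, 0.6), n, n)
    expect_equal(dominant_eigenvalue(A), max(Mod(eigen(A)$values)),
                 tolerance = 1e-8)
  }
})

test_that("equilibria: extinction under decline, interior fixed point, lambda 1", {
  std <- fix_std()
  # declining species (all survivals low, no density dependence)
  dec <- species_params(c(logit(0.3), 0, 0, 0), c(logit(0.4), 0, 0, 0),
                        tau = 0.1, gamma = 0.1, rho = 0.3, name = "dec")
  topo1 <- dispersal_topology("p1", retention = 1)
  eq <- find_equilibrium(list(dec), 500, topo1, std, tol = 1e-10)
  expect_true(eq$converged)
  expect_lt(max(eq$state), 1e-6)

  # interior fixed point with self-limiting adult survival
  solo <- fix_solo_species()
  eq <- find_equilibrium(list(solo), 500, topo1, std, tol = 1e-10)
  expect_true(eq$converged)
  expect_true(all(eq$state > 1))
  rates <- dynmix:::community_rates(list(solo), eq$state, 500, std)
  nxt <- expected_step(eq$state, rates, build_dispersal_matrix(topo1))
  expect_lt(max(abs(nxt - eq$state)), 1e-8)

  lam <- dominant_eigenvalue(build_local_matrix(rates$theta[1, 1],
                                                rates$phi[1, 1], solo$tau,
                                                solo$gamma, solo$rho, 1))
  expect_equal(lam, 1, tolerance = 1e-6)
})

test_that("projection: zero steps, matrix-power equivalence at frozen rates", {
  std <- fix_std()
  truth <- make_truth(2, 0, seed = 2)  # zero slopes: rates frozen
  topo <- default_topology(4)
  D <- build_dispersal_matrix(topo)
  init <- array(runif(4 * 2 * 3, 5, 15), dim = c(4, 2, 3))
  rain <- rep(500, 6)

  tr0 <- project_community(init, truth, rain, 0, topo, std)
  expect_equal(array(tr0[1, , , ], dim = dim(init)), init)

  traj <- project_community(init, truth, rain, 5, topo, std, mode = "meanfield")
  rates <- dynmix:::community_rates(truth, init, 500, std)
  for (i in 1:2) {
    locs <- lapply(1:4, function(j) {
      build_local_matrix(rates$theta[j, i], rates$phi[j, i], rates$tau[i],
                         rates$gamma[i], rates$rho[i], retention = D[j, j])
    })
    M <- assemble_metapop(locs, D, rates$rho[i])
    x <- as.vector(rbind(init[, i, 1], init[, i, 2], init[, i, 3]))
    for (s in 1:5) x <- M %*% x
    got <- as.vector(rbind(traj[6, , i, 1], traj[6, , i, 2], traj[6, , i, 3]))
    expect_equal(got, as.vector(x), tolerance = 1e-10)
  }
})

test_that("in-sample style check: observations inside 95% projection bands", {
  fx <- fix_small_sim(seed = 31, n_species = 3, n_plots = 6, n_years = 10)
  data <- fx$sim$data
  P <- 6; K <- 3
  init <- array(data$counts[, 1, , ], dim = c(P, K, 3)); init[is.na(init)] <- 0
  rain <- unname(data$rainfall$values)
  n_rep <- 200
  finals <- array(NA_real_, dim = c(n_rep, P, K, 2))
  for (r in seq_len(n_rep)) {
    tr <- project_community(init, fx$truth, rain, 9, fx$topo,
                            fx$sim$truth$std, seed = 1000 + r)
    finals[r, , , ] <- tr[10, , , 2:3]
  }
  lo <- apply(finals, c(2, 3, 4), quantile, 0.025)
  hi <- apply(finals, c(2, 3, 4), quantile, 0.975)
  obs <- array(data$counts[, 10, , 2:3], dim = c(P, K, 2))
  covered <- mean(obs >= lo & obs <= hi)
  expect_gt(covered, 0.8)
})
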