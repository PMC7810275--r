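# Transition matrices, projections, stationary distributions, rotations.

test_that("constructed transition matrices are column-stochastic", {
  m <- toy_model()
  for (lu in land_use_levels()) {
    P <- transition_matrix(m, covariate_profile(lu))
    expect_equal(colSums(P), setNames(rep(1, 4), paste0("from", 0:3)),
                 tolerance = 1e-12)
    expect_true(all(P >= 0))
    ev <- eigen(unclass(P))$values
    expect_lt(abs(max(Mod(ev)) - 1), 1e-10)
  }
})

test_that("columns shift mass upward with the source level (stochastic ordering)", {
  m <- transition_model(c(-1, 0, 1), alpha = c(1, 2, 3))
  P <- transition_matrix(m)
  cum <- apply(P, 2, cumsum)
  for (j in 1:3) expect_true(all(diff(cum[j, ]) < 0))
})

test_that("an extreme negative land-use effect saturates every column to level 0", {
  m <- transition_model(c(-1, 0, 1), alpha = c(1, 2, 3),
                        coefs = c(paddy_rice = -60))
  P <- transition_matrix(m, covariate_profile("paddy_rice"))
  expect_equal(unname(P[1, ]), rep(1, 4), tolerance = 1e-12)
})

test_that("projection follows q_t = P q_{t-1} with exact mass conservation", {
  I4 <- diag(4)
  q0 <- c(0.1, 0.2, 0.3, 0.4)
  tr <- project_trajectory(I4, q0, horizon = 5)
  for (t in 1:5)
    expect_equal(as.numeric(tr[t, -1]), q0, tolerance = 1e-15)

  cvec <- c(0.4, 0.3, 0.2, 0.1)
  R <- matrix(cvec, 4, 4)
  tr2 <- project_trajectory(R, state_delta(3), horizon = 3)
  expect_equal(as.numeric(tr2[1, -1]), cvec, tolerance = 1e-15)

  P <- transition_matrix(toy_model())
  tr3 <- project_trajectory(P, state_delta(3), horizon = 20)
  expect_equal(nrow(tr3), 20L)
  expect_equal(unname(rowSums(tr3[, -1])), rep(1, 20), tolerance = 1e-12)
})

test_that("projection is linear in the initial distribution", {
  P <- transition_matrix(toy_model())
  a <- c(1, 0, 0, 0); b <- c(0, 0, 0, 1); w <- 0.3
  mix <- project_trajectory(P, w * a + (1 - w) * b, horizon = 10)
  ta <- project_trajectory(P, a, horizon = 10)
  tb <- project_trajectory(P, b, horizon = 10)
  expect_equal(as.matrix(mix[, -1]),
               w * as.matrix(ta[, -1]) + (1 - w) * as.matrix(tb[, -1]),
               tolerance = 1e-12)
})

test_that("stationary distributions match symmetry cases and the power-iteration oracle", {
  cvec <- c(0.4, 0.3, 0.2, 0.1)
  eq <- stationary_distribution(matrix(cvec, 4, 4))
  expect_equal(eq$phases[[1]], cvec, tolerance = 1e-12)

  DS <- matrix(0.25, 4, 4)  # doubly stochastic
  expect_equal(stationary_distribution(DS)$phases[[1]], rep(0.25, 4),
               tolerance = 1e-12)

  set.seed(404)
  for (i in 1:50) {
    P <- random_stochastic_matrix()
    eq <- stationary_distribution(P)
    expect_lt(abs(eq$dominant_eigenvalue - 1), 1e-8)
    expect_lt(eq$residual, 1e-10)
    expect_equal(eq$phases[[1]], oracle_power_stationary(P),
                 tolerance = 1e-10)
  }
})

test_that("reducible chains with non-unique stationary vectors are flagged", {
  P <- diag(4)  # every distribution is stationary
  eq <- stationary_distribution(P)
  expect_true(length(eq$warnings) > 0)
  expect_equal(sum(eq$phases[[1]]), 1, tolerance = 1e-12)
})

test_that("rotation equilibria satisfy the phase fixed-point identities", {
  P <- transition_matrix(toy_model())
  same <- rotation_equilibrium(P, P)
  expect_equal(same$phases[[1]], stationary_distribution(P)$phases[[1]],
               tolerance = 1e-10)
  expect_equal(same$phases[[1]], same$phases[[2]], tolerance = 1e-10)

  set.seed(405)
  for (i in 1:20) {
    P1 <- random_stochastic_matrix()
    P2 <- random_stochastic_matrix()
    eq <- rotation_equilibrium(P1, P2)
    q1 <- eq$phases[[1]]; q2 <- eq$phases[[2]]
    expect_equal(as.numeric(P2 %*% q1), q2, tolerance = 1e-10)
    expect_equal(as.numeric(P1 %*% q2), q1, tolerance = 1e-10)
  }
})

test_that("convergence time is 0 at the target, 1 for rank-1 chains, monotone in tol", {
  cvec <- c(0.4, 0.3, 0.2, 0.1)
  R <- matrix(cvec, 4, 4)
  tr <- project_trajectory(R, cvec, horizon = 5)
  expect_equal(convergence_time(tr, cvec), 0L)
  tr2 <- project_trajectory(R, state_delta(0), horizon = 5)
  expect_equal(convergence_time(tr2, cvec), 1L)

  P <- transition_matrix(toy_model())
  q <- stationary_distribution(P)$phases[[1]]
  tr3 <- project_trajectory(P, state_delta(3), horizon = 200)
  times <- vapply(c(0.001, 0.01, 0.05, 0.2), function(tol)
    convergence_time(tr3, q, tol), integer(1))
  expect_true(all(diff(times) <= 0))
  # long-horizon projection settles on the stationary vector
  expect_equal(as.numeric(tr3[200, -1]), q, tolerance = 1e-10)

  expect_error(convergence_time(tr3, q, tol = 0), "tol")
  short <- project_trajectory(P, state_delta(3), horizon = 1)
  expect_true(is.na(convergence_time(short, q, tol = 1e-6)))
})
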