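# Conditional transition probabilities, design encoding, and the marginal
# likelihood against brute-force integration.

test_that("conditional transition probabilities match hand evaluation of the logistic formula", {
  m <- transition_model(c(-1, 0, 1))
  expect_equal(unname(transition_probs(m, 0)),
               c(0.26894, 0.23106, 0.23106, 0.26894), tolerance = 1e-4)
  m2 <- transition_model(c(0, 1, 2))
  expect_equal(unname(transition_probs(m2, 0)),
               c(0.50000, 0.23106, 0.14974, 0.11920), tolerance = 1e-4)
  # exact identities, not just the frozen decimals
  expect_equal(sum(transition_probs(m2, 2)), 1, tolerance = 1e-12)
  expect_equal(unname(transition_probs(m, 0))[1], plogis(-1),
               tolerance = 1e-12)
})

test_that("extreme linear predictors saturate to degenerate vectors", {
  m <- transition_model(c(-1, 0, 1), coefs = c(paddy_rice = -1000))
  p <- transition_probs(m, 3, covariate_profile("paddy_rice"))
  expect_equal(unname(p), c(1, 0, 0, 0))
  p2 <- transition_probs(m, 0, epsilon = Inf)
  expect_equal(unname(p2), c(0, 0, 0, 1))
})

test_that("transition vectors are stochastically monotone in the linear predictor", {
  cut <- c(-1.3, 0.2, 1.7)
  etas <- seq(-6, 6, by = 0.5)
  P <- weeddyn:::.cell_probs(cut, etas)
  cum <- t(apply(P, 1, cumsum))
  for (j in 1:3) expect_true(all(diff(cum[, j]) < 0))
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), rep(1, length(etas)), tolerance = 1e-12)
})

test_that("design encoding uses treatment coding with wheat/level-0 baseline", {
  spec <- model_spec()
  base <- transition_pairs(toy_survey())[1, ]  # wheat, no irr, no delay
  base$delayed_sowing <- 0L
  des <- encode_design(base, spec)
  expect_equal(unname(des$X[1, names(des$X[1, ]) != "temperature"]),
               rep(0, 7))
  expect_equal(unname(des$X[1, "temperature"]), 7.0)

  pr <- transition_pairs(toy_survey())[2, ]   # barley with irrigation
  des2 <- encode_design(pr, model_spec(c("irrigation", "land_use")))
  expect_equal(sum(des2$X[1, ]), 2)
  expect_equal(unname(des2$X[1, c("irrigation", "barley")]), c(1, 1))

  pr$temp_dec_apr <- 7.19
  des3 <- encode_design(pr, spec)
  expect_equal(unname(des3$X[1, "temperature"]), 7.19)

  pr$temp_dec_apr <- NA_real_
  expect_error(encode_design(pr, spec), "site A, year 2000")
})

test_that("sigma = 0 marginal likelihood is the conditional log-likelihood at eps = 0", {
  m <- toy_model(sigma = 0)
  prs <- transition_pairs(toy_sim(seed = 5L, n_sites = 10L)$survey)
  ll <- marginal_loglik(m, prs)
  by_hand <- sum(vapply(seq_len(nrow(prs)), function(k) {
    prof <- covariate_profile(prs$land_use[k], prs$irrigation[k],
                              prs$delayed_sowing[k], prs$temp_dec_apr[k])
    log(transition_probs(m, prs$from_level[k], prof)[prs$to_level[k] + 1L])
  }, numeric(1)))
  expect_equal(as.numeric(ll), by_hand, tolerance = 1e-10)
})

test_that("adaptive Gauss-Hermite agrees with brute-force trapezoid integration", {
  m <- toy_model(sigma = 1)
  prs <- transition_pairs(toy_sim(seed = 6L, n_sites = 8L)$survey)
  site <- unique(prs$site_id)[1]
  sp <- prs[prs$site_id == site, ][1:3, ]
  oracle <- oracle_site_loglik(m, sp)
  expect_equal(as.numeric(marginal_loglik(m, sp, nodes = 31)), oracle,
               tolerance = 1e-6)
  # self-convergence: doubling the nodes no longer moves the value
  expect_equal(as.numeric(marginal_loglik(m, sp, nodes = 15)),
               as.numeric(marginal_loglik(m, sp, nodes = 31)),
               tolerance = 1e-6)
  # quadrature error shrinks (weakly) as nodes grow
  errs <- vapply(c(3L, 7L, 15L), function(g)
    abs(as.numeric(marginal_loglik(m, sp, nodes = g)) - oracle), numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
  # Laplace is close but not relied on for accuracy
  expect_equal(as.numeric(marginal_loglik(m, sp, quadrature = "laplace")),
               oracle, tolerance = 1e-2)
})

test_that("the analytic gradient matches finite differences of the objective", {
  prs <- transition_pairs(toy_sim(seed = 9L, n_sites = 12L)$survey)
  spec <- model_spec(c("prev_coverage", "irrigation", "land_use"))
  des <- encode_design(prs, spec)
  nm <- weeddyn:::.theta_names(spec, TRUE)
  obj <- weeddyn:::.make_objective(des, spec, NULL, nm)
  theta <- setNames(c(-1.2, -0.3, 0.1, 0.8, 1.7, 2.5,
                      -0.6, 0.2, -1, -2, -1.5, -0.4, -0.2), nm)
  expect_equal(obj$gr(theta), weeddyn:::.num_grad(obj$fn, theta),
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("negative sigma is rejected", {
  prs <- transition_pairs(toy_survey())
  expect_error(fit_transition_model(prs, model_spec("irrigation"),
                                    sigma_fixed = -1), "sigma")
})
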