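# Fitting, model selection, and serialization.

sim_fit <- toy_sim(seed = 21L, n_sites = 50L)
pairs_fit <- transition_pairs(sim_fit$survey)
spec_fit <- model_spec(c("prev_coverage", "irrigation", "land_use"),
                       nodes = 7L)
fit_main <- fit_transition_model(pairs_fit, spec_fit, n_starts = 1L)

test_that("the AIC identity holds exactly and matches stats::AIC", {
  expect_equal(fit_main$aic, -2 * fit_main$loglik + 2 * fit_main$n_params)
  expect_equal(AIC(fit_main), fit_main$aic)
  expect_equal(fit_main$n_params, 3 + 3 + 6 + 1)
  expect_equal(attr(logLik(fit_main), "df"), fit_main$n_params)
  expect_equal(nobs(fit_main), nrow(pairs_fit))
})

test_that("thresholds are strictly ordered and sigma nonnegative in every fit", {
  expect_true(all(diff(fit_main$thresholds) > 0))
  expect_gte(fit_main$sigma, 0)
})

test_that("refitting with identical inputs is deterministic", {
  fit2 <- fit_transition_model(pairs_fit, spec_fit, n_starts = 1L)
  expect_identical(fit_main$thresholds, fit2$thresholds)
  expect_identical(fit_main$coefs, fit2$coefs)
  expect_identical(fit_main$loglik, fit2$loglik)
})

test_that("estimates land near the generating values on a moderate survey", {
  truth <- toy_model()
  expect_lt(max(abs(fit_main$thresholds - truth$thresholds)), 0.6)
  expect_lt(abs(fit_main$coefs[["irrigation"]] -
                  truth$coefs[["irrigation"]]), 0.5)
  expect_lt(abs(fit_main$sigma - truth$sigma), 0.6)
})

test_that("the sigma = 0 fit reproduces the fixed-effects proportional-odds oracle", {
  skip_if_not_installed("MASS")
  f0 <- fit_transition_model(pairs_fit, spec_fit, sigma_fixed = 0)
  d <- data.frame(y = factor(pairs_fit$to_level, levels = 0:3),
                  f = factor(pairs_fit$from_level, levels = 0:3),
                  irr = pairs_fit$irrigation,
                  lu = factor(pairs_fit$land_use,
                              levels = land_use_levels()))
  pf <- MASS::polr(y ~ f + irr + lu, data = d)
  expect_equal(f0$loglik, as.numeric(logLik(pf)), tolerance = 1e-6)
  # identical parameterization: polr also models logit P(Y<=j) = zeta_j - eta
  expect_equal(unname(f0$coefs[["irrigation"]]),
               unname(pf$coefficients[["irr"]]), tolerance = 1e-3)
  expect_equal(unname(f0$thresholds), unname(pf$zeta), tolerance = 1e-3)
})

test_that("a truly predictive single-term model survives backward selection", {
  truth <- transition_model(c(-1, 0.5, 2),
                            coefs = c(irrigation = -2.5), sigma = 0.5)
  cfg <- simulation_config(n_sites = 40L, years = c(2001, 2008),
                           true_model = truth,
                           management = list(irrigation_rate = 0.5),
                           seed = 31L)
  prs <- transition_pairs(simulate_survey(cfg)$survey)
  sel <- backward_select(prs, model_spec("irrigation", nodes = 7L),
                         n_starts = 1L)
  expect_equal(sel$best$spec$terms, "irrigation")
  # the ladder contains both the kept model and the rejected null model
  expect_equal(nrow(sel$ladder), 2L)
  expect_lt(sel$fits[["irrigation"]]$aic, sel$fits[[2L]]$aic)
})

test_that("backward selection drops terms that carry no signal", {
  # delayed sowing has zero effect under toy_model(); selection must never
  # keep it when starting from a spec that includes it
  sel <- backward_select(
    pairs_fit[1:150, ],
    model_spec(c("prev_coverage", "irrigation", "delayed_sowing"),
               nodes = 7L),
    n_starts = 1L)
  expect_false("delayed_sowing" %in% sel$best$spec$terms)
  expect_true(all(diff(sel$ladder$step) >= 0))
})

test_that("quasi-separated coefficients are flagged, not hidden", {
  truth <- transition_model(c(-1, 0.5, 2), alpha = c(1, 2, 3),
                            coefs = c(paddy_rice = -30), sigma = 0)
  cfg <- simulation_config(
    n_sites = 40L, years = c(2001, 2008), true_model = truth,
    management = list(land_use_probs = setNames(
      c(0.7, 0, 0, 0.3, 0, 0), land_use_levels())),
    initial = c(0, 0.4, 0.3, 0.3), seed = 33L)
  prs <- transition_pairs(simulate_survey(cfg)$survey)
  fit <- fit_transition_model(
    prs, model_spec(c("prev_coverage", "land_use"), nodes = 7L),
    sigma_fixed = 0, n_starts = 1L)
  expect_lt(fit$coefs[["paddy_rice"]], -10)
  expect_true(any(grepl("quasi-separated", fit$warnings)))
})

test_that("model JSON serialization round-trips bit for bit", {
  f <- tempfile(fileext = ".json")
  write_model_json(fit_main, f)
  back <- read_model_json(f)
  expect_identical(back$thresholds, fit_main$thresholds)
  expect_identical(back$alpha, fit_main$alpha)
  expect_identical(back$coefs, fit_main$coefs)
  expect_identical(back$sigma, fit_main$sigma)
  expect_identical(back$loglik, fit_main$loglik)
  expect_identical(back$aic, fit_main$aic)
  expect_equal(back$spec$terms, fit_main$spec$terms)
})

test_that("selection tables lay candidates out one row per model with blanks", {
  sel <- backward_select(pairs_fit[1:150, ],
                         model_spec(c("prev_coverage", "irrigation"),
                                    nodes = 7L), n_starts = 1L)
  f <- tempfile(fileext = ".csv")
  tab <- selection_table(sel, f)
  expect_true(file.exists(f))
  expect_equal(nrow(tab), nrow(sel$ladder))
  expect_true(all(c("Lv0|Lv1", "AIC", "irrigation") %in% names(tab)))
  expect_equal(tab$AIC, sort(tab$AIC))
})
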