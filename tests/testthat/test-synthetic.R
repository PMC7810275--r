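# The synthetic survey generator and the survey-scale reconstruction.

test_that("simulation is deterministic given the seed and sensitive to it", {
  cfg <- simulation_config(n_sites = 8L, years = c(2000, 2006),
                           true_model = toy_model(), seed = 99L)
  s1 <- simulate_survey(cfg)
  s2 <- simulate_survey(cfg)
  expect_identical(as.data.frame(s1$survey), as.data.frame(s2$survey))
  expect_identical(s1$truth$epsilon, s2$truth$epsilon)
  cfg$seed <- 100L
  s3 <- simulate_survey(cfg)
  expect_false(identical(as.data.frame(s1$survey), as.data.frame(s3$survey)))
})

test_that("per-site substreams keep existing sites fixed when sites are added", {
  cfg5 <- simulation_config(n_sites = 5L, years = c(2000, 2006),
                            true_model = toy_model(), seed = 7L)
  cfg6 <- cfg5; cfg6$n_sites <- 6L
  s5 <- simulate_survey(cfg5)$survey
  s6 <- simulate_survey(cfg6)$survey
  expect_identical(as.data.frame(s5),
                   as.data.frame(s6[s6$site_id %in% s5$site_id, ]))
})

test_that("simulated values respect the closed vocabularies and unique keys", {
  sim <- toy_sim(seed = 3L, n_sites = 20L)
  ds <- sim$survey
  expect_true(all(ds$coverage %in% 0:3))
  expect_true(all(ds$land_use %in% land_use_levels()))
  expect_false(anyDuplicated(paste(ds$site_id, ds$year)) > 0)
})

test_that("a lethal land-use coefficient drives every post-initial level to 0", {
  truth <- transition_model(c(-1, 0.5, 2), alpha = c(1, 2, 3),
                            coefs = c(other_crop = -50), sigma = 0)
  cfg <- simulation_config(
    n_sites = 30L, years = c(2000, 2005), true_model = truth,
    management = list(land_use_probs = setNames(c(0, 0, 1, 0, 0, 0),
                                                land_use_levels())),
    initial = c(0, 0, 0, 1), seed = 5L)
  ds <- simulate_survey(cfg)$survey
  first <- ave(ds$year, ds$site_id, FUN = min)
  expect_true(all(ds$coverage[ds$year > first] == 0L))
})

test_that("empirical transition frequencies match the model probabilities", {
  # 10,000 independent one-step transitions from level 1 at fixed
  # covariates and eps = 0, against the closed-form multinomial
  truth <- toy_model(sigma = 0)
  cfg <- simulation_config(
    n_sites = 10000L, years = c(2000, 2001), true_model = truth,
    management = list(land_use_probs = setNames(c(1, 0, 0, 0, 0, 0),
                                                land_use_levels()),
                      irrigation_rate = 0, delayed_rate = 0),
    initial = c(0, 1, 0, 0), seed = 17L)
  prs <- transition_pairs(simulate_survey(cfg)$survey)
  expect_equal(nrow(prs), 10000L)
  p <- unname(transition_probs(truth, 1))
  freq <- tabulate(prs$to_level + 1L, 4L) / nrow(prs)
  se <- sqrt(p * (1 - p) / nrow(prs))
  expect_true(all(abs(freq - p) <= 3 * se))
})

test_that("larger sigma produces more between-site heterogeneity", {
  mean_site_sd <- function(sigma) {
    sim <- toy_sim(seed = 11L, n_sites = 40L, sigma = sigma)
    sd(tapply(sim$survey$coverage, sim$survey$site_id, mean))
  }
  expect_lt(mean_site_sd(0), mean_site_sd(3))
})

test_that("the survey-scale reconstruction reproduces the published skeleton", {
  sim <- simulate_ibaraki_survey(seed = 2L)
  ds <- sim$survey
  expect_equal(nrow(ds), 425L)
  expect_equal(length(unique(ds$site_id)), 41L)
  rep <- validate_survey(ds)
  tab <- ibaraki_site_table()
  expect_equal(sum(tab$last_year - tab$first_year + 1L), 425L)
  spans <- rep$site_spans[match(tab$site_id, rep$site_spans$site_id), ]
  expect_equal(spans$first_year, tab$first_year)
  expect_equal(spans$last_year, tab$last_year)
  expect_equal(nrow(rep$gaps), 0L)   # spans are complete
  expect_true(all(ds$temp_dec_apr > 4 & ds$temp_dec_apr < 10))
  # site 1's temperatures follow its own climate summary
  t1 <- ds$temp_dec_apr[ds$site_id == "1"]
  expect_lt(abs(mean(t1) - 7.19), 4 * 0.67 / sqrt(length(t1)))
})

test_that("the survey-like random config lands near 425 records on average", {
  n <- vapply(1:20, function(s)
    nrow(simulate_survey(ibaraki_config(seed = s))$survey), numeric(1))
  expect_lt(abs(mean(n) - 425) / 425, 0.10)
})

test_that("a single-replicate recovery report has one replicate row", {
  cfg <- simulation_config(n_sites = 25L, years = c(2001, 2006),
                           true_model = toy_model(sigma = 0.5), seed = 8L)
  rec <- parameter_recovery(cfg, n_reps = 1L, nodes = 7L)
  expect_equal(nrow(rec$estimates), 1L)
  expect_equal(rec$n_failed, 0L)
  expect_true(all(c("parameter", "bias", "rmse", "coverage") %in%
                    names(rec$summary)))
})

test_that("with sigma = 0 and ample data the thresholds are recovered closely", {
  # 600 sites x 12 years gives threshold standard errors near 0.03, so a
  # 0.1 margin is a 3-sigma consistency check
  truth <- transition_model(c(-1, 0.5, 2),
                            coefs = c(irrigation = -1), sigma = 0)
  cfg <- simulation_config(n_sites = 600L, years = c(1998, 2009),
                           true_model = truth, seed = 14L)
  prs <- transition_pairs(simulate_survey(cfg)$survey)
  fit <- fit_transition_model(
    prs, model_spec("irrigation", nodes = 7L),
    sigma_fixed = 0, n_starts = 1L)
  expect_lt(max(abs(fit$thresholds - truth$thresholds)), 0.1)
  expect_lt(abs(fit$coefs[["irrigation"]] + 1), 0.1)
})
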