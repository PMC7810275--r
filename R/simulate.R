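# Synthetic survey generator: data with exactly the statistical structure
# the transition model assumes, for testing and parameter recovery.

#' Configure a synthetic survey simulation
#'
#' The generator draws one random intercept per site, an initial coverage
#' level per site, then walks each site forward year by year: management
#' covariates are drawn from `management`, and the next level from the
#' multinomial implied by the true model's conditional transition
#' probabilities. Site-years are then hidden independently at
#' `missing_rate`, which creates the gaps [transition_pairs()] must respect.
#'
#' @param n_sites number of sites (>= 1).
#' @param years inclusive calendar range, e.g. `c(1997, 2009)`.
#' @param true_model a `weed_clmm`-shaped parameter set (usually from
#'   [transition_model()]): thresholds, alpha, coefs, sigma.
#' @param management list with `land_use_probs` (named 6-vector summing
#'   to 1), `irrigation_rate`, `delayed_rate`, `temp_mean`, `temp_sd`.
#' @param initial probability 4-vector for the first observed level.
#' @param missing_rate probability a site-year is unobserved.
#' @param seed integer seed; per-site substreams are derived from it, so
#'   adding sites does not perturb existing ones.
#' @return a `weed_sim_config` list.
#' @export
simulation_config <- function(n_sites, years, true_model,
                              management = list(), initial = rep(0.25, 4),
                              missing_rate = 0, seed = 1L) {
  mg <- utils::modifyList(list(
    land_use_probs = setNames(c(0.4, 0.15, 0.1, 0.1, 0.1, 0.15),
                              land_use_levels()),
    irrigation_rate = 0.3, delayed_rate = 0.3,
    temp_mean = 6.8, temp_sd = 0.6), management)
  stopifnot(n_sites >= 1, length(years) == 2L, years[1L] <= years[2L],
            true_model$sigma >= 0, missing_rate >= 0, missing_rate < 1,
            abs(sum(mg$land_use_probs) - 1) < 1e-8,
            all(mg$land_use_probs >= 0),
            identical(names(mg$land_use_probs), land_use_levels()))
  structure(list(n_sites = as.integer(n_sites), years = as.integer(years),
                 true_model = true_model, management = mg,
                 initial = .as_state(initial),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "weed_sim_config")
}

# deterministic per-site substream seed, kept below 2^31
.site_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 7919) %% 2147483647
}

# simulate one site on a fixed year grid; returns a data frame plus epsilon
.simulate_site <- function(site_id, years, cfg) {
  tm <- cfg$true_model
  mg <- cfg$management
  n <- length(years)
  eps <- rnorm(1L, 0, tm$sigma)
  land_use <- sample(land_use_levels(), n, replace = TRUE,
                     prob = mg$land_use_probs)
  irrigation <- rbinom(n, 1L, mg$irrigation_rate)
  delayed <- rbinom(n, 1L, mg$delayed_rate)
  temp <- rnorm(n, mg$temp_mean, mg$temp_sd)
  cut <- unname(tm$thresholds)
  level <- integer(n)
  level[1L] <- sample(0:3, 1L, prob = cfg$initial)
  for (t in seq_len(n)[-1L]) {
    prof <- covariate_profile(land_use[t], irrigation[t], delayed[t],
                              temp[t])
    eta <- c(0, unname(tm$alpha))[level[t - 1L] + 1L] +
      .profile_eta(tm, prof) + eps
    level[t] <- sample(0:3, 1L, prob = .cell_probs(cut, eta)[1L, ])
  }
  list(df = data.frame(site_id = site_id, year = years, coverage = level,
                       land_use = land_use, irrigation = irrigation,
                       delayed_sowing = delayed,
                       temp_dec_apr = round(temp, 2),
                       stringsAsFactors = FALSE),
       epsilon = eps)
}

#' Simulate a synthetic survey dataset
#'
#' @param config a [simulation_config()].
#' @param year_ranges optional data frame (`site_id`, `first_year`,
#'   `last_year`) giving each site its own observation span; overrides
#'   `config$n_sites`/`config$years` and disables missingness (used to
#'   reproduce a fixed survey skeleton exactly).
#' @return a `weed_sim` list: `survey` (a `weed_survey` data frame) and
#'   `truth` (generating model, per-site `epsilon`, the config).
#' @export
simulate_survey <- function(config, year_ranges = NULL) {
  if (is.null(year_ranges)) {
    year_ranges <- data.frame(
      site_id = sprintf("S%02d", seq_len(config$n_sites)),
      first_year = config$years[1L], last_year = config$years[2L],
      stringsAsFactors = FALSE)
    apply_missing <- config$missing_rate > 0
  } else apply_missing <- FALSE

  out <- vector("list", nrow(year_ranges))
  eps <- setNames(numeric(nrow(year_ranges)), year_ranges$site_id)
  for (i in seq_len(nrow(year_ranges))) {
    set.seed(.site_seed(config$seed, i))
    sim <- .simulate_site(year_ranges$site_id[i],
                          seq(year_ranges$first_year[i],
                              year_ranges$last_year[i]), config)
    d <- sim$df
    if (apply_missing) {
      keep <- runif(nrow(d)) >= config$missing_rate
      d <- d[keep, , drop = FALSE]
    }
    out[[i]] <- d
    eps[i] <- sim$epsilon
  }
  survey <- as_weed_survey(do.call(rbind, out), source = "simulated")
  structure(list(survey = survey,
                 truth = list(model = config$true_model, epsilon = eps,
                              config = config)),
            class = "weed_sim")
}

#' Default configuration for parameter-recovery experiments
#'
#' 300 sites observed over 12 consecutive years, moderate effect sizes, a
#' balanced management mix, and a unit-SD site intercept: enough information
#' that the marginal-ML estimator should recover thresholds and the
#' irrigation coefficient with small bias.
#'
#' @param seed integer seed.
#' @param n_sites,years overridable study dimensions.
#' @return a `weed_sim_config`.
#' @export
recovery_config <- function(seed = 1L, n_sites = 300L, years = c(1998, 2009)) {
  truth <- transition_model(
    thresholds = c(-1, 0.5, 2),
    alpha = c(1.5, 3, 4.5),
    coefs = c(irrigation = -1, barley = 0.3, other_crop = -2,
              paddy_rice = -3, fallow_managed = -2.5,
              fallow_unmanaged = -1),
    sigma = 1)
  simulation_config(n_sites = n_sites, years = years, true_model = truth,
                    seed = seed)
}

#' Parameter-recovery experiment
#'
#' Simulates `n_reps` datasets from `config`, refits each with the matching
#' model specification, and aggregates per-parameter bias, RMSE and Wald
#' confidence-interval coverage. Replicates whose fit fails are counted and
#' excluded with a warning.
#'
#' @param config a [simulation_config()].
#' @param n_reps number of replicates (>= 1).
#' @param terms model terms to fit; defaults to the terms implied by the
#'   generating model.
#' @param nodes quadrature nodes for the refits (default 7; accuracy grows
#'   with cluster size, and 7 adaptive nodes are ample at sigma near 1).
#' @param conf_level Wald interval level for the coverage column.
#' @return a `weed_recovery` list: `summary` (data frame: parameter, truth,
#'   mean_est, bias, rmse, coverage), `estimates` (replicate x parameter
#'   matrix), `ses`, `n_failed`.
#' @export
parameter_recovery <- function(config, n_reps, terms = NULL, nodes = 7L,
                               conf_level = 0.95) {
  stopifnot(n_reps >= 1)
  truth <- config$true_model
  if (is.null(terms)) terms <- truth$spec$terms
  spec <- model_spec(terms = terms, nodes = nodes)

  par_names <- c("Lv0|Lv1", "Lv1|Lv2", "Lv2|Lv3",
                 if ("prev_coverage" %in% terms) c("Lv1", "Lv2", "Lv3"),
                 .coef_names(spec), "sigma")
  true_vals <- setNames(rep(0, length(par_names)), par_names)
  true_vals[c("Lv0|Lv1", "Lv1|Lv2", "Lv2|Lv3")] <- unname(truth$thresholds)
  if ("prev_coverage" %in% terms)
    true_vals[c("Lv1", "Lv2", "Lv3")] <- unname(truth$alpha)
  keep <- intersect(.coef_names(spec), names(truth$coefs))
  true_vals[keep] <- truth$coefs[keep]
  true_vals["sigma"] <- truth$sigma

  est <- ses <- matrix(NA_real_, n_reps, length(par_names),
                       dimnames = list(NULL, par_names))
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r * 101L
    fit <- tryCatch({
      sim <- simulate_survey(cfg)
      prs <- transition_pairs(sim$survey)
      fit_transition_model(prs, spec, n_starts = 1L)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      n_failed <- n_failed + 1L
      warning("replicate ", r, " failed: ", conditionMessage(fit))
      next
    }
    est[r, ] <- c(unname(fit$thresholds),
                  if ("prev_coverage" %in% terms) unname(fit$alpha),
                  unname(fit$coefs), fit$sigma)
    if (!is.null(fit$se)) ses[r, ] <- fit$se[par_names]
  }
  ok <- complete.cases(est)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  cover <- colMeans(abs(est[ok, , drop = FALSE] -
                          rep(true_vals, each = sum(ok))) <=
                      z * ses[ok, , drop = FALSE], na.rm = TRUE)
  summary <- data.frame(
    parameter = par_names,
    truth = unname(true_vals),
    mean_est = colMeans(est[ok, , drop = FALSE]),
    bias = colMeans(est[ok, , drop = FALSE]) - unname(true_vals),
    mean_abs_error = colMeans(abs(est[ok, , drop = FALSE] -
                                    rep(true_vals, each = sum(ok)))),
    rmse = sqrt(colMeans((est[ok, , drop = FALSE] -
                            rep(true_vals, each = sum(ok)))^2)),
    coverage = unname(cover),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(summary = summary, estimates = est, ses = ses,
                 n_failed = n_failed, conf_level = conf_level),
            class = "weed_recovery")
}

#' @export
print.weed_recovery <- function(x, ...) {
  cat("Parameter recovery over", nrow(x$estimates), "replicates (",
      x$n_failed, "failed )\n")
  print(cbind(x$summary[, "parameter", drop = FALSE],
              round(x$summary[, -1L], 3)), row.names = FALSE)
  invisible(x)
}
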