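# Independent oracles and small fixtures shared across the test files.
# Each oracle deliberately re-derives its quantity by a different route
# than the package (enumeration, brute-force integration, power iteration).

# exhaustive scan over sorted site-years: how many record couples are
# adjacent-with-no-intermediate and at most max_gap years apart?
oracle_pair_count <- function(ds, max_gap = 1L) {
  n <- 0L
  for (s in unique(ds$site_id)) {
    years <- sort(ds$year[ds$site_id == s])
    for (i in seq_along(years)) {
      for (j in seq_along(years)) {
        g <- years[j] - years[i]
        if (g >= 1L && g <= max_gap &&
            !any(years > years[i] & years < years[j]))
          n <- n + 1L
      }
    }
  }
  n
}

# brute-force trapezoid integration of one site's marginal likelihood over
# the random intercept
oracle_site_loglik <- function(model, site_pairs,
                               lo = -8, hi = 8, n_grid = 100001L) {
  eps <- seq(lo, hi, length.out = n_grid)
  cut <- unname(model$thresholds)
  logf <- numeric(length(eps))
  for (k in seq_len(nrow(site_pairs))) {
    prof <- covariate_profile(site_pairs$land_use[k],
                              site_pairs$irrigation[k],
                              site_pairs$delayed_sowing[k],
                              site_pairs$temp_dec_apr[k])
    eta <- c(0, unname(model$alpha))[site_pairs$from_level[k] + 1L] +
      weeddyn:::.profile_eta(model, prof) + eps
    cum <- vapply(cut, function(ci) plogis(ci - eta), numeric(length(eta)))
    p4 <- cbind(cum[, 1], cum[, 2] - cum[, 1], cum[, 3] - cum[, 2],
                1 - cum[, 3])
    logf <- logf + log(p4[cbind(seq_along(eps),
                                site_pairs$to_level[k] + 1L)])
  }
  logf <- logf + dnorm(eps, 0, model$sigma, log = TRUE)
  m <- max(logf)
  h <- eps[2L] - eps[1L]
  w <- rep(h, length(eps)); w[c(1L, length(eps))] <- h / 2
  m + log(sum(w * exp(logf - m)))
}

# 500-step power iteration from the uniform distribution
oracle_power_stationary <- function(P, steps = 500L) {
  q <- rep(0.25, 4)
  for (i in seq_len(steps)) q <- as.numeric(P %*% q) / sum(as.numeric(P %*% q))
  q
}

# random column-stochastic 4x4 matrix
random_stochastic_matrix <- function() {
  M <- matrix(rexp(16), 4, 4)
  sweep(M, 2, colSums(M), "/")
}

# small in-memory survey: one site fully observed 1998-2000, one with a
# gap, one singleton
toy_survey <- function() {
  as_weed_survey(data.frame(
    site_id = c("A", "A", "A", "B", "B", "C"),
    year = c(1998L, 1999L, 2000L, 1998L, 2000L, 1999L),
    coverage = c(0L, 1L, 2L, 3L, 3L, 0L),
    land_use = c("wheat", "wheat", "barley", "wheat", "paddy_rice", "wheat"),
    irrigation = c(0L, 0L, 1L, 0L, 0L, 0L),
    delayed_sowing = c(0L, 1L, 0L, 0L, 0L, 0L),
    temp_dec_apr = c(6.5, 7.0, 6.8, 6.9, 7.1, 6.6),
    stringsAsFactors = FALSE))
}

# toy mixed-model parameter set with mild effects (the paddy coefficient is
# capped at -8 here so small fixtures keep a non-degenerate likelihood)
toy_model <- function(sigma = 1) {
  transition_model(
    thresholds = c(-1, 0.5, 2),
    alpha = c(1, 2, 3),
    coefs = c(irrigation = -1, barley = 0.3, other_crop = -2,
              paddy_rice = -8, fallow_managed = -2.5,
              fallow_unmanaged = -1),
    sigma = sigma)
}

# small simulated survey for fitting tests: moderate size, moderate effects
toy_sim <- function(seed = 42L, n_sites = 60L, years = c(2000, 2009),
                    sigma = 1) {
  cfg <- simulation_config(
    n_sites = n_sites, years = years, true_model = toy_model(sigma),
    seed = seed)
  simulate_survey(cfg)
}
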