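# Synthetic reconstruction of the 41-site Ibaraki wild-oat monitoring
# survey (1997-2009, 425 site-year observations).
#
# The site-level skeleton -- which sites were observed in which years, and
# each site's mean and SD of December-April temperature -- is public summary
# information from the original monitoring study and is reproduced verbatim
# below. Everything else (coverage levels, management sequences, yearly
# temperatures) is SYNTHETIC: simulated from the reported transition-model
# coefficients. The reconstruction has the exact observation count and site
# structure of the real survey, but its outcome values are not the real
# observations, so likelihood-based quantities refit from it describe the
# simulation, not the original data.

#' Site skeleton of the Ibaraki wild-oat monitoring survey
#'
#' One row per site: observation span (inclusive calendar years) and the
#' site's mean and standard deviation of December-April temperature in
#' degrees C. The 41 spans sum to 425 site-years.
#'
#' @return data frame with columns `site_id`, `first_year`, `last_year`,
#'   `temp_mean`, `temp_sd`.
#' @export
ibaraki_site_table <- function() {
  tab <- matrix(c(
     1, 1998, 2009, 7.19, 0.67,   2, 1998, 2009, 7.19, 0.67,
     3, 1998, 2009, 7.44, 0.68,   4, 1998, 2009, 7.19, 0.67,
     5, 2000, 2009, 7.33, 0.69,   6, 1998, 2009, 6.91, 0.61,
     7, 2005, 2008, 6.74, 0.69,   8, 1997, 2008, 6.89, 0.59,
     9, 1999, 2009, 6.90, 0.66,  10, 1999, 2006, 6.68, 0.60,
    11, 1998, 2009, 6.89, 0.63,  12, 1999, 2008, 6.78, 0.63,
    13, 1999, 2009, 6.87, 0.66,  14, 1998, 2009, 7.01, 0.61,
    15, 1998, 2009, 7.01, 0.61,  16, 1998, 2009, 7.01, 0.61,
    17, 1998, 2006, 6.79, 0.58,  18, 1999, 2009, 6.57, 0.65,
    19, 1997, 2009, 6.66, 0.60,  20, 1998, 2009, 6.65, 0.63,
    21, 1998, 2009, 6.78, 0.63,  22, 1998, 2006, 6.65, 0.57,
    23, 1998, 2009, 6.62, 0.63,  24, 1998, 2009, 6.68, 0.63,
    25, 1998, 2002, 6.78, 0.50,  26, 1998, 2005, 6.64, 0.52,
    27, 1998, 2009, 6.77, 0.63,  28, 1998, 2004, 6.67, 0.56,
    29, 1999, 2009, 6.73, 0.65,  30, 1999, 2003, 6.57, 0.62,
    31, 1999, 2008, 6.60, 0.62,  32, 1999, 2008, 6.60, 0.62,
    33, 1999, 2008, 6.65, 0.62,  34, 1997, 2009, 6.88, 0.59,
    35, 1998, 2007, 6.67, 0.63,  36, 1999, 2008, 6.58, 0.62,
    37, 1998, 2008, 6.60, 0.60,  38, 1998, 2007, 6.75, 0.63,
    39, 1998, 2009, 6.82, 0.62,  40, 1999, 2003, 6.76, 0.61,
    41, 1998, 2009, 6.67, 0.63), ncol = 5, byrow = TRUE)
  data.frame(site_id = as.character(tab[, 1L]),
             first_year = as.integer(tab[, 2L]),
             last_year = as.integer(tab[, 3L]),
             temp_mean = tab[, 4L], temp_sd = tab[, 5L],
             stringsAsFactors = FALSE)
}

#' Transition-model coefficient sets for the Ibaraki survey
#'
#' `ibaraki_projection_model()` returns the reported estimates of the
#' projection model (previous coverage, summer irrigation, farmland use; no
#' delayed sowing or temperature term) from the original 41-site survey, as
#' a `weed_clmm` parameter object usable with [transition_matrix()] and the
#' scenario tools. The paddy-rice coefficient is quasi-separated (paddy
#' years were followed by zero coverage essentially without exception), so
#' its value conveys saturation, not a finite effect size.
#'
#' `ibaraki_generating_model()` is the same coefficient set rounded to one
#' decimal with a unit-SD site intercept added; it is the default truth for
#' [simulate_ibaraki_survey()].
#'
#' @return a `weed_clmm` parameter object (see [transition_model()]).
#' @export
ibaraki_projection_model <- function() {
  transition_model(
    thresholds = c(-3.08, 0.22, 2.23),
    alpha = c(4.22, 8.44, 12.57),
    coefs = c(irrigation = -1.39, barley = 0.26, other_crop = -6.73,
              paddy_rice = -18.79, fallow_managed = -5.36,
              fallow_unmanaged = -1.54),
    sigma = 0)
}

#' @rdname ibaraki_projection_model
#' @param sigma site random-intercept SD of the generating model.
#' @export
ibaraki_generating_model <- function(sigma = 1) {
  transition_model(
    thresholds = c(-3.1, 0.2, 2.2),
    alpha = c(4.2, 8.4, 12.6),
    coefs = c(irrigation = -1.4, barley = 0.3, other_crop = -6.7,
              paddy_rice = -18.8, fallow_managed = -5.4,
              fallow_unmanaged = -1.5),
    sigma = sigma)
}

# management mix typical of the surveyed fields: winter-cereal dominated,
# occasional rotation years, irrigation and delayed sowing in a minority of
# site-years
.ibaraki_management <- function() {
  list(land_use_probs = setNames(c(0.55, 0.20, 0.06, 0.06, 0.04, 0.09),
                                 land_use_levels()),
       irrigation_rate = 0.10, delayed_rate = 0.15,
       temp_mean = 6.8, temp_sd = 0.6)
}

#' Survey-scale simulation configuration
#'
#' A [simulation_config()] shaped like the Ibaraki survey: 41 sites over
#' 1997-2009 with the missingness rate tuned so the expected record count is
#' 425 (the real survey's size), site intercept SD 1, winter temperatures
#' around 6.8 +/- 0.6 degrees C, and a winter-cereal-dominated management
#' mix. Initial levels favour low-to-medium coverage, matching the selection
#' of fields where the weed had already colonized.
#'
#' @param seed integer seed.
#' @return a `weed_sim_config`.
#' @export
ibaraki_config <- function(seed = 1L) {
  simulation_config(
    n_sites = 41L, years = c(1997L, 2009L),
    true_model = ibaraki_generating_model(),
    management = .ibaraki_management(),
    initial = c(0.10, 0.45, 0.25, 0.20),
    missing_rate = 1 - 425 / (41 * 13),
    seed = seed)
}

#' Simulate the synthetic Ibaraki survey reconstruction
#'
#' Generates a dataset on the exact site-by-year skeleton of
#' [ibaraki_site_table()] (41 sites, 425 observations, no missing years
#' within a site's span), with each site's yearly temperature drawn from its
#' own published mean/SD and coverage transitions simulated from
#' `truth`. This is the package's stand-in for the original survey data,
#' which is not redistributed here; see the package vignette for what
#' analyses of it can and cannot establish.
#'
#' @param seed integer seed.
#' @param truth generating `weed_clmm` parameters (default
#'   [ibaraki_generating_model()]).
#' @return a `weed_sim` list (`survey`, `truth`), as [simulate_survey()].
#' @export
simulate_ibaraki_survey <- function(seed = 1L,
                                    truth = ibaraki_generating_model()) {
  sites <- ibaraki_site_table()
  cfg <- simulation_config(
    n_sites = nrow(sites), years = range(c(sites$first_year,
                                           sites$last_year)),
    true_model = truth, management = .ibaraki_management(),
    initial = c(0.10, 0.45, 0.25, 0.20), missing_rate = 0, seed = seed)
  sim <- simulate_survey(cfg, year_ranges = sites)
  # per-site temperatures: redraw from each site's own climate summary so
  # the covariate matches the published site table rather than a common mean
  for (i in seq_len(nrow(sites))) {
    set.seed(.site_seed(seed + 271828, i))
    rows <- sim$survey$site_id == sites$site_id[i]
    sim$survey$temp_dec_apr[rows] <-
      round(rnorm(sum(rows), sites$temp_mean[i], sites$temp_sd[i]), 2)
  }
  sim
}
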