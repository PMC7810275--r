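# Management scenarios: definition, execution, and equilibrium tables.

#' Define a management scenario
#'
#' A scenario is a cyclic sequence of management profiles (length 1 for a
#' constant environment, 2 for an alternating rotation, any length allowed),
#' a projection horizon, and an initial coverage distribution.
#'
#' @param id scenario identifier token.
#' @param cycle a [covariate_profile()] or non-empty list of them, applied
#'   cyclically year after year.
#' @param horizon projection length in years (default 20).
#' @param initial initial state: a coverage level 0-3 or a probability
#'   4-vector (default certainty of level 0).
#' @return a `weed_scenario` list.
#' @export
scenario_def <- function(id, cycle, horizon = 20L, initial = 0) {
  if (inherits(cycle, "weed_profile")) cycle <- list(cycle)
  if (!length(cycle)) stop("cycle must be non-empty")
  if (horizon < 1) stop("horizon must be >= 1")
  structure(list(id = id, cycle = cycle, horizon = as.integer(horizon),
                 initial = .as_state(initial)),
            class = "weed_scenario")
}

#' The standard management scenarios
#'
#' The eight scenarios compared in the analysis — continuous wheat, wheat
#' rotated with each of the five other farmland uses, continuously irrigated
#' wheat, and wheat alternating with irrigated wheat — each started both
#' from certainty of level 0 (absent) and of level 3 (high coverage), giving
#' 16 runs. All profiles hold the random effect at 0.
#'
#' @param horizon projection length in years (default 20).
#' @param temp_dec_apr temperature to use in every profile (only needed for
#'   models retaining the temperature term).
#' @return named list of 16 `weed_scenario` objects.
#' @export
default_scenarios <- function(horizon = 20L, temp_dec_apr = NA_real_) {
  wheat <- covariate_profile("wheat", temp_dec_apr = temp_dec_apr)
  irrig <- covariate_profile("wheat", irrigation = 1,
                             temp_dec_apr = temp_dec_apr)
  cycles <- list(
    wheat = list(wheat),
    `wheat-barley` = list(wheat, covariate_profile("barley",
                                                   temp_dec_apr = temp_dec_apr)),
    `wheat-other_crop` = list(wheat, covariate_profile("other_crop",
                                                       temp_dec_apr = temp_dec_apr)),
    `wheat-paddy_rice` = list(wheat, covariate_profile("paddy_rice",
                                                       temp_dec_apr = temp_dec_apr)),
    `wheat-fallow_managed` = list(wheat, covariate_profile("fallow_managed",
                                                           temp_dec_apr = temp_dec_apr)),
    `wheat-fallow_unmanaged` = list(wheat, covariate_profile("fallow_unmanaged",
                                                             temp_dec_apr = temp_dec_apr)),
    `wheat_irrigated` = list(irrig),
    `wheat-wheat_irrigated` = list(wheat, irrig)
  )
  out <- list()
  for (nm in names(cycles))
    for (lv in c(0L, 3L))
      out[[paste0(nm, "_from", lv)]] <-
        scenario_def(paste0(nm, "_from", lv), cycles[[nm]],
                     horizon = horizon, initial = lv)
  out
}

#' Run one management scenario
#'
#' Builds the per-phase transition matrices, projects the trajectory,
#' computes the (rotation) equilibrium, and measures the convergence year:
#' the first year whose state is within `tol` (L-infinity) of the
#' equilibrium phase matching that year's position in the cycle. Fully
#' deterministic.
#'
#' @param model a `weed_clmm` object.
#' @param scenario a `weed_scenario` ([scenario_def()]).
#' @param tol convergence tolerance (default 0.01).
#' @param force project from a non-converged fit.
#' @return a `weed_scenario_result` list: `scenario`, `matrices`,
#'   `trajectory`, `equilibrium`, `convergence_years` (`NA` = not reached).
#' @export
run_scenario <- function(model, scenario, tol = 0.01, force = FALSE) {
  mats <- tryCatch(
    lapply(scenario$cycle, function(p) transition_matrix(model, p, force)),
    error = function(e) stop("scenario '", scenario$id, "': ",
                             conditionMessage(e)))
  L <- length(mats)
  eq <- if (L == 1L) stationary_distribution(mats[[1L]]) else
    rotation_equilibrium(mats)
  tr <- project_trajectory(mats, scenario$initial, scenario$horizon)

  # phase-aligned convergence: the state in year t is compared with the
  # equilibrium phase of the matrix applied in year t
  conv <- NA_integer_
  if (max(abs(scenario$initial - eq$phases[[L]])) < tol) {
    conv <- 0L
  } else {
    Q <- as.matrix(tr[, paste0("p_level", 0:3)])
    for (t in seq_len(nrow(Q))) {
      ph <- eq$phases[[((t - 1L) %% L) + 1L]]
      if (max(abs(Q[t, ] - ph)) < tol) { conv <- t; break }
    }
  }
  eq$convergence_years <- conv
  structure(list(scenario = scenario, matrices = mats, trajectory = tr,
                 equilibrium = eq, convergence_years = conv),
            class = "weed_scenario_result")
}

#' @export
print.weed_scenario_result <- function(x, ...) {
  cat("Scenario", x$scenario$id, "- horizon", x$scenario$horizon, "years\n")
  print(x$equilibrium)
  cat("  convergence year:",
      if (is.na(x$convergence_years)) "not reached" else x$convergence_years,
      "\n")
  invisible(x)
}

#' Equilibrium probabilities per rotation and phase
#'
#' One row per rotation phase: the equilibrium probability of each coverage
#' level in the years when that phase's farmland use is grown. A constant
#' cycle contributes a single row. Values are unrounded unless `digits` is
#' given; unrounded row sums are exactly 1 up to numerical residual.
#'
#' @param model a `weed_clmm` object.
#' @param scenarios list of `weed_scenario` objects; defaults to the eight
#'   standard cycles (initial state is irrelevant at equilibrium, so each
#'   cycle appears once).
#' @param digits optional rounding (use 2 to mirror conventional reporting).
#' @param tol,force passed to [run_scenario()].
#' @return data frame with columns `rotation`, `phase`, `p_level0`..`p_level3`.
#' @export
equilibrium_table <- function(model, scenarios = NULL, digits = NULL,
                              tol = 0.01, force = FALSE) {
  if (is.null(scenarios)) {
    scenarios <- default_scenarios()
    scenarios <- scenarios[grep("_from0$", names(scenarios))]
    for (i in seq_along(scenarios))
      scenarios[[i]]$id <- sub("_from0$", "", scenarios[[i]]$id)
  }
  rows <- list()
  for (sc in scenarios) {
    res <- run_scenario(model, sc, tol = tol, force = force)
    for (i in seq_along(res$equilibrium$phases)) {
      q <- res$equilibrium$phases[[i]]
      if (!is.null(digits)) q <- round(q, digits)
      rows[[length(rows) + 1L]] <- data.frame(
        rotation = sc$id,
        phase = .profile_label(sc$cycle[[i]]),
        p_level0 = q[1L], p_level1 = q[2L], p_level2 = q[3L],
        p_level3 = q[4L], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write per-scenario trajectories to CSV
#'
#' @param results list of `weed_scenario_result` objects.
#' @param path output CSV path.
#' @return the combined data frame, invisibly.
#' @export
write_trajectories <- function(results, path) {
  rows <- lapply(results, function(r) {
    cbind(scenario = r$scenario$id,
          initial = paste0("level", which(r$scenario$initial == 1) - 1L)[1L],
          r$trajectory)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
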