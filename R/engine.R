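# Transition matrices, projections, stationary distributions and rotation
# equilibria for the 4-state coverage chain.

#' Define a management covariate profile
#'
#' One year's management setting for projection: the covariates entering the
#' linear predictor, plus the value at which the site random intercept is
#' held (0 by default, the population-average site; nonzero values support
#' sensitivity analyses).
#'
#' @param land_use one of the six farmland-use tokens (see
#'   [land_use_levels()]).
#' @param irrigation,delayed_sowing binary indicators (0/1).
#' @param temp_dec_apr mean December-April temperature in degrees C, or `NA`
#'   when the model has no temperature term.
#' @param epsilon site random-intercept value used at projection time.
#' @return a `weed_profile` list.
#' @export
covariate_profile <- function(land_use = "wheat", irrigation = 0,
                              delayed_sowing = 0, temp_dec_apr = NA_real_,
                              epsilon = 0) {
  if (!land_use %in% land_use_levels())
    stop("unknown land_use token: ", land_use)
  stopifnot(irrigation %in% c(0, 1), delayed_sowing %in% c(0, 1))
  structure(list(land_use = land_use, irrigation = irrigation,
                 delayed_sowing = delayed_sowing,
                 temp_dec_apr = temp_dec_apr, epsilon = epsilon),
            class = "weed_profile")
}

# short printable label for a profile
.profile_label <- function(p) {
  lab <- p$land_use
  if (p$irrigation == 1) lab <- paste0(lab, " (irrigation)")
  if (p$delayed_sowing == 1) lab <- paste0(lab, " (delayed sowing)")
  lab
}

#' Build the 4x4 transition matrix for one covariate profile
#'
#' Column i (i = 0..3) holds the probabilities of this year's level given
#' level i last year, evaluated at the profile's covariates and `epsilon`;
#' every column sums to 1 by construction.
#'
#' @param model a `weed_clmm` object.
#' @param profile a [covariate_profile()].
#' @param force build the matrix even if the fit did not converge.
#' @return a `weed_tmat`: a 4x4 column-stochastic matrix with the profile
#'   attached as attribute `profile`.
#' @export
transition_matrix <- function(model, profile = covariate_profile(),
                              force = FALSE) {
  if (isFALSE(model$converged) && !force)
    stop("model did not converge; pass force = TRUE to project anyway")
  P <- vapply(0:3, function(i)
    unname(transition_probs(model, i, profile, epsilon = profile$epsilon)),
    numeric(4))
  dimnames(P) <- list(paste0("to", 0:3), paste0("from", 0:3))
  structure(P, class = c("weed_tmat", "matrix"), profile = profile)
}

#' @export
print.weed_tmat <- function(x, digits = 3, ...) {
  cat("Transition matrix --", .profile_label(attr(x, "profile")), "\n")
  print(round(unclass(x)[, , drop = FALSE], digits))
  invisible(x)
}

.check_stochastic <- function(P, tol = 1e-8) {
  if (!is.matrix(P) || any(dim(P) != c(4L, 4L)))
    stop("a transition matrix must be 4x4")
  if (any(P < -1e-12) || any(abs(colSums(P) - 1) > tol))
    stop("matrix is not column-stochastic")
  invisible(P)
}

#' Project a state distribution through a (cyclic) matrix sequence
#'
#' Applies `q_t = P_t q_{t-1}` for `horizon` years, cycling through the
#' supplied matrices (a single matrix gives a constant environment; a list
#' of two gives a two-phase rotation, and so on).
#'
#' @param matrices a `weed_tmat` or list of them, used cyclically.
#' @param q0 initial state distribution (nonnegative 4-vector summing to 1),
#'   e.g. `state_delta(3)` for certainty of high coverage.
#' @param horizon number of years to project (>= 1).
#' @return a `weed_trajectory` data frame with columns `year` (1..horizon)
#'   and `p_level0`..`p_level3`; `q0` and the cycle length are attributes.
#' @export
project_trajectory <- function(matrices, q0, horizon = 20L) {
  if (horizon < 1) stop("horizon must be >= 1")
  if (inherits(matrices, "weed_tmat") || (is.matrix(matrices)))
    matrices <- list(matrices)
  lapply(matrices, .check_stochastic)
  q0 <- .as_state(q0)
  L <- length(matrices)
  out <- matrix(NA_real_, nrow = horizon, ncol = 4)
  q <- q0
  for (t in seq_len(horizon)) {
    q <- as.numeric(matrices[[((t - 1L) %% L) + 1L]] %*% q)
    q <- q / sum(q)
    out[t, ] <- q
  }
  tr <- data.frame(year = seq_len(horizon), out)
  names(tr) <- c("year", paste0("p_level", 0:3))
  structure(tr, class = c("weed_trajectory", "data.frame"),
            q0 = q0, cycle_length = L)
}

# coerce a level index or probability vector to a state distribution
.as_state <- function(q) {
  if (length(q) == 1L && q %in% 0:3) return(state_delta(q))
  q <- as.numeric(q)
  if (length(q) != 4L || any(q < -1e-12) || abs(sum(q) - 1) > 1e-8)
    stop("a state distribution is a nonnegative 4-vector summing to 1")
  pmax(q, 0) / sum(pmax(q, 0))
}

#' @rdname project_trajectory
#' @param level coverage level 0-3.
#' @export
state_delta <- function(level) {
  stopifnot(level %in% 0:3)
  as.numeric(0:3 == level)
}

# 500-step power iteration; also the documented oracle fallback
.power_stationary <- function(P, steps = 500L, q = rep(0.25, 4)) {
  for (i in seq_len(steps)) q <- as.numeric(P %*% q) / sum(P %*% q)
  q
}

#' Stationary distribution of a transition matrix
#'
#' The right eigenvector of the eigenvalue closest to 1 (for a
#' column-stochastic matrix the dominant eigenvalue is exactly 1),
#' normalized to a nonnegative unit-sum vector. If the eigen-decomposition
#' yields a numerically complex vector the routine falls back to power
#' iteration; a reducible or periodic matrix whose stationary vector is not
#' unique is flagged and the power-iteration limit returned with a warning.
#'
#' @param P a column-stochastic 4x4 matrix (e.g. a `weed_tmat`, or a product
#'   of them for rotation phases).
#' @return a `weed_equilibrium` list: `phases` (list of one state vector),
#'   `dominant_eigenvalue`, `residual` (`max |Pq* - q*|`), `convergence_years`
#'   (`NA`; filled by [run_scenario()]), `warnings`.
#' @export
stationary_distribution <- function(P) {
  .check_stochastic(P)
  warn <- character(0)
  e <- eigen(unclass(P))
  mod <- Mod(e$values)
  k <- which.min(Mod(e$values - 1))
  # a second eigenvalue on (or numerically at) the unit circle means the
  # stationary vector is not unique (reducible or periodic chain)
  if (sum(mod > 1 - 1e-10) > 1L) {
    warn <- c(warn, "stationary distribution may not be unique; returning power-iteration limit")
    q <- .power_stationary(P, steps = 10000L)
  } else {
    v <- e$vectors[, k]
    if (max(abs(Im(v))) > 1e-8 * max(abs(Re(v)))) {
      warn <- c(warn, "complex eigenvector; fell back to power iteration")
      q <- .power_stationary(P)
    } else {
      q <- Re(v)
      if (sum(q) < 0) q <- -q
    }
  }
  q[abs(q) < 1e-12] <- 0
  if (any(q < 0)) {
    warn <- c(warn, "negative eigenvector entries; fell back to power iteration")
    q <- .power_stationary(P)
  }
  q <- q / sum(q)
  structure(list(phases = list(q),
                 dominant_eigenvalue = Re(e$values[k]),
                 residual = max(abs(as.numeric(P %*% q) - q)),
                 convergence_years = NA_integer_, warnings = warn),
            class = "weed_equilibrium")
}

#' Phase equilibria of a cyclic rotation
#'
#' For a two-use rotation with matrices `P1`, `P2` the coverage distribution
#' oscillates between two phase states at equilibrium: the state observed in
#' use-1 years is the stationary vector of `P1 P2`, the state in use-2 years
#' that of `P2 P1`, and they map onto each other (`q1* = P1 q2*`,
#' `q2* = P2 q1*`). Any cycle length is supported: phase i is the stationary
#' vector of the cyclic product ending with the phase-i matrix applied last.
#'
#' @param ... two or more column-stochastic matrices, or a single list of
#'   them, in cycle order.
#' @return a `weed_equilibrium` whose `phases` list has one state vector per
#'   phase, with the largest phase residual reported.
#' @export
rotation_equilibrium <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1L]]) && !is.matrix(mats[[1L]]))
    mats <- mats[[1L]]
  L <- length(mats)
  lapply(mats, .check_stochastic)
  phases <- vector("list", L)
  lambdas <- resids <- numeric(L)
  warn <- character(0)
  for (i in seq_len(L)) {
    # product applying a full cycle and ending in phase i:
    # P_i P_{i-1} ... P_1 P_L ... P_{i+1}
    ord <- ((i - seq_len(L)) %% L) + 1L
    M <- Reduce(`%*%`, mats[ord])
    eq <- stationary_distribution(M)
    phases[[i]] <- eq$phases[[1L]]
    lambdas[i] <- eq$dominant_eigenvalue
    resids[i] <- eq$residual
    warn <- c(warn, eq$warnings)
  }
  structure(list(phases = phases,
                 dominant_eigenvalue = lambdas[1L],
                 residual = max(resids),
                 convergence_years = NA_integer_, warnings = unique(warn)),
            class = "weed_equilibrium")
}

#' @export
print.weed_equilibrium <- function(x, digits = 3, ...) {
  cat("Equilibrium (lambda =", format(x$dominant_eigenvalue, digits = 10),
      ", residual =", format(x$residual, digits = 3), ")\n")
  for (i in seq_along(x$phases))
    cat("  phase", i, ":", paste(round(x$phases[[i]], digits),
                                 collapse = "  "), "\n")
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}

#' Years until a trajectory is within tolerance of a target state
#'
#' Smallest year `t` with `max |q_t - target| < tol`; year 0 (the initial
#' state) counts, so a trajectory starting at the target returns 0.
#'
#' @param trajectory a `weed_trajectory`.
#' @param target a state distribution.
#' @param tol L-infinity tolerance (> 0); default 0.01, matching 2-decimal
#'   reporting granularity.
#' @return integer year, or `NA` if the tolerance is never reached within
#'   the trajectory's horizon ("not reached").
#' @export
convergence_time <- function(trajectory, target, tol = 0.01) {
  if (tol <= 0) stop("tol must be > 0")
  target <- .as_state(target)
  if (max(abs(attr(trajectory, "q0") - target)) < tol) return(0L)
  Q <- as.matrix(trajectory[, paste0("p_level", 0:3)])
  d <- apply(abs(Q - rep(target, each = nrow(Q))), 1L, max)
  hit <- which(d < tol)
  if (!length(hit)) NA_integer_ else trajectory$year[hit[1L]]
}
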