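# Stable cumulative-logit cell probabilities and their derivatives.
#
# A transition into level j given linear predictor eta has probability
#   p_j = F(c_j - eta) - F(c_{j-1} - eta),  F = logistic,
# with c_0..c_2 the three cutpoints and c_{-1} = -Inf, c_3 = +Inf. All
# computations run in log space via the exact identity
#   F(a) - F(b) = F(a) * F(-b) * (1 - exp(b - a)),  a > b,
# which stays accurate when both arguments sit in the same tail.

# log(F(a) - F(b)) for a > b, vectorized, -Inf/+Inf endpoints allowed
.log_interval_prob <- function(a, b) {
  d <- b - a                      # <= 0; -Inf when b = -Inf
  tail_term <- ifelse(d == -Inf, 0, log1p(-exp(d)))
  plogis(a, log.p = TRUE) + plogis(-b, log.p = TRUE) + tail_term
}

# per-observation log p and its derivatives. With derivs = TRUE also
# returns wa = f(a)/p and wb = f(b)/p (f = logistic density), the
# building blocks of the cutpoint and linear-predictor gradients:
#   d log p / d eta  = wb - wa
#   d log p / d c_upper = wa,  d log p / d c_lower = -wb.
# to: integer 0..3; eta: numeric vector or matrix (recycled against to)
.cell_loglik <- function(cut, to, eta, derivs = FALSE) {
  upper <- c(cut, Inf)[to + 1L]
  lower <- c(-Inf, cut)[to + 1L]
  a <- upper - eta
  b <- lower - eta
  lp <- .log_interval_prob(a, b)
  if (!derivs) return(list(logp = lp))
  # log f(x) with f the logistic density; f(+-Inf) = 0
  lfa <- plogis(a, log.p = TRUE) + plogis(-a, log.p = TRUE)
  lfb <- plogis(b, log.p = TRUE) + plogis(-b, log.p = TRUE)
  wa <- exp(lfa - lp)
  wb <- exp(lfb - lp)
  g <- wb - wa
  d2 <- wa * (1 - 2 * plogis(a)) - wb * (1 - 2 * plogis(b)) - g * g
  list(logp = lp, g = g, d2 = d2, wa = wa, wb = wb)
}

# 4-vector (or 4-row matrix) of cell probabilities at linear predictor eta
.cell_probs <- function(cut, eta) {
  cum <- vapply(cut, function(ci) plogis(ci - eta), numeric(length(eta)))
  cum <- matrix(cum, nrow = length(eta))
  p <- cbind(cum[, 1L], cum[, 2L] - cum[, 1L], cum[, 3L] - cum[, 2L],
             1 - cum[, 3L])
  p[p < 0] <- 0                   # guard against tiny negative round-off
  p / rowSums(p)
}

#' Conditional transition probabilities
#'
#' Evaluates the probability of each destination coverage level given the
#' source level and a covariate profile: the proportional-odds cell
#' probabilities at linear predictor `eta = alpha[from] + beta.x + epsilon`.
#' Infinite `eta` saturates to a degenerate vector rather than erroring.
#'
#' @param model a `weed_clmm` object ([fit_transition_model()] or
#'   [transition_model()]).
#' @param from_level source coverage level, integer 0-3.
#' @param profile a [covariate_profile()]; the default (all-baseline wheat
#'   profile) contributes nothing to `eta`.
#' @param epsilon value of the site random intercept (default 0, the
#'   population-average site).
#' @return named numeric 4-vector (p_level0..p_level3), nonnegative, summing
#'   to 1.
#' @export
#' @examples
#' m <- transition_model(c(-1, 0, 1))
#' transition_probs(m, 0)                 # (0.269, 0.231, 0.231, 0.269)
transition_probs <- function(model, from_level, profile = covariate_profile(),
                             epsilon = 0) {
  stopifnot(from_level %in% 0:3)
  eta <- c(0, model$alpha)[from_level + 1L] + .profile_eta(model, profile) +
    epsilon
  p <- if (is.infinite(eta)) {
    if (eta < 0) c(1, 0, 0, 0) else c(0, 0, 0, 1)
  } else {
    as.numeric(.cell_probs(unname(model$thresholds), eta))
  }
  setNames(p, paste0("p_level", 0:3))
}
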