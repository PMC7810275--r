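# Marginal likelihood of the mixed cumulative-link transition model.
#
# Each site s contributes
#   L_s = int prod_k p_{to_k, from_k}(x_k, eps) * N(eps; 0, sigma^2) d eps,
# the random intercept being shared by all of a site's transitions. The
# integral is evaluated by adaptive Gauss-Hermite quadrature centred and
# scaled at the per-site posterior mode (found by a vectorized Newton
# iteration on the concave integrand), or by the Laplace approximation.

.gh_rule <- function(nodes) {
  if (nodes == 1L) return(list(x = 0, w = sqrt(pi)))
  pracma::gaussHermite(nodes)
}

# Newton iteration for the per-site mode of
#   h_s(eps) = sum_k log p_k(eta_fix_k + eps) + log N(eps; 0, sigma^2).
# Returns mode, h(mode) and h''(mode) for all sites at once.
.site_modes <- function(cut, to, eta_fix, site, n_sites, sigma, eps0 = NULL) {
  eps <- if (is.null(eps0)) numeric(n_sites) else eps0
  inv_var <- 1 / sigma^2
  for (iter in seq_len(60L)) {
    cl <- .cell_loglik(cut, to, eta_fix + eps[site], derivs = TRUE)
    agg <- rowsum(cbind(cl$g, cl$d2), site)
    hp <- agg[, 1L] - eps * inv_var
    hpp <- agg[, 2L] - inv_var           # < 0: log-concave integrand
    step <- pmin(pmax(-hp / hpp, -4), 4)
    eps <- eps + step
    if (max(abs(step)) < 1e-10) break
  }
  cl <- .cell_loglik(cut, to, eta_fix + eps[site], derivs = TRUE)
  agg <- rowsum(cbind(cl$logp, cl$d2), site)
  h <- agg[, 1L] + dnorm(eps, 0, sigma, log = TRUE)
  list(eps = eps, h = h, hpp = agg[, 2L] - inv_var)
}

# Total marginal log-likelihood for parameter blocks on the natural scale.
# des is the output of encode_design(); cache (an environment or NULL)
# carries per-site modes across nearby evaluations to shorten the Newton
# iteration inside optimization.
.marginal_loglik <- function(cut, alpha, beta, sigma, des,
                             quadrature = "agq", nodes = 15L, cache = NULL) {
  eta_fix <- c(0, alpha)[des$from + 1L]
  if (ncol(des$X)) eta_fix <- eta_fix + as.vector(des$X %*% beta)
  site <- as.integer(des$site)
  n_sites <- nlevels(des$site)

  if (sigma < 1e-10) {
    lp <- .cell_loglik(cut, des$to, eta_fix)$logp
    ll_site <- rowsum(lp, site)[, 1L]
    return(structure(sum(ll_site), by_site = ll_site))
  }

  eps0 <- if (!is.null(cache)) cache$eps else NULL
  if (!is.null(eps0) && length(eps0) != n_sites) eps0 <- NULL
  m <- .site_modes(cut, des$to, eta_fix, site, n_sites, sigma, eps0)
  if (!is.null(cache)) cache$eps <- m$eps
  s_hat <- sqrt(-1 / m$hpp)

  if (quadrature == "laplace") {
    ll_site <- m$h + 0.5 * log(2 * pi) + log(s_hat)
    return(structure(sum(ll_site), by_site = ll_site))
  }

  gh <- .gh_rule(nodes)
  G <- length(gh$x)
  eps_nodes <- m$eps + sqrt(2) * s_hat %o% gh$x          # n_sites x G
  eta_mat <- eta_fix + eps_nodes[site, , drop = FALSE]   # n x G
  lp <- .cell_loglik(cut, des$to, eta_mat)$logp
  H <- rowsum(lp, site) + dnorm(eps_nodes, 0, sigma, log = TRUE)
  A <- H + matrix(log(gh$w) + gh$x^2, n_sites, G, byrow = TRUE)
  Amax <- apply(A, 1L, max)
  ll_site <- Amax + log(rowSums(exp(A - Amax))) + log(sqrt(2) * s_hat)
  structure(sum(ll_site), by_site = ll_site)
}

# Objective factory for the optimizer: negative marginal log-likelihood and
# its gradient on the internal scale (t1, ld2, ld3, alpha, beta, lsig). The
# gradient integrates d h / d theta over the same adaptive quadrature nodes
# as the likelihood (node positions treated as fixed), which matches the
# exact marginal gradient up to quadrature error; fn and gr share one
# evaluation through a small memo, and per-site modes are cached across
# calls to shorten the Newton iteration.
.make_objective <- function(des, spec, sigma_fixed, nm) {
  cache <- new.env(parent = emptyenv())
  memo <- new.env(parent = emptyenv())
  site <- as.integer(des$site)
  n_sites <- nlevels(des$site)
  estimate_sigma <- is.null(sigma_fixed)
  has_alpha <- "prev_coverage" %in% spec$terms
  n <- des$n
  from_mask <- lapply(1:3, function(i) des$from == i)
  up_mask <- lapply(1:3, function(j) des$to == j - 1L)   # upper cut = c_j
  low_mask <- lapply(1:3, function(j) des$to == j)       # lower cut = c_j

  eval_both <- function(theta) {
    th <- setNames(theta, nm)
    p <- .theta_unpack(th, spec, sigma_fixed)
    cut <- p$cut; sigma <- p$sigma
    eta_fix <- c(0, p$alpha)[des$from + 1L]
    if (ncol(des$X)) eta_fix <- eta_fix + as.vector(des$X %*% p$beta)

    if (sigma < 1e-10) {
      cl <- .cell_loglik(cut, des$to, eta_fix, derivs = TRUE)
      ll <- sum(cl$logp)
      V <- 1
      gbar <- cl$g
      wa_bar <- cl$wa
      wb_bar <- cl$wb
      grad_lsig <- NULL
    } else {
      eps0 <- cache$eps
      if (!is.null(eps0) && length(eps0) != n_sites) eps0 <- NULL
      m <- .site_modes(cut, des$to, eta_fix, site, n_sites, sigma, eps0)
      cache$eps <- m$eps
      s_hat <- sqrt(-1 / m$hpp)
      gh <- if (spec$quadrature == "laplace") list(x = 0, w = sqrt(pi))
            else .gh_rule(spec$nodes)
      G <- length(gh$x)
      eps_nodes <- m$eps + sqrt(2) * s_hat %o% gh$x
      eta_mat <- eta_fix + eps_nodes[site, , drop = FALSE]
      cl <- .cell_loglik(cut, des$to, eta_mat, derivs = TRUE)
      H <- rowsum(cl$logp, site) + dnorm(eps_nodes, 0, sigma, log = TRUE)
      A <- H + matrix(log(gh$w) + gh$x^2, n_sites, G, byrow = TRUE)
      Amax <- apply(A, 1L, max)
      lse <- log(rowSums(exp(A - Amax)))
      ll <- sum(Amax + lse + log(sqrt(2) * s_hat))
      W <- exp(A - Amax - lse)                       # posterior node weights
      V <- W[site, , drop = FALSE]
      gbar <- rowSums(V * cl$g)
      wa_bar <- rowSums(V * cl$wa)
      wb_bar <- rowSums(V * cl$wb)
      grad_lsig <- if (estimate_sigma)
        sum(W * (eps_nodes^2 / sigma^2 - 1)) else NULL
    }
    if (!is.finite(ll))
      return(list(value = 1e10, grad = rep(0, length(nm))))

    dc <- vapply(1:3, function(j)
      sum(wa_bar[up_mask[[j]]]) - sum(wb_bar[low_mask[[j]]]), numeric(1))
    grad <- setNames(numeric(length(nm)), nm)
    grad[["t1"]] <- sum(dc)
    grad[["ld2"]] <- exp(th[["ld2"]]) * (dc[2L] + dc[3L])
    grad[["ld3"]] <- exp(th[["ld3"]]) * dc[3L]
    if (has_alpha)
      grad[c("Lv1", "Lv2", "Lv3")] <-
        vapply(from_mask, function(mk) sum(gbar[mk]), numeric(1))
    cn <- .coef_names(spec)
    if (length(cn)) grad[cn] <- as.vector(crossprod(des$X, gbar))
    if (estimate_sigma) grad[["lsig"]] <- grad_lsig
    list(value = -ll, grad = -grad)
  }

  fn <- function(theta) {
    key <- paste(format(theta, digits = 17), collapse = ",")
    if (identical(memo$key, key)) return(memo$res$value)
    res <- eval_both(theta)
    memo$key <- key; memo$res <- res
    res$value
  }
  gr <- function(theta) {
    key <- paste(format(theta, digits = 17), collapse = ",")
    if (identical(memo$key, key)) return(memo$res$grad)
    res <- eval_both(theta)
    memo$key <- key; memo$res <- res
    res$grad
  }
  list(fn = fn, gr = gr)
}

#' Marginal log-likelihood of a transition model
#'
#' Integrates the site random intercept out of the multinomial transition
#' likelihood, site by site. Applied to the pairs of a single site this is
#' the site-level marginal log-likelihood
#' `log int prod_k p_k(eps) N(eps; 0, sigma^2) d eps`; summing over sites
#' gives the objective maximized by [fit_transition_model()]. With
#' `sigma = 0` it degenerates exactly to the conditional log-likelihood at
#' `eps = 0`.
#'
#' @param model a `weed_clmm` object supplying the parameter values.
#' @param pairs a `weed_pairs` data frame (one or several sites).
#' @param quadrature,nodes override the model spec's integration settings.
#' @return total log-likelihood (numeric scalar) with attribute `by_site`.
#' @export
marginal_loglik <- function(model, pairs, quadrature = NULL, nodes = NULL) {
  spec <- model$spec
  if (!is.null(quadrature)) spec$quadrature <- quadrature
  if (!is.null(nodes)) spec$nodes <- as.integer(nodes)
  des <- encode_design(pairs, spec)
  .marginal_loglik(unname(model$thresholds), unname(model$alpha),
                   .model_beta(model, spec), model$sigma, des,
                   quadrature = spec$quadrature, nodes = spec$nodes)
}

# coefficient vector aligned to the spec's design columns (zeros for terms
# the model object does not carry)
.model_beta <- function(model, spec) {
  nm <- .coef_names(spec)
  beta <- setNames(numeric(length(nm)), nm)
  keep <- intersect(nm, names(model$coefs))
  beta[keep] <- model$coefs[keep]
  beta
}
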