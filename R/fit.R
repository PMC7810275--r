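# Marginal maximum-likelihood fitting of the mixed cumulative-link
# transition model, plus AIC-based backward selection.

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- internal parameterization -------------------------------------------
# theta = (t1, ld2, ld3 [, alpha1..3] [, beta...] [, lsig])
# Cutpoints are t1, t1 + exp(ld2), t1 + exp(ld2) + exp(ld3), so the strict
# threshold ordering holds at every optimizer iterate by construction;
# sigma is exp(lsig) when estimated.

.theta_names <- function(spec, estimate_sigma) {
  c("t1", "ld2", "ld3",
    if ("prev_coverage" %in% spec$terms) c("Lv1", "Lv2", "Lv3"),
    .coef_names(spec),
    if (estimate_sigma) "lsig")
}

.theta_unpack <- function(theta, spec, sigma_fixed = NULL) {
  cut <- cumsum(c(theta[["t1"]], exp(theta[["ld2"]]), exp(theta[["ld3"]])))
  alpha <- if ("prev_coverage" %in% spec$terms)
    unname(theta[c("Lv1", "Lv2", "Lv3")]) else c(0, 0, 0)
  nm <- .coef_names(spec)
  beta <- if (length(nm)) unname(theta[nm]) else numeric(0)
  sigma <- if (is.null(sigma_fixed)) exp(theta[["lsig"]]) else sigma_fixed
  list(cut = cut, alpha = alpha, beta = beta, sigma = sigma)
}

.num_grad <- function(fn, theta, h = 1e-4) {
  vapply(seq_along(theta), function(i) {
    hi <- h * max(1, abs(theta[i]))
    tp <- theta; tp[i] <- tp[i] + hi
    tm <- theta; tm[i] <- tm[i] - hi
    (fn(tp) - fn(tm)) / (2 * hi)
  }, numeric(1))
}

.start_heuristic <- function(des, spec, estimate_sigma, lsig = 0) {
  cf <- vapply(0:2, function(j) mean(des$to <= j), numeric(1))
  cf <- pmin(pmax(cf, 0.02), 0.98)
  cf <- cummax(cf + c(0, 1e-3, 2e-3))          # enforce strict increase
  cut <- qlogis(pmin(cf, 0.985))
  theta <- setNames(numeric(length(.theta_names(spec, estimate_sigma))),
                    .theta_names(spec, estimate_sigma))
  theta[["t1"]] <- cut[1L]
  theta[["ld2"]] <- log(max(cut[2L] - cut[1L], 0.1))
  theta[["ld3"]] <- log(max(cut[3L] - cut[2L], 0.1))
  if (estimate_sigma) theta[["lsig"]] <- lsig
  theta
}

.theta_bounds <- function(nm) {
  lower <- setNames(rep(-25, length(nm)), nm)
  upper <- setNames(rep(25, length(nm)), nm)
  lower[c("t1")] <- -30; upper[c("t1")] <- 30
  lower[c("ld2", "ld3")] <- -8; upper[c("ld2", "ld3")] <- 4
  if ("lsig" %in% nm) { lower[["lsig"]] <- -7; upper[["lsig"]] <- 2.5 }
  list(lower = lower, upper = upper)
}

#' Fit the mixed cumulative-link transition model
#'
#' Maximizes the total marginal log-likelihood (random intercept integrated
#' out per site, see [marginal_loglik()]) over thresholds, previous-coverage
#' effects, covariate coefficients and `log sigma`, using L-BFGS-B with
#' central-difference gradients from several deterministic start points:
#' a warm start at the fixed-effects (`sigma = 0`) optimum, a frequency-based
#' null start, and a jittered copy of it. The best final value wins, so
#' repeated calls are reproducible bit for bit.
#'
#' Coefficients larger than 10 in magnitude are reported as quasi-separated
#' (typical for land uses under which the outcome is deterministic in the
#' data, e.g. paddy rice); they are returned as-is since projections only
#' need the saturated probabilities.
#'
#' @param pairs a `weed_pairs` data frame ([transition_pairs()]).
#' @param spec a [model_spec()] naming the terms and quadrature.
#' @param sigma_fixed fix the random-intercept SD at this value instead of
#'   estimating it (0 gives the plain fixed-effects proportional-odds fit).
#' @param start optional named start vector on the internal scale
#'   (overrides the multi-start strategy).
#' @param n_starts number of start points to use, 1-3 (default 3; use 1 for
#'   large simulation studies, which then rely on the warm start only).
#' @param control list: `maxit` (default 300), `factr` (1e7), `grad_tol`
#'   (1e-3; exceeding it appends a warning, it does not flip `converged`).
#' @return a `weed_clmm` object: named `thresholds`, `alpha`, `coefs`,
#'   `sigma`, `loglik`, `n_params`, `aic`, `converged`, `grad_norm`,
#'   `warnings`, `se`/`vcov` on the natural scale, `nobs`, `n_sites`.
#' @export
fit_transition_model <- function(pairs, spec = model_spec(),
                                 sigma_fixed = NULL, start = NULL,
                                 n_starts = 3L, control = list()) {
  if (!nrow(pairs)) stop("no transition pairs to fit")
  if (!is.null(sigma_fixed) && sigma_fixed < 0)
    stop("sigma must be >= 0 (it is parameterized internally as log sigma)")
  des <- encode_design(pairs, spec)
  estimate_sigma <- is.null(sigma_fixed)
  nm <- .theta_names(spec, estimate_sigma)
  obj <- .make_objective(des, spec, sigma_fixed, nm)
  negll <- obj$fn
  grad <- obj$gr

  starts <- if (!is.null(start)) {
    list(setNames(start[nm], nm))
  } else {
    base <- .start_heuristic(des, spec, estimate_sigma)
    s <- list()
    if (estimate_sigma) {
      warm <- fit_transition_model(pairs, spec, sigma_fixed = 0,
                                   start = .start_heuristic(des, spec, FALSE),
                                   control = control)
      w <- setNames(numeric(length(nm)), nm)
      w[["t1"]] <- warm$thresholds[[1L]]
      w[["ld2"]] <- log(max(diff(warm$thresholds)[1L], 1e-3))
      w[["ld3"]] <- log(max(diff(warm$thresholds)[2L], 1e-3))
      if ("prev_coverage" %in% spec$terms)
        w[c("Lv1", "Lv2", "Lv3")] <- unname(warm$alpha)
      cn <- .coef_names(spec)
      if (length(cn)) w[cn] <- unname(warm$coefs[cn])
      w[["lsig"]] <- log(0.5)
      s <- c(s, list(w))
    }
    s <- c(s, list(base),
           list(base + 0.3 * sin(1.7 * seq_along(base))))
    s[seq_len(min(n_starts, length(s)))]
  }

  b <- .theta_bounds(nm)
  runs <- lapply(starts, function(s0) {
    s0 <- pmin(pmax(s0, b$lower + 1e-6), b$upper - 1e-6)
    tryCatch(
      optim(s0, negll, gr = grad, method = "L-BFGS-B",
            lower = b$lower, upper = b$upper,
            control = list(maxit = control$maxit %||% 500L,
                           factr = control$factr %||% 1e6)),
      error = function(e)
        optim(s0, negll, method = "Nelder-Mead",
              control = list(maxit = 2000L))
    )
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]

  # gradient norm over interior coordinates only: at an active box bound
  # (the quasi-separated case) the projected gradient need not vanish
  grad_norm <- function(par) {
    interior <- par > b$lower + 1e-6 & par < b$upper - 1e-6
    sqrt(sum(.num_grad(negll, par)[interior]^2))
  }
  gn <- grad_norm(best$par)
  if (best$convergence != 0 || gn > (control$grad_tol %||% 1e-3)) {
    # polish with finite-difference gradients if the run stalled short of a
    # stationary point
    polish <- tryCatch(
      optim(best$par, negll, gr = function(t) .num_grad(negll, t),
            method = "L-BFGS-B", lower = b$lower, upper = b$upper,
            control = list(maxit = 200L, factr = 10)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$value) {
      best$par <- polish$par
      best$value <- polish$value
      gn <- grad_norm(best$par)
      # a stationary point is a converged fit no matter which run found it
      if (gn <= (control$grad_tol %||% 1e-3)) best$convergence <- 0
    }
  }
  theta <- setNames(best$par, nm)
  p <- .theta_unpack(theta, spec, sigma_fixed)
  warn <- character(0)
  if (best$convergence != 0)
    warn <- c(warn, paste0("optimizer did not report convergence (code ",
                           best$convergence, ")"))
  if (gn > (control$grad_tol %||% 1e-3))
    warn <- c(warn, sprintf("gradient norm %.2e above tolerance", gn))
  sep <- abs(c(p$alpha, p$beta)) > 10
  if (any(sep))
    warn <- c(warn, paste0("quasi-separated coefficient(s): ",
                           paste(c(if ("prev_coverage" %in% spec$terms)
                             c("Lv1", "Lv2", "Lv3") else character(3),
                             .coef_names(spec))[sep], collapse = ", ")))
  if ("prev_coverage" %in% spec$terms) {
    a <- c(0, p$alpha)
    if (!(all(diff(a) > 0) || all(diff(a) < 0)))
      warn <- c(warn, "previous-coverage effects are not monotone in level")
  }
  if (estimate_sigma && theta[["lsig"]] <= -6.9)
    warn <- c(warn, "sigma estimated at the boundary (effectively 0)")

  # observed-information covariance, mapped to the natural scale
  vc <- se <- NULL
  H <- tryCatch(optimHess(theta, negll, gr = grad), error = function(e) NULL)
  if (!is.null(H)) {
    Vint <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vint)) {
      J <- diag(length(nm))
      dimnames(J) <- list(nm, nm)
      J["t1", "t1"] <- 1
      J["ld2", "ld2"] <- 0; J["ld3", "ld3"] <- 0
      # rows for cutpoints 2 and 3 overwrite the ld rows
      J["ld2", c("t1", "ld2")] <- c(1, exp(theta[["ld2"]]))
      J["ld3", c("t1", "ld2", "ld3")] <-
        c(1, exp(theta[["ld2"]]), exp(theta[["ld3"]]))
      if (estimate_sigma) J["lsig", "lsig"] <- p$sigma
      vc <- J %*% Vint %*% t(J)
      natural <- c("Lv0|Lv1", "Lv1|Lv2", "Lv2|Lv3",
                   nm[!(nm %in% c("t1", "ld2", "ld3", "lsig"))],
                   if (estimate_sigma) "sigma")
      dimnames(vc) <- list(natural, natural)
      se <- sqrt(pmax(diag(vc), 0))
    }
  }

  n_params <- length(theta)
  ll <- -best$value
  out <- structure(list(
    thresholds = setNames(p$cut, c("Lv0|Lv1", "Lv1|Lv2", "Lv2|Lv3")),
    alpha = setNames(p$alpha, c("Lv1", "Lv2", "Lv3")),
    coefs = setNames(p$beta, .coef_names(spec)),
    sigma = unname(p$sigma),
    loglik = ll, n_params = n_params,
    aic = -2 * ll + 2 * n_params,
    converged = best$convergence == 0,
    grad_norm = gn, warnings = warn,
    spec = spec, se = se, vcov = vc,
    nobs = des$n, n_sites = nlevels(des$site),
    sigma_fixed = sigma_fixed, theta = theta
  ), class = "weed_clmm")
  out
}

#' @export
logLik.weed_clmm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$nobs,
            class = "logLik")
}

#' @export
nobs.weed_clmm <- function(object, ...) object$nobs

#' @export
print.weed_clmm <- function(x, digits = 3, ...) {
  cat("Mixed cumulative-link transition model\n")
  cat("  terms:", paste(x$spec$terms, collapse = ", "), "\n")
  cat("  thresholds:", paste(names(x$thresholds),
                             round(x$thresholds, digits), collapse = "  "),
      "\n")
  if ("prev_coverage" %in% x$spec$terms)
    cat("  prev coverage:", paste(names(x$alpha), round(x$alpha, digits),
                                  collapse = "  "), "\n")
  if (length(x$coefs))
    cat("  coefficients:", paste(names(x$coefs), round(x$coefs, digits),
                                 collapse = "  "), "\n")
  cat("  sigma:", round(x$sigma, digits), "\n")
  if (is.finite(x$loglik))
    cat(sprintf("  logLik %.3f  AIC %.2f  (%d params, %d pairs, %d sites)\n",
                x$loglik, x$aic, x$n_params, x$nobs, x$n_sites))
  if (isFALSE(x$converged)) cat("  ** fit did not converge **\n")
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}

#' Backward model selection by AIC
#'
#' Starting from `full_spec`, repeatedly drops the single term whose removal
#' most lowers the AIC until no removal lowers it; AIC ties (within 1e-6)
#' are resolved toward the model with fewer parameters, i.e. the term is
#' dropped. The ladder of every candidate evaluated along the way is kept so
#' the whole comparison table can be reconstructed. Candidates whose fit
#' fails are recorded and excluded with a warning.
#'
#' @param pairs a `weed_pairs` data frame.
#' @param full_spec the starting [model_spec()].
#' @inheritParams fit_transition_model
#' @return a `weed_selection` list: `best` (the winning `weed_clmm`),
#'   `best_spec`, `ladder` (data frame: step, terms, dropped, n_params,
#'   loglik, aic, converged), and `fits` (all fitted candidates, named by
#'   their term sets).
#' @export
backward_select <- function(pairs, full_spec = model_spec(),
                            n_starts = 3L, control = list()) {
  key <- function(terms) paste(terms, collapse = "+")
  fits <- list()
  ladder <- list()
  step <- 0L
  record <- function(fit, dropped) {
    ladder[[length(ladder) + 1L]] <<- data.frame(
      step = step, terms = key(fit$spec$terms), dropped = dropped,
      n_params = fit$n_params, loglik = fit$loglik, aic = fit$aic,
      converged = fit$converged, stringsAsFactors = FALSE)
    fits[[key(fit$spec$terms)]] <<- fit
  }

  current <- fit_transition_model(pairs, full_spec, n_starts = n_starts,
                                  control = control)
  record(current, dropped = "")
  repeat {
    terms <- current$spec$terms
    if (!length(terms)) break
    step <- step + 1L
    cands <- list()
    for (tm in terms) {
      sp <- full_spec
      sp$terms <- setdiff(terms, tm)
      fit <- tryCatch(
        fit_transition_model(pairs, sp, n_starts = n_starts,
                             control = control),
        error = function(e) e)
      if (inherits(fit, "error")) {
        warning("candidate dropping '", tm, "' failed: ",
                conditionMessage(fit))
        next
      }
      record(fit, dropped = tm)
      if (!fit$converged) {
        warning("candidate dropping '", tm,
                "' did not converge; excluded from selection")
        next
      }
      cands[[tm]] <- fit
    }
    if (!length(cands)) break
    aics <- vapply(cands, `[[`, numeric(1), "aic")
    nps <- vapply(cands, `[[`, numeric(1), "n_params")
    ord <- order(round(aics / 1e-6), nps, names(cands))
    winner <- cands[[ord[1L]]]
    if (winner$aic < current$aic - 1e-6 ||
        abs(winner$aic - current$aic) <= 1e-6) {
      current <- winner
    } else break
  }
  structure(list(best = current, best_spec = current$spec,
                 ladder = do.call(rbind, ladder), fits = fits),
            class = "weed_selection")
}

#' @export
print.weed_selection <- function(x, ...) {
  cat("Backward AIC selection (", nrow(x$ladder), " candidates)\n", sep = "")
  print(x$ladder[, c("step", "terms", "dropped", "n_params", "aic")],
        row.names = FALSE)
  cat("best:", paste(x$best$spec$terms, collapse = ", "),
      sprintf(" AIC %.2f\n", x$best$aic))
  invisible(x)
}

#' Export a selection ladder as a coefficient comparison table
#'
#' One row per evaluated candidate, one column per possible coefficient,
#' blank cells for terms the candidate excludes; mirrors the conventional
#' layout of ordinal-regression model-comparison tables.
#'
#' @param sel a `weed_selection` from [backward_select()].
#' @param path output CSV path, or `NULL` to just return the table.
#' @return the table as a data frame (invisibly when written).
#' @export
selection_table <- function(sel, path = NULL) {
  cols <- c("Lv1", "Lv2", "Lv3", "irrigation", "delayed_sowing",
            .land_use_dummies(), "temperature",
            "Lv0|Lv1", "Lv1|Lv2", "Lv2|Lv3", "AIC")
  rows <- lapply(sel$fits, function(f) {
    r <- setNames(rep(NA_real_, length(cols)), cols)
    if ("prev_coverage" %in% f$spec$terms) r[c("Lv1", "Lv2", "Lv3")] <- f$alpha
    r[names(f$coefs)] <- f$coefs
    r[c("Lv0|Lv1", "Lv1|Lv2", "Lv2|Lv3")] <- f$thresholds
    r["AIC"] <- f$aic
    r
  })
  tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  tab <- tab[order(tab$AIC), , drop = FALSE]
  if (!is.null(path)) {
    out <- tab
    out[] <- lapply(out, function(v) ifelse(is.na(v), "", format(round(v, 2))))
    utils::write.csv(cbind(model = rownames(tab), out), path,
                     row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}
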