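#' Define a transition-model specification
#'
#' A specification names the fixed-effect terms to include and the
#' integration method for the site-level random intercept (which is always
#' present; fix `sigma` at 0 in [fit_transition_model()] to drop it).
#'
#' @param terms character subset of `"prev_coverage"`, `"irrigation"`,
#'   `"delayed_sowing"`, `"land_use"`, `"temperature"`.
#' @param quadrature `"agq"` (adaptive Gauss-Hermite, the default) or
#'   `"laplace"`.
#' @param nodes odd number of quadrature nodes for `"agq"` (default 15).
#' @return a `weed_model_spec` list.
#' @export
model_spec <- function(terms = .all_terms(),
                       quadrature = c("agq", "laplace"),
                       nodes = 15L) {
  quadrature <- match.arg(quadrature)
  unknown <- setdiff(terms, .all_terms())
  if (length(unknown))
    stop("unknown model term(s): ", paste(unknown, collapse = ", "))
  nodes <- as.integer(nodes)
  if (nodes < 1L || nodes %% 2L == 0L)
    stop("nodes must be a positive odd integer")
  structure(list(terms = intersect(.all_terms(), terms),
                 quadrature = quadrature, nodes = nodes),
            class = "weed_model_spec")
}

# fixed-effect coefficient names implied by a spec (excludes prev_coverage,
# which is handled as the alpha block)
.coef_names <- function(spec) {
  nm <- character(0)
  if ("irrigation" %in% spec$terms) nm <- c(nm, "irrigation")
  if ("delayed_sowing" %in% spec$terms) nm <- c(nm, "delayed_sowing")
  if ("land_use" %in% spec$terms) nm <- c(nm, .land_use_dummies())
  if ("temperature" %in% spec$terms) nm <- c(nm, "temperature")
  nm
}

#' Encode transition pairs as a fixed-effect design
#'
#' Treatment coding throughout: land use is expanded into five dummies with
#' "wheat" as baseline, previous coverage is kept as an index (its effect is
#' the alpha block with level 0 as baseline, coded separately from the
#' design matrix), temperature enters raw in degrees C, uncentered.
#'
#' @param pairs a `weed_pairs` data frame (a single row works too).
#' @param spec a [model_spec()].
#' @return list with `X` (n x p fixed-effect matrix, p possibly 0), `from`
#'   and `to` (integer levels 0-3), `site` (factor), and `n`.
#' @export
encode_design <- function(pairs, spec = model_spec()) {
  n <- nrow(pairs)
  cols <- list()
  if ("irrigation" %in% spec$terms)
    cols$irrigation <- as.numeric(pairs$irrigation)
  if ("delayed_sowing" %in% spec$terms)
    cols$delayed_sowing <- as.numeric(pairs$delayed_sowing)
  if ("land_use" %in% spec$terms)
    for (lu in .land_use_dummies())
      cols[[lu]] <- as.numeric(pairs$land_use == lu)
  if ("temperature" %in% spec$terms) {
    if (anyNA(pairs$temp_dec_apr)) {
      i <- which(is.na(pairs$temp_dec_apr))[1L]
      stop("temperature term requested but temp_dec_apr is missing for site ",
           pairs$site_id[i], ", year ", pairs$year[i])
    }
    cols$temperature <- as.numeric(pairs$temp_dec_apr)
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = n, ncol = 0)
  list(X = X, from = as.integer(pairs$from_level),
       to = as.integer(pairs$to_level),
       site = factor(pairs$site_id), n = n)
}

#' Construct a transition model from known coefficients
#'
#' Builds the same object that [fit_transition_model()] returns, but from
#' user-supplied parameter values (for simulation truth, projection from
#' published estimates, or toy examples). Likelihood-dependent fields are
#' `NA`.
#'
#' @param thresholds strictly increasing numeric 3-vector of cutpoints on
#'   the logit scale (level 0|1, 1|2, 2|3).
#' @param alpha numeric 3-vector: effect of previous-year coverage levels
#'   1-3 (level 0 is the baseline, fixed at 0). Use `c(0, 0, 0)` for a model
#'   without previous-coverage dependence.
#' @param coefs named numeric vector of fixed-effect coefficients; valid
#'   names are `irrigation`, `delayed_sowing`, the five non-wheat land-use
#'   tokens, and `temperature`. Omitted terms are treated as absent.
#' @param sigma random-intercept standard deviation (>= 0).
#' @return a `weed_clmm` object.
#' @export
#' @examples
#' m <- transition_model(c(-1, 0, 1))
#' transition_probs(m, from_level = 0)
transition_model <- function(thresholds, alpha = c(0, 0, 0),
                             coefs = numeric(0), sigma = 0) {
  stopifnot(length(thresholds) == 3L, all(diff(thresholds) > 0),
            length(alpha) == 3L, sigma >= 0)
  valid <- c("irrigation", "delayed_sowing", .land_use_dummies(),
             "temperature")
  if (length(coefs)) {
    if (is.null(names(coefs)) || !all(names(coefs) %in% valid))
      stop("coefs must be named from: ", paste(valid, collapse = ", "))
  }
  terms <- character(0)
  if (any(alpha != 0)) terms <- "prev_coverage"
  if ("irrigation" %in% names(coefs)) terms <- c(terms, "irrigation")
  if ("delayed_sowing" %in% names(coefs)) terms <- c(terms, "delayed_sowing")
  if (any(.land_use_dummies() %in% names(coefs))) terms <- c(terms, "land_use")
  if ("temperature" %in% names(coefs)) terms <- c(terms, "temperature")
  structure(list(
    thresholds = setNames(as.numeric(thresholds),
                          c("Lv0|Lv1", "Lv1|Lv2", "Lv2|Lv3")),
    alpha = setNames(as.numeric(alpha), c("Lv1", "Lv2", "Lv3")),
    coefs = if (length(coefs)) coefs[order(match(names(coefs), valid))]
            else setNames(numeric(0), character(0)),
    sigma = as.numeric(sigma),
    loglik = NA_real_, n_params = NA_integer_, aic = NA_real_,
    converged = NA, grad_norm = NA_real_, warnings = character(0),
    spec = model_spec(terms = unique(c(terms,
      if (any(alpha != 0)) "prev_coverage"))),
    se = NULL, vcov = NULL, nobs = NA_integer_, n_sites = NA_integer_
  ), class = "weed_clmm")
}

# linear predictor of one covariate profile under a model (excluding alpha
# and epsilon): beta . x with x built from the profile
.profile_eta <- function(model, profile) {
  cf <- model$coefs
  if (!length(cf)) return(0)
  x <- setNames(numeric(length(cf)), names(cf))
  if ("irrigation" %in% names(cf)) x["irrigation"] <- profile$irrigation
  if ("delayed_sowing" %in% names(cf))
    x["delayed_sowing"] <- profile$delayed_sowing
  for (lu in intersect(.land_use_dummies(), names(cf)))
    x[lu] <- as.numeric(profile$land_use == lu)
  if ("temperature" %in% names(cf)) {
    if (is.na(profile$temp_dec_apr))
      stop("model includes temperature but the profile has no temp_dec_apr")
    x["temperature"] <- profile$temp_dec_apr
  }
  sum(cf * x)
}
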