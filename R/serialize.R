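# JSON serialization of fitted models (17 significant digits, so a write /
# read round trip reproduces every double bit for bit).

#' Serialize a transition model to JSON
#'
#' @param model a `weed_clmm` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_model_json()]
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    thresholds = as.list(model$thresholds),
    alpha = as.list(model$alpha),
    coefs = as.list(model$coefs),
    sigma = model$sigma,
    loglik = model$loglik, n_params = model$n_params, aic = model$aic,
    converged = model$converged, grad_norm = model$grad_norm,
    warnings = model$warnings,
    terms = model$spec$terms,
    quadrature = model$spec$quadrature, nodes = model$spec$nodes,
    nobs = model$nobs, n_sites = model$n_sites
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Read a transition model from JSON
#'
#' @param path file written by [write_model_json()].
#' @return a `weed_clmm` object.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  spec <- model_spec(terms = as.character(obj$terms %||% character(0)),
                     quadrature = obj$quadrature %||% "agq",
                     nodes = obj$nodes %||% 15L)
  structure(list(
    thresholds = unlist(obj$thresholds),
    alpha = unlist(obj$alpha),
    coefs = if (length(obj$coefs)) unlist(obj$coefs)
            else setNames(numeric(0), character(0)),
    sigma = num(obj$sigma),
    loglik = num(obj$loglik),
    n_params = if (is.null(obj$n_params)) NA_integer_
               else as.integer(obj$n_params),
    aic = num(obj$aic),
    converged = obj$converged %||% NA,
    grad_norm = num(obj$grad_norm),
    warnings = as.character(obj$warnings %||% character(0)),
    spec = spec, se = NULL, vcov = NULL,
    nobs = if (is.null(obj$nobs)) NA_integer_ else as.integer(obj$nobs),
    n_sites = if (is.null(obj$n_sites)) NA_integer_
              else as.integer(obj$n_sites)
  ), class = "weed_clmm")
}
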