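#' Coverage levels and farmland-use tokens
#'
#' The ordinal coverage scale has four states: 0 = "absent" (0% cover),
#' 1 = "low" (<20%), 2 = "medium" (20-50%), 3 = "high" (>50%). Farmland use
#' is a closed six-category factor with "wheat" as the reference category.
#'
#' @return `coverage_levels()` returns a data frame with columns `value`
#'   (0-3) and `label`; `land_use_levels()` returns the six valid tokens in
#'   their conventional order (baseline first).
#' @export
#' @examples
#' coverage_levels()
#' land_use_levels()
coverage_levels <- function() {
  data.frame(
    value = 0:3,
    label = c("absent", "low", "medium", "high"),
    stringsAsFactors = FALSE
  )
}

#' @rdname coverage_levels
#' @export
land_use_levels <- function() {
  c("wheat", "barley", "other_crop", "paddy_rice",
    "fallow_managed", "fallow_unmanaged")
}

#' @rdname coverage_levels
#' @param value integer vector of coverage values in 0:3
#' @export
coverage_label <- function(value) {
  stopifnot(all(value %in% 0:3))
  c("absent", "low", "medium", "high")[value + 1L]
}

# non-baseline land uses, i.e. the dummy columns of the design matrix
.land_use_dummies <- function() land_use_levels()[-1L]

# names of all candidate model terms
.all_terms <- function() {
  c("prev_coverage", "irrigation", "delayed_sowing", "land_use",
    "temperature")
}
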