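#' Read a longitudinal coverage survey from CSV
#'
#' Reads one row per site-by-year observation. Mandatory columns are
#' `site_id`, `year`, `coverage`, `land_use`, `irrigation`, `delayed_sowing`;
#' `temp_dec_apr` (mean December-April temperature, degrees C) is optional.
#' The file must be comma-separated UTF-8 with a header row, "." as the
#' decimal point and binary columns coded 0/1.
#'
#' Rows that fail validation (coverage outside 0-3, unknown land-use token,
#' non-binary indicator, year outside 1900-2100) are dropped and collected in
#' the `"rejected"` attribute of the result rather than aborting the read.
#' A missing mandatory column or a duplicated (site, year) key is fatal.
#'
#' @param path path to the CSV file.
#' @param column_map optional named character vector renaming file columns to
#'   the canonical names, e.g. `c(site_id = "Site ID")` means the file column
#'   "Site ID" holds `site_id`.
#' @return a `weed_survey` data frame with canonical columns, one row per
#'   observation, with attributes `rejected` (data frame of dropped rows and
#'   reasons) and `source` (the file path).
#' @seealso [validate_survey()], [transition_pairs()], [write_survey()]
#' @export
read_survey <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      file_col <- column_map[[canon]]
      if (!file_col %in% names(raw))
        stop("mapped column not found in file: ", file_col)
      names(raw)[names(raw) == file_col] <- canon
    }
  }
  mandatory <- c("site_id", "year", "coverage", "land_use",
                 "irrigation", "delayed_sowing")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  if (!"temp_dec_apr" %in% names(raw)) raw$temp_dec_apr <- NA_real_

  df <- data.frame(
    site_id = as.character(raw$site_id),
    year = suppressWarnings(as.integer(raw$year)),
    coverage = suppressWarnings(as.integer(raw$coverage)),
    land_use = as.character(raw$land_use),
    irrigation = suppressWarnings(as.integer(raw$irrigation)),
    delayed_sowing = suppressWarnings(as.integer(raw$delayed_sowing)),
    temp_dec_apr = suppressWarnings(as.numeric(raw$temp_dec_apr)),
    stringsAsFactors = FALSE
  )
  as_weed_survey(df, source = path)
}

#' Construct a weed_survey from a data frame
#'
#' Applies the row-level validation rules of [read_survey()] to an in-memory
#' data frame. Invalid rows are dropped into the `"rejected"` attribute;
#' duplicated (site, year) keys abort.
#'
#' @param df data frame with the canonical survey columns.
#' @param source optional provenance string stored on the result.
#' @return a `weed_survey` data frame.
#' @export
as_weed_survey <- function(df, source = NA_character_) {
  reasons <- character(nrow(df))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reasons[cond & !nzchar(reasons)] <<- why
  }
  bad(!is.finite(df$year) | df$year < 1900L | df$year > 2100L,
      "year outside 1900-2100")
  bad(!(df$coverage %in% 0:3), "coverage outside 0-3")
  bad(!(df$land_use %in% land_use_levels()), "unknown land_use token")
  bad(!(df$irrigation %in% c(0L, 1L)), "irrigation not 0/1")
  bad(!(df$delayed_sowing %in% c(0L, 1L)), "delayed_sowing not 0/1")
  bad(is.na(df$site_id) | !nzchar(df$site_id), "empty site_id")

  rejected <- df[nzchar(reasons), , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reasons[nzchar(reasons)]
  ds <- df[!nzchar(reasons), , drop = FALSE]
  rownames(ds) <- NULL

  key <- paste(ds$site_id, ds$year, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (site_id, year) keys: ",
         paste(gsub("\r", "/", utils::head(dup, 5L)), collapse = ", "))
  }
  structure(ds,
            class = c("weed_survey", "data.frame"),
            rejected = rejected, source = source)
}

#' Write a survey or transition-pair table to CSV
#'
#' @param x a `weed_survey` or `weed_pairs` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Validate a survey dataset
#'
#' Pure report: the dataset is not modified. The report lists duplicate
#' (site, year) keys, within-site gaps in the observation years, unknown
#' land-use tokens, and the number of missing temperature values.
#'
#' @param ds a `weed_survey` data frame (or any data frame with the canonical
#'   columns).
#' @return a `weed_survey_report` list with elements `n_records`, `n_sites`,
#'   `empty`, `duplicates`, `gaps` (data frame site_id/from/to/gap),
#'   `unknown_land_use`, `n_missing_temp`, and `site_spans` (data frame
#'   site_id/first_year/last_year/n_obs).
#' @export
validate_survey <- function(ds) {
  rep <- list(
    n_records = nrow(ds),
    n_sites = length(unique(ds$site_id)),
    empty = nrow(ds) == 0L,
    duplicates = character(0),
    gaps = data.frame(site_id = character(0), from = integer(0),
                      to = integer(0), gap = integer(0),
                      stringsAsFactors = FALSE),
    unknown_land_use = setdiff(unique(ds$land_use), land_use_levels()),
    n_missing_temp = sum(is.na(ds$temp_dec_apr)),
    site_spans = data.frame(site_id = character(0), first_year = integer(0),
                            last_year = integer(0), n_obs = integer(0),
                            stringsAsFactors = FALSE)
  )
  if (rep$empty) {
    class(rep) <- "weed_survey_report"
    return(rep)
  }
  key <- paste(ds$site_id, ds$year, sep = "/")
  rep$duplicates <- unique(key[duplicated(key)])

  spans <- lapply(split(ds$year, ds$site_id), function(y) {
    y <- sort(unique(y))
    list(first = y[1L], last = y[length(y)], n = length(y), years = y)
  })
  rep$site_spans <- data.frame(
    site_id = names(spans),
    first_year = vapply(spans, `[[`, integer(1), "first"),
    last_year = vapply(spans, `[[`, integer(1), "last"),
    n_obs = vapply(spans, `[[`, integer(1), "n"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  gap_rows <- lapply(names(spans), function(s) {
    y <- spans[[s]]$years
    d <- diff(y)
    i <- which(d > 1L)
    if (!length(i)) return(NULL)
    data.frame(site_id = s, from = y[i], to = y[i + 1L], gap = d[i],
               stringsAsFactors = FALSE)
  })
  gap_rows <- gap_rows[!vapply(gap_rows, is.null, logical(1))]
  if (length(gap_rows)) rep$gaps <- do.call(rbind, gap_rows)
  class(rep) <- "weed_survey_report"
  rep
}

#' @export
print.weed_survey_report <- function(x, ...) {
  cat("Survey validation report\n")
  cat("  records:", x$n_records, " sites:", x$n_sites, "\n")
  if (x$empty) cat("  dataset is empty\n")
  if (length(x$duplicates))
    cat("  duplicate keys:", paste(x$duplicates, collapse = ", "), "\n")
  cat("  within-site year gaps:", nrow(x$gaps), "\n")
  if (length(x$unknown_land_use))
    cat("  unknown land_use tokens:",
        paste(x$unknown_land_use, collapse = ", "), "\n")
  cat("  missing temp_dec_apr:", x$n_missing_temp, "\n")
  invisible(x)
}

#' Build year-to-year transition pairs
#'
#' For each site, records are sorted by year and every couple of successive
#' observations at most `max_gap` years apart becomes one transition pair:
#' the earlier record supplies the source level, the later record supplies
#' the destination level *and all covariates* (management acts in the
#' destination year; summer irrigation refers to the summer preceding the
#' destination survey). Non-adjacent records never pair, so with the default
#' `max_gap = 1` a missing survey year breaks the chain rather than silently
#' bridging it.
#'
#' @param ds a `weed_survey` data frame.
#' @param max_gap maximum year difference allowed between the two records of
#'   a pair (default 1, i.e. consecutive years only).
#' @return a `weed_pairs` data frame with columns `site_id`, `year`
#'   (destination year), `gap`, `from_level`, `to_level`, `land_use`,
#'   `irrigation`, `delayed_sowing`, `temp_dec_apr`.
#' @export
transition_pairs <- function(ds, max_gap = 1L) {
  if (!is.numeric(max_gap) || max_gap < 1) stop("max_gap must be >= 1")
  max_gap <- as.integer(max_gap)
  ds <- as.data.frame(ds)
  ds <- ds[order(ds$site_id, ds$year), , drop = FALSE]
  out <- lapply(split(ds, ds$site_id), function(d) {
    if (nrow(d) < 2L) return(NULL)
    g <- diff(d$year)
    i <- which(g <= max_gap)          # index of source record in d
    if (!length(i)) return(NULL)
    data.frame(
      site_id = d$site_id[i],
      year = d$year[i + 1L],
      gap = g[i],
      from_level = d$coverage[i],
      to_level = d$coverage[i + 1L],
      land_use = d$land_use[i + 1L],
      irrigation = d$irrigation[i + 1L],
      delayed_sowing = d$delayed_sowing[i + 1L],
      temp_dec_apr = d$temp_dec_apr[i + 1L],
      stringsAsFactors = FALSE
    )
  })
  out <- out[!vapply(out, is.null, logical(1))]
  pairs <- if (length(out)) do.call(rbind, out) else data.frame(
    site_id = character(0), year = integer(0), gap = integer(0),
    from_level = integer(0), to_level = integer(0), land_use = character(0),
    irrigation = integer(0), delayed_sowing = integer(0),
    temp_dec_apr = numeric(0), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  structure(pairs, class = c("weed_pairs", "data.frame"), max_gap = max_gap)
}
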