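#' Per-sample metadata sheet
#'
#' Validates and normalizes the sample metadata used across the pipeline:
#' locality, geographic coordinates, season label, collection year and date,
#' and pool size. Month-only collection dates (`"2012-07"`) are completed to
#' the 15th of the month so that day-resolved windows (e.g. the 14 days
#' before collection) can always be formed.
#'
#' @param df data.frame with columns `sample_id`, `locality`, `latitude`,
#'   `longitude`, `season` (`"spring"`/`"fall"`, `NA` allowed for samples used
#'   only in the clinal analysis), `year`, `collection_date`, `n_flies`.
#' @return a `sample_sheet` (a validated data.frame).
#' @export
sample_sheet <- function(df) {
  df <- as.data.frame(df)
  need <- c("sample_id", "locality", "latitude", "longitude", "season",
            "year", "collection_date", "n_flies")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_invalid("sample_sheet: missing required column(s): %s",
                 paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop_invalid("sample_sheet: duplicated sample ids")
  if (any(df$latitude < -90 | df$latitude > 90, na.rm = TRUE))
    stop_invalid("sample_sheet: latitude outside [-90, 90]")
  if (any(df$longitude < -180 | df$longitude > 180, na.rm = TRUE))
    stop_invalid("sample_sheet: longitude outside [-180, 180]")
  bad <- !(df$season %in% c("spring", "fall") | is.na(df$season))
  if (any(bad))
    stop_invalid("sample_sheet: season must be 'spring' or 'fall' (got '%s')",
                 df$season[bad][1])
  if (any(df$n_flies < 1, na.rm = TRUE))
    stop_invalid("sample_sheet: n_flies must be >= 1")
  df$collection_date <- complete_month_date(df$collection_date)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

as_sample_sheet <- function(x) {
  if (inherits(x, "sample_sheet")) x else sample_sheet(x)
}

#' Complete month-only dates to the 15th of the month
#'
#' @param x character dates, either `"YYYY-MM-DD"` or `"YYYY-MM"`; `NA`
#'   passes through (samples without a usable date are later dropped from
#'   date-dependent analyses with a logged reason).
#' @return `Date` vector.
#' @export
complete_month_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  month_only <- !is.na(x) & grepl("^\\d{4}-\\d{2}$", x)
  x[month_only] <- paste0(x[month_only], "-15")
  bad <- !is.na(x) & !grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(bad))
    stop_invalid("collection_date not ISO 'YYYY-MM-DD' or 'YYYY-MM': '%s'", x[bad][1])
  as.Date(x)
}

#' Resolve the paired spring/fall design
#'
#' Each (locality, year) combination used seasonally must have exactly one
#' spring and one fall sample; samples with `NA` season (clinal-only) are
#' ignored.
#'
#' @param sheet a `sample_sheet`.
#' @return data.frame with one row per pair: `pair_id`, `locality`, `year`,
#'   `spring_id`, `fall_id`, `latitude`, `longitude`.
#' @export
season_pairs <- function(sheet) {
  sheet <- as_sample_sheet(sheet)
  s <- sheet[!is.na(sheet$season), , drop = FALSE]
  if (nrow(s) == 0) stop_invalid("season_pairs: no seasonal samples in sheet")
  key <- paste(s$locality, s$year, sep = "_")
  out <- lapply(split(seq_len(nrow(s)), key), function(idx) {
    sp <- idx[s$season[idx] == "spring"]
    fa <- idx[s$season[idx] == "fall"]
    if (length(sp) != 1L || length(fa) != 1L)
      stop_invalid("season_pairs: locality/year '%s' does not have exactly one spring and one fall sample",
                   key[idx[1]])
    data.frame(pair_id = key[idx[1]], locality = s$locality[sp], year = s$year[sp],
               spring_id = s$sample_id[sp], fall_id = s$sample_id[fa],
               latitude = s$latitude[sp], longitude = s$longitude[sp],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$pair_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
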