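#' Keyword lists for suspected-pneumonia admission screening
#'
#' Free-text admission reasons are screened with case-insensitive
#' substring matching: a record is kept when its reason contains at least
#' one inclusion term and no exclusion term. The exclusion terms remove
#' chemical pneumonitis, pneumothorax and aspiration pneumonia, which
#' would otherwise match the broad inclusion substrings.
#'
#' @return Character vector of matching terms.
#' @export
pneumonia_include_terms <- function() c("monia", "brpn", "bpn", "pcp")

#' @rdname pneumonia_include_terms
#' @export
pneumonia_exclude_terms <- function() c("chem", "pneumothorax", "asp")

#' Filter admission records to suspected pneumonia
#'
#' Keeps records whose free-text reason contains at least one inclusion
#' substring and no exclusion substring (case-insensitive, no
#' tokenisation; exclusion takes precedence). Row order is preserved and
#' the input is not modified, so the operation is idempotent.
#'
#' @param records Data frame of admission records with a free-text reason
#'   column.
#' @param reason_col Name of the reason column (default `"reason_text"`).
#' @param include,exclude Substring term lists; defaults
#'   [pneumonia_include_terms()] / [pneumonia_exclude_terms()].
#'
#' @return A tibble containing only the matching records.
#' @export
#' @examples
#' recs <- tibble::tibble(reason_text = c("Bronchopneumonia", "pneumothorax",
#'                                        "aspiration pneumonia", "PCP"))
#' filter_pneumonia(recs)
filter_pneumonia <- function(records, reason_col = "reason_text",
                             include = pneumonia_include_terms(),
                             exclude = pneumonia_exclude_terms()) {
  stopifnot(reason_col %in% names(records))
  txt <- tolower(as.character(records[[reason_col]]))
  txt[is.na(txt)] <- ""
  hit <- function(terms) {
    Reduce(`|`, lapply(tolower(terms), function(tm) grepl(tm, txt, fixed = TRUE)),
           accumulate = FALSE)
  }
  keep <- hit(include) & !hit(exclude)
  tibble::as_tibble(records[keep, , drop = FALSE])
}

#' Reconstruct missing admission dates from discharge and length of stay
#'
#' An admission whose date is missing but whose discharge date and length
#' of stay (whole days) are recorded is dated
#' `discharge_date - length_of_stay` (length of stay 0 means a same-day
#' admission). The returned tibble carries a `date_status` column:
#' * `"observed"` — admission date was already present (left unchanged);
#' * `"reconstructed"` — recovered from discharge and length of stay;
#' * `"needs_imputation"` — discharge present but length of stay missing
#'   (resolvable once the length of stay is imputed);
#' * `"excluded"` — both dates missing; such records cannot enter the
#'   time series.
#'
#' @param records Data frame with `admission_date`, `discharge_date`
#'   (Date) and `length_of_stay` (non-negative integer days) columns, any
#'   of which may be `NA`.
#' @return A tibble with `admission_date` filled where recoverable and a
#'   `date_status` column.
#' @export
reconstruct_admission_dates <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("admission_date", "discharge_date", "length_of_stay")
                %in% names(records)))
  los <- records$length_of_stay
  if (any(los < 0, na.rm = TRUE)) {
    stop("length_of_stay must be non-negative", call. = FALSE)
  }
  has_adm <- !is.na(records$admission_date)
  has_dis <- !is.na(records$discharge_date)
  has_los <- !is.na(los)

  status <- dplyr::case_when(
    has_adm ~ "observed",
    has_dis & has_los ~ "reconstructed",
    has_dis & !has_los ~ "needs_imputation",
    .default = "excluded"
  )
  recon <- status == "reconstructed"
  records$admission_date[recon] <-
    records$discharge_date[recon] - los[recon]
  records$date_status <- status
  records
}

#' Aggregate admission records to a zero-filled daily count series
#'
#' Counts dated admissions per calendar day over `[start_date, end_date]`,
#' inserting zero-count rows for days with no admissions, and joins the
#' daily meteorology. Records dated outside the window are dropped (their
#' number is reported via a message and the `n_dropped` attribute);
#' records without a resolved admission date are dropped likewise
#' (`n_undated` attribute).
#'
#' @param records Data frame with a resolved `admission_date` column.
#' @param meteorology Data frame with one row per day: `date`,
#'   `mean_temp` (deg C), `rh` (%), and either `dtr` (deg C) or
#'   `min_temp`/`max_temp` from which `dtr = max_temp - min_temp` is
#'   computed. Must cover the full window with no gaps.
#' @param start_date,end_date Study window (Dates); defaults to the
#'   window 2007-10-10 to 2015-12-31.
#'
#' @return A tibble with columns `date`, `count`, `mean_temp`, `rh`,
#'   `dtr`, `dow` (factor, Sunday first), one row per day, strictly
#'   consecutive.
#' @export
aggregate_daily <- function(records, meteorology,
                            start_date = as.Date("2007-10-10"),
                            end_date = as.Date("2015-12-31")) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  stopifnot(start_date <= end_date)
  days <- seq(start_date, end_date, by = "day")

  met <- tibble::as_tibble(meteorology)
  met$date <- as.Date(met$date)
  if (!"dtr" %in% names(met)) {
    stopifnot(all(c("min_temp", "max_temp") %in% names(met)))
    met$dtr <- met$max_temp - met$min_temp
  }
  missing_days <- days[!days %in% met$date]
  if (length(missing_days) > 0) {
    stop("meteorology has no rows for ",
         paste(utils::head(missing_days, 5), collapse = ", "),
         if (length(missing_days) > 5) sprintf(" (and %d more)",
                                               length(missing_days) - 5),
         call. = FALSE)
  }

  adm <- as.Date(records$admission_date)
  n_undated <- sum(is.na(adm))
  adm <- adm[!is.na(adm)]
  in_range <- adm >= start_date & adm <= end_date
  n_dropped <- sum(!in_range)
  if (n_dropped > 0) {
    message(n_dropped, " record(s) dated outside [", start_date, ", ",
            end_date, "] dropped")
  }
  counts <- table(factor(as.character(adm[in_range]),
                         levels = as.character(days)))

  out <- tibble::tibble(date = days, count = as.integer(counts)) |>
    dplyr::left_join(
      dplyr::select(met, "date", "mean_temp", "rh", "dtr"),
      by = "date"
    ) |>
    dplyr::mutate(dow = dow_factor(.data$date))
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_undated") <- n_undated
  out
}

#' Day-of-week factor with Sunday as the reference level
#' @param dates Date vector.
#' @return Factor with levels `Sun`..`Sat`.
#' @export
dow_factor <- function(dates) {
  factor(c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")[
    lubridate::wday(dates, week_start = 7)],
    levels = c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat"))
}

#' Read admission records from delimited text
#'
#' Thin readr wrapper with configurable column names; dates must be
#' ISO-8601.
#'
#' @param path File path (csv/tsv detected from extension).
#' @param col_map Named character vector mapping the canonical names
#'   (`reason_text`, `admission_date`, `discharge_date`,
#'   `length_of_stay`) to the file's column names; identity by default.
#' @return A tibble with the canonical column names.
#' @export
read_admission_records <- function(path, col_map = NULL) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  x <- reader(path, show_col_types = FALSE)
  if (!is.null(col_map)) {
    x <- dplyr::rename(x, !!!rlang::set_names(rlang::syms(unname(col_map)),
                                              names(col_map)))
  }
  for (col in c("admission_date", "discharge_date")) {
    if (col %in% names(x)) x[[col]] <- as.Date(x[[col]])
  }
  tibble::as_tibble(x)
}

#' Write a daily series to delimited text
#' @param daily Tibble from [aggregate_daily()] or [simulate_admissions()].
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_daily_series <- function(daily, path) {
  readr::write_tsv(
    dplyr::select(daily, dplyr::any_of(c("date", "count", "mean_temp",
                                         "rh", "dtr"))), path)
  invisible(path)
}
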