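#' Read a well-records CSV
#'
#' Reads the documented well schema: one row per unconventional well with its
#' pad identifier, WGS84 coordinates, development chronology (spud,
#' stimulation, first and last production dates, ISO-8601), total depth in
#' meters and average daily gas production volume in cubic meters per day.
#' Empty date cells become \code{NA} (a missing date is data, not an error);
#' malformed dates, out-of-range coordinates, non-positive depths or unknown
#' columns raise a data error naming the offending row and column.
#'
#' @param path path to a CSV file with columns \code{well_id, pad_id, lat,
#'   lon, spud_date, stimulation_date, first_production_date,
#'   last_production_date, total_depth_m, avg_daily_gas_volume_m3}.
#' @return a data frame of well records with \code{Date} columns for the four
#'   chronology fields.
#' @seealso [validate_chronology()], [write_wells()]
#' @export
load_wells <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("wells file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  expected <- c("well_id", "pad_id", "lat", "lon", "spud_date",
                "stimulation_date", "first_production_date",
                "last_production_date", "total_depth_m",
                "avg_daily_gas_volume_m3")
  if (!setequal(names(raw), expected)) {
    extra <- setdiff(names(raw), expected)
    miss <- setdiff(expected, names(raw))
    stop_data(sprintf("wells schema mismatch: unknown columns [%s], missing [%s]",
                      paste(extra, collapse = ", "), paste(miss, collapse = ", ")))
  }
  raw <- raw[expected]
  num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & nzchar(trimws(raw[[col]])))
    if (length(bad))
      stop_data(sprintf("unparseable number in column %s, row %d: '%s'",
                        col, bad[1], raw[[col]][bad[1]]))
    x
  }
  wells <- data.frame(
    well_id = raw$well_id,
    pad_id = raw$pad_id,
    lat = num("lat"),
    lon = num("lon"),
    spud_date = as_date_strict(raw$spud_date, "spud_date"),
    stimulation_date = as_date_strict(raw$stimulation_date, "stimulation_date"),
    first_production_date = as_date_strict(raw$first_production_date,
                                           "first_production_date"),
    last_production_date = as_date_strict(raw$last_production_date,
                                          "last_production_date"),
    total_depth_m = num("total_depth_m"),
    avg_daily_gas_volume_m3 = num("avg_daily_gas_volume_m3"),
    stringsAsFactors = FALSE
  )
  if (nrow(wells)) {
    check_latlon(wells$lat, wells$lon, "well coordinate")
    bad <- which(!is.na(wells$total_depth_m) & wells$total_depth_m <= 0)
    if (length(bad))
      stop_data(sprintf("non-positive total_depth_m at row %d", bad[1]))
    bad <- which(!is.na(wells$avg_daily_gas_volume_m3) &
                   wells$avg_daily_gas_volume_m3 < 0)
    if (length(bad))
      stop_data(sprintf("negative avg_daily_gas_volume_m3 at row %d", bad[1]))
  }
  wells
}

#' Write well records to CSV
#'
#' Inverse of [load_wells()]: dates are ISO-8601, missing values are empty
#' cells, so save/load round-trips a valid collection exactly.
#'
#' @param wells a well-records data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wells <- function(wells, path) {
  out <- wells
  for (col in c("spud_date", "stimulation_date", "first_production_date",
                "last_production_date"))
    out[[col]] <- ifelse(is.na(out[[col]]), "", format(out[[col]], "%Y-%m-%d"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Chronological-feasibility screen for well records
#'
#' Partitions wells into a kept set satisfying
#' spud <= stimulation <= first production <= last production over all dates
#' that are present (same-day transitions allowed), and an exclusion set.
#' A well missing every chronology date is excluded with reason
#' \code{missing_dates}; an order violation (e.g. first production before
#' spud) gives reason \code{illogical_chronology}. Validation never errors on
#' content, and kept + excluded partition the input.
#'
#' A well with a spud date but no stimulation date is kept: it can still
#' contribute pad-preparation, drilling and production days.
#'
#' @param wells a well-records data frame as from [load_wells()].
#' @return a list with elements \code{kept} (well records) and
#'   \code{excluded} (data frame \code{well_id}, \code{reason}).
#' @export
validate_chronology <- function(wells) {
  date_cols <- c("spud_date", "stimulation_date", "first_production_date",
                 "last_production_date")
  n <- nrow(wells)
  reason <- rep(NA_character_, n)
  if (n) {
    dm <- matrix(NA_real_, n, 4)
    for (k in seq_along(date_cols)) dm[, k] <- as.numeric(wells[[date_cols[k]]])
    all_missing <- rowSums(!is.na(dm)) == 0L
    # non-decreasing over present dates, in chronology order
    violated <- rep(FALSE, n)
    for (i in 1:3) for (j in (i + 1):4) {
      cmp <- dm[, i] > dm[, j]
      violated <- violated | (!is.na(cmp) & cmp)
    }
    reason[all_missing] <- "missing_dates"
    reason[!all_missing & violated] <- "illogical_chronology"
  }
  keep <- is.na(reason)
  list(
    kept = wells[keep, , drop = FALSE],
    excluded = data.frame(well_id = wells$well_id[!keep],
                          reason = reason[!keep], stringsAsFactors = FALSE)
  )
}

#' Drop wells with no active day inside the study period
#'
#' A well contributes nothing to any exposure metric on inactive days, so
#' wells with zero phase-active days inside \code{[study_start, study_end]}
#' (e.g. fully developed and off production before the study began) are
#' excluded with reason \code{inactive_in_period}.
#'
#' @param wells well records.
#' @param phase_calendar daily phase calendar for these wells, as built by
#'   [build_phase_calendar()].
#' @param study_start,study_end study period bounds (Dates or ISO strings).
#' @return a list \code{kept} / \code{excluded}, as [validate_chronology()].
#' @export
filter_active_in_period <- function(wells, phase_calendar, study_start, study_end) {
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  cal <- phase_calendar[phase_calendar$date >= study_start &
                          phase_calendar$date <= study_end, , drop = FALSE]
  active <- wells$well_id %in% unique(cal$well_id)
  list(
    kept = wells[active, , drop = FALSE],
    excluded = data.frame(well_id = wells$well_id[!active],
                          reason = rep("inactive_in_period", sum(!active)),
                          stringsAsFactors = FALSE)
  )
}

#' Earliest spud date per pad
#'
#' Pad preparation belongs to the pad, not the well: it precedes the spud of
#' the first well drilled on the pad. Pads whose wells all lack spud dates are
#' omitted from the mapping.
#'
#' @param wells well records with \code{pad_id} and \code{spud_date}.
#' @return a data frame \code{pad_id}, \code{first_spud} (Date), one row per
#'   pad with at least one spudded well.
#' @export
earliest_pad_spud <- function(wells) {
  has <- !is.na(wells$spud_date)
  if (!any(has))
    return(data.frame(pad_id = character(), first_spud = as.Date(character())))
  agg <- stats::aggregate(list(first_spud = wells$spud_date[has]),
                          by = list(pad_id = wells$pad_id[has]), FUN = min)
  agg[order(agg$pad_id), , drop = FALSE]
}
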