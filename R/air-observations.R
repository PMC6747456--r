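#' Read raw pollutant observations
#'
#' Reads the observations schema \code{receptor_id, datetime, pollutant,
#' value, units}. Hourly vs daily granularity is auto-detected from the
#' datetime column: values with a time component (\code{YYYY-MM-DDTHH:MM} or
#' \code{YYYY-MM-DD HH:MM[:SS]}) are hourly, date-only values are daily; a
#' file mixing the two is a schema error, as is a malformed datetime (the
#' error names the row).
#'
#' @param path CSV path.
#' @param pollutant optional pollutant code to filter to.
#' @return data frame \code{receptor_id, datetime (POSIXct, UTC), pollutant,
#'   value, units} with attribute \code{granularity} ("hourly" or "daily";
#'   "empty" for a headers-only file).
#' @export
load_observations <- function(path, pollutant = NULL) {
  if (!file.exists(path))
    stop_config(sprintf("observations file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("receptor_id", "datetime", "pollutant", "value", "units")
  if (!all(need %in% names(raw)))
    stop_data(sprintf("observations schema mismatch: missing [%s]",
                      paste(setdiff(need, names(raw)), collapse = ", ")))
  if (!is.null(pollutant)) raw <- raw[raw$pollutant == pollutant, , drop = FALSE]
  if (!nrow(raw)) {
    out <- data.frame(receptor_id = character(),
                      datetime = as.POSIXct(character(), tz = "UTC"),
                      pollutant = character(), value = numeric(),
                      units = character())
    attr(out, "granularity") <- "empty"
    return(out)
  }
  dt <- trimws(raw$datetime)
  is_daily <- grepl("^\\d{4}-\\d{2}-\\d{2}$", dt)
  is_hourly <- grepl("^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}(:\\d{2})?$", dt)
  bad <- which(!is_daily & !is_hourly)
  if (length(bad))
    stop_data(sprintf("malformed datetime '%s' at row %d", dt[bad[1]], bad[1]))
  if (any(is_daily) && any(is_hourly))
    stop_data("mixed hourly and daily datetimes in one file")
  granularity <- if (all(is_daily)) "daily" else "hourly"
  stamp <- if (granularity == "daily") paste(dt, "00:00:00") else
    sub("T", " ", dt)
  parsed <- as.POSIXct(stamp, tz = "UTC")
  if (anyNA(parsed))
    stop_data(sprintf("malformed datetime at row %d", which(is.na(parsed))[1]))
  val <- suppressWarnings(as.numeric(raw$value))
  if (anyNA(val))
    stop_data(sprintf("unparseable value at row %d", which(is.na(val))[1]))
  out <- data.frame(receptor_id = raw$receptor_id, datetime = parsed,
                    pollutant = raw$pollutant, value = val,
                    units = raw$units, stringsAsFactors = FALSE)
  attr(out, "granularity") <- granularity
  out
}

# Maximum daily 8-hour running mean for one receptor's hourly ozone series.
# Windows start at each hour of the day and may run into the next day; a
# window counts only when >= min_hours of its 8 hours are present.
mda8_daily <- function(datetime, value, min_hours = 6) {
  hours <- as.numeric(datetime) %/% 3600
  series <- stats::setNames(value, hours)
  days <- unique(as.Date(datetime))
  res <- vapply(days, function(d) {
    h0 <- as.numeric(as.POSIXct(paste(d, "00:00:00"), tz = "UTC")) %/% 3600
    best <- -Inf
    for (s in h0:(h0 + 23)) {
      v <- series[as.character(s:(s + 7))]
      if (sum(!is.na(v)) >= min_hours) best <- max(best, mean(v, na.rm = TRUE))
    }
    if (is.finite(best)) best else NA_real_
  }, numeric(1))
  data.frame(date = days, value = res)[!is.na(res), , drop = FALSE]
}

#' Daily pollutant summaries
#'
#' Collapses raw observations to one value per receptor-day, by pollutant
#' convention:
#' \itemize{
#'   \item \code{co}, \code{no2}, \code{so2}, \code{pm25} (hourly input):
#'     daily mean and maximum of the available 1-h values (basis
#'     \code{mean_1h});
#'   \item \code{o3} (hourly input): the maximum daily 8-h running average
#'     (MDA8), taking windows starting each hour with at least 6 of 8 hourly
#'     values present (basis \code{mda8});
#'   \item \code{benzene} or any daily-granularity input: the 24-h sample
#'     value passed through (basis \code{sample_24h}).
#' }
#' Days with no observations are absent from the output.
#'
#' @param raw observations from [load_observations()] (single pollutant).
#' @param pollutant pollutant code; defaults to the one in \code{raw}.
#' @return data frame \code{receptor_id, date, pollutant, daily_mean,
#'   daily_max, basis}.
#' @export
daily_summary <- function(raw, pollutant = NULL) {
  if (is.null(pollutant)) {
    pollutant <- unique(raw$pollutant)
    if (length(pollutant) > 1)
      stop_data("daily_summary expects a single pollutant per call")
    if (!length(pollutant)) pollutant <- NA_character_
  } else raw <- raw[raw$pollutant == pollutant, , drop = FALSE]
  empty <- data.frame(receptor_id = character(), date = as.Date(character()),
                      pollutant = character(), daily_mean = numeric(),
                      daily_max = numeric(), basis = character())
  if (!nrow(raw)) return(empty)
  granularity <- attr(raw, "granularity")
  if (is.null(granularity))
    granularity <- if (any(format(raw$datetime, "%H%M") != "0000")) "hourly"
                   else "daily"
  pl <- tolower(pollutant)

  if (granularity == "daily" || pl == "benzene") {
    out <- data.frame(receptor_id = raw$receptor_id,
                      date = as.Date(raw$datetime, tz = "UTC"),
                      pollutant = pollutant, daily_mean = raw$value,
                      daily_max = NA_real_, basis = "sample_24h",
                      stringsAsFactors = FALSE)
    return(out[order(out$receptor_id, out$date), , drop = FALSE])
  }

  parts <- split(raw, raw$receptor_id)
  res <- lapply(names(parts), function(rid) {
    p <- parts[[rid]]
    if (pl == "o3") {
      m <- mda8_daily(p$datetime, p$value)
      if (!nrow(m)) return(NULL)
      data.frame(receptor_id = rid, date = m$date, pollutant = pollutant,
                 daily_mean = m$value, daily_max = NA_real_, basis = "mda8",
                 stringsAsFactors = FALSE)
    } else {
      day <- as.Date(p$datetime, tz = "UTC")
      mu <- tapply(p$value, day, mean)
      mx <- tapply(p$value, day, max)
      data.frame(receptor_id = rid,
                 date = as.Date(names(mu)), pollutant = pollutant,
                 daily_mean = as.numeric(mu), daily_max = as.numeric(mx),
                 basis = "mean_1h", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out[order(out$receptor_id, out$date), , drop = FALSE]
}

#' Trailing rolling mean of a daily concentration series
#'
#' For each day with an observation, the mean of \code{daily_mean} over the
#' trailing closed calendar window \code{[day - window_days + 1, day]},
#' emitted only when at least \code{min_obs} daily values fall inside the
#' window (so sparse series such as 1-in-6-day benzene sampling still
#' qualify, while near-empty windows are dropped). Handles all receptors in
#' the input independently; \code{basis} is preserved and \code{daily_max}
#' is not carried over.
#'
#' @param daily output of [daily_summary()] for one pollutant.
#' @param window_days positive window length in days (90 and 180 are the
#'   conventional sensitivity choices).
#' @param min_obs minimum daily values per window (default 5).
#' @return data frame in the [daily_summary()] layout.
#' @export
rolling_mean <- function(daily, window_days, min_obs = 5) {
  if (!is.numeric(window_days) || length(window_days) != 1 || window_days < 1)
    stop_config("window_days must be a positive number of days")
  parts <- split(daily, daily$receptor_id)
  res <- lapply(parts, function(p) {
    p <- p[order(p$date), , drop = FALSE]
    dn <- as.numeric(p$date)
    lo <- findInterval(dn - window_days, dn) + 1L  # first index with date > d - w
    hi <- seq_along(dn)
    cs <- c(0, cumsum(p$daily_mean))
    cnt <- hi - lo + 1L
    mu <- (cs[hi + 1L] - cs[lo]) / cnt
    keep <- cnt >= min_obs
    if (!any(keep)) return(NULL)
    data.frame(receptor_id = p$receptor_id[keep], date = p$date[keep],
               pollutant = p$pollutant[keep], daily_mean = mu[keep],
               daily_max = NA_real_, basis = p$basis[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- daily[0, c("receptor_id", "date", "pollutant", "daily_mean",
                      "daily_max", "basis")]
  rownames(out) <- NULL
  out
}

#' Drop receptors by region tag
#'
#' Removes receptors whose \code{region_tag} is in \code{excluded_tags} —
#' e.g. monitors in a metropolitan area with no nearby wells and strong
#' unrelated urban sources.
#'
#' @param receptors receptor data frame with a \code{region_tag} column.
#' @param excluded_tags character vector of tags to drop (default "metro").
#' @return the kept receptors.
#' @export
exclude_region <- function(receptors, excluded_tags = "metro") {
  receptors[!(receptors$region_tag %in% excluded_tags), , drop = FALSE]
}
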