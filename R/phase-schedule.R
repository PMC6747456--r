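#' Midrank depth percentile
#'
#' Fraction in [0, 1] giving the position of a well's total depth within the
#' fleet's depth distribution, computed as the midrank (ties averaged) shifted
#' by one half: \code{(midrank - 0.5) / n}. The shallowest of n distinct
#' depths maps to \code{0.5/n}, the deepest to \code{1 - 0.5/n}, so the
#' implied drilling durations span the 1--30 day range without pinning the
#' extremes to the bounds for small fleets.
#'
#' @param depth_m depth(s) to place, meters.
#' @param all_depths the fleet's depths, meters (non-empty).
#' @return numeric vector of fractions in (0, 1).
#' @export
depth_percentile <- function(depth_m, all_depths) {
  if (!length(all_depths)) stop_config("all_depths must be non-empty")
  n <- length(all_depths)
  vapply(depth_m, function(d) {
    (sum(all_depths < d) + (sum(all_depths == d) + 1) / 2 - 0.5) / n
  }, numeric(1))
}

#' Drilling-phase duration from a depth percentile
#'
#' The drilling phase begins on the spud date and lasts between 1 and 30 days
#' depending on well depth. The map from depth percentile p to days is linear,
#' \code{round(1 + 29 p)} with half-up rounding, clamped to [1, 30]; it is
#' monotone non-decreasing in p and attains both bounds (p = 0 gives 1 day,
#' p = 1 gives 30).
#'
#' @param depth_percentile fraction(s) in [0, 1], e.g. from
#'   [depth_percentile()].
#' @return integer day count(s) in 1..30.
#' @export
drilling_duration_days <- function(depth_percentile) {
  if (any(!is.finite(depth_percentile) | depth_percentile < 0 |
            depth_percentile > 1))
    stop_config("depth_percentile must lie in [0, 1]")
  d <- floor(1 + 29 * depth_percentile + 0.5)  # round half-up
  as.integer(pmin(pmax(d, 1), 30))
}

#' Phase windows for a single well
#'
#' Builds the closed date intervals of the four development phases:
#' \itemize{
#'   \item pad preparation: the 30 days before the pad's first spud date,
#'     \code{[pad_first_spud - 30, pad_first_spud - 1]}, attributed to the
#'     first-spudded well on the pad only (so a pad is counted once);
#'   \item drilling: \code{[spud, spud + duration - 1]} with duration from
#'     [drilling_duration_days()] on the well's depth percentile;
#'   \item fracturing: the 7 days \code{[stimulation, stimulation + 6]},
#'     present only when a stimulation date is;
#'   \item production: \code{[first_production, min(last_production,
#'     study_end)]}, with a missing last production date read as "still
#'     producing", i.e. through \code{study_end}.
#' }
#'
#' @param well a single-row well-records data frame.
#' @param pad_first_spud earliest spud date on the well's pad.
#' @param all_depths fleet depths used for the drilling-duration percentile.
#' @param study_end last study day (production is truncated here).
#' @param is_pad_first does this well carry the pad-preparation window?
#'   Defaults to "its spud equals the pad's first spud"; the calendar builder
#'   passes an exact flag with ties broken by lowest well_id.
#' @return a list of phase intervals (each \code{NULL} or
#'   \code{c(start, end)} Dates) with the well id attached.
#' @export
build_phase_windows <- function(well, pad_first_spud, all_depths, study_end,
                                is_pad_first = isTRUE(well$spud_date == pad_first_spud)) {
  study_end <- as.Date(study_end)
  win <- list(well_id = well$well_id, pad_preparation = NULL, drilling = NULL,
              fracturing = NULL, production = NULL)
  if (is_pad_first && !is.na(pad_first_spud))
    win$pad_preparation <- c(pad_first_spud - 30, pad_first_spud - 1)
  if (!is.na(well$spud_date)) {
    dur <- drilling_duration_days(depth_percentile(well$total_depth_m, all_depths))
    win$drilling <- c(well$spud_date, well$spud_date + dur - 1)
  }
  if (!is.na(well$stimulation_date))
    win$fracturing <- c(well$stimulation_date, well$stimulation_date + 6)
  if (!is.na(well$first_production_date)) {
    pend <- if (is.na(well$last_production_date)) study_end
            else min(well$last_production_date, study_end)
    if (pend >= well$first_production_date)
      win$production <- c(well$first_production_date, pend)
  }
  win
}

#' Daily phase calendar for a well fleet
#'
#' Expands every well's phase windows to one record per active well-day,
#' clipped to \code{[study_start, study_end]}. Inactive days (in no window)
#' are simply absent. Where windows overlap on a day, exactly one phase is
#' kept using the precedence production > fracturing > drilling >
#' pad_preparation, so the later stage of development wins.
#'
#' @param wells validated well records (see [validate_chronology()]).
#' @param study_start,study_end study period bounds.
#' @return a data frame \code{well_id}, \code{date}, \code{phase} (factor with
#'   levels pad_preparation, drilling, fracturing, production), at most one
#'   row per (well, date).
#' @export
build_phase_calendar <- function(wells, study_start, study_end) {
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (study_start > study_end) stop_config("study_start must not exceed study_end")
  if (!nrow(wells))
    return(data.frame(well_id = character(), date = as.Date(character()),
                      phase = factor(character(), levels = PHASES)))

  pads <- earliest_pad_spud(wells)
  first_spud <- pads$first_spud[match(wells$pad_id, pads$pad_id)]
  # pad-prep carrier: earliest spud on the pad, ties to the lowest well_id
  carrier <- rep(FALSE, nrow(wells))
  has_spud <- !is.na(wells$spud_date) & !is.na(first_spud) &
    wells$spud_date == first_spud
  for (p in unique(wells$pad_id[has_spud])) {
    idx <- which(has_spud & wells$pad_id == p)
    carrier[idx[order(wells$well_id[idx])[1]]] <- TRUE
  }

  all_depths <- wells$total_depth_m
  acc <- vector("list", nrow(wells) * 4L); k <- 0L
  for (i in seq_len(nrow(wells))) {
    win <- build_phase_windows(wells[i, , drop = FALSE], first_spud[i],
                               all_depths, study_end, is_pad_first = carrier[i])
    for (ph in PHASES) {
      iv <- win[[ph]]
      if (is.null(iv)) next
      lo <- max(iv[1], study_start); hi <- min(iv[2], study_end)
      if (lo > hi) next
      days <- seq.Date(lo, hi, by = "day")
      k <- k + 1L
      acc[[k]] <- list(id = rep(wells$well_id[i], length(days)),
                       date = as.numeric(days), ph = rep(ph, length(days)))
    }
  }
  acc <- acc[seq_len(k)]
  cal <- data.frame(
    well_id = unlist(lapply(acc, `[[`, "id"), use.names = FALSE),
    date = as.Date(unlist(lapply(acc, `[[`, "date"), use.names = FALSE),
                   origin = "1970-01-01"),
    phase = factor(unlist(lapply(acc, `[[`, "ph"), use.names = FALSE),
                   levels = PHASES),
    stringsAsFactors = FALSE)
  # precedence: keep the latest phase where windows overlap on a day
  ord <- order(cal$well_id, cal$date, -as.integer(cal$phase))
  cal <- cal[ord, , drop = FALSE]
  cal <- cal[!duplicated(cal[c("well_id", "date")]), , drop = FALSE]
  rownames(cal) <- NULL
  cal
}

#' Wells active in a phase on a date
#'
#' @param calendar a phase calendar from [build_phase_calendar()].
#' @param date a single date.
#' @param phase one of \code{"pad_preparation"}, \code{"drilling"},
#'   \code{"fracturing"}, \code{"production"}.
#' @return character vector of well ids.
#' @export
wells_active_on <- function(calendar, date, phase) {
  phase <- match.arg(phase, PHASES)
  calendar$well_id[calendar$date == as.Date(date) & calendar$phase == phase]
}

#' Export a phase calendar to CSV
#'
#' @param calendar a phase calendar.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phase_calendar <- function(calendar, path) {
  out <- data.frame(well_id = calendar$well_id,
                    date = format(calendar$date, "%Y-%m-%d"),
                    phase = as.character(calendar$phase))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
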