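# Per-operation RNG offsets keep each stage independently reproducible from
# one config seed.
SEED_OFFSET <- c(wells = 101L, receptors = 202L, concentrations = 303L)

#' Simulation configuration
#'
#' Bundles and validates everything the synthetic-data generator needs. The
#' defaults sketch a Marcellus-like setting: a multi-county bounding box, a
#' five-year study window, a fleet of multi-well pads, depths around 2 km and
#' lognormal gas production volumes.
#'
#' @param n_pads number of well pads.
#' @param wells_per_pad wells per pad: a single positive integer, or a length-2
#'   vector \code{c(min, max)} sampled uniformly per pad.
#' @param bbox named or positional vector \code{(lat_min, lat_max, lon_min,
#'   lon_max)} in decimal degrees.
#' @param study_start,study_end study period (Dates or ISO strings).
#' @param n_receptors number of receptor (monitor) locations.
#' @param depth_mean_m,depth_sd_m normal depth distribution, meters, truncated
#'   below at 500 m.
#' @param volume_log_mean,volume_log_sd lognormal parameters of average daily
#'   gas production volume (log m3/day).
#' @param gap_days_max maximum inactive gap, in days, drawn uniformly between
#'   consecutive phases (default 90; development phases are sequential but can
#'   be separated by idle stretches).
#' @param mode \code{"independent"} (concentrations unrelated to wells) or
#'   \code{"coupled"} (concentrations a monotone function of total WA plus
#'   lognormal noise).
#' @param coupling_gamma coupling strength on the rank-standardized total WA
#'   (ignored in independent mode).
#' @param noise_sd log-scale concentration noise (also the spread of the
#'   independent-mode series).
#' @param conc_log_mean log-scale location of simulated concentrations
#'   (default \code{log(0.16)}, a benzene-like median in ppbv).
#' @param seed integer RNG seed; every generator derives its stream from it.
#' @return object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_pads = 100, wells_per_pad = 3,
                              bbox = c(lat_min = 39.8, lat_max = 42.0,
                                       lon_min = -80.5, lon_max = -75.0),
                              study_start = "2011-01-01",
                              study_end = "2015-12-31",
                              n_receptors = 76,
                              depth_mean_m = 2000, depth_sd_m = 400,
                              volume_log_mean = log(5e4), volume_log_sd = 0.8,
                              gap_days_max = 90,
                              mode = c("independent", "coupled"),
                              coupling_gamma = 1, noise_sd = 0.5,
                              conc_log_mean = log(0.16), seed = 1) {
  mode <- match.arg(mode)
  if (length(bbox) != 4) stop_config("bbox must have 4 elements")
  if (is.null(names(bbox)) || !all(nzchar(names(bbox))))
    names(bbox) <- c("lat_min", "lat_max", "lon_min", "lon_max")
  bbox <- bbox[c("lat_min", "lat_max", "lon_min", "lon_max")]
  if (anyNA(bbox) || bbox["lat_min"] >= bbox["lat_max"] ||
        bbox["lon_min"] >= bbox["lon_max"] ||
        bbox["lat_min"] < -90 || bbox["lat_max"] > 90 ||
        bbox["lon_min"] < -180 || bbox["lon_max"] > 180)
    stop_config("malformed bbox")
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (is.na(study_start) || is.na(study_end) || study_start >= study_end)
    stop_config("study_start must precede study_end")
  if (n_pads < 1 || n_receptors < 0) stop_config("non-positive counts")
  if (length(wells_per_pad) == 1) wells_per_pad <- rep(wells_per_pad, 2)
  if (length(wells_per_pad) != 2 || any(wells_per_pad < 1) ||
        wells_per_pad[1] > wells_per_pad[2])
    stop_config("wells_per_pad must be a positive integer or c(min, max)")
  if (depth_sd_m < 0 || gap_days_max < 0 || coupling_gamma < 0 || noise_sd < 0)
    stop_config("depth_sd_m, gap_days_max, coupling_gamma, noise_sd must be >= 0")
  structure(list(n_pads = as.integer(n_pads),
                 wells_per_pad = as.integer(wells_per_pad), bbox = bbox,
                 study_start = study_start, study_end = study_end,
                 n_receptors = as.integer(n_receptors),
                 depth_mean_m = depth_mean_m, depth_sd_m = depth_sd_m,
                 volume_log_mean = volume_log_mean,
                 volume_log_sd = volume_log_sd,
                 gap_days_max = as.integer(gap_days_max), mode = mode,
                 coupling_gamma = coupling_gamma, noise_sd = noise_sd,
                 conc_log_mean = conc_log_mean, seed = as.integer(seed)),
            class = "simulation_config")
}

# Normal truncated below at `lower` via inverse-CDF (no mass point at the bound).
rnorm_trunc_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(pmax(mean, lower), n))
  u <- stats::runif(n, stats::pnorm(lower, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

#' Simulate a well fleet
#'
#' Pads are placed uniformly in the bounding box and each pad's wells are
#' jittered at most 200 m around the pad center (multi-well pads share a
#' site). Chronologies are built forward — spud, then stimulation after the
#' drilling stretch plus an inactive gap uniform on \code{[0, gap_days_max]},
#' then first production after the 7-day fracturing window plus another gap,
#' then a production run of 180 days to 3 years — so every well passes
#' [validate_chronology()] by construction. Depths are normal truncated below
#' at 500 m; production volumes lognormal. Deterministic for a fixed seed.
#'
#' @param config a [simulation_config()].
#' @return a well-records data frame (see [load_wells()]).
#' @export
simulate_wells <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed + SEED_OFFSET[["wells"]], {
    np <- config$n_pads
    bb <- config$bbox
    pad_lat <- stats::runif(np, bb["lat_min"], bb["lat_max"])
    pad_lon <- stats::runif(np, bb["lon_min"], bb["lon_max"])
    n_wells_pad <- if (config$wells_per_pad[1] == config$wells_per_pad[2])
      rep(config$wells_per_pad[1], np)
    else sample(config$wells_per_pad[1]:config$wells_per_pad[2], np,
                replace = TRUE)
    n <- sum(n_wells_pad)
    pad_idx <- rep(seq_len(np), n_wells_pad)
    # jitter <= 200 m around the pad center
    r <- 200 * sqrt(stats::runif(n)); theta <- stats::runif(n, 0, 2 * pi)
    lat <- pad_lat[pad_idx] + (r * sin(theta)) / 111320
    lon <- pad_lon[pad_idx] +
      (r * cos(theta)) / (111320 * cos(pad_lat[pad_idx] * pi / 180))
    lat <- pmin(pmax(lat, bb["lat_min"]), bb["lat_max"])
    lon <- pmin(pmax(lon, bb["lon_min"]), bb["lon_max"])

    depth <- rnorm_trunc_lower(n, config$depth_mean_m, config$depth_sd_m, 500)
    volume <- stats::rlnorm(n, config$volume_log_mean, config$volume_log_sd)

    span <- as.integer(config$study_end - config$study_start)
    spud <- config$study_start +
      sample(seq(-120L, max(span - 90L, -119L)), n, replace = TRUE)
    gap1 <- sample(0:config$gap_days_max, n, replace = TRUE)
    gap2 <- sample(0:config$gap_days_max, n, replace = TRUE)
    drill_days <- sample(1:30, n, replace = TRUE)  # chronology spacing only
    stimulation <- spud + drill_days + gap1
    first_prod <- stimulation + 7L + gap2
    prod_days <- sample(180:1095, n, replace = TRUE)
    last_prod <- first_prod + prod_days

    data.frame(
      well_id = sprintf("W%05d", seq_len(n)),
      pad_id = sprintf("P%04d", pad_idx),
      lat = as.numeric(lat), lon = as.numeric(lon),
      spud_date = spud, stimulation_date = stimulation,
      first_production_date = first_prod, last_production_date = last_prod,
      total_depth_m = depth, avg_daily_gas_volume_m3 = volume,
      stringsAsFactors = FALSE)
  })
}

#' Simulate receptor (monitor) locations
#'
#' Receptors are uniform in the bounding box. Real monitors are intentionally
#' sited (population centers, suspected hot spots), so uniform placement is a
#' neutral stand-in, not an emulation of siting policy. The last
#' \code{n_metro} receptors are tagged \code{"metro"} so the downstream
#' region-exclusion filter is exercisable; the rest are tagged
#' \code{"study"}. Deterministic for a fixed seed.
#'
#' @param config a [simulation_config()].
#' @param n_metro how many receptors to tag "metro" (default 0).
#' @return data frame \code{receptor_id, lat, lon, region_tag}.
#' @export
simulate_receptors <- function(config, n_metro = 0) {
  stopifnot(inherits(config, "simulation_config"))
  nr <- config$n_receptors
  if (n_metro > nr) stop_config("n_metro exceeds n_receptors")
  with_seed(config$seed + SEED_OFFSET[["receptors"]], {
    bb <- config$bbox
    data.frame(
      receptor_id = sprintf("R%03d", seq_len(nr)),
      lat = stats::runif(nr, bb["lat_min"], bb["lat_max"]),
      lon = stats::runif(nr, bb["lon_min"], bb["lon_max"]),
      region_tag = rep(c("study", "metro"), c(nr - n_metro, n_metro)),
      stringsAsFactors = FALSE)
  })
}

#' Simulate daily pollutant concentrations
#'
#' Two regimes:
#' \itemize{
#'   \item \code{independent}: \eqn{c = \exp(\mu + \sigma \epsilon)},
#'     lognormal and unrelated to any well data, one value per receptor per
#'     study day;
#'   \item \code{coupled}: \eqn{c = \exp(\mu + \gamma z + \sigma \epsilon)}
#'     where \eqn{z} is the rank-standardized total WA (the sum of the four
#'     metrics at that receptor-day, converted to a normal score via
#'     \code{qnorm(rank/(n+1))}) — a strictly increasing function of total WA
#'     wherever WA values are distinct. Rank-standardizing before coupling
#'     gives \eqn{\gamma} a stable meaning across configurations. Emitted for
#'     exactly the (receptor, day) pairs present in \code{wa_table}; a
#'     receptor in \code{receptors} missing from \code{wa_table} is an error.
#' }
#' Here \eqn{\mu} is \code{conc_log_mean} and \eqn{\sigma} is
#' \code{noise_sd}. Values are strictly positive; deterministic for a fixed
#' seed.
#'
#' @param receptors receptor data frame.
#' @param config a [simulation_config()] (its \code{mode} selects the regime).
#' @param wa_table daily WA table (required in coupled mode).
#' @param pollutant label for the simulated series (default "benzene").
#' @param stream extra non-negative seed offset so several pollutant series
#'   from one config are mutually independent (default 0).
#' @return data frame in the [daily_summary()] layout (basis
#'   \code{sample_24h}).
#' @export
simulate_concentrations <- function(receptors, config, wa_table = NULL,
                                    pollutant = "benzene", stream = 0L) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed + SEED_OFFSET[["concentrations"]] + as.integer(stream), {
    if (config$mode == "independent") {
      days <- seq.Date(config$study_start, config$study_end, by = "day")
      nr <- nrow(receptors); nd <- length(days)
      logc <- config$conc_log_mean + config$noise_sd * stats::rnorm(nr * nd)
      out <- data.frame(
        receptor_id = rep(receptors$receptor_id, nd),
        date = rep(days, each = nr),
        pollutant = pollutant,
        daily_mean = exp(logc), daily_max = NA_real_, basis = "sample_24h",
        stringsAsFactors = FALSE)
    } else {
      if (is.null(wa_table))
        stop_config("coupled mode requires a wa_table")
      miss <- setdiff(receptors$receptor_id, unique(wa_table$receptor_id))
      if (length(miss))
        stop_data(sprintf("coupled mode: receptors missing from wa_table: %s",
                          paste(miss, collapse = ", ")))
      wa <- wa_table[wa_table$receptor_id %in% receptors$receptor_id, ,
                     drop = FALSE]
      total <- wa$wa_pad_prep + wa$wa_drilling + wa$wa_fracturing +
        wa$wa_production
      nt <- length(total)
      z <- stats::qnorm(rank(total, ties.method = "average") / (nt + 1))
      logc <- config$conc_log_mean + config$coupling_gamma * z +
        config$noise_sd * stats::rnorm(nt)
      out <- data.frame(
        receptor_id = wa$receptor_id, date = wa$date, pollutant = pollutant,
        daily_mean = exp(logc), daily_max = NA_real_, basis = "sample_24h",
        stringsAsFactors = FALSE)
    }
    out
  })
}

#' Paired independent uniform quartile classifications
#'
#' The no-association benchmark: n category pairs with each coordinate drawn
#' independently and uniformly from the four exposure categories. Under this
#' null the expected identical-category proportion and mirror-opposite
#' proportion are both 1/4 (four cells each of a uniform 4x4 table) and the
#' weighted kappa converges to 0.
#'
#' @param n number of pairs.
#' @param seed RNG seed.
#' @return data frame with integer columns \code{conc_cat}, \code{wa_cat} in
#'   1..4.
#' @export
null_classification_pairs <- function(n, seed) {
  if (n < 1) stop_config("n must be >= 1")
  with_seed(seed, {
    data.frame(conc_cat = sample.int(4L, n, replace = TRUE),
               wa_cat = sample.int(4L, n, replace = TRUE))
  })
}

#' Write receptors / daily concentrations in the documented CSV schemas
#' @param receptors receptor data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_receptors <- function(receptors, path) {
  utils::write.csv(receptors, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read receptors from CSV
#' @param path path to a receptors CSV (\code{receptor_id, lat, lon,
#'   region_tag}).
#' @return receptor data frame.
#' @export
load_receptors <- function(path) {
  if (!file.exists(path))
    stop_config(sprintf("receptors file not found: %s", path))
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("receptor_id", "lat", "lon", "region_tag")
  if (!all(need %in% names(out)))
    stop_data(sprintf("receptors schema mismatch: missing [%s]",
                      paste(setdiff(need, names(out)), collapse = ", ")))
  check_latlon(out$lat, out$lon, "receptor coordinate")
  out
}

#' Write daily concentrations as an observations CSV
#'
#' Serializes simulated daily series in the raw observations schema
#' (\code{receptor_id, datetime, pollutant, value, units}) so the ingestion
#' path reads simulated and real data identically.
#'
#' @param daily data frame in [daily_summary()] layout.
#' @param path output path.
#' @param units units label to record (default "ppbv").
#' @return `path`, invisibly.
#' @export
write_observations <- function(daily, path, units = "ppbv") {
  out <- data.frame(receptor_id = daily$receptor_id,
                    datetime = format(daily$date, "%Y-%m-%d"),
                    pollutant = daily$pollutant, value = daily$daily_mean,
                    units = units)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
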