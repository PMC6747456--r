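#' Run the full WA-vs-concentration pipeline from a config
#'
#' Orchestrates an end-to-end run: obtain wells, receptors and observations
#' (simulated, or ingested from the documented CSVs), screen well
#' chronologies, build the daily phase calendar, drop wells inactive in the
#' study period and metro-tagged receptors, compute daily WA at each
#' receptor, summarize concentrations, and run the quartile-agreement
#' analysis. Every stage's artifact is materialized in \code{out_dir} so
#' stages are independently inspectable and the agreement stage can be re-run
#' from cached CSVs; a run manifest records the config snapshot, seed, input
#' file digests, per-stage record counts, warnings and the package version.
#' Identical config + seed give identical artifact digests.
#'
#' Config keys (YAML file or list): \code{mode} ("simulate" or "ingest");
#' \code{seed}; \code{simulation} (fields of [simulation_config()], plus
#' optional \code{n_metro}); \code{pollutants} (labels to simulate; simulate
#' mode); \code{inputs} (paths \code{wells}, \code{receptors},
#' \code{observations}; ingest mode); \code{study_start}/\code{study_end}
#' (ingest mode); \code{analysis} (\code{buffer_km} — number or "none",
#' \code{window_days}, \code{weights}, \code{opposite}).
#'
#' @param config path to a YAML config file, or an equivalent named list.
#' @param out_dir run directory for artifacts (created if needed).
#' @return the run manifest (a list), invisibly; also written as
#'   \code{manifest.json} in \code{out_dir}.
#' @export
run_pipeline <- function(config, out_dir = "wa_run") {
  if (is.character(config)) {
    if (!file.exists(config))
      stop_config(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a file path or a list")
  mode <- config$mode %||% "simulate"
  if (!mode %in% c("simulate", "ingest"))
    stop_config(sprintf("unknown mode '%s'", mode))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_seen <- character(0)
  note <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  counts <- list()
  digests <- list()

  withCallingHandlers(warning = note, {
    if (mode == "simulate") {
      sim_args <- config$simulation %||% list()
      n_metro <- sim_args$n_metro %||% 0
      sim_args$n_metro <- NULL
      if (!is.null(config$seed)) sim_args$seed <- config$seed
      if (!is.null(sim_args$bbox)) sim_args$bbox <- unlist(sim_args$bbox)
      cfg <- do.call(simulation_config, sim_args)
      wells_raw <- simulate_wells(cfg)
      receptors <- simulate_receptors(cfg, n_metro = n_metro)
      study_start <- cfg$study_start; study_end <- cfg$study_end
      pollutants <- config$pollutants %||% "benzene"
    } else {
      paths <- config$inputs %||% list()
      for (p in c("wells", "receptors", "observations"))
        if (is.null(paths[[p]]) || !file.exists(paths[[p]]))
          stop_config(sprintf("ingest mode: missing input file for '%s'%s", p,
                              if (is.null(paths[[p]])) "" else
                                sprintf(" (%s)", paths[[p]])))
      wells_raw <- load_wells(paths$wells)
      receptors <- load_receptors(paths$receptors)
      if (is.null(config$study_start) || is.null(config$study_end))
        stop_config("ingest mode requires study_start and study_end")
      study_start <- as.Date(config$study_start)
      study_end <- as.Date(config$study_end)
      digests <- lapply(paths, function(p) unname(tools::md5sum(p)))
    }
    counts$wells_input <- nrow(wells_raw)
    counts$receptors_input <- nrow(receptors)

    chron <- validate_chronology(wells_raw)
    counts$wells_excluded_chronology <- nrow(chron$excluded)
    calendar <- build_phase_calendar(chron$kept, study_start, study_end)
    act <- filter_active_in_period(chron$kept, calendar, study_start, study_end)
    counts$wells_excluded_inactive <- nrow(act$excluded)
    wells <- act$kept
    counts$wells_kept <- nrow(wells)
    calendar <- calendar[calendar$well_id %in% wells$well_id, , drop = FALSE]
    counts$calendar_rows <- nrow(calendar)

    receptors <- exclude_region(receptors, "metro")
    counts$receptors_kept <- nrow(receptors)

    write_wells(wells, file.path(out_dir, "wells.csv"))
    write_receptors(receptors, file.path(out_dir, "receptors.csv"))
    write_phase_calendar(calendar, file.path(out_dir, "calendar.csv"))

    an <- config$analysis %||% list()
    buffer_km <- an$buffer_km %||% Inf
    if (identical(buffer_km, "none")) buffer_km <- Inf
    window_days <- an$window_days %||% 1
    weights <- an$weights %||% "linear"
    opposite <- an$opposite %||% "mirror"

    if (mode == "simulate") {
      if (cfg$mode == "coupled") {
        wa_table <- compute_daily_wa(receptors, calendar, wells)
        daily <- do.call(rbind, lapply(seq_along(pollutants), function(i)
          simulate_concentrations(receptors, cfg, wa_table,
                                  pollutant = pollutants[i], stream = i - 1L)))
      } else {
        daily <- do.call(rbind, lapply(seq_along(pollutants), function(i)
          simulate_concentrations(receptors, cfg, pollutant = pollutants[i],
                                  stream = i - 1L)))
        wa_table <- compute_daily_wa(receptors, calendar, wells,
                                     dates = unique(daily$date))
      }
      write_observations(daily, file.path(out_dir, "observations.csv"))
    } else {
      obs <- load_observations(paths$observations)
      pollutants <- sort(unique(obs$pollutant))
      daily <- do.call(rbind, lapply(pollutants, function(pl) {
        sub <- obs[obs$pollutant == pl, , drop = FALSE]
        attr(sub, "granularity") <- attr(obs, "granularity")
        daily_summary(sub, pl)
      }))
      wa_table <- compute_daily_wa(receptors, calendar, wells,
                                   dates = unique(daily$date))
    }
    daily <- daily[daily$receptor_id %in% receptors$receptor_id, , drop = FALSE]
    counts$daily_rows <- nrow(daily)
    counts$wa_rows <- nrow(wa_table)
    write_daily_wa(wa_table, file.path(out_dir, "wa_daily.csv"))
    daily_out <- daily; daily_out$date <- format(daily_out$date, "%Y-%m-%d")
    utils::write.csv(daily_out, file.path(out_dir, "daily.csv"),
                     row.names = FALSE, quote = FALSE)

    study <- run_agreement_study(wa_table, daily, receptors = receptors,
                                 wells = wells, buffer_km = buffer_km,
                                 window_days = window_days, weights = weights,
                                 opposite = opposite)
    counts$reports_emitted <- nrow(study$kappas)
    write_agreement_reports(study, out_dir)
  })

  for (f in c("wells.csv", "receptors.csv", "calendar.csv", "wa_daily.csv",
              "daily.csv", "observations.csv"))
    if (file.exists(file.path(out_dir, f)))
      digests[[f]] <- unname(tools::md5sum(file.path(out_dir, f)))

  manifest <- list(
    tool = "waagree",
    version = as.character(utils::packageVersion("waagree")),
    mode = mode,
    seed = config$seed %||% (if (mode == "simulate") cfg$seed else NA),
    config = config,
    study_period = c(format(study_start), format(study_end)),
    counts = counts,
    digests = digests,
    warnings = warnings_seen)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

#' Write agreement reports to a run directory
#'
#' One JSON per pollutant x metric report (table, kappa, CI, agreement and
#' opposite proportions, row-conditional distributions) plus a flat
#' \code{kappas.csv} across all conditions.
#'
#' @param study a \code{wa_agreement_study}.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_agreement_reports <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- lapply(study$reports, function(r) {
    list(pollutant = r$pollutant, metric = r$metric,
         buffer_km = if (is.infinite(study$buffer_km)) "none" else study$buffer_km,
         window_days = study$window_days, n = r$n,
         table = unname(apply(r$table, 1, as.integer, simplify = FALSE)),
         kappa = r$kappa_w, se = r$se, ci95 = r$ci95,
         p_agree = r$p_agree, p_opposite = r$p_opposite,
         row_conditional = unname(apply(r$row_conditional, 1, as.numeric,
                                        simplify = FALSE)))
  })
  jsonlite::write_json(reports, file.path(out_dir, "agreement_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.csv(study$kappas, file.path(out_dir, "kappas.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
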