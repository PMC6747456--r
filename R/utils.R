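# Internal helpers: classed error conditions and a scoped RNG.

stop_config <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("waagree_config_error", "waagree_error")))
}

stop_data <- function(msg) {
  stop(errorCondition(msg, class = c("waagree_data_error", "waagree_error")))
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

as_date_strict <- function(x, what = "date") {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  nonblank <- !is.na(x) & nzchar(trimws(x))
  if (any(nonblank)) {
    ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x[nonblank])
    parsed <- as.Date(x[nonblank], format = "%Y-%m-%d")
    if (any(!ok | is.na(parsed))) {
      bad <- which(nonblank)[which(!ok | is.na(parsed))[1]]
      stop_data(sprintf("unparseable %s '%s' (row %d); expected YYYY-MM-DD",
                        what, x[bad], bad))
    }
    out[nonblank] <- parsed
  }
  out
}

check_latlon <- function(lat, lon, context = "coordinate") {
  bad <- which(!is.finite(lat) | !is.finite(lon) | lat < -90 | lat > 90 |
                 lon < -180 | lon > 180)
  if (length(bad))
    stop_data(sprintf("invalid %s at row %d: lat=%s lon=%s",
                      context, bad[1], lat[bad[1]], lon[bad[1]]))
  invisible(TRUE)
}

PHASES <- c("pad_preparation", "drilling", "fracturing", "production")
CATEGORY_LEVELS <- c("very_low", "low", "medium", "high")
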