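# Fixture builders and independent brute-force oracles shared across tests.

EARTH_R <- 6371008.8

well_row <- function(well_id = "W1", pad_id = "P1", lat = 41, lon = -77.5,
                     spud = "2012-06-15", stim = "2012-07-10",
                     first_prod = "2012-08-01", last_prod = "2014-12-31",
                     depth = 2000, volume = 5e4) {
  as_d <- function(x) if (is.null(x)) as.Date(NA) else as.Date(x)
  data.frame(well_id = well_id, pad_id = pad_id, lat = lat, lon = lon,
             spud_date = as_d(spud), stimulation_date = as_d(stim),
             first_production_date = as_d(first_prod),
             last_production_date = as_d(last_prod),
             total_depth_m = depth, avg_daily_gas_volume_m3 = volume,
             stringsAsFactors = FALSE)
}

wells_fixture <- function(...) do.call(rbind, list(...))

receptor_row <- function(receptor_id = "R1", lat = 41, lon = -77.5,
                         region_tag = "study") {
  data.frame(receptor_id = receptor_id, lat = lat, lon = lon,
             region_tag = region_tag, stringsAsFactors = FALSE)
}

# A point `meters` due north of (lat, lon): the meridian arc on a sphere is
# exact, so the haversine distance is `meters` to machine precision.
offset_north <- function(lat, meters) lat + (meters / EARTH_R) * 180 / pi

# Independent WA oracle: scalar triple loop straight off the metric
# definitions, no shared code with compute_daily_wa.
naive_daily_wa <- function(receptors, calendar, wells, dates) {
  hav <- function(lat1, lon1, lat2, lon2) {
    rad <- pi / 180
    dlat <- (lat2 - lat1) * rad / 2; dlon <- (lon2 - lon1) * rad / 2
    a <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
    2 * EARTH_R * asin(sqrt(a))
  }
  phase_metric <- c(pad_preparation = "wa_pad_prep", drilling = "wa_drilling",
                    fracturing = "wa_fracturing", production = "wa_production")
  out <- expand.grid(receptor_id = receptors$receptor_id,
                     date = as.Date(dates), stringsAsFactors = FALSE)
  out$wa_pad_prep <- out$wa_drilling <- out$wa_fracturing <-
    out$wa_production <- 0
  for (row in seq_len(nrow(out))) {
    ri <- match(out$receptor_id[row], receptors$receptor_id)
    for (ph in names(phase_metric)) {
      ids <- calendar$well_id[calendar$date == out$date[row] &
                                calendar$phase == ph]
      s <- 0
      for (id in ids) {
        wi <- match(id, wells$well_id)
        d <- hav(receptors$lat[ri], receptors$lon[ri],
                 wells$lat[wi], wells$lon[wi])
        wgt <- switch(ph, pad_preparation = 1, drilling = 1,
                      fracturing = wells$total_depth_m[wi],
                      production = wells$avg_daily_gas_volume_m3[wi])
        s <- s + wgt / d^2
      }
      out[[phase_metric[[ph]]]][row] <- s
    }
  }
  out[c("receptor_id", "date", "wa_pad_prep", "wa_drilling", "wa_fracturing",
        "wa_production")]
}

# Independent weighted-kappa oracle: literal element-wise evaluation of the
# definition with explicit loops (no matrix algebra shared with the package).
naive_weighted_kappa <- function(tab, quadratic = FALSE) {
  k <- nrow(tab); n <- sum(tab)
  po <- 0; pe <- 0
  for (i in 1:k) for (j in 1:k) {
    w <- if (quadratic) 1 - ((i - j) / (k - 1))^2 else 1 - abs(i - j) / (k - 1)
    po <- po + w * tab[i, j] / n
    pe <- pe + w * (sum(tab[i, ]) / n) * (sum(tab[, j]) / n)
  }
  (po - pe) / (1 - pe)
}

# Sorted-order linear-interpolation quantile oracle (the standard sample
# quantile, re-derived from first principles).
naive_quantile <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
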