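#' Pooled quartile cut-points
#'
#' Computes the 25th/50th/75th empirical percentiles of a pooled series
#' (linear interpolation between order statistics, the default sample
#' quantile), defining the 'very low' / 'low' / 'medium' / 'high' exposure
#' categories. Exposure series with a mass point — e.g. many zero-WA days —
#' can give non-strictly-increasing cut-points; that is allowed but a warning
#' is emitted since the resulting categories are degenerate.
#'
#' @param values pooled numeric series (all receptors and days), at least 4
#'   non-missing values.
#' @param source label for where the series came from (a WA metric name or
#'   \code{"concentration"}).
#' @param pollutant optional pollutant code, carried for reporting.
#' @return an object of class \code{quartile_scheme}: list with \code{cut25},
#'   \code{cut50}, \code{cut75}, \code{source}, \code{pollutant},
#'   \code{n_pooled}.
#' @export
quartile_scheme <- function(values, source = "concentration", pollutant = NA) {
  values <- values[!is.na(values)]
  if (length(values) < 4)
    stop_data("quartile_scheme needs at least 4 non-missing values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (any(diff(q) <= 0))
    warning(sprintf(
      "degenerate quartile cut-points for %s (%s): %s — series has mass points",
      source, pollutant, paste(signif(q, 6), collapse = ", ")),
      call. = FALSE)
  structure(list(cut25 = q[1], cut50 = q[2], cut75 = q[3], source = source,
                 pollutant = pollutant, n_pooled = length(values)),
            class = "quartile_scheme")
}

#' @export
print.quartile_scheme <- function(x, ...) {
  cat(sprintf("Quartile scheme (%s%s, n = %d): 25%% = %g, 50%% = %g, 75%% = %g\n",
              x$source, if (is.na(x$pollutant)) "" else paste0(", ", x$pollutant),
              x$n_pooled, x$cut25, x$cut50, x$cut75))
  invisible(x)
}

#' Assign quartile exposure categories
#'
#' Values at or below the 25th percentile are 'very_low', at or below the
#' median 'low', at or below the 75th percentile 'medium', above it 'high'
#' (boundary values go to the lower category).
#'
#' @param value numeric vector.
#' @param scheme a [quartile_scheme()].
#' @return ordered factor with levels very_low < low < medium < high.
#' @export
assign_category <- function(value, scheme) {
  code <- 1L + (value > scheme$cut25) + (value > scheme$cut50) +
    (value > scheme$cut75)
  factor(CATEGORY_LEVELS[code], levels = CATEGORY_LEVELS, ordered = TRUE)
}

kappa_weight_matrix <- function(k, weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  dist <- abs(outer(seq_len(k), seq_len(k), "-"))
  if (weights == "linear") 1 - dist / (k - 1) else 1 - (dist / (k - 1))^2
}

#' Weighted Cohen's kappa for a square contingency table
#'
#' Chance-corrected agreement for ordinal categories. With cell proportions
#' \eqn{p_{ij}}, margins \eqn{p_{i.}, p_{.j}} and agreement weights
#' \eqn{w_{ij} = 1 - |i-j|/(k-1)} (linear, the default; quadratic optional),
#' \deqn{\kappa_w = (p_o - p_e)/(1 - p_e), \quad p_o = \sum w_{ij} p_{ij},
#'   \quad p_e = \sum w_{ij} p_{i.} p_{.j}.}
#' The standard error is the Fleiss-Cohen-Everitt large-sample form for
#' weighted kappa (not assuming the null), and the confidence interval is
#' normal, \eqn{\kappa_w \pm z_{1-\alpha/2} \mathrm{se}}.
#'
#' @param table a square matrix of counts (rows: first rater / concentration
#'   category, columns: second rater / WA category).
#' @param weights \code{"linear"} (default) or \code{"quadratic"}.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return object of class \code{weighted_kappa}: list with \code{kappa},
#'   \code{se}, \code{ci} (length 2), \code{p_o}, \code{p_e}, \code{weights},
#'   \code{n}.
#' @references Fleiss, J.L., Cohen, J. and Everitt, B.S. (1969). Large sample
#'   standard errors of kappa and weighted kappa. Psychological Bulletin 72,
#'   323-327.
#' @export
weighted_kappa <- function(table, weights = c("linear", "quadratic"),
                           conf_level = 0.95) {
  weights <- match.arg(weights)
  tab <- as.matrix(table)
  if (nrow(tab) != ncol(tab)) stop_data("weighted_kappa needs a square table")
  n <- sum(tab)
  if (n < 1) stop_data("weighted_kappa needs a non-empty table")
  k <- nrow(tab)
  w <- kappa_weight_matrix(k, weights)
  p <- tab / n
  pi_ <- rowSums(p); pj <- colSums(p)
  p_o <- sum(w * p)
  p_e <- sum(w * outer(pi_, pj))
  if (1 - p_e < .Machine$double.eps^0.5)
    stop_data("weighted kappa undefined: expected agreement is 1 (all mass in one row and one column)")
  kappa <- (p_o - p_e) / (1 - p_e)
  # Fleiss-Cohen-Everitt large-sample variance
  wbar_i <- as.vector(w %*% pj)   # row-conditional expected weights
  wbar_j <- as.vector(pi_ %*% w)
  term <- sum(p * (w - outer(wbar_i, wbar_j, "+") * (1 - kappa))^2)
  var_k <- (term - (kappa - p_e * (1 - kappa))^2) / (n * (1 - p_e)^2)
  se <- sqrt(max(var_k, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(kappa = kappa, se = se, ci = c(kappa - z * se, kappa + z * se),
                 p_o = p_o, p_e = p_e, weights = weights, n = n,
                 conf_level = conf_level),
            class = "weighted_kappa")
}

#' @export
print.weighted_kappa <- function(x, digits = 4, ...) {
  cat(sprintf("Weighted kappa (%s weights): %.*f (se %.*f, %d%% CI %.*f to %.*f), n = %d\n",
              x$weights, digits, x$kappa, digits, x$se,
              round(100 * x$conf_level), digits, x$ci[1], digits, x$ci[2], x$n))
  invisible(x)
}

as_category_codes <- function(x) {
  if (is.factor(x)) {
    code <- as.integer(x)
  } else if (is.numeric(x)) {
    code <- as.integer(x)
    if (any(is.na(code) | code < 1 | code > 4))
      stop_data("numeric categories must be integers in 1..4")
  } else if (is.character(x)) {
    code <- match(x, CATEGORY_LEVELS)
    if (anyNA(code)) stop_data("unknown category label")
  } else stop_data("unsupported category representation")
  code
}

#' Cross-tabulate two quartile classifications
#'
#' Pairs a concentration-based and a WA-based 4-level classification of the
#' same receptor-days, and summarizes their agreement: the 4x4 table (rows =
#' concentration category, columns = WA category), the proportion of pairs in
#' the identical category, the proportion in opposite categories, the
#' row-conditional distribution of WA categories within each concentration
#' category, and the weighted kappa with its confidence interval.
#'
#' "Opposite" defaults to mirrored categories — codes summing to 5 under 1-4
#' coding, i.e. very_low<->high and low<->medium in either order; set
#' \code{opposite = "extremes"} to count only the very_low<->high corners.
#'
#' @param conc,wa either aligned vectors/factors of categories, or data
#'   frames with columns \code{receptor_id}, \code{date}, \code{category}
#'   which are joined on (receptor_id, date); keys present on one side only
#'   are dropped with a message.
#' @param weights kappa weights, \code{"linear"} or \code{"quadratic"}.
#' @param opposite \code{"mirror"} (default) or \code{"extremes"}.
#' @param pollutant,metric labels carried into the report.
#' @return object of class \code{wa_agreement}: list with \code{table},
#'   \code{kappa_w}, \code{se}, \code{ci95}, \code{p_agree},
#'   \code{p_opposite}, \code{row_conditional}, \code{n}, plus the labels.
#' @export
cross_tabulate <- function(conc, wa, weights = c("linear", "quadratic"),
                           opposite = c("mirror", "extremes"),
                           pollutant = NA, metric = NA) {
  weights <- match.arg(weights)
  opposite <- match.arg(opposite)
  if (is.data.frame(conc) || is.data.frame(wa)) {
    if (!(is.data.frame(conc) && is.data.frame(wa)))
      stop_data("conc and wa must both be data frames or both vectors")
    key_c <- paste(conc$receptor_id, conc$date)
    key_w <- paste(wa$receptor_id, wa$date)
    common <- intersect(key_c, key_w)
    dropped <- (nrow(conc) - length(common)) + (nrow(wa) - length(common))
    if (dropped > 0)
      message(sprintf("cross_tabulate: dropped %d records with unmatched (receptor, date) keys", dropped))
    ci <- as_category_codes(conc$category[match(common, key_c)])
    wi <- as_category_codes(wa$category[match(common, key_w)])
  } else {
    if (length(conc) != length(wa))
      stop_data("aligned category vectors must have equal length")
    ci <- as_category_codes(conc)
    wi <- as_category_codes(wa)
  }
  n <- length(ci)
  if (!n) stop_data("no paired observations to cross-tabulate")
  tab <- table(factor(ci, 1:4, labels = CATEGORY_LEVELS),
               factor(wi, 1:4, labels = CATEGORY_LEVELS),
               dnn = c("concentration", "wa"))
  tab <- unclass(tab)
  kap <- weighted_kappa(tab, weights = weights)
  p_agree <- sum(diag(tab)) / n
  opp <- if (opposite == "mirror") outer(1:4, 1:4, function(i, j) i + j == 5)
         else outer(1:4, 1:4, function(i, j) (i == 1 & j == 4) | (i == 4 & j == 1))
  p_opposite <- sum(tab[opp]) / n
  rs <- rowSums(tab)
  row_conditional <- sweep(tab, 1, ifelse(rs > 0, rs, 1), "/")
  structure(list(pollutant = pollutant, metric = metric, table = tab,
                 kappa_w = kap$kappa, se = kap$se, ci95 = kap$ci,
                 p_agree = p_agree, p_opposite = p_opposite,
                 row_conditional = row_conditional, n = n,
                 weights = weights, opposite = opposite),
            class = "wa_agreement")
}

#' @export
print.wa_agreement <- function(x, digits = 4, ...) {
  hdr <- sprintf("Agreement%s%s (n = %d pairs)",
                 if (is.na(x$pollutant)) "" else paste0(": ", x$pollutant),
                 if (is.na(x$metric)) "" else paste0(" vs ", x$metric), x$n)
  cat(hdr, "\n")
  cat(sprintf("  weighted kappa (%s): %.*f  [95%% CI %.*f, %.*f]\n",
              x$weights, digits, x$kappa_w, digits, x$ci95[1], digits, x$ci95[2]))
  cat(sprintf("  identical category: %.1f%%   opposite (%s): %.1f%%\n",
              100 * x$p_agree, x$opposite, 100 * x$p_opposite))
  cat("  4x4 table (rows = concentration, cols = WA):\n")
  print(x$table)
  invisible(x)
}

#' Restrict receptors to those with a well inside a buffer radius
#'
#' Sensitivity-analysis filter: keeps only receptors whose nearest well (over
#' the whole fleet, irrespective of date) lies strictly within
#' \code{radius_km}. \code{Inf} keeps every receptor.
#'
#' @param receptors receptor data frame.
#' @param wells well records.
#' @param radius_km buffer radius in kilometers (10, 30 or \code{Inf} are the
#'   conventional choices).
#' @return the kept receptors.
#' @export
buffer_filter <- function(receptors, wells, radius_km = Inf) {
  if (is.infinite(radius_km) || !nrow(receptors)) return(receptors)
  if (!nrow(wells)) return(receptors[0, , drop = FALSE])
  nearest <- vapply(seq_len(nrow(receptors)), function(i) {
    min(geodesic_distance_m(receptors$lat[i], receptors$lon[i],
                            wells$lat, wells$lon))
  }, numeric(1))
  receptors[nearest < radius_km * 1000, , drop = FALSE]
}

#' Full quartile-agreement analysis of WA metrics vs concentrations
#'
#' The study driver: for each pollutant in \code{daily_conc} and each of the
#' four WA metrics, it
#' \enumerate{
#'   \item restricts to the (receptor, day) pairs with an observation of that
#'     pollutant (WA is only compared where there is air data);
#'   \item optionally drops receptors with no well within \code{buffer_km};
#'   \item optionally replaces single-day concentrations with trailing
#'     rolling means over \code{window_days} days;
#'   \item pools the filtered WA values and concentrations across all
#'     receptors and days, builds a quartile scheme for each (schemes are
#'     recomputed after every filter, since the quartiles of the analyzed
#'     subset are what define the categories);
#'   \item classifies both series and cross-tabulates them.
#' }
#'
#' @param wa_table daily WA values from [compute_daily_wa()].
#' @param daily_conc daily concentration summaries from [daily_summary()]
#'   (multiple pollutants may be stacked).
#' @param receptors,wells needed when \code{buffer_km} is finite.
#' @param buffer_km buffer radius in km (default \code{Inf} = no buffer).
#' @param window_days 1 (single-day, default), 90 or 180 (rolling averages).
#' @param weights kappa weights, \code{"linear"} or \code{"quadratic"}.
#' @param opposite opposite-category definition, see [cross_tabulate()].
#' @param min_obs minimum observations per rolling window.
#' @return object of class \code{wa_agreement_study}: a list with
#'   \code{reports} (one [cross_tabulate()] report per pollutant x metric),
#'   \code{kappas} (flat data frame of kappa, CI, agreement proportions) and
#'   the options used. Methods: \code{print}, \code{summary}, \code{plot},
#'   \code{coef}, \code{as.data.frame}.
#' @export
run_agreement_study <- function(wa_table, daily_conc, receptors = NULL,
                                wells = NULL, buffer_km = Inf, window_days = 1,
                                weights = c("linear", "quadratic"),
                                opposite = c("mirror", "extremes"),
                                min_obs = 5) {
  weights <- match.arg(weights)
  opposite <- match.arg(opposite)
  if (!window_days %in% c(1, 90, 180))
    stop_config("window_days must be 1, 90 or 180")
  if (is.finite(buffer_km)) {
    if (is.null(receptors) || is.null(wells))
      stop_config("buffer_km is finite but receptors/wells were not supplied")
    receptors <- buffer_filter(receptors, wells, buffer_km)
    keep <- daily_conc$receptor_id %in% receptors$receptor_id
    daily_conc <- daily_conc[keep, , drop = FALSE]
    wa_table <- wa_table[wa_table$receptor_id %in% receptors$receptor_id, ,
                         drop = FALSE]
  }
  metrics <- c("wa_pad_prep", "wa_drilling", "wa_fracturing", "wa_production")
  pollutants <- sort(unique(daily_conc$pollutant))
  if (!length(pollutants)) stop_data("no pollutants in daily_conc")
  wa_key <- paste(wa_table$receptor_id, wa_table$date)

  reports <- list()
  for (pl in pollutants) {
    conc <- daily_conc[daily_conc$pollutant == pl, , drop = FALSE]
    if (window_days > 1) conc <- rolling_mean(conc, window_days, min_obs = min_obs)
    idx <- match(paste(conc$receptor_id, conc$date), wa_key)
    ok <- !is.na(idx)
    if (sum(ok) < 4)
      stop_data(sprintf("pollutant %s: fewer than 4 receptor-days with both WA and concentration", pl))
    conc <- conc[ok, , drop = FALSE]
    wa_rows <- wa_table[idx[ok], , drop = FALSE]
    conc_scheme <- quartile_scheme(conc$daily_mean, "concentration", pl)
    conc_cat <- assign_category(conc$daily_mean, conc_scheme)
    for (m in metrics) {
      wa_scheme <- quartile_scheme(wa_rows[[m]], m, pl)
      wa_cat <- assign_category(wa_rows[[m]], wa_scheme)
      rep_ <- cross_tabulate(conc_cat, wa_cat, weights = weights,
                             opposite = opposite, pollutant = pl, metric = m)
      rep_$conc_scheme <- conc_scheme
      rep_$wa_scheme <- wa_scheme
      reports[[paste(pl, m, sep = ".")]] <- rep_
    }
  }
  kappas <- do.call(rbind, lapply(reports, function(r) {
    data.frame(pollutant = r$pollutant, metric = r$metric,
               buffer_km = buffer_km, window_days = window_days,
               n = r$n, kappa = r$kappa_w, se = r$se,
               ci_lower = r$ci95[1], ci_upper = r$ci95[2],
               p_agree = r$p_agree, p_opposite = r$p_opposite,
               stringsAsFactors = FALSE)
  }))
  rownames(kappas) <- NULL
  structure(list(reports = reports, kappas = kappas, buffer_km = buffer_km,
                 window_days = window_days, weights = weights,
                 opposite = opposite),
            class = "wa_agreement_study")
}

#' @export
print.wa_agreement_study <- function(x, digits = 3, ...) {
  cat(sprintf("Well-activity vs concentration agreement study (%d reports)\n",
              nrow(x$kappas)))
  cat(sprintf("  buffer: %s km, window: %d day(s), %s kappa weights\n",
              if (is.infinite(x$buffer_km)) "no" else x$buffer_km,
              x$window_days, x$weights))
  df <- x$kappas
  df$kappa <- round(df$kappa, digits)
  df$p_agree <- round(df$p_agree, digits)
  df$p_opposite <- round(df$p_opposite, digits)
  print(df[c("pollutant", "metric", "n", "kappa", "p_agree", "p_opposite")],
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.wa_agreement_study <- function(object, ...) {
  k <- object$kappas$kappa
  cat("Well-activity vs concentration agreement study\n")
  cat(sprintf("  %d pollutant x metric reports, %s pairs total\n",
              nrow(object$kappas), format(sum(object$kappas$n), big.mark = ",")))
  cat(sprintf("  weighted kappa: min %.3f, median %.3f, max %.3f\n",
              min(k), stats::median(k), max(k)))
  cat(sprintf("  identical-category proportion: %.1f%% - %.1f%%\n",
              100 * min(object$kappas$p_agree), 100 * max(object$kappas$p_agree)))
  cat(sprintf("  opposite-category proportion: %.1f%% - %.1f%%\n",
              100 * min(object$kappas$p_opposite),
              100 * max(object$kappas$p_opposite)))
  invisible(object$kappas)
}

#' @export
coef.wa_agreement_study <- function(object, ...) {
  with(object$kappas,
       stats::xtabs(kappa ~ pollutant + metric))
}

#' @export
as.data.frame.wa_agreement_study <- function(x, ...) x$kappas

#' Plot weighted kappas per pollutant and metric
#'
#' Dot-and-interval chart of the weighted kappa (with 95\% CI) for every
#' pollutant x WA-metric combination, grouped by metric, with reference lines
#' at 0 and +/-0.2 (the boundary below which agreement is read as none to
#' poor).
#'
#' @param x a \code{wa_agreement_study}.
#' @param ... passed to \code{plot}.
#' @export
plot.wa_agreement_study <- function(x, ...) {
  df <- x$kappas
  df <- df[order(df$metric, df$pollutant), , drop = FALSE]
  y <- rev(seq_len(nrow(df)))
  old <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(old))
  rng <- range(c(df$ci_lower, df$ci_upper, -0.25, 0.25))
  graphics::plot(df$kappa, y, xlim = rng, yaxt = "n", pch = 19,
                 xlab = "weighted kappa", ylab = "",
                 main = "WA vs concentration quartile agreement", ...)
  graphics::segments(df$ci_lower, y, df$ci_upper, y)
  graphics::abline(v = 0, lty = 1, col = "grey40")
  graphics::abline(v = c(-0.2, 0.2), lty = 3, col = "grey60")
  graphics::axis(2, at = y, labels = paste(df$pollutant, df$metric, sep = " / "),
                 las = 1, cex.axis = 0.7)
  invisible(x)
}
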