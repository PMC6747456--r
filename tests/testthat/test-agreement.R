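test_that("quartile cut-points match the sorted-order interpolation oracle", {
  expect_equal(unlist(quartile_scheme(1:8)[c("cut25", "cut50", "cut75")]),
               c(cut25 = 2.75, cut50 = 4.5, cut75 = 6.25))
  set.seed(2)
  for (x in list(rlnorm(37), rnorm(101), runif(400))) {
    s <- quartile_scheme(x)
    expect_equal(s$cut25, naive_quantile(x, 0.25))
    expect_equal(s$cut50, naive_quantile(x, 0.50))
    expect_equal(s$cut75, naive_quantile(x, 0.75))
  }
  expect_warning(quartile_scheme(rep(3, 10)), "degenerate")
  expect_error(quartile_scheme(1:3), "at least 4")
})

test_that("a series engineered to the benzene quantiles recovers them as cut-points", {
  # piecewise-linear series whose empirical quartiles are 0.11 / 0.16 / 0.23
  x <- c(seq(0.05, 0.11, length.out = 26), seq(0.11, 0.16, length.out = 26)[-1],
         seq(0.16, 0.23, length.out = 26)[-1], seq(0.23, 0.60, length.out = 26)[-1])
  s <- quartile_scheme(x, "concentration", "benzene")
  expect_equal(s$cut25, 0.11, tolerance = 1e-6)
  expect_equal(s$cut50, 0.16, tolerance = 1e-6)
  expect_equal(s$cut75, 0.23, tolerance = 1e-6)
})

test_that("category assignment sends boundaries down and splits mass evenly", {
  s <- quartile_scheme(1:8)
  expect_equal(as.character(assign_category(s$cut25, s)), "very_low")
  expect_equal(as.character(assign_category(s$cut50, s)), "low")
  expect_equal(as.character(assign_category(s$cut75 + 1e-9, s)), "high")
  set.seed(3)
  x <- runif(1e5)
  cats <- assign_category(x, quartile_scheme(x))
  expect_true(all(abs(as.numeric(table(cats)) / 1e5 - 0.25) < 0.01))
})

test_that("weighted kappa reproduces independently computed values on fixed tables", {
  tab <- matrix(c(10, 5, 3, 2,
                  4, 10, 4, 2,
                  2, 4, 10, 4,
                  1, 3, 5, 11), 4, 4, byrow = TRUE)
  k <- weighted_kappa(tab)
  # frozen values from an independent numerical evaluation of the definition
  expect_equal(k$kappa, 0.4387755102040818, tolerance = 1e-12)
  expect_equal(k$se, 0.0772308123188895, tolerance = 1e-10)
  expect_equal(k$ci, k$kappa + c(-1, 1) * qnorm(0.975) * k$se)
  expect_equal(weighted_kappa(tab, weights = "quadratic")$kappa, 0.515625,
               tolerance = 1e-12)
  # literal-formula oracle agrees on random tables
  set.seed(8)
  for (i in 1:20) {
    t2 <- matrix(rpois(16, 8), 4, 4)
    if (sum(t2) == 0) next
    expect_equal(weighted_kappa(t2)$kappa, naive_weighted_kappa(t2),
                 tolerance = 1e-12)
    expect_equal(weighted_kappa(t2, weights = "quadratic")$kappa,
                 naive_weighted_kappa(t2, quadratic = TRUE), tolerance = 1e-12)
  }
})

test_that("weighted kappa honors its boundary and symmetry properties", {
  diag_tab <- diag(c(5, 7, 3, 9))
  expect_equal(weighted_kappa(diag_tab)$kappa, 1)
  uniform <- matrix(4, 4, 4)
  expect_equal(weighted_kappa(uniform)$kappa, 0)
  set.seed(12)
  for (i in 1:10) {
    t2 <- matrix(rpois(16, 5), 4, 4)
    k <- weighted_kappa(t2)$kappa
    expect_gte(k, -1); expect_lte(k, 1)
    expect_equal(weighted_kappa(t(t2))$kappa, k)
    # kappa = 1 only with an empty off-diagonal
    if (sum(t2) - sum(diag(t2)) > 0) expect_lt(k, 1)
  }
  degenerate <- matrix(0, 4, 4); degenerate[2, 2] <- 10
  expect_error(weighted_kappa(degenerate), "undefined")
})

test_that("cross-tabulation reports agreement, opposition and row conditionals", {
  set.seed(21)
  a <- sample(1:4, 500, replace = TRUE)

  ident <- cross_tabulate(a, a)
  expect_equal(ident$p_agree, 1)
  expect_equal(ident$p_opposite, 0)
  expect_equal(ident$kappa_w, 1)

  rev_ <- cross_tabulate(a, 5 - a)
  expect_equal(rev_$p_agree, 0)
  expect_equal(rev_$p_opposite, 1)

  # extremes-only opposite counts just the VL<->H corners
  ext <- cross_tabulate(a, 5 - a, opposite = "extremes")
  expect_equal(ext$p_opposite, mean(a %in% c(1, 4)))

  b <- sample(1:4, 500, replace = TRUE)
  rep_ <- cross_tabulate(a, b)
  expect_equal(sum(rep_$table), 500)
  rs <- rowSums(rep_$row_conditional)
  expect_true(all(abs(rs[rowSums(rep_$table) > 0] - 1) < 1e-12))
  expect_true(rep_$ci95[1] <= rep_$kappa_w && rep_$kappa_w <= rep_$ci95[2])
})

test_that("keyed category series are joined on (receptor, date), dropping strays", {
  days <- as.Date("2012-06-01") + 0:9
  conc <- data.frame(receptor_id = "R1", date = days,
                     category = rep(1:4, length.out = 10))
  wa <- data.frame(receptor_id = "R1", date = days + 2,   # 8-day overlap
                   category = rep(1:4, length.out = 10))
  expect_message(rep_ <- cross_tabulate(conc, wa), "dropped 4")
  expect_equal(rep_$n, 8)
  common <- as.Date(intersect(conc$date, wa$date), origin = "1970-01-01")
  aligned_c <- conc$category[match(common, conc$date)]
  aligned_w <- wa$category[match(common, wa$date)]
  expect_equal(rep_$table, cross_tabulate(aligned_c, aligned_w)$table)
})

test_that("agreement outputs are invariant under strictly increasing transforms", {
  set.seed(31)
  conc_vals <- rlnorm(800)
  wa_vals <- conc_vals * exp(rnorm(800, sd = 0.8))
  base_rep <- cross_tabulate(
    assign_category(conc_vals, quartile_scheme(conc_vals)),
    assign_category(wa_vals, quartile_scheme(wa_vals)))
  for (f in list(function(x) log(x), function(x) x^3 + 2 * x,
                 function(x) rank(x, ties.method = "first"))) {
    tc <- f(conc_vals); tw <- f(wa_vals)
    rep_t <- cross_tabulate(assign_category(tc, quartile_scheme(tc)),
                            assign_category(tw, quartile_scheme(tw)))
    expect_equal(rep_t$table, base_rep$table)
    expect_equal(rep_t$kappa_w, base_rep$kappa_w)
    expect_equal(rep_t$p_agree, base_rep$p_agree)
    expect_equal(rep_t$p_opposite, base_rep$p_opposite)
  }
})

test_that("buffer filter keeps exactly the receptors with a well in radius", {
  wells <- well_row("W1", lat = 40, lon = -78)
  r12 <- receptor_row("R12", lat = offset_north(40, 12000), lon = -78)
  expect_equal(nrow(buffer_filter(r12, wells, 10)), 0)
  expect_equal(nrow(buffer_filter(r12, wells, 30)), 1)
  expect_equal(buffer_filter(r12, wells, Inf), r12)

  set.seed(14)
  receptors <- do.call(rbind, lapply(1:10, function(i)
    receptor_row(sprintf("R%02d", i), runif(1, 40, 41), runif(1, -79, -77))))
  fleet <- do.call(rbind, lapply(1:12, function(i)
    well_row(sprintf("W%02d", i), lat = runif(1, 40, 41),
             lon = runif(1, -79, -77))))
  for (radius in c(10, 30)) {
    kept <- buffer_filter(receptors, fleet, radius)
    brute <- vapply(seq_len(nrow(receptors)), function(i)
      min(geodesic_distance_m(receptors$lat[i], receptors$lon[i],
                              fleet$lat, fleet$lon)) < radius * 1000,
      logical(1))
    expect_equal(kept$receptor_id, receptors$receptor_id[brute])
  }
})

test_that("the study driver emits one report per pollutant and metric", {
  set.seed(41)
  days <- as.Date("2012-01-01") + 0:199
  receptors <- do.call(rbind, lapply(1:5, function(i)
    receptor_row(sprintf("R%d", i), runif(1, 40, 41), runif(1, -79, -77))))
  wa <- expand.grid(receptor_id = receptors$receptor_id, date = days,
                    stringsAsFactors = FALSE)
  for (m in c("wa_pad_prep", "wa_drilling", "wa_fracturing", "wa_production"))
    wa[[m]] <- rlnorm(nrow(wa))
  conc <- do.call(rbind, lapply(c("benzene", "co", "no2", "o3", "pm25", "so2"),
    function(pl) data.frame(receptor_id = wa$receptor_id, date = wa$date,
                            pollutant = pl, daily_mean = rlnorm(nrow(wa)),
                            daily_max = NA_real_, basis = "sample_24h")))
  st <- run_agreement_study(wa, conc)
  expect_s3_class(st, "wa_agreement_study")
  expect_equal(nrow(st$kappas), 24)
  expect_setequal(unique(st$kappas$pollutant),
                  c("benzene", "co", "no2", "o3", "pm25", "so2"))
  expect_equal(as.data.frame(st), st$kappas)
  expect_equal(dim(coef(st)), c(6, 4))
  expect_output(print(st), "24 reports")
  expect_output(print(summary(st)), "weighted kappa")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(st))
})

test_that("rolling windows and buffers change the analyzed subset coherently", {
  set.seed(51)
  days <- as.Date("2012-01-01") + seq(0, 594, by = 6)
  wells <- well_row("W1", lat = 40, lon = -78)
  near <- receptor_row("Rnear", lat = offset_north(40, 5000), lon = -78)
  far <- receptor_row("Rfar", lat = offset_north(40, 50000), lon = -78)
  receptors <- rbind(near, far)
  wa <- expand.grid(receptor_id = receptors$receptor_id, date = days,
                    stringsAsFactors = FALSE)
  for (m in c("wa_pad_prep", "wa_drilling", "wa_fracturing", "wa_production"))
    wa[[m]] <- rlnorm(nrow(wa))
  conc <- data.frame(receptor_id = wa$receptor_id, date = wa$date,
                     pollutant = "benzene", daily_mean = rlnorm(nrow(wa)),
                     daily_max = NA_real_, basis = "sample_24h")
  # 10-km buffer keeps only the near receptor
  st10 <- run_agreement_study(wa, conc, receptors = receptors, wells = wells,
                              buffer_km = 10)
  expect_equal(st10$kappas$n[1], sum(conc$receptor_id == "Rnear"))
  expect_error(run_agreement_study(wa, conc, buffer_km = 10), "receptors")
  # 90-day rolling averages shrink the series by the window spin-up only
  st90 <- run_agreement_study(wa, conc, window_days = 90)
  expect_lt(st90$kappas$n[1], nrow(conc))
  expect_gt(st90$kappas$n[1], 0.8 * nrow(conc))
  expect_error(run_agreement_study(wa, conc, window_days = 45), "window_days")
})
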