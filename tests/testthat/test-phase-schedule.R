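test_that("drilling duration spans 1..30 days, linearly and monotonically in depth percentile", {
  expect_equal(drilling_duration_days(0), 1L)
  expect_equal(drilling_duration_days(1), 30L)
  expect_equal(drilling_duration_days(0.5), 16L)  # round half-up of 15.5
  expect_error(drilling_duration_days(1.2), "\\[0, 1\\]")

  p <- seq(0, 1, by = 0.01)
  d <- drilling_duration_days(p)
  expect_true(all(d >= 1 & d <= 30))
  expect_true(all(diff(d) >= 0))
})

test_that("midrank depth percentile handles ties and single-depth fleets", {
  depths <- c(1000, 1500, 1500, 2000)
  p <- depth_percentile(depths, depths)
  expect_equal(p, c(0.125, 0.5, 0.5, 0.875))
  expect_equal(depth_percentile(3000, 3000), 0.5)
})

test_that("phase windows have the stated lengths and bounds", {
  w <- well_row("W1", spud = "2012-06-15", stim = "2012-06-15",
                first_prod = "2013-01-01", last_prod = NULL)
  win <- build_phase_windows(w, pad_first_spud = as.Date("2012-06-15"),
                             all_depths = 2000, study_end = "2015-12-31")
  # pad prep: the 30 days before the pad's first spud
  expect_equal(win$pad_preparation,
               as.Date(c("2012-05-16", "2012-06-14")))
  expect_equal(as.integer(diff(win$pad_preparation)) + 1L, 30L)
  # fracturing: exactly 7 days from the stimulation date
  expect_equal(win$fracturing, as.Date(c("2012-06-15", "2012-06-21")))
  expect_equal(as.integer(diff(win$fracturing)) + 1L, 7L)
  # missing last production reads as "through the end of the study"
  expect_equal(win$production, as.Date(c("2013-01-01", "2015-12-31")))
  # drilling within [1, 30] days starting on the spud date
  expect_equal(win$drilling[1], as.Date("2012-06-15"))
  expect_lte(as.integer(diff(win$drilling)) + 1L, 30L)

  # non-first well on the pad carries no pad-prep window
  win2 <- build_phase_windows(w, pad_first_spud = as.Date("2012-06-01"),
                              all_depths = 2000, study_end = "2015-12-31")
  expect_null(win2$pad_preparation)
})

test_that("calendar expansion clips to the study period, one phase per well-day", {
  w <- well_row("W1", spud = "2012-06-15", stim = "2012-06-20",
                first_prod = "2012-08-01", last_prod = "2014-06-30",
                depth = 2500)
  cal <- build_phase_calendar(w, "2012-01-01", "2013-12-31")
  expect_true(all(cal$date >= as.Date("2012-01-01")))
  expect_true(all(cal$date <= as.Date("2013-12-31")))
  expect_equal(anyDuplicated(cal[c("well_id", "date")]), 0)
  # production truncated at study_end, not at last_production
  expect_equal(max(cal$date[cal$phase == "production"]), as.Date("2013-12-31"))

  # a well whose only window is production covering the whole study
  w2 <- well_row("W2", spud = "2010-01-01", stim = "2010-02-01",
                 first_prod = "2010-03-01", last_prod = NULL)
  cal2 <- build_phase_calendar(w2, "2012-01-01", "2012-12-31")
  expect_equal(nrow(cal2), 366)
  expect_true(all(cal2$phase == "production"))

  expect_equal(nrow(build_phase_calendar(w[0, ], "2012-01-01", "2012-12-31")), 0)
  expect_error(build_phase_calendar(w, "2013-01-01", "2012-01-01"),
               "study_start")
})

test_that("overlapping windows resolve by later-phase precedence", {
  # drilling [d0, d0+9] overlapping fracturing [d0+8, d0+14]
  d0 <- as.Date("2012-06-15")
  w <- well_row("W1", spud = d0, stim = d0 + 8, first_prod = NULL,
                last_prod = NULL, depth = 10000)  # deep => 30-day drilling
  cal <- build_phase_calendar(w, "2012-01-01", "2012-12-31")
  ph <- function(d) as.character(cal$phase[cal$date == d])
  expect_equal(ph(d0 + 7), "drilling")
  expect_equal(ph(d0 + 8), "fracturing")
  expect_equal(ph(d0 + 9), "fracturing")
  # production wins over everything from the first production day onward
  # (the 30 days before the spud are still the pad-preparation window)
  w2 <- well_row("W2", spud = d0, stim = d0, first_prod = d0,
                 last_prod = d0 + 400)
  cal2 <- build_phase_calendar(w2, "2012-01-01", "2012-12-31")
  expect_true(all(cal2$phase[cal2$date >= d0] == "production"))
  expect_true(all(cal2$phase[cal2$date < d0] == "pad_preparation"))
})

test_that("pad preparation is attributed once per pad, to the first-spudded well", {
  wells <- wells_fixture(
    well_row("W2", "P1", spud = "2012-06-15", stim = NULL, first_prod = NULL,
             last_prod = NULL),
    well_row("W1", "P1", spud = "2012-06-15", stim = NULL, first_prod = NULL,
             last_prod = NULL),   # tie -> lowest well_id carries pad prep
    well_row("W3", "P1", spud = "2012-09-01", stim = NULL, first_prod = NULL,
             last_prod = NULL))
  cal <- build_phase_calendar(wells, "2012-01-01", "2012-12-31")
  prep <- cal[cal$phase == "pad_preparation", ]
  expect_equal(unique(prep$well_id), "W1")
  expect_equal(nrow(prep), 30)
})

test_that("active-well lookup matches an exhaustive scan (staggered five-well fleet)", {
  wells <- do.call(rbind, lapply(1:5, function(i)
    well_row(sprintf("W%d", i), sprintf("P%d", i),
             spud = as.Date("2011-01-10") + 25 * i,
             stim = as.Date("2011-03-01") + 25 * i,
             first_prod = as.Date("2011-05-01") + 25 * i,
             last_prod = as.Date("2011-12-01") + 10 * i)))
  cal <- build_phase_calendar(wells, "2011-01-01", "2011-12-31")
  dates <- seq.Date(as.Date("2011-01-01"), as.Date("2011-12-31"), by = "15 days")
  for (d in as.list(dates)) for (ph in levels(cal$phase)) {
    brute <- sort(unique(cal$well_id[cal$date == d &
                                       as.character(cal$phase) == ph]))
    expect_equal(sort(wells_active_on(cal, d, ph)), brute)
  }
  # a date before any window
  expect_length(wells_active_on(cal, "2010-06-01", "drilling"), 0)
})

test_that("per-day phase counts add up to per-day totals over a simulated fleet", {
  cfg <- simulation_config(n_pads = 20, wells_per_pad = 2, seed = 5,
                           study_start = "2012-01-01", study_end = "2012-12-31")
  wells <- simulate_wells(cfg)
  cal <- build_phase_calendar(wells, cfg$study_start, cfg$study_end)
  by_day_phase <- table(cal$date, cal$phase)
  expect_equal(unname(rowSums(by_day_phase)),
               unname(as.vector(table(cal$date))))
  expect_equal(anyDuplicated(cal[c("well_id", "date")]), 0)
})
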