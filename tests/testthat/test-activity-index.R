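test_that("independence filter applies the last-retained rule", {
  r <- rec("s1", "boar", c("2015-01-01 00:00:00", "2015-01-01 00:20:00",
                           "2015-01-01 00:40:00"))
  ev <- filter_independent_events(r, 30)
  expect_equal(format(ev$timestamp, "%H:%M"), c("00:00", "00:40"))

  # different species are independent streams
  r2 <- rbind(rec("s1", "boar", "2015-01-01 00:00:00"),
              rec("s1", "civet", "2015-01-01 00:05:00"))
  expect_equal(nrow(filter_independent_events(r2, 30)), 2)

  # individually distinguished animals are independent streams
  r3 <- rbind(rec("s1", "boar", "2015-01-01 00:00:00", "A"),
              rec("s1", "boar", "2015-01-01 00:05:00", "B"))
  expect_equal(nrow(filter_independent_events(r3, 30)), 2)

  expect_error(filter_independent_events(r, -5), "non-negative")
})

test_that("filtering is idempotent and monotone in the interval", {
  set.seed(7)
  for (case in 1:10) {
    n <- 40
    r <- rec(sample(c("s1", "s2"), n, TRUE), sample(c("a", "b"), n, TRUE),
             as.POSIXct("2015-01-01", tz = "UTC") +
               sort(sample.int(36 * 3600, n)))
    ev <- filter_independent_events(r, 30)
    ev2 <- filter_independent_events(ev, 30)
    expect_equal(nrow(ev2), nrow(ev))
    expect_equal(ev2$timestamp, ev$timestamp)
    n60 <- nrow(filter_independent_events(r, 60))
    expect_lte(n60, nrow(ev))
  }
})

test_that("trap-night accounting subtracts malfunction nights", {
  dep <- data.frame(site_id = "s1", camera_brand = "KeepGuard",
                    interval_type = c("active", "malfunction"),
                    start_date = as.Date(c("2015-01-01", "2015-01-11")),
                    end_date = as.Date(c("2015-01-30", "2015-01-15")))
  expect_equal(compute_trap_nights(dep)$trap_nights, 25L)

  dep2 <- data.frame(site_id = "s1", camera_brand = "KeepGuard",
                     interval_type = "active",
                     start_date = as.Date(c("2015-01-01", "2015-03-01")),
                     end_date = as.Date(c("2015-01-10", "2015-03-10")))
  expect_equal(compute_trap_nights(dep2)$trap_nights, 20L)

  dep3 <- data.frame(site_id = "s1", camera_brand = "KeepGuard",
                     interval_type = c("active", "malfunction"),
                     start_date = as.Date("2015-01-01"),
                     end_date = as.Date("2015-01-30"))
  expect_equal(compute_trap_nights(dep3)$trap_nights, 0L)

  dep4 <- data.frame(site_id = "s1", camera_brand = "KeepGuard",
                     interval_type = c("active", "malfunction"),
                     start_date = as.Date(c("2015-01-01", "2015-02-10")),
                     end_date = as.Date(c("2015-01-30", "2015-02-12")))
  expect_error(compute_trap_nights(dep4), "outside active")
})

test_that("RAI is events per 100 trap-nights with zero-fill", {
  tn <- data.frame(site_id = "s1", trap_nights = 250L)
  ev <- rec("s1", "boar", as.POSIXct("2015-01-01", tz = "UTC") +
              3600 * seq_len(5) * 24)
  ev$season <- assign_season(ev$timestamp)
  r <- compute_rai(ev, tn, species = c("boar", "civet"))
  expect_equal(r$rai[r$species_id == "boar"], 2.0)
  expect_equal(r$rai[r$species_id == "civet"], 0.0)

  tn2 <- data.frame(site_id = "s1", trap_nights = 100L)
  expect_equal(compute_rai(ev, tn2)$rai, 5.0)

  # scale property: doubling events and nights leaves RAI unchanged
  extra <- rec("s1", "boar", ev$timestamp + 12 * 3600)
  extra$season <- assign_season(extra$timestamp)
  ev2 <- rbind(ev, extra)
  tn3 <- data.frame(site_id = "s1", trap_nights = 500L)
  expect_equal(compute_rai(ev2, tn3)$rai, 2.0)

  # events at a site with zero effort is inconsistent
  tn0 <- data.frame(site_id = "s1", trap_nights = 0L)
  expect_error(compute_rai(ev, tn0), "zero trap-nights")
})

test_that("seasonal RAI averages monthly RAIs at qualifying sites", {
  # one site, effort across two seasons, >= 60 days each
  dep <- data.frame(site_id = "s1", camera_brand = "KeepGuard",
                    interval_type = "active",
                    start_date = as.Date("2015-04-01"),
                    end_date = as.Date("2015-09-30"))
  # May: 2 events over 31 nights; June: 4 events over 30 nights
  ts <- as.POSIXct(c("2015-05-02 01:00:00", "2015-05-20 03:00:00",
                     "2015-06-01 02:00:00", "2015-06-08 02:00:00",
                     "2015-06-15 02:00:00", "2015-06-22 02:00:00"),
                   tz = "UTC")
  ev <- rec("s1", "civet", ts)
  ev$season <- assign_season(ev$timestamp)
  sr <- seasonal_rai(ev, dep, min_days_per_season = 60, min_seasons = 2)
  got <- sr$rai[sr$season == "APR_JUL" & sr$species_id == "civet"]
  # monthly RAIs: Apr 0, May 100*2/31, Jun 100*4/30, Jul 100*0/31
  expect_equal(got, mean(c(0, 100 * 2 / 31, 100 * 4 / 30, 0)))

  # 59 days per season -> excluded
  dep59 <- data.frame(site_id = "s1", camera_brand = "KeepGuard",
                      interval_type = "active",
                      start_date = as.Date(c("2015-04-01", "2015-08-02")),
                      end_date = as.Date(c("2015-05-29", "2015-09-29")))
  ev59 <- ev[1:2, ]
  expect_warning(sr59 <- seasonal_rai(ev59, dep59, 60, 2), "no site")
  expect_equal(nrow(sr59), 0)

  # single-season site -> excluded
  dep1 <- data.frame(site_id = "s1", camera_brand = "KeepGuard",
                     interval_type = "active",
                     start_date = as.Date("2015-04-10"),
                     end_date = as.Date("2015-07-20"))
  expect_warning(sr1 <- seasonal_rai(ev, dep1, 60, 2), "no site")
  expect_equal(nrow(sr1), 0)
})

test_that("Mann-Whitney U matches hand/oracle values", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_identical(r$method, "exact")

  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_error(mann_whitney_u(numeric(0), 1), "empty")

  # large samples switch to the normal approximation
  set.seed(1)
  big <- mann_whitney_u(rnorm(15), rnorm(15, 1))
  expect_identical(big$method, "normal")
  expect_true(big$p >= 0 && big$p <= 1)
})
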