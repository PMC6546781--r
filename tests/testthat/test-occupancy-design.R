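test_that("detection occasions discretize effort as specified", {
  dep <- data.frame(site_id = "s1", camera_brand = "Cuddeback",
                    interval_type = "active",
                    start_date = as.Date("2015-01-01"),
                    end_date = as.Date("2015-01-30"))
  ev <- rec("s1", "boar", c("2015-01-02 01:00:00", "2015-01-25 01:00:00"))
  ev$season <- assign_season(ev$timestamp)
  h <- build_detection_history(ev, dep, occasion_length_days = 10)
  expect_equal(h$K, 3L)                       # 30 effort days / 10
  expect_equal(h$y["boar", "s1"], 2L)         # occasions 1 and 3

  # repeats within an occasion collapse
  ev2 <- rec("s1", "boar", c("2015-01-02 01:00:00", "2015-01-02 09:00:00"))
  ev2$season <- assign_season(ev2$timestamp)
  h2 <- build_detection_history(ev2, dep, occasion_length_days = 10)
  expect_equal(h2$y["boar", "s1"], 1L)

  # trailing partial occasion counts; y <= K always
  h3 <- build_detection_history(ev, dep, occasion_length_days = 7)
  expect_equal(h3$K, ceiling(30 / 7))
  expect_true(all(h3$y <= h3$K))
  expect_equal(h3$brand, "Cuddeback")
})

test_that("covariate preparation standardizes and squares correctly", {
  set.seed(3)
  n <- 12
  cov <- data.frame(site_id = sprintf("s%02d", 1:n),
                    x = runif(n), y = runif(n),
                    dist_settlement_m = runif(n, 100, 2000),
                    dist_water_m = runif(n, 10, 500),
                    elevation_m = runif(n, 100, 1000),
                    slope_deg = runif(n, 0, 40),
                    solar_radiation = rnorm(n, 1, 0.1),
                    vegetation = "broadleaf")
  rai <- rbind(data.frame(site_id = cov$site_id, species_id = "dog",
                          events = rpois(n, 3), trap_nights = 100,
                          rai = NA),
               data.frame(site_id = cov$site_id, species_id = "cat",
                          events = rpois(n, 1), trap_nights = 100,
                          rai = NA))
  rai$rai <- 100 * rai$events / rai$trap_nights
  rai$rai[1] <- 0  # log1p(0) = 0 path
  brand <- setNames(rep(c("KeepGuard", "Cuddeback", "Reconyx"), length.out = n),
                    cov$site_id)
  d <- prepare_covariates(cov, rai, brand, cov$site_id)

  for (cc in c("dist_settlement", "dog_rai", "cat_rai")) {
    expect_lt(abs(mean(d$occ[, cc])), 1e-12)
    expect_equal(sd(d$occ[, cc]), 1, tolerance = 1e-12)
  }
  expect_equal(d$occ[, "dog_rai_sq"], d$occ[, "dog_rai"]^2)
  # the transform record reproduces the standardization
  tr <- d$transform$log_dog_rai
  dog_raw <- rai$rai[rai$species_id == "dog"]
  expect_equal(unname(d$occ[, "dog_rai"]),
               (log1p(dog_raw) - tr$mean) / tr$sd)
  # brand indicators mutually exclusive, KeepGuard reference
  expect_true(all(d$det[, "cuddeback"] + d$det[, "reconyx"] <= 1))
  expect_equal(sum(d$det[brand == "KeepGuard", c("cuddeback", "reconyx")]), 0)

  cov$dist_settlement_m <- 500  # constant
  expect_error(prepare_covariates(cov, rai, brand, cov$site_id),
               "zero-variance")
})

test_that("correlation screen flags collinear pairs", {
  x <- c(1, 2, 3, 4)
  scr <- correlation_screen(cbind(a = x, b = x, c = -x, d = c(1, 3, 2, 4)),
                            r_threshold = 0.3)
  expect_equal(scr$r[scr$var_a == "a" & scr$var_b == "b"], 1)
  expect_equal(scr$r[scr$var_a == "a" & scr$var_b == "c"], -1)
  expect_equal(scr$r[scr$var_a == "a" & scr$var_b == "d"], 0.8)
  expect_true(all(scr$flagged[abs(scr$r) >= 0.3]))
  expect_error(correlation_screen(cbind(1:2, 2:1)), "at least 3")
})
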