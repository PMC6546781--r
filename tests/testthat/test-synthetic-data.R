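test_that("von Mises sampler has the right circular moments", {
  set.seed(51)
  x <- rvonmises(5000, pi, 8)
  cm <- atan2(mean(sin(x)), mean(cos(x))) %% (2 * pi)
  expect_lt(abs(cm - pi), 0.05)
  expect_true(all(x >= 0 & x < 2 * pi))

  # balanced antipodal mixture: resultant length near 0
  mix <- list(weights = c(0.5, 0.5), mu = c(0, pi), kappa = c(4, 4))
  y <- simulate_diel_samples(mix, 5000, seed = 52)
  expect_lt(sqrt(mean(cos(y))^2 + mean(sin(y))^2), 0.05)

  y1 <- simulate_diel_samples(mix, 1, seed = 53)
  expect_true(y1 >= 0 && y1 < 2 * pi)
  bad <- list(weights = c(0.6, 0.6), mu = c(0, pi), kappa = c(1, 1))
  expect_error(simulate_diel_samples(bad, 10), "sum to 1")
})

test_that("simulation config validates its fields", {
  expect_error(simulation_config(n_sites = 0), "n_sites")
  expect_error(simulation_config(
    occ_hyper = list(mu = rep(0, 6), sigma = c(rep(1, 5), -1))), "sigma")
  expect_error(simulation_config(
    det_hyper = list(mu = rep(0, 3), sigma = rep(1, 3))), "5 families")
  cfg <- paper_scale_config()
  expect_equal(cfg$n_sites, 121)
  expect_equal(cfg$n_species, 9)
  expect_equal(cfg$mean_deployment_days, 143)
})

test_that("simulated studies are deterministic and internally consistent", {
  cfg <- simulation_config(n_sites = 15, n_species = 3, seed = 99)
  sim1 <- simulate_community(cfg)
  sim2 <- simulate_community(cfg)
  expect_identical(sim1$detections, sim2$detections)
  expect_identical(sim1$deployments, sim2$deployments)
  expect_identical(sim1$covariates, sim2$covariates)

  # all generated records validate against their own deployments
  ds <- validate_dataset(sim1$detections, sim1$deployments, sim1$covariates)
  expect_s3_class(ds, "camtrap_dataset")

  # every native detection implies z = 1 at its site/species
  natives <- grep("^native", unique(sim1$detections$species_id), value = TRUE)
  for (sp in natives) {
    sites_with <- unique(sim1$detections$site_id[
      sim1$detections$species_id == sp])
    expect_true(all(sim1$truth$z[sp, sites_with] == 1))
  }
})

test_that("degenerate probabilities saturate detections", {
  cfg <- simulation_config(
    n_sites = 8, n_species = 2, seed = 7,
    occ_hyper = list(mu = c(20, 0, 0, 0, 0, 0), sigma = rep(1e-6, 6)),
    det_hyper = list(mu = c(20, 0, 0, 0, 0), sigma = rep(1e-6, 5)))
  sim <- simulate_community(cfg)
  expect_true(all(sim$truth$z == 1))
  ds <- validate_dataset(sim$detections, sim$deployments, sim$covariates)
  ev <- filter_independent_events(ds$records)
  h <- build_detection_history(
    ev[grepl("^native", ev$species_id), ], ds$deployments,
    cfg$occasion_length_days,
    species = rownames(sim$truth$z))
  expect_true(all(h$y == matrix(h$K, nrow(h$y), ncol(h$y), byrow = TRUE)))
})

test_that("realized occupancy tracks psi at scale", {
  sim <- simulate_detection_history(2000, 1, 1,
                                    occ_hyper = list(mu = qlogis(0.5),
                                                     sigma = 1e-6),
                                    det_hyper = list(mu = 20, sigma = 1e-6),
                                    seed = 8)
  expect_lt(abs(mean(sim$truth$z) - 0.5), 0.03)
})

test_that("carnivore streams reproduce their configured activity rates", {
  cfg <- simulation_config(n_sites = 80, n_species = 2, seed = 13)
  sim <- simulate_community(cfg)
  ds <- validate_dataset(sim$detections, sim$deployments, sim$covariates)
  ev <- filter_independent_events(ds$records)
  # streams are laid out >= 1 h apart: the filter keeps every record
  raw_dog <- sum(ds$records$species_id == "dog")
  expect_equal(sum(ev$species_id == "dog"), raw_dog)
  # empirical RAI recomputed by the pipeline matches the truth table
  tn <- compute_trap_nights(ds$deployments)
  rai <- compute_rai(ev, tn)
  dog <- rai[rai$species_id == "dog", ]
  expect_equal(setNames(dog$rai, dog$site_id)[names(sim$truth$dog_rai)],
               sim$truth$dog_rai, tolerance = 1e-8)
})
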