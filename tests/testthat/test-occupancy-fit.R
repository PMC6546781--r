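test_that("gelman_rubin equals the hand formula", {
  expect_equal(gelman_rubin(list(as.numeric(1:100), as.numeric(1:100))),
               sqrt(99 / 100), tolerance = 1e-12)
  expect_equal(gelman_rubin(list(c(1, 2, 3), c(4, 5, 6))),
               sqrt((2 / 3 * 1 + 13.5 / 3) / 1), tolerance = 1e-12)
  expect_warning(r <- gelman_rubin(list(rep(2, 5), rep(2, 5))), "constant")
  expect_equal(r, 1.0)
  expect_error(gelman_rubin(list(1:3)), "2 chains")
  expect_error(gelman_rubin(list(1:3, 1:4)), "equal length")
})

test_that("posterior summaries follow the stated percentile rule", {
  m <- cbind(theta = rep(0.7, 50))
  s <- summarize_posterior(m)
  expect_equal(s$mean, 0.7)
  expect_equal(s$sd, 0)
  expect_equal(c(s$ci_low, s$ci_high), c(0.7, 0.7))

  m2 <- cbind(theta = as.numeric(1:100))
  s2 <- summarize_posterior(m2)
  expect_equal(s2$ci_low, unname(quantile(1:100, 0.025)))  # 3.475, type 7
  expect_equal(s2$ci_low, 3.475)
  expect_equal(s2$ci_high, 97.525)

  set.seed(5)
  m3 <- cbind(theta = rnorm(4000))
  s3 <- summarize_posterior(m3)
  expect_lt(abs(s3$mean), 3 * s3$sd / sqrt(4000))
})

test_that("degenerate saturated data force occupancy everywhere", {
  S <- 3; J <- 8; K <- 5
  y <- matrix(K, S, J, dimnames = list(paste0("sp", 1:S), paste0("s", 1:J)))
  h <- list(y = y, K = rep(K, J))
  X <- cbind(intercept = rep(1, J))
  fit <- suppressWarnings(fit_community_occupancy(
    h, X, X, mcmc = mcmc_config(chains = 2, iter = 500, burnin = 200,
                                thin = 5, seed = 1)))
  expect_true(all(fit$z == 1))  # y > 0 pins z at 1 in every draw
  r <- site_richness(fit)
  expect_true(all(r$per_site$mean == S))
  expect_equal(r$study_mean, S)
})

test_that("z is pinned at 1 wherever the species was detected", {
  set.seed(11)
  sim <- simulate_detection_history(40, 4, 6, seed = 11)
  fit <- suppressWarnings(fit_community_occupancy(
    sim$history, sim$occ_design, sim$det_design,
    mcmc = mcmc_config(chains = 2, iter = 600, burnin = 300, thin = 5,
                       seed = 2)))
  det <- which(sim$history$y > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(det)))
    expect_true(all(fit$z[det[r, 1], det[r, 2], ] == 1))
  # richness never exceeds the species count
  expect_true(all(apply(fit$z, c(2, 3), sum) <= 4))
})

test_that("species relabeling leaves hyper-parameter posteriors invariant", {
  sim <- simulate_detection_history(60, 5, 8, seed = 3)
  mc <- mcmc_config(chains = 2, iter = 2000, burnin = 800, thin = 5, seed = 4)
  fit1 <- suppressWarnings(fit_community_occupancy(
    sim$history, sim$occ_design, sim$det_design, mcmc = mc))
  perm <- c(3, 1, 5, 2, 4)
  h2 <- sim$history
  h2$y <- h2$y[perm, ]
  fit2 <- suppressWarnings(fit_community_occupancy(
    h2, sim$occ_design, sim$det_design, mcmc = mc))
  h1s <- summarize_posterior(fit1)$hyper
  h2s <- summarize_posterior(fit2)$hyper
  expect_equal(h1s$mean, h2s$mean, tolerance = 0.25)  # within MC error
})

test_that("stepwise selection keeps only candidates whose CI excludes 0", {
  # zero candidates: identity
  sim <- simulate_detection_history(30, 3, 5, seed = 5)
  base <- cbind(intercept = rep(1, 30))
  out <- stepwise_covariate_selection(sim$history, base, base, list(),
                                      mcmc = mcmc_config(chains = 2,
                                                         iter = 200,
                                                         burnin = 100,
                                                         thin = 2, seed = 1))
  expect_equal(out$occ_design, base)
  expect_equal(out$det_design, base)
  expect_equal(out$retained, character(0))

  # one strong occurrence covariate is retained and lands in the design
  sim2 <- simulate_detection_history(150, 8, 10,
                                     occ_hyper = list(mu = c(0, 2),
                                                      sigma = c(0.8, 0.3)),
                                     seed = 6)
  cand <- list(x1 = list(role = "occ",
                         cols = cbind(x1 = sim2$occ_design[, 2])))
  out2 <- stepwise_covariate_selection(
    sim2$history, cbind(intercept = rep(1, 150)),
    cbind(intercept = rep(1, 150)), cand,
    mcmc = mcmc_config(chains = 2, iter = 1500, burnin = 600, thin = 5,
                       seed = 2))
  expect_true("x1" %in% out2$retained)
  expect_true("x1" %in% colnames(out2$occ_design))
  expect_true(all(c("candidate", "ci_low", "ci_high", "retained") %in%
                    names(out2$audit)))
})

test_that("seeded fits are reproducible", {
  sim <- simulate_detection_history(30, 3, 5, seed = 9)
  mc <- mcmc_config(chains = 2, iter = 400, burnin = 200, thin = 4, seed = 77)
  f1 <- suppressWarnings(fit_community_occupancy(
    sim$history, sim$occ_design, sim$det_design, mcmc = mc))
  f2 <- suppressWarnings(fit_community_occupancy(
    sim$history, sim$occ_design, sim$det_design, mcmc = mc))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$z, f2$z)
})
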