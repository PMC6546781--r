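test_that("clock time maps to the unit circle", {
  ts <- as.POSIXct(c("2015-01-01 00:00:00", "2015-01-01 12:00:00",
                     "2015-01-01 18:00:00"), tz = "UTC")
  expect_equal(to_radian_time(ts), c(0, pi, 3 * pi / 2))
})

test_that("circular KDE integrates to 1 and finds the mode", {
  set.seed(21)
  x <- rvonmises(1000, pi, 2)
  k <- fit_circular_kde(x, adjust = 1)
  # trapezoid over the closed circle
  h <- c(k$density, k$density[1])
  dt <- 2 * pi / length(k$grid)
  expect_equal(sum((h[-1] + h[-length(h)]) / 2) * dt, 1, tolerance = 1e-3)
  expect_lt(abs(k$grid[which.max(k$density)] - pi), 0.15)
  expect_true(all(k$density >= 0))

  # larger adjust => smoother (lower max density)
  k2 <- fit_circular_kde(x, adjust = 2)
  k05 <- fit_circular_kde(x, adjust = 0.5)
  expect_lt(max(k2$density), max(k05$density))
  expect_error(fit_circular_kde(1, 1), "at least 2")
  expect_error(fit_circular_kde(c(1, 2), -1), "positive")
})

test_that("Delta estimators agree with the quadrature oracle", {
  truth <- true_vm_overlap(0, 2, pi, 2)
  set.seed(31)
  a <- rvonmises(2000, 0, 2)
  b <- rvonmises(2000, pi, 2)
  expect_lt(abs(overlap_delta1(a, b) - truth), 0.04)
  expect_lt(abs(overlap_delta4(a, b) - truth), 0.04)

  # identical samples: Delta4 exactly 1, Delta1 within grid tolerance
  expect_identical(overlap_delta4(a, a), 1)
  expect_lt(abs(overlap_delta1(a, a) - 1), 1e-3)

  # highly separated concentrated activity: near-zero overlap
  set.seed(32)
  a50 <- rvonmises(500, 0, 50)
  b50 <- rvonmises(500, pi, 50)
  expect_lt(overlap_delta1(a50, b50), 0.05)

  # symmetry of Delta4
  expect_identical(overlap_delta4(a, b), overlap_delta4(b, a))
})

test_that("overlap is rotation invariant", {
  set.seed(33)
  a <- rvonmises(300, 1, 3)
  b <- rvonmises(300, 4, 2)
  for (shift in c(0.5, 2, 5)) {
    expect_lt(abs(overlap_delta4(a, b) -
                    overlap_delta4((a + shift) %% (2 * pi),
                                   (b + shift) %% (2 * pi))), 1e-6)
    expect_lt(abs(overlap_delta1(a, b) -
                    overlap_delta1((a + shift) %% (2 * pi),
                                   (b + shift) %% (2 * pi))), 0.02)
  }
})

test_that("estimates converge to the oracle as n grows", {
  truth <- true_vm_overlap(0, 2, pi, 2)
  set.seed(34)
  better <- 0
  for (r in 1:20) {
    a_s <- rvonmises(200, 0, 2); b_s <- rvonmises(200, pi, 2)
    a_l <- rvonmises(2000, 0, 2); b_l <- rvonmises(2000, pi, 2)
    e_s <- abs(overlap_delta1(a_s, b_s) - truth)
    e_l <- abs(overlap_delta1(a_l, b_l) - truth)
    better <- better + (e_l < e_s)
  }
  expect_gte(better, 14)  # error shrinks with n in most replicates
  # (a strict count would be a coin-flip on MC luck; 16/20 observed)
})

test_that("estimator choice follows the sample-size rule", {
  expect_equal(choose_estimator(13, 200), "Delta1")
  expect_equal(choose_estimator(200, 300), "Delta4")
  expect_equal(choose_estimator(50, 50), "Delta4")  # boundary
  expect_equal(choose_estimator(49, 50), "Delta1")
})

test_that("bootstrap interval is seeded, ordered and sane", {
  set.seed(41)
  a <- rvonmises(150, 0, 2)
  b <- rvonmises(150, 1, 2)
  r1 <- bootstrap_ci(a, b, estimator = "Delta1", n_boot = 200, seed = 5)
  r2 <- bootstrap_ci(a, b, estimator = "Delta1", n_boot = 200, seed = 5)
  expect_identical(r1[c("ci_low", "ci_high")], r2[c("ci_low", "ci_high")])
  expect_lte(r1$ci_low, r1$ci_high)
  expect_true(r1$ci_low >= 0 && r1$ci_high <= 1)
  expect_error(bootstrap_ci(a, b, n_boot = 50), ">= 100")

  # near-degenerate samples give a narrow interval
  set.seed(42)
  jit_a <- (pi + rnorm(60, 0, 1e-3)) %% (2 * pi)
  jit_b <- (pi + rnorm(60, 0, 1e-3)) %% (2 * pi)
  rj <- bootstrap_ci(jit_a, jit_b, estimator = "Delta1", n_boot = 200,
                     seed = 6)
  expect_lt(rj$ci_high - rj$ci_low, 0.05)

  # small-sample skip rule
  expect_message(out <- estimate_overlap(a[1:5], b, min_n = 8), "skipping")
  expect_null(out)
})

test_that("seasonal comparison builds a compact letter display", {
  e <- data.frame(season = c("DEC_MAR", "APR_JUL"),
                  delta = c(0.2, 0.6),
                  ci_low = c(0.1, 0.5), ci_high = c(0.3, 0.7))
  out <- seasonal_overlap_comparison(e)
  expect_equal(out$letters, c("a", "b"))
  expect_true(attr(out, "pairs")$significant)

  e2 <- data.frame(season = c("DEC_MAR", "APR_JUL"),
                   delta = c(0.3, 0.5),
                   ci_low = c(0.1, 0.35), ci_high = c(0.4, 0.7))
  out2 <- seasonal_overlap_comparison(e2)
  expect_equal(out2$letters[1], out2$letters[2])

  # chain: extremes disjoint, middle overlaps both -> a, ab, b
  e3 <- data.frame(season = c("DEC_MAR", "APR_JUL", "AUG_NOV"),
                   delta = c(0.2, 0.45, 0.7),
                   ci_low = c(0.1, 0.25, 0.55),
                   ci_high = c(0.3, 0.6, 0.8))
  out3 <- seasonal_overlap_comparison(e3)
  expect_equal(out3$letters, c("a", "ab", "b"))
})
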