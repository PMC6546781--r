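# Shared fixtures and independent oracles for the test suite.

# --- toy field tables -------------------------------------------------

toy_tables <- function() {
  detections <- data.frame(
    site_id = c("s1", "s1", "s1", "s2", "s2"),
    species_id = c("muntjac", "muntjac", "civet", "muntjac", "dog"),
    timestamp = c("2015-01-10T01:00:00", "2015-01-10T02:00:00",
                  "2015-01-11T23:30:00", "2015-05-02T12:00:00",
                  "2015-05-03T06:15:00"),
    individual_id = "")
  deployments <- data.frame(
    site_id = c("s1", "s1", "s2"),
    camera_brand = c("KeepGuard", "KeepGuard", "Reconyx"),
    interval_type = c("active", "malfunction", "active"),
    start_date = c("2015-01-01", "2015-02-01", "2015-04-20"),
    end_date = c("2015-03-01", "2015-02-05", "2015-06-10"))
  covariates <- data.frame(
    site_id = c("s1", "s2"),
    x = c(0, 1000), y = c(0, 500),
    dist_settlement_m = c(200, 1500), dist_water_m = c(50, 300),
    elevation_m = c(300, 800), slope_deg = c(5, 25),
    solar_radiation = c(1.0, 1.2),
    vegetation = c("broadleaf", "mixed"))
  list(detections = detections, deployments = deployments,
       covariates = covariates)
}

write_toy_tables <- function(dir = tempfile()) {
  tt <- toy_tables()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("detections.csv", "deployments.csv",
                            "covariates.csv"))
  write.csv(tt$detections, paths[1], row.names = FALSE)
  write.csv(tt$deployments, paths[2], row.names = FALSE)
  write.csv(tt$covariates, paths[3], row.names = FALSE)
  paths
}

# records helper: build a detection-record data frame from clock strings
rec <- function(site, species, times, individual = NA_character_) {
  data.frame(site_id = site, species_id = species,
             timestamp = as.POSIXct(times, tz = "UTC"),
             individual_id = individual)
}

# --- oracles ----------------------------------------------------------

# closed-form von Mises density
vm_pdf <- function(t, mu, kappa) {
  exp(kappa * (cos(t - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

# true overlap integral min(f, g) by fine quadrature of exact densities
true_vm_overlap <- function(mu1, k1, mu2, k2, n_grid = 20000) {
  t <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  mean(pmin(vm_pdf(t, mu1, k1), vm_pdf(t, mu2, k2))) * 2 * pi
}

# brute-force Mann-Whitney: statistic and exact two-sided p by direct
# enumeration of label assignments (independent of the implementation)
brute_mw <- function(a, b) {
  u_stat <- function(x, y) {
    u <- 0
    for (xi in x) for (yj in y)
      u <- u + (xi > yj) + 0.5 * (xi == yj)
    min(u, length(x) * length(y) - u)
  }
  obs <- u_stat(a, b)
  pooled <- c(a, b)
  idx <- utils::combn(length(pooled), length(a))
  us <- apply(idx, 2, function(s) u_stat(pooled[s], pooled[-s]))
  list(U = obs, p = mean(us <= obs + 1e-9))
}

# brute-force single-species occupancy posterior on a parameter grid
# (2 x 2-ish problems): returns posterior means of psi and p under
# priors alpha0, beta0 ~ N(0, prior_sd^2)
grid_occu_posterior <- function(y, K, prior_sd = 10, lim = 40, step = 0.1) {
  g <- seq(-lim, lim, by = step)
  psi <- plogis(g)
  loglik_site <- function(yj) {
    # log sum over z for every (alpha, beta) combination: J_a x J_b matrix
    outer(seq_along(g), seq_along(g), function(ia, ib) {
      pj <- plogis(g[ib])
      lik_z1 <- psi[ia] * dbinom(yj, K, pj)
      lik_z0 <- (1 - psi[ia]) * (yj == 0)
      log(lik_z1 + lik_z0)
    })
  }
  lp <- Reduce(`+`, lapply(y, loglik_site))
  lp <- lp + outer(dnorm(g, 0, prior_sd, log = TRUE),
                   dnorm(g, 0, prior_sd, log = TRUE), `+`)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  list(mean_psi = sum(rowSums(w) * psi),
       mean_p = sum(colSums(w) * plogis(g)))
}

# maximum-likelihood oracle for the single-species occupancy model
ml_occu <- function(y, K) {
  nll <- function(par) {
    psi <- plogis(par[1]); p <- plogis(par[2])
    -sum(log(psi * dbinom(y, K, p) + (1 - psi) * (y == 0)))
  }
  fit <- optim(c(0, 0), nll, method = "BFGS")
  c(psi = plogis(fit$par[1]), p = plogis(fit$par[2]))
}
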