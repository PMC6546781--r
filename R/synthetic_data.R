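## Synthetic community generator: produces detection, deployment and
## covariate tables with the generative structure the analysis assumes,
## together with the realized truth for recovery tests.

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler.
#'
#' @param n sample size.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0; 0 gives the circular uniform).
#' @return numeric vector in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 1L
  while (i <= n) {
    u <- runif(3)
    zc <- cos(pi * u[1])
    f <- (1 + r * zc) / (r + zc)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

#' Sample times of day from a von Mises mixture
#'
#' @param mixture list with numeric vectors `weights` (summing to 1),
#'   `mu` (radians) and `kappa`.
#' @param n sample size (>= 1).
#' @param seed optional integer seed.
#' @return numeric vector in `[0, 2*pi)` (a radian time sample).
#' @export
simulate_diel_samples <- function(mixture, n, seed = NULL) {
  stopifnot(n >= 1)
  w <- mixture$weights
  if (abs(sum(w) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (length(w) != length(mixture$mu) || length(w) != length(mixture$kappa))
    stop("mixture component lengths differ")
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  out <- numeric(n)
  for (k in seq_along(w)) {
    idx <- comp == k
    if (any(idx)) out[idx] <- rvonmises(sum(idx), mixture$mu[k], mixture$kappa[k])
  }
  out
}

# clock hour -> radians
hour_rad <- function(h) 2 * pi * h / 24

#' Build a simulation configuration
#'
#' Defaults mirror the scale of a multi-year single-park camera survey:
#' 121 sites, 9 native species plus 2 invasive carnivores (dog, cat),
#' deployments averaging 143 days. Hyper-parameter defaults for the
#' printed coefficient families follow the field study's community
#' estimates (settlement distance +, dog RAI strong hump-shaped, cat RAI
#' null, Reconyx detection -); intercepts and hyper-sds are unprinted and
#' therefore illustrative (see the methods vignette).
#'
#' @param n_sites,n_species study dimensions (native species only).
#' @param mean_deployment_days mean active deployment length.
#' @param study_start,study_end study window (deployment starts are
#'   staggered uniformly).
#' @param occ_hyper,det_hyper lists with `mu` and `sigma` vectors over
#'   the coefficient families; occurrence families are `(intercept,
#'   dist_settlement, dog_rai, dog_rai_sq, cat_rai, cat_rai_sq)`,
#'   detection families `(intercept, cuddeback, reconyx, dog_rai,
#'   cat_rai)`.
#' @param diel list of mixtures: `native` (list per species, recycled),
#'   `dog`, `cat`. Defaults: nocturnal/crepuscular natives, diurnal dogs
#'   with dawn/dusk peaks, cathemeral cats with dawn/dusk peaks.
#' @param dog_rate,cat_rate log-normal parameters (meanlog, sdlog) of
#'   site-level expected events per 100 trap-nights for the carnivores.
#' @param malfunction_prob probability a deployment has a malfunction gap.
#' @param mean_records_per_occasion mean of the (>= 1, shifted-geometric)
#'   number of records within a detected occasion.
#' @param occasion_length_days occasion length used by the generator.
#' @param brand_probs sampling probabilities of the three camera brands.
#' @param seed master seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_sites = 121, n_species = 9,
    mean_deployment_days = 143,
    study_start = as.Date("2012-03-01"), study_end = as.Date("2017-07-31"),
    occ_hyper = list(mu = c(-0.4, 0.41, 3.13, -3.34, 0.49, -0.82),
                     sigma = c(1.2, 0.5, 0.8, 0.8, 0.6, 0.6)),
    det_hyper = list(mu = c(-1.15, -0.25, -0.37, 0.11, 0.43),
                     sigma = c(0.9, 0.4, 0.4, 0.3, 0.3)),
    diel = NULL,
    dog_rate = c(meanlog = log(1.2), sdlog = 0.8),
    cat_rate = c(meanlog = log(0.5), sdlog = 0.8),
    malfunction_prob = 0.15,
    mean_records_per_occasion = 2,
    occasion_length_days = 10,
    brand_probs = c(KeepGuard = 1 / 3, Cuddeback = 1 / 3, Reconyx = 1 / 3),
    seed = 1) {
  if (is.null(diel)) {
    crep <- list(weights = c(0.5, 0.5),
                 mu = hour_rad(c(5.5, 18.5)), kappa = c(3, 3))
    nocturnal <- list(weights = 1, mu = hour_rad(1), kappa = 1.5)
    diel <- list(
      native = rep(list(crep, nocturnal), length.out = n_species),
      dog = list(weights = c(0.35, 0.35, 0.3),
                 mu = hour_rad(c(6, 18, 12)), kappa = c(4, 4, 1)),
      cat = list(weights = c(0.3, 0.3, 0.4),
                 mu = hour_rad(c(5.5, 19, 12)), kappa = c(3, 3, 0.1)))
  }
  cfg <- list(n_sites = n_sites, n_species = n_species,
              mean_deployment_days = mean_deployment_days,
              study_start = study_start, study_end = study_end,
              occ_hyper = occ_hyper, det_hyper = det_hyper, diel = diel,
              dog_rate = dog_rate, cat_rate = cat_rate,
              malfunction_prob = malfunction_prob,
              mean_records_per_occasion = mean_records_per_occasion,
              occasion_length_days = occasion_length_days,
              brand_probs = brand_probs, seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  if (cfg$n_sites < 1) stop("invalid config field: n_sites")
  if (cfg$n_species < 1) stop("invalid config field: n_species")
  for (h in c("occ_hyper", "det_hyper")) {
    if (length(cfg[[h]]$mu) != length(cfg[[h]]$sigma))
      stop("invalid config field: ", h, " (mu/sigma length mismatch)")
    if (any(cfg[[h]]$sigma <= 0))
      stop("invalid config field: ", h, " (sigma must be > 0)")
  }
  if (length(cfg$occ_hyper$mu) != 6)
    stop("invalid config field: occ_hyper (6 families expected)")
  if (length(cfg$det_hyper$mu) != 5)
    stop("invalid config field: det_hyper (5 families expected)")
  for (m in c(cfg$diel$native, list(cfg$diel$dog, cfg$diel$cat)))
    if (abs(sum(m$weights) - 1) > 1e-8)
      stop("invalid config field: diel (weights must sum to 1)")
  if (abs(sum(cfg$brand_probs) - 1) > 1e-8)
    stop("invalid config field: brand_probs")
  invisible(cfg)
}

#' Configuration at the scale of the reference field study
#'
#' 121 sites, 9 native species, deployments averaging 143 days.
#' Quantities the study never printed (hyper-sds, intercepts, diel
#' mixtures, carnivore rates) carry illustrative defaults.
#'
#' @param ... overrides passed to [simulation_config()].
#' @return a `simulation_config`.
#' @export
paper_scale_config <- function(...) simulation_config(...)

# shifted geometric with mean `m` (support >= 1)
r_records <- function(n, m) 1L + rgeom(n, prob = 1 / max(m, 1))

#' Simulate a complete synthetic camera-trap study
#'
#' Generates the three standard input tables plus the realized truth.
#' Species coefficients are drawn from the configured community normal
#' hyper-distributions; covariates are drawn and transformed exactly as
#' [prepare_covariates()] will transform them; occupancy `z` is
#' Bernoulli(psi); detection within an occasion is Bernoulli(z*p); each
#' detected occasion is expanded into >= 1 timestamped records with
#' times of day from the species' von Mises mixture. Dog and cat
#' activity is generated as site-level event streams whose rates are the
#' very RAI values entering the design matrix, so the pipeline's
#' internally recomputed carnivore RAIs approximate the simulated design
#' (streams are laid out >= 1 h apart, so independence filtering keeps
#' them all).
#'
#' @param config a `simulation_config`.
#' @return list with `detections`, `deployments`, `covariates`
#'   (data frames in the [load_dataset()] schema) and `truth` (realized
#'   parameters: `alpha`, `beta`, hyper values, `psi`, `p`, `z`,
#'   design matrices, diel mixtures, config).
#' @export
simulate_community <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  ns <- config$n_sites; S <- config$n_species
  sites <- sprintf("site%03d", seq_len(ns))
  species <- sprintf("native%02d", seq_len(S))

  ## deployments: one active interval per site, staggered starts
  len <- pmax(60, round(rnorm(ns, config$mean_deployment_days, 40)))
  max_start <- as.integer(config$study_end - config$study_start) - max(len)
  start <- config$study_start + sample.int(max(max_start, 1), ns, replace = TRUE)
  end <- start + len - 1
  brand <- sample(names(config$brand_probs), ns, replace = TRUE,
                  prob = config$brand_probs)
  deployments <- data.frame(site_id = sites, camera_brand = brand,
                            interval_type = "active",
                            start_date = as.character(start),
                            end_date = as.character(end))
  has_mal <- runif(ns) < config$malfunction_prob & len > 40
  for (j in which(has_mal)) {
    gap_len <- sample(3:14, 1)
    gap_start <- start[j] + sample.int(len[j] - gap_len - 2, 1)
    deployments <- rbind(deployments, data.frame(
      site_id = sites[j], camera_brand = brand[j],
      interval_type = "malfunction",
      start_date = as.character(gap_start),
      end_date = as.character(gap_start + gap_len - 1)))
  }

  ## site covariates (distance distribution log-normal ~50-3000 m,
  ## illustrative)
  covariates <- data.frame(
    site_id = sites,
    x = runif(ns, 0, 15000), y = runif(ns, 0, 12000),
    dist_settlement_m = pmin(pmax(rlnorm(ns, log(500), 0.8), 50), 3000),
    dist_water_m = pmin(pmax(rlnorm(ns, log(300), 0.7), 20), 2000),
    elevation_m = runif(ns, 56, 1120),
    slope_deg = runif(ns, 0, 45),
    solar_radiation = rnorm(ns, 1, 0.2),
    vegetation = sample(VEGETATION_CLASSES, ns, replace = TRUE,
                        prob = c(0.15, 0.7, 0.15)))

  ## carnivore site-level RAIs (events per 100 trap-nights)
  dog_rai_true <- rlnorm(ns, config$dog_rate["meanlog"], config$dog_rate["sdlog"])
  cat_rai_true <- rlnorm(ns, config$cat_rate["meanlog"], config$cat_rate["sdlog"])

  ## effort days per site
  eff_days <- lapply(seq_len(ns), function(j) {
    d <- deployments[deployments$site_id == sites[j], ]
    d$start_date <- as.Date(d$start_date); d$end_date <- as.Date(d$end_date)
    act <- interval_days(d[d$interval_type == "active", , drop = FALSE])
    mal <- interval_days(d[d$interval_type == "malfunction", , drop = FALSE])
    sort(as.Date(setdiff(act, mal), origin = "1970-01-01"))
  })

  ## carnivore event streams: counts hit the configured RAI exactly in
  ## expectation; events placed >= 1 h apart in the day so the 30-min
  ## independence filter keeps them all
  carn_records <- list()
  for (j in seq_len(ns)) {
    tn <- length(eff_days[[j]])
    for (carn in c("dog", "cat")) {
      lambda <- if (carn == "dog") dog_rai_true[j] else cat_rai_true[j]
      n_ev <- rpois(1, lambda * tn / 100)
      if (!n_ev) next
      days <- sample(eff_days[[j]], n_ev, replace = TRUE)
      tod <- simulate_diel_samples(config$diel[[carn]], n_ev)
      # spread same-day events by forcing distinct hour slots
      ts <- as.POSIXct(paste0(as.character(days), " 00:00:00"), tz = "UTC") +
        round(tod / (2 * pi) * 86400)
      ts <- make_independent_times(ts, days)
      carn_records[[length(carn_records) + 1]] <- data.frame(
        site_id = sites[j], species_id = carn,
        timestamp = format(ts, "%Y-%m-%dT%H:%M:%S"),
        individual_id = "")
    }
  }

  ## realized carnivore RAI (from generated streams) -> design matrices,
  ## computed with the same transforms prepare_covariates applies
  carn_df <- if (length(carn_records)) do.call(rbind, carn_records) else
    stop("config generated no carnivore events; raise dog_rate/cat_rate")
  carn_counts <- function(sp) {
    v <- table(carn_df$site_id[carn_df$species_id == sp])
    out <- setNames(numeric(ns), sites)
    out[names(v)] <- as.numeric(v)
    out
  }
  tn_all <- vapply(eff_days, length, integer(1))
  dog_rai_obs <- 100 * carn_counts("dog") / tn_all
  cat_rai_obs <- 100 * carn_counts("cat") / tn_all
  zdist <- standardize(covariates$dist_settlement_m, "dist")$z
  zdog <- standardize(log1p(dog_rai_obs), "dog")$z
  zcat <- standardize(log1p(cat_rai_obs), "cat")$z
  X_occ <- cbind(intercept = 1, dist_settlement = zdist,
                 dog_rai = zdog, dog_rai_sq = zdog^2,
                 cat_rai = zcat, cat_rai_sq = zcat^2)
  X_det <- cbind(intercept = 1,
                 cuddeback = as.numeric(brand == "Cuddeback"),
                 reconyx = as.numeric(brand == "Reconyx"),
                 dog_rai = zdog, cat_rai = zcat)

  ## species coefficients from the community hyper-distributions
  alpha <- sapply(seq_along(config$occ_hyper$mu), function(k)
    rnorm(S, config$occ_hyper$mu[k], config$occ_hyper$sigma[k]))
  beta <- sapply(seq_along(config$det_hyper$mu), function(k)
    rnorm(S, config$det_hyper$mu[k], config$det_hyper$sigma[k]))
  alpha <- matrix(alpha, S); beta <- matrix(beta, S)
  rownames(alpha) <- rownames(beta) <- species

  psi <- plogis(alpha %*% t(X_occ))
  p <- plogis(beta %*% t(X_det))
  z <- matrix(rbinom(S * ns, 1, psi), S, ns,
              dimnames = list(species, sites))

  ## native detections per occasion, expanded to timestamped records
  native_records <- list()
  for (j in seq_len(ns)) {
    days <- eff_days[[j]]
    if (!length(days)) next
    Kj <- ceiling(length(days) / config$occasion_length_days)
    occ_of_day <- rep(seq_len(Kj), each = config$occasion_length_days,
                      length.out = length(days))
    for (i in seq_len(S)) {
      if (!z[i, j]) next
      det <- which(rbinom(Kj, 1, p[i, j]) == 1)
      for (o in det) {
        n_rec <- r_records(1, config$mean_records_per_occasion)
        odays <- days[occ_of_day == o]
        rdays <- sample(odays, n_rec, replace = TRUE)
        tod <- simulate_diel_samples(config$diel$native[[i]], n_rec)
        ts <- as.POSIXct(paste0(as.character(rdays), " 00:00:00"),
                         tz = "UTC") + round(tod / (2 * pi) * 86400)
        native_records[[length(native_records) + 1]] <- data.frame(
          site_id = sites[j], species_id = species[i],
          timestamp = format(ts, "%Y-%m-%dT%H:%M:%S"),
          individual_id = "")
      }
    }
  }
  detections <- rbind(do.call(rbind, native_records), carn_df)
  detections <- detections[order(detections$site_id, detections$species_id,
                                 detections$timestamp), ]
  rownames(detections) <- NULL

  truth <- list(alpha = alpha, beta = beta,
                occ_hyper = config$occ_hyper, det_hyper = config$det_hyper,
                psi = psi, p = p, z = z,
                X_occ = X_occ, X_det = X_det,
                dog_rai = dog_rai_obs, cat_rai = cat_rai_obs,
                diel = config$diel, config = config)
  list(detections = detections, deployments = deployments,
       covariates = covariates, truth = truth)
}

# nudge same-day same-site timestamps >= 1 h apart so the generated
# carnivore stream survives the 30-min independence rule unchanged
make_independent_times <- function(ts, days) {
  key <- as.character(days)
  for (d in unique(key)) {
    idx <- which(key == d)
    if (length(idx) < 2) next
    base <- as.numeric(as.POSIXct(paste0(d, " 00:00:00"), tz = "UTC"))
    s <- sort(round(as.numeric(ts[idx]) - base))
    for (k in seq_along(s)[-1]) s[k] <- max(s[k], s[k - 1] + 3600)
    if (s[length(s)] > 86399) {  # shift the day's chain back into range
      s <- s - (s[length(s)] - 86399)
      s <- pmax(s, (seq_along(s) - 1) * 3600)
    }
    ts[idx] <- as.POSIXct(base + s, origin = "1970-01-01", tz = "UTC")
  }
  ts
}

#' Simulate a detection history directly from the occupancy model
#'
#' Bypasses the tabular layer: draws standardized covariates, species
#' coefficients from the hyper-distributions, `z` and `y`, returning
#' exactly what [fit_community_occupancy()] consumes. This is the
#' generator behind the hyper-parameter recovery and covariate-selection
#' operating-characteristic checks.
#'
#' @param n_sites,n_species,K study dimensions (constant `K` per site).
#' @param occ_hyper,det_hyper lists with `mu`, `sigma`; element 1 is the
#'   intercept, later elements get standard-normal covariate columns.
#' @param seed integer seed.
#' @return list `history` (class `detection_history`), `occ_design`,
#'   `det_design`, `truth` (alpha, beta, psi, p, z).
#' @export
simulate_detection_history <- function(n_sites, n_species, K,
                                       occ_hyper = list(mu = c(0, 0.5),
                                                        sigma = c(1, 0.3)),
                                       det_hyper = list(mu = c(-0.5),
                                                        sigma = c(0.4)),
                                       seed = 1) {
  set.seed(seed)
  P <- length(occ_hyper$mu); Q <- length(det_hyper$mu)
  X_occ <- cbind(1, matrix(rnorm(n_sites * (P - 1)), n_sites))
  colnames(X_occ) <- c("intercept", if (P > 1) paste0("x", seq_len(P - 1)))
  X_det <- cbind(1, matrix(rnorm(n_sites * (Q - 1)), n_sites))
  colnames(X_det) <- c("intercept", if (Q > 1) paste0("w", seq_len(Q - 1)))
  alpha <- matrix(rnorm(n_species * P, rep(occ_hyper$mu, each = n_species),
                        rep(occ_hyper$sigma, each = n_species)), n_species)
  beta <- matrix(rnorm(n_species * Q, rep(det_hyper$mu, each = n_species),
                       rep(det_hyper$sigma, each = n_species)), n_species)
  psi <- plogis(alpha %*% t(X_occ))
  p <- plogis(beta %*% t(X_det))
  z <- matrix(rbinom(n_species * n_sites, 1, psi), n_species)
  y <- matrix(rbinom(n_species * n_sites, K, as.vector(z * p)), n_species)
  sp <- sprintf("sp%02d", seq_len(n_species))
  st <- sprintf("site%03d", seq_len(n_sites))
  dimnames(y) <- list(sp, st)
  history <- structure(list(y = y, K = rep(K, n_sites), sites = st,
                            species = sp, brand = rep("KeepGuard", n_sites),
                            occasion_length_days = NA),
                       class = "detection_history")
  list(history = history, occ_design = X_occ, det_design = X_det,
       truth = list(alpha = alpha, beta = beta, psi = psi, p = p, z = z,
                    occ_hyper = occ_hyper, det_hyper = det_hyper))
}
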