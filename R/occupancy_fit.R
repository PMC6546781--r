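## Bayesian multi-species hierarchical occupancy model.
##
## For species i and site j:
##   z_ij ~ Bernoulli(psi_ij),   logit(psi_ij) = x_occ[j,] alpha_i
##   y_ij | z_ij ~ Binomial(K_j, z_ij * p_ij), logit(p_ij) = x_det[j,] beta_i
## and each coefficient family k is drawn from a community-level normal
## hyper-distribution: alpha_ik ~ N(mu_k, sigma_k^2) (likewise beta).
## Occurrence is interpreted as "site use" (closure relaxed).
##
## The sampler (compiled, see src/occu_mcmc.cpp) is Metropolis-within-
## Gibbs: exact Bernoulli full conditional for z, adaptive random-walk
## proposals for coefficients (adaptation frozen after burn-in), and
## conjugate/conditional updates for the hyper-parameters.

#' Prior settings for the community occupancy model
#'
#' Conventional vague community-model priors: hyper-means
#' `mu_k ~ N(0, mu_sd^2)` and hyper-sds `sigma_k ~ Uniform(0,
#' sigma_upper)`. For a single-species fit the community layer is
#' skipped and coefficients get the fixed prior `N(0, mu_sd^2)`.
#'
#' @param mu_sd prior sd of the hyper-means (default 10).
#' @param sigma_upper upper bound of the uniform prior on hyper-sds.
#' @return list of class `occu_priors`.
#' @export
occu_priors <- function(mu_sd = 10, sigma_upper = 10) {
  stopifnot(mu_sd > 0, sigma_upper > 0)
  structure(list(mu_sd = mu_sd, sigma_upper = sigma_upper),
            class = "occu_priors")
}

#' MCMC settings
#'
#' `iter` counts post-burn-in iterations per chain; kept draws per chain
#' are `iter / thin`. The desk-scale default (3 chains x 6,000 after a
#' 1,000 burn-in, thinned by 5) is sized for routine use; the fidelity
#' profile (3 x 50,000 after 10,000, thinned by 50) reproduces the
#' field-study settings.
#'
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param iter post-burn-in iterations per chain.
#' @param burnin burn-in iterations per chain.
#' @param thin thinning interval.
#' @param seed integer seed (chains are run sequentially from one stream).
#' @param profile "desk" or "paper"; presets overridden by explicit args.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3, iter = 6000, burnin = 1000, thin = 5,
                        seed = 1, profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  if (profile == "paper" && missing(iter)) {
    iter <- 50000; burnin <- 10000; thin <- 50
  }
  stopifnot(chains >= 1, iter >= thin, burnin >= 0, thin >= 1)
  structure(list(chains = chains, iter = iter, burnin = burnin,
                 thin = thin, seed = as.integer(seed), profile = profile),
            class = "mcmc_config")
}

#' Fit the multi-species hierarchical occupancy model
#'
#' @param history a `detection_history` from [build_detection_history()],
#'   or a list with integer matrix `y` (species x sites) and vector `K`.
#' @param occ_design,det_design site-level design matrices (first column
#'   intercept), e.g. from [prepare_covariates()].
#' @param priors an [occu_priors()] object.
#' @param mcmc an [mcmc_config()] object.
#' @param store_z keep posterior draws of the occupancy matrix `z`
#'   (needed for [site_richness()]).
#' @return object of class `occu_fit`: per-chain draw matrices for
#'   species coefficients and community hyper-parameters, `z` draws,
#'   convergence report, and the inputs needed by the summary methods.
#'   If any monitored R-hat is >= 1.1 the fit is returned but flagged
#'   (`converged = FALSE`) with a warning.
#' @export
fit_community_occupancy <- function(history, occ_design, det_design,
                                    priors = occu_priors(),
                                    mcmc = mcmc_config(),
                                    store_z = TRUE) {
  y <- history$y
  K <- as.integer(history$K)
  if (!is.matrix(y)) stop("history$y must be a species x site matrix")
  S <- nrow(y); J <- ncol(y)
  occ_design <- as.matrix(occ_design); det_design <- as.matrix(det_design)
  if (nrow(occ_design) != J || nrow(det_design) != J || length(K) != J)
    stop("dimension mismatch between history and design matrices")
  if (any(y > matrix(K, S, J, byrow = TRUE)))
    stop("y exceeds K at some site")
  storage.mode(y) <- "integer"

  set.seed(mcmc$seed)
  chains <- lapply(seq_len(mcmc$chains), function(ch)
    cpp_occu_chain(y, K, occ_design, det_design,
                   mcmc$burnin, mcmc$iter, mcmc$thin,
                   priors$mu_sd, priors$sigma_upper, store_z))

  P <- ncol(occ_design); Q <- ncol(det_design)
  sp <- rownames(y); if (is.null(sp)) sp <- paste0("sp", seq_len(S))
  occ_nm <- colnames(occ_design); det_nm <- colnames(det_design)
  if (is.null(occ_nm)) occ_nm <- paste0("occ", seq_len(P) - 1)
  if (is.null(det_nm)) det_nm <- paste0("det", seq_len(Q) - 1)

  name_block <- function(prefix, covs, species = NULL) {
    if (is.null(species)) paste0(prefix, "[", covs, "]")
    else as.vector(outer(species, covs, function(s, c)
      paste0(prefix, "[", s, ",", c, "]")))
  }
  draws <- lapply(chains, function(ch) {
    m <- cbind(ch$alpha, ch$beta, ch$mu_alpha, ch$sd_alpha,
               ch$mu_beta, ch$sd_beta)
    colnames(m) <- c(name_block("alpha", occ_nm, sp),
                     name_block("beta", det_nm, sp),
                     name_block("mu_alpha", occ_nm),
                     name_block("sd_alpha", occ_nm),
                     name_block("mu_beta", det_nm),
                     name_block("sd_beta", det_nm))
    m
  })

  n_keep <- chains[[1]]$n_keep
  z <- NULL
  if (store_z) {
    z <- array(unlist(lapply(chains, `[[`, "z"), use.names = FALSE),
               dim = c(S, J, n_keep * mcmc$chains),
               dimnames = list(sp, colnames(y), NULL))
  }

  conv <- convergence_report(draws)
  fit <- structure(list(
    draws = draws, z = z, species = sp, sites = colnames(y),
    occ_terms = occ_nm, det_terms = det_nm,
    n_species = S, n_sites = J, K = K,
    priors = priors, mcmc = mcmc, convergence = conv,
    converged = all(conv$pass)), class = "occu_fit")
  if (!fit$converged)
    warning("non-convergence flagged: max R-hat = ",
            format(max(conv$rhat), digits = 4))
  fit
}

#' @export
print.occu_fit <- function(x, ...) {
  cat("Multi-species occupancy fit:", x$n_species, "species x",
      x$n_sites, "sites\n")
  cat(sprintf("%d chains x %d kept draws; max R-hat = %.3f (%s)\n",
              length(x$draws), nrow(x$draws[[1]]),
              max(x$convergence$rhat),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction statistic
#'
#' `R-hat = sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean
#' within-chain variance and `B = n * var(chain means)`. Identical
#' chains give the formula's floor `sqrt((n-1)/n)`; constant chains
#' (`W = 0`) are defined as 1 with a warning. Values below 1.1 are
#' conventionally taken as converged.
#'
#' @param chains a list of equal-length numeric vectors (one per chain)
#'   or an iterations x chains matrix.
#' @return the R-hat value.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  m <- length(chains)
  if (m < 2) stop("need at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1 || n < 2) stop("chains must have equal length >= 2")
  W <- mean(vapply(chains, var, numeric(1)))
  B <- n * var(vapply(chains, mean, numeric(1)))
  if (W == 0) {
    warning("constant chains: R-hat defined as 1")
    return(1.0)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence report over monitored parameters
#'
#' @param draws list of per-chain draw matrices with common columns.
#' @param threshold pass threshold for R-hat (default 1.1).
#' @return data frame `parameter`, `rhat`, `pass`.
#' @export
convergence_report <- function(draws, threshold = 1.1) {
  params <- colnames(draws[[1]])
  rhat <- vapply(params, function(p) {
    ch <- lapply(draws, function(m) m[, p])
    if (all(vapply(ch, var, numeric(1)) == 0)) return(1.0)
    gelman_rubin(ch)
  }, numeric(1))
  data.frame(parameter = params, rhat = unname(rhat),
             pass = unname(rhat) < threshold, row.names = NULL)
}

#' Posterior summary tables
#'
#' Per parameter: posterior mean, SD and the central 95% equal-tailed
#' percentile interval (2.5/97.5 percentiles, default R quantile rule).
#' Returns the community hyper-parameter table (one row per coefficient
#' family) and the species-level coefficient table.
#'
#' @param fit an `occu_fit`, or a plain draws matrix for `level =
#'   "all"`.
#' @param prob interval mass (default 0.95).
#' @return list with data frames `hyper` and `species` (or a single
#'   data frame if `fit` is a matrix).
#' @export
summarize_posterior <- function(fit, prob = 0.95) {
  a <- (1 - prob) / 2
  summarize_mat <- function(m) {
    data.frame(parameter = colnames(m),
               mean = colMeans(m),
               sd = apply(m, 2, sd),
               ci_low = apply(m, 2, quantile, probs = a),
               ci_high = apply(m, 2, quantile, probs = 1 - a),
               row.names = NULL)
  }
  if (is.matrix(fit)) return(summarize_mat(fit))
  stopifnot(inherits(fit, "occu_fit"))
  all_draws <- do.call(rbind, fit$draws)
  tab <- summarize_mat(all_draws)
  is_hyper <- grepl("^(mu|sd)_", tab$parameter)
  list(hyper = tab[is_hyper, ], species = tab[!is_hyper, ])
}

#' Site-level species richness from occupancy draws
#'
#' Richness summarizes the latent `z` draws (not psi), so it is
#' conditioned on the observed detections. Per site: posterior mean, SD
#' and 95% interval of `sum_i z[i,j]`. Two study-level summaries are
#' returned because the averaging order is ambiguous in common usage:
#' `mean_of_site_means` (average over sites of posterior-mean richness)
#' and the posterior distribution of the per-draw across-site mean
#' (`study_mean`, `study_sd`, `study_ci`).
#'
#' @param fit an `occu_fit` fitted with `store_z = TRUE`.
#' @param prob interval mass.
#' @return list with `per_site` data frame and study-level scalars.
#' @export
site_richness <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "occu_fit"))
  if (is.null(fit$z)) stop("fit was run with store_z = FALSE")
  a <- (1 - prob) / 2
  rich <- apply(fit$z, c(2, 3), sum)  # sites x draws
  per_site <- data.frame(
    site_id = fit$sites,
    mean = rowMeans(rich),
    sd = apply(rich, 1, sd),
    ci_low = apply(rich, 1, quantile, probs = a),
    ci_high = apply(rich, 1, quantile, probs = 1 - a),
    row.names = NULL)
  draw_means <- colMeans(rich)
  list(per_site = per_site,
       mean_of_site_means = mean(per_site$mean),
       study_mean = mean(draw_means),
       study_sd = sd(draw_means),
       study_ci = unname(quantile(draw_means, c(a, 1 - a))))
}

#' Stepwise covariate retention for the community model
#'
#' Candidates are evaluated one at a time against the growing base
#' model: detection candidates first, then occurrence candidates, in the
#' user-supplied order. A candidate is retained iff the 95% posterior
#' interval of its community-level mean excludes zero (for multi-column
#' candidates such as factor indicator blocks, any column qualifies).
#' Every fit and decision is recorded in the audit log.
#'
#' @param history a `detection_history`.
#' @param base_occ,base_det base design matrices (intercept at least).
#' @param candidates named list; each element is
#'   `list(role = "occ"|"det", cols = <site x m matrix>)`.
#' @param priors,mcmc passed to [fit_community_occupancy()].
#' @param prob interval mass for the retention rule.
#' @return list `occ_design`, `det_design` (final matrices), `retained`
#'   (character), `audit` (data frame, one row per candidate column).
#' @export
stepwise_covariate_selection <- function(history, base_occ, base_det,
                                         candidates,
                                         priors = occu_priors(),
                                         mcmc = mcmc_config(),
                                         prob = 0.95) {
  occ <- as.matrix(base_occ); det <- as.matrix(base_det)
  audit <- list(); retained <- character(0)
  roles <- vapply(candidates, `[[`, character(1), "role")
  order_idx <- c(which(roles == "det"), which(roles == "occ"))
  seed_k <- mcmc$seed
  for (k in order_idx) {
    cand <- candidates[[k]]; nm <- names(candidates)[k]
    cols <- as.matrix(cand$cols)
    if (is.null(colnames(cols)))
      colnames(cols) <- if (ncol(cols) == 1) nm else
        paste0(nm, seq_len(ncol(cols)))
    trial_occ <- occ; trial_det <- det
    if (cand$role == "occ") trial_occ <- cbind(occ, cols)
    else trial_det <- cbind(det, cols)
    seed_k <- seed_k + 1L
    mc <- mcmc; mc$seed <- seed_k
    fit <- suppressWarnings(
      fit_community_occupancy(history, trial_occ, trial_det,
                              priors = priors, mcmc = mc, store_z = FALSE))
    hyper <- summarize_posterior(fit, prob = prob)$hyper
    pref <- if (cand$role == "occ") "mu_alpha" else "mu_beta"
    rows <- hyper[hyper$parameter %in%
                    paste0(pref, "[", colnames(cols), "]"), ]
    keep <- any(rows$ci_low > 0 | rows$ci_high < 0)
    if (keep) {
      retained <- c(retained, nm)
      if (cand$role == "occ") occ <- trial_occ else det <- trial_det
    }
    audit[[length(audit) + 1]] <- data.frame(
      candidate = nm, role = cand$role, column = colnames(cols),
      ci_low = rows$ci_low, ci_high = rows$ci_high,
      excludes_zero = rows$ci_low > 0 | rows$ci_high < 0,
      retained = keep, max_rhat = max(fit$convergence$rhat),
      row.names = NULL)
  }
  list(occ_design = occ, det_design = det, retained = retained,
       audit = if (length(audit)) do.call(rbind, audit) else
         data.frame(candidate = character(0)))
}
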