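## End-to-end pipeline: validate -> rai -> fit -> overlap -> report,
## with stage logging and a reproducibility manifest.

#' Build a pipeline run configuration
#'
#' Defaults follow the reference field protocol where it states one
#' (30-min independence rule, smoothing 1.25 for Delta-1 and 1.00 for
#' Delta-4, R-hat threshold 1.1, seasonal-effort rule 60 days x 2
#' seasons). The `paper` profile also uses the fidelity-scale MCMC
#' (3 x 50,000 after 10,000 burn-in, thin 50) and 10,000 bootstrap
#' replicates; the default `desk` profile scales both down for routine
#' runs.
#'
#' @param detections,deployments,covariates input CSV paths.
#' @param out_dir output directory.
#' @param seed master seed; stage seeds derive from it.
#' @param profile `"desk"` or `"paper"`.
#' @param interval_minutes independence interval.
#' @param occasion_length_days detection-occasion length.
#' @param min_days_per_season,min_seasons seasonal RAI site rule.
#' @param dog_species,cat_species carnivore species ids.
#' @param mcmc an [mcmc_config()]; built from the profile if `NULL`.
#' @param n_boot bootstrap replicates; from profile if `NULL`.
#' @param small_n_threshold,min_overlap_n overlap estimator rules.
#' @param run_selection run stepwise covariate retention before the
#'   final fit (slow; off by default).
#' @param seasonal_subset_only restrict diel samples to the seasonal-RAI
#'   camera subset instead of the full pooled set.
#' @return list of class `run_config`.
#' @export
run_config <- function(detections, deployments, covariates,
                       out_dir = "camtrap_run", seed = 1,
                       profile = c("desk", "paper"),
                       interval_minutes = 30, occasion_length_days = 10,
                       min_days_per_season = 60, min_seasons = 2,
                       dog_species = "dog", cat_species = "cat",
                       mcmc = NULL, n_boot = NULL,
                       small_n_threshold = 50, min_overlap_n = 8,
                       run_selection = FALSE,
                       seasonal_subset_only = FALSE) {
  profile <- match.arg(profile)
  if (is.null(mcmc))
    mcmc <- mcmc_config(seed = seed, profile = profile)
  if (is.null(n_boot)) n_boot <- if (profile == "paper") 10000 else 1000
  structure(list(detections = detections, deployments = deployments,
                 covariates = covariates, out_dir = out_dir,
                 seed = as.integer(seed), profile = profile,
                 interval_minutes = interval_minutes,
                 occasion_length_days = occasion_length_days,
                 min_days_per_season = min_days_per_season,
                 min_seasons = min_seasons,
                 dog_species = dog_species, cat_species = cat_species,
                 mcmc = mcmc, n_boot = n_boot,
                 small_n_threshold = small_n_threshold,
                 min_overlap_n = min_overlap_n,
                 run_selection = run_selection,
                 seasonal_subset_only = seasonal_subset_only),
            class = "run_config")
}

stage_error <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage,
               conditionMessage(e)), call. = FALSE)
}

write_table <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full community analysis pipeline
#'
#' Stages: **validate** (read and cross-check the three tables), **rai**
#' (independence filter, trap nights, RAI, seasonal RAI, seasonal
#' Mann-Whitney tests for the carnivores), **fit** (detection history,
#' design matrices, correlation screen, community occupancy model,
#' posterior summaries, richness, convergence report), **overlap**
#' (diel overlap of each native species and the pooled native community
#' against dog and cat, per season, with bootstrap CIs and
#' compact-letter seasonal comparison), **report** (delimited output
#' tables + JSON manifest with config echo, seeds, digests and
#' timings). A stage failure aborts with a stage-named error; outputs
#' written so far are retained.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with all stage results and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t_all <- list(); results <- list()
  tick <- function() proc.time()[["elapsed"]]

  ## validate
  t0 <- tick()
  dataset <- tryCatch(
    load_dataset(config$detections, config$deployments, config$covariates),
    error = function(e) stage_error("validate", e))
  t_all$validate <- tick() - t0

  ## rai
  t0 <- tick()
  rai_res <- tryCatch({
    events <- filter_independent_events(dataset$records,
                                        config$interval_minutes)
    tn <- compute_trap_nights(dataset$deployments)
    rai <- compute_rai(events, tn)
    srai <- suppressWarnings(
      seasonal_rai(events, dataset$deployments,
                   config$min_days_per_season, config$min_seasons))
    mw <- do.call(rbind, lapply(
      intersect(c(config$dog_species, config$cat_species),
                unique(srai$species_id)),
      function(sp) seasonal_rai_tests(srai, sp)))
    list(events = events, trap_nights = tn, rai = rai,
         seasonal = srai, seasonal_tests = mw)
  }, error = function(e) stage_error("rai", e))
  t_all$rai <- tick() - t0

  ## fit
  t0 <- tick()
  fit_res <- tryCatch({
    carn <- c(config$dog_species, config$cat_species)
    natives <- setdiff(sort(unique(rai_res$events$species_id)), carn)
    history <- build_detection_history(
      rai_res$events[rai_res$events$species_id %in% natives, ],
      dataset$deployments, config$occasion_length_days, species = natives)
    brand <- setNames(history$brand, history$sites)
    designs <- prepare_covariates(dataset$covariates, rai_res$rai, brand,
                                  history$sites, config$dog_species,
                                  config$cat_species)
    screen <- correlation_screen(
      designs$occ[, c("dist_settlement", "dog_rai", "cat_rai")])
    sel <- NULL
    occ_d <- designs$occ; det_d <- designs$det
    if (config$run_selection) {
      cand <- list(
        elevation = list(role = "occ", cols = cbind(
          elevation = standardize(dataset$covariates[
            match(history$sites, dataset$covariates$site_id),
            "elevation_m"], "elevation")$z)),
        slope = list(role = "occ", cols = cbind(
          slope = standardize(dataset$covariates[
            match(history$sites, dataset$covariates$site_id),
            "slope_deg"], "slope")$z)),
        dist_water = list(role = "occ", cols = cbind(
          dist_water = standardize(dataset$covariates[
            match(history$sites, dataset$covariates$site_id),
            "dist_water_m"], "dist_water")$z)))
      sel <- stepwise_covariate_selection(
        history, designs$occ, designs$det, cand,
        mcmc = config$mcmc)
      occ_d <- sel$occ_design; det_d <- sel$det_design
    }
    fit <- suppressWarnings(
      fit_community_occupancy(history, occ_d, det_d, mcmc = config$mcmc))
    summ <- summarize_posterior(fit)
    rich <- site_richness(fit)
    list(history = history, designs = designs, screen = screen,
         selection = sel, fit = fit, summary = summ, richness = rich)
  }, error = function(e) stage_error("fit", e))
  t_all$fit <- tick() - t0

  ## overlap
  t0 <- tick()
  overlap_res <- tryCatch({
    ev <- rai_res$events
    if (config$seasonal_subset_only) {
      keep_sites <- unique(rai_res$seasonal$site_id)
      ev <- ev[ev$site_id %in% keep_sites, ]
    }
    carn <- c(dog = config$dog_species, cat = config$cat_species)
    natives <- setdiff(sort(unique(ev$species_id)), carn)
    groups <- c(setNames(as.list(natives), natives),
                list(community = natives))
    rows <- list(); letters_tabs <- list()
    seed_i <- config$seed
    for (gname in names(groups)) {
      for (cname in names(carn)) {
        ests <- list()
        for (season in SEASON_LEVELS) {
          a <- to_radian_time(ev$timestamp[
            ev$species_id %in% groups[[gname]] & ev$season == season])
          b <- to_radian_time(ev$timestamp[
            ev$species_id == carn[[cname]] & ev$season == season])
          seed_i <- seed_i + 1L
          est <- estimate_overlap(a, b, min_n = config$min_overlap_n,
                                  small_n_threshold = config$small_n_threshold,
                                  n_boot = config$n_boot, seed = seed_i)
          if (is.null(est)) next
          ests[[season]] <- est
          rows[[length(rows) + 1]] <- data.frame(
            group = gname, carnivore = cname, season = season,
            estimator = est$estimator, delta = est$delta,
            ci_low = est$ci_low, ci_high = est$ci_high,
            n_group = est$n_a, n_carnivore = est$n_b)
        }
        if (length(ests) >= 2) {
          tab <- do.call(rbind, lapply(names(ests), function(s)
            data.frame(season = s, delta = ests[[s]]$delta,
                       ci_low = ests[[s]]$ci_low,
                       ci_high = ests[[s]]$ci_high)))
          cmp <- seasonal_overlap_comparison(tab)
          cmp$group <- gname; cmp$carnivore <- cname
          letters_tabs[[length(letters_tabs) + 1]] <- cmp
        }
      }
    }
    list(table = if (length(rows)) do.call(rbind, rows) else NULL,
         letters = if (length(letters_tabs)) do.call(rbind, letters_tabs)
         else NULL)
  }, error = function(e) stage_error("overlap", e))
  t_all$overlap <- tick() - t0

  ## report
  t0 <- tick()
  paths <- tryCatch({
    p <- c(
      write_table(rai_res$rai, config$out_dir, "rai"),
      write_table(rai_res$seasonal, config$out_dir, "seasonal_rai"),
      write_table(fit_res$summary$hyper, config$out_dir, "hyper_summary"),
      write_table(fit_res$summary$species, config$out_dir, "species_summary"),
      write_table(fit_res$richness$per_site, config$out_dir, "site_richness"),
      write_table(fit_res$fit$convergence, config$out_dir, "convergence"),
      write_table(fit_res$screen, config$out_dir, "correlation_screen"))
    if (!is.null(rai_res$seasonal_tests) && nrow(rai_res$seasonal_tests))
      p <- c(p, write_table(rai_res$seasonal_tests, config$out_dir,
                            "seasonal_rai_tests"))
    if (!is.null(overlap_res$table))
      p <- c(p, write_table(overlap_res$table, config$out_dir, "overlap"))
    if (!is.null(overlap_res$letters))
      p <- c(p, write_table(overlap_res$letters, config$out_dir,
                            "overlap_letters"))
    if (!is.null(fit_res$selection))
      p <- c(p, write_table(fit_res$selection$audit, config$out_dir,
                            "selection_audit"))
    rich_summary <- data.frame(
      statistic = c("mean_of_site_means", "study_mean", "study_sd",
                    "study_ci_low", "study_ci_high"),
      value = c(fit_res$richness$mean_of_site_means,
                fit_res$richness$study_mean, fit_res$richness$study_sd,
                fit_res$richness$study_ci))
    p <- c(p, write_table(rich_summary, config$out_dir, "richness_summary"))
    p
  }, error = function(e) stage_error("report", e))

  manifest <- list(
    package_version = as.character(utils::packageVersion("camtrapcomm")),
    seed = config$seed,
    profile = config$profile,
    config = config[setdiff(names(config), "mcmc")],
    mcmc = unclass(config$mcmc),
    timings_sec = lapply(t_all, round, 3),
    outputs = as.list(tools::md5sum(sort(paths))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  t_all$report <- tick() - t0

  invisible(list(dataset = dataset, rai = rai_res, fit = fit_res,
                 overlap = overlap_res, manifest = manifest,
                 out_dir = config$out_dir))
}
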