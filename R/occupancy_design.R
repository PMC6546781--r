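## Detection-history and design-matrix construction for the
## multi-species occupancy model.

#' Discretize camera effort into detection occasions
#'
#' Each site's effective effort nights (active minus malfunction days,
#' in calendar order) are partitioned into consecutive occasions of
#' `occasion_length_days` effort nights; a trailing partial occasion
#' counts if it holds at least one effort night. `K[j]` is the number of
#' occasions and `y[i,j]` the number of occasions with at least one
#' independent event of species `i`. Sites with no effort are dropped
#' with a warning.
#'
#' @param events output of [filter_independent_events()].
#' @param deployments deployment table.
#' @param occasion_length_days occasion length (>= 1, default 10: a
#'   typical ~143-day deployment yields ~14 occasions).
#' @param species optional species vector defining the rows of `y`.
#' @return object of class `detection_history`: list with `y` (species
#'   x site integer matrix), `K` (occasions per site), `sites`,
#'   `species`, `brand` (per site) and `occasion_length_days`.
#' @export
build_detection_history <- function(events, deployments,
                                    occasion_length_days = 10,
                                    species = NULL) {
  if (occasion_length_days < 1) stop("occasion_length_days must be >= 1")
  if (is.null(species)) species <- sort(unique(events$species_id))
  sites <- sort(unique(deployments$site_id))

  site_days <- lapply(sites, function(s) {
    d <- deployments[deployments$site_id == s, ]
    act <- interval_days(d[d$interval_type == "active", , drop = FALSE])
    mal <- interval_days(d[d$interval_type == "malfunction", , drop = FALSE])
    sort(as.Date(setdiff(act, mal), origin = "1970-01-01"))
  })
  names(site_days) <- sites
  empty <- vapply(site_days, length, integer(1)) == 0
  if (any(empty)) {
    warning("dropping site(s) with zero effort: ",
            paste(sites[empty], collapse = ", "))
    sites <- sites[!empty]; site_days <- site_days[!empty]
  }

  K <- vapply(site_days, function(d)
    as.integer(ceiling(length(d) / occasion_length_days)), integer(1))
  y <- matrix(0L, length(species), length(sites),
              dimnames = list(species, sites))
  ev_day <- as.Date(events$timestamp)
  for (j in seq_along(sites)) {
    e <- events[events$site_id == sites[j], ]
    if (!nrow(e)) next
    occ_of_day <- setNames(
      rep(seq_len(K[j]), each = occasion_length_days,
          length.out = length(site_days[[j]])),
      as.character(site_days[[j]]))
    dkey <- as.character(ev_day[events$site_id == sites[j]])
    occ <- occ_of_day[dkey]
    if (anyNA(occ)) {
      warning("event(s) on non-effort days at site ", sites[j], " ignored")
      e <- e[!is.na(occ), ]; occ <- occ[!is.na(occ)]
    }
    for (sp in unique(e$species_id)) {
      if (!sp %in% species) next
      y[sp, j] <- length(unique(occ[e$species_id == sp]))
    }
  }
  brand <- vapply(sites, function(s) {
    b <- unique(deployments$camera_brand[deployments$site_id == s])
    b[1]
  }, character(1))
  structure(list(y = y, K = unname(K), sites = sites, species = species,
                 brand = unname(brand),
                 occasion_length_days = occasion_length_days),
            class = "detection_history")
}

standardize <- function(x, name) {
  m <- mean(x); s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("zero-variance covariate: ", name)
  list(z = (x - m) / s, mean = m, sd = s)
}

#' Build occurrence and detection design matrices
#'
#' Dog and cat RAIs are transformed as `log(RAI + 1)` and then
#' standardized to mean 0, sd 1; distance to settlement is standardized;
#' quadratic columns are squares of the *standardized* linear columns.
#' The detection design holds brand indicators (Cuddeback and Reconyx
#' against the KeepGuard reference) plus the standardized log RAIs.
#'
#' @param covariates site-covariate table (one row per modeled site).
#' @param rai_table output of [compute_rai()] holding the dog and cat
#'   rows (full-deployment window by default).
#' @param brand_by_site named character vector, camera brand per site.
#' @param sites sites to include, in design order.
#' @param dog_species,cat_species species ids of the invasive carnivores.
#' @return list with `occ` and `det` design matrices (first column the
#'   intercept), `transform` (means/sds used, for back-transformation)
#'   and `sites`.
#' @export
prepare_covariates <- function(covariates, rai_table, brand_by_site, sites,
                               dog_species = "dog", cat_species = "cat") {
  rownames(covariates) <- covariates$site_id
  if (!all(sites %in% covariates$site_id))
    stop("missing covariates for site(s): ",
         paste(setdiff(sites, covariates$site_id), collapse = ", "))
  get_rai <- function(sp) {
    r <- rai_table[rai_table$species_id == sp, ]
    v <- setNames(r$rai, r$site_id)
    if (!all(sites %in% names(v)))
      stop("missing ", sp, " RAI for site(s): ",
           paste(setdiff(sites, names(v)), collapse = ", "))
    unname(v[sites])
  }
  dist <- standardize(covariates[sites, "dist_settlement_m"], "dist_settlement_m")
  dog <- standardize(log1p(get_rai(dog_species)), "log dog RAI")
  cat_ <- standardize(log1p(get_rai(cat_species)), "log cat RAI")

  occ <- cbind(intercept = 1, dist_settlement = dist$z,
               dog_rai = dog$z, dog_rai_sq = dog$z^2,
               cat_rai = cat_$z, cat_rai_sq = cat_$z^2)
  brand <- brand_by_site[sites]
  det <- cbind(intercept = 1,
               cuddeback = as.numeric(brand == "Cuddeback"),
               reconyx = as.numeric(brand == "Reconyx"),
               dog_rai = dog$z, cat_rai = cat_$z)
  rownames(occ) <- rownames(det) <- sites
  list(occ = occ, det = det, sites = sites,
       transform = list(
         dist_settlement = dist[c("mean", "sd")],
         log_dog_rai = dog[c("mean", "sd")],
         log_cat_rai = cat_[c("mean", "sd")]))
}

#' Pairwise Pearson correlation screen for covariates
#'
#' Flags covariate pairs whose absolute Pearson correlation meets or
#' exceeds `r_threshold`; `p` from [stats::cor.test()] is reported for
#' reference. Intended to verify that continuous covariates entering
#' the model jointly are not collinear.
#'
#' @param covariate_columns numeric matrix or data frame (>= 3 rows).
#' @param r_threshold absolute-correlation threshold (default 0.3).
#' @param alpha reported significance level.
#' @return data frame `var_a`, `var_b`, `r`, `p`, `flagged`.
#' @export
correlation_screen <- function(covariate_columns, r_threshold = 0.3,
                               alpha = 0.05) {
  x <- as.matrix(covariate_columns)
  if (nrow(x) < 3) stop("need at least 3 sites")
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(x)))
  pairs <- combn(ncol(x), 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    r <- cor(x[, i], x[, j])
    p <- if (abs(r) >= 1 - 1e-12) 0 else cor.test(x[, i], x[, j])$p.value
    data.frame(var_a = nm[i], var_b = nm[j], r = r, p = p,
               flagged = abs(r) >= r_threshold)
  })
  res <- do.call(rbind, out)
  attr(res, "r_threshold") <- r_threshold
  attr(res, "alpha") <- alpha
  res
}
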