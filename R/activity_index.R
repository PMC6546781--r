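## Activity indices: independence filtering, trap-night accounting, RAI
## (independent detections per 100 trap-nights), seasonal RAI, and the
## Mann-Whitney seasonal comparison.

#' Filter camera triggers into independent detection events
#'
#' Within each (site, species) stream, consecutive triggers are deemed
#' independent when separated by at least `interval_minutes` (default
#' 30 min, the 0.5-h rule) or when the animals are individually
#' distinguishable. The gap is measured from the *last retained* event,
#' not the immediately preceding raw trigger, so an unbroken chain of
#' sub-interval triggers cannot collapse hours of activity into a single
#' event. Records with distinct `individual_id` form independent
#' streams; records with no id share one stream.
#'
#' @param records detection records (`site_id`, `species_id`,
#'   `timestamp` POSIXct, optional `individual_id`), e.g.
#'   `dataset$records` from [load_dataset()].
#' @param interval_minutes independence interval; must be >= 0.
#' @return data frame of retained events with a `season` column added.
#' @export
filter_independent_events <- function(records, interval_minutes = 30) {
  if (interval_minutes < 0) stop("interval_minutes must be non-negative")
  if (is.null(records$individual_id)) records$individual_id <- NA_character_
  stream <- paste(records$site_id, records$species_id,
                  ifelse(is.na(records$individual_id), "",
                         records$individual_id), sep = "\r")
  ord <- order(stream, records$timestamp)
  records <- records[ord, , drop = FALSE]
  stream <- stream[ord]
  keep <- logical(nrow(records))
  gap <- interval_minutes * 60
  last_t <- -Inf; last_s <- ""
  tsec <- as.numeric(records$timestamp)
  for (r in seq_len(nrow(records))) {
    if (stream[r] != last_s || tsec[r] - last_t >= gap) {
      keep[r] <- TRUE
      last_t <- tsec[r]; last_s <- stream[r]
    }
  }
  out <- records[keep, , drop = FALSE]
  out$season <- assign_season(out$timestamp)
  rownames(out) <- NULL
  out
}

#' Trap-nights of effort per site
#'
#' A trap-night is one calendar night of functioning camera effort:
#' nights covered by active intervals minus nights covered by
#' malfunction intervals. Partial first/last days count as effort
#' (sub-day precision is unavailable in the field records).
#'
#' @param deployments deployment table (see [load_dataset()]).
#' @return data frame `site_id`, `trap_nights`.
#' @export
compute_trap_nights <- function(deployments) {
  sites <- unique(deployments$site_id)
  tn <- vapply(sites, function(s) {
    d <- deployments[deployments$site_id == s, ]
    act <- interval_days(d[d$interval_type == "active", , drop = FALSE])
    mal <- interval_days(d[d$interval_type == "malfunction", , drop = FALSE])
    if (length(setdiff(mal, act)))
      stop("malfunction interval outside active interval at site ", s)
    length(setdiff(act, mal))
  }, integer(1))
  data.frame(site_id = sites, trap_nights = tn, row.names = NULL)
}

# effort nights per (site, calendar month "YYYY-MM")
monthly_effort <- function(deployments) {
  out <- lapply(unique(deployments$site_id), function(s) {
    d <- deployments[deployments$site_id == s, ]
    act <- interval_days(d[d$interval_type == "active", , drop = FALSE])
    mal <- interval_days(d[d$interval_type == "malfunction", , drop = FALSE])
    days <- setdiff(act, mal)
    if (!length(days)) return(NULL)
    days <- as.Date(days, origin = "1970-01-01")
    tab <- table(format(days, "%Y-%m"))
    data.frame(site_id = s, month = names(tab),
               effort_nights = as.integer(tab), row.names = NULL)
  })
  do.call(rbind, out)
}

#' Relative activity index (RAI)
#'
#' RAI = 100 x independent events / trap-nights per (site, species).
#' Species present in `species` (or seen anywhere in `events`) but with
#' no events at a site get RAI 0 for that site.
#'
#' @param events output of [filter_independent_events()].
#' @param trap_nights output of [compute_trap_nights()].
#' @param species optional character vector of species to tabulate.
#' @return data frame `site_id`, `species_id`, `events`, `trap_nights`,
#'   `rai`.
#' @export
compute_rai <- function(events, trap_nights, species = NULL) {
  if (is.null(species)) species <- sort(unique(events$species_id))
  bad <- setdiff(unique(events$site_id), trap_nights$site_id)
  if (length(bad))
    stop("events at site(s) with no recorded effort: ", paste(bad, collapse = ", "))
  tn <- setNames(trap_nights$trap_nights, trap_nights$site_id)
  ev_site <- unique(events$site_id)
  if (any(tn[ev_site] <= 0))
    stop("inconsistent effort: site with events but zero trap-nights")
  grid <- expand.grid(site_id = trap_nights$site_id, species_id = species,
                      stringsAsFactors = FALSE)
  key <- paste(events$site_id, events$species_id, sep = "\r")
  cnt <- table(key)
  gkey <- paste(grid$site_id, grid$species_id, sep = "\r")
  grid$events <- as.integer(ifelse(gkey %in% names(cnt), cnt[gkey], 0L))
  grid$trap_nights <- as.integer(tn[grid$site_id])
  grid$rai <- ifelse(grid$trap_nights > 0,
                     100 * grid$events / grid$trap_nights, 0)
  grid[order(grid$site_id, grid$species_id), ]
}

#' Monthly RAI per site and species
#'
#' Each calendar month of effort gets its own denominator; months with
#' zero effort are omitted (not zero-filled).
#'
#' @inheritParams compute_rai
#' @param deployments deployment table.
#' @return data frame `site_id`, `species_id`, `month`, `season`,
#'   `events`, `effort_nights`, `rai`.
#' @export
monthly_rai <- function(events, deployments, species = NULL) {
  if (is.null(species)) species <- sort(unique(events$species_id))
  eff <- monthly_effort(deployments)
  grid <- merge(eff, data.frame(species_id = species), by = NULL)
  ev_month <- format(as.Date(events$timestamp), "%Y-%m")
  key <- paste(events$site_id, events$species_id, ev_month, sep = "\r")
  cnt <- table(key)
  gkey <- paste(grid$site_id, grid$species_id, grid$month, sep = "\r")
  grid$events <- as.integer(ifelse(gkey %in% names(cnt), cnt[gkey], 0L))
  grid$rai <- 100 * grid$events / grid$effort_nights
  grid$season <- assign_season(as.Date(paste0(grid$month, "-15")))
  grid[order(grid$site_id, grid$species_id, grid$month),
       c("site_id", "species_id", "month", "season", "events",
         "effort_nights", "rai")]
}

#' Seasonal RAI at qualifying sites
#'
#' The seasonal RAI of a species at a site is the arithmetic mean of the
#' site's monthly RAIs within the season. Only sites active for at least
#' `min_seasons` seasons with at least `min_days_per_season` effort
#' nights each qualify, reducing spatial confounding when seasons are
#' compared.
#'
#' @inheritParams monthly_rai
#' @param min_days_per_season minimum effort nights for a season to count.
#' @param min_seasons minimum number of qualifying seasons per site.
#' @return data frame `site_id`, `species_id`, `season`, `rai`
#'   (mean monthly RAI), `n_months`. Empty (with a warning) if no site
#'   qualifies.
#' @export
seasonal_rai <- function(events, deployments, min_days_per_season = 60,
                         min_seasons = 2, species = NULL) {
  mon <- monthly_rai(events, deployments, species = species)
  eff <- unique(mon[, c("site_id", "month", "season", "effort_nights")])
  eff_season <- aggregate(effort_nights ~ site_id + season, data = eff, sum)
  qual <- vapply(unique(eff_season$site_id), function(s) {
    e <- eff_season[eff_season$site_id == s, ]
    sum(e$effort_nights >= min_days_per_season) >= min_seasons
  }, logical(1))
  keep_sites <- unique(eff_season$site_id)[qual]
  if (!length(keep_sites)) {
    warning("no site meets the seasonal-effort rule; returning empty table")
    return(data.frame(site_id = character(0), species_id = character(0),
                      season = factor(character(0), levels = SEASON_LEVELS),
                      rai = numeric(0), n_months = integer(0)))
  }
  # keep only qualifying seasons within qualifying sites
  ok_key <- with(eff_season[eff_season$effort_nights >= min_days_per_season &
                              eff_season$site_id %in% keep_sites, ],
                 paste(site_id, season, sep = "\r"))
  mon <- mon[paste(mon$site_id, mon$season, sep = "\r") %in% ok_key, ]
  agg <- aggregate(rai ~ site_id + species_id + season, data = mon, mean)
  nm <- aggregate(rai ~ site_id + species_id + season, data = mon, length)
  names(nm)[4] <- "n_months"
  out <- merge(agg, nm, by = c("site_id", "species_id", "season"))
  out$season <- factor(as.character(out$season), levels = SEASON_LEVELS)
  out[order(out$site_id, out$species_id, out$season), ]
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For combined sample size <= 20 the p-value
#' is exact by full enumeration of all label assignments of the pooled
#' values (ties handled by midranks); above that a normal approximation
#' with tie correction and continuity correction is used. The reported
#' statistic is `min(U_a, U_b)`.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @param exact_max combined size at or below which enumeration is exact.
#' @return list `U`, `p`, `method` ("exact" or "normal").
#' @export
mann_whitney_u <- function(sample_a, sample_b, exact_max = 20) {
  if (!length(sample_a) || !length(sample_b)) stop("empty sample")
  na <- length(sample_a); nb <- length(sample_b); n <- na + nb
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)
  u_from_ranksum <- function(rs, m) rs - m * (m + 1) / 2
  ua <- u_from_ranksum(sum(r[seq_len(na)]), na)
  ub <- na * nb - ua
  u <- min(ua, ub)
  if (n <= exact_max) {
    sel <- combn(n, na)
    rs <- colSums(matrix(r[sel], nrow = na))
    ua_all <- u_from_ranksum(rs, na)
    u_all <- pmin(ua_all, na * nb - ua_all)
    p <- mean(u_all <= u + 1e-9)
    return(list(U = u, p = p, method = "exact"))
  }
  mu <- na * nb / 2
  ties <- table(pooled)
  tie_adj <- sum(ties^3 - ties) / (n * (n - 1))
  s2 <- na * nb / 12 * ((n + 1) - tie_adj)
  if (s2 <= 0) return(list(U = u, p = 1, method = "normal"))
  z <- (u - mu + 0.5) / sqrt(s2)  # continuity-corrected; u <= mu by construction
  p <- min(1, 2 * pnorm(z))
  list(U = u, p = p, method = "normal")
}

#' Pairwise seasonal Mann-Whitney tests on site-level seasonal RAI
#'
#' For one species, compares the distribution of site-level seasonal RAI
#' between every pair of seasons.
#'
#' @param srai output of [seasonal_rai()].
#' @param species species to test.
#' @return data frame `species_id`, `season_a`, `season_b`, `n_a`,
#'   `n_b`, `U`, `p`.
#' @export
seasonal_rai_tests <- function(srai, species) {
  s <- srai[srai$species_id == species, ]
  seasons <- levels(droplevels(s$season))
  if (length(seasons) < 2)
    return(data.frame(species_id = character(0), season_a = character(0),
                      season_b = character(0), n_a = integer(0),
                      n_b = integer(0), U = numeric(0), p = numeric(0)))
  pairs <- combn(seasons, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- s$rai[s$season == pairs[1, k]]
    b <- s$rai[s$season == pairs[2, k]]
    if (!length(a) || !length(b)) return(NULL)
    mw <- mann_whitney_u(a, b)
    data.frame(species_id = species, season_a = pairs[1, k],
               season_b = pairs[2, k], n_a = length(a), n_b = length(b),
               U = mw$U, p = mw$p)
  })
  do.call(rbind, out)
}
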