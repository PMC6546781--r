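## Field data input/validation: detection records, deployments, site
## covariates. All timestamps are naive local clock times (single-park
## studies; the diel analysis needs clock time only), carried as POSIXct
## in UTC so no DST arithmetic ever applies.

CAMERA_BRANDS <- c("KeepGuard", "Cuddeback", "Reconyx")
VEGETATION_CLASSES <- c("herbaceous", "broadleaf", "mixed")
SEASON_LEVELS <- c("DEC_MAR", "APR_JUL", "AUG_NOV")

DETECTION_COLS <- c("site_id", "species_id", "timestamp", "individual_id")
DEPLOYMENT_COLS <- c("site_id", "camera_brand", "interval_type",
                     "start_date", "end_date")
COVARIATE_COLS <- c("site_id", "x", "y", "dist_settlement_m", "dist_water_m",
                    "elevation_m", "slope_deg", "solar_radiation", "vegetation")

#' Assign a calendar date to a field season
#'
#' The year is split into three four-month seasons: `DEC_MAR`
#' (December-March, the colder season), `APR_JUL` (April-July, hotter
#' and drier) and `AUG_NOV` (August-November, hotter and wetter).
#'
#' @param date a `Date`, `POSIXct`, or anything `as.Date()` accepts.
#' @return factor with levels `DEC_MAR`, `APR_JUL`, `AUG_NOV`.
#' @export
#' @examples
#' assign_season(as.Date("2015-12-15"))  # DEC_MAR
assign_season <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  lab <- ifelse(m %in% c(12L, 1L, 2L, 3L), "DEC_MAR",
                ifelse(m %in% 4:7, "APR_JUL", "AUG_NOV"))
  factor(lab, levels = SEASON_LEVELS)
}

parse_timestamp <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (anyNA(out)) stop("unparseable timestamps: ",
                       paste(head(x[is.na(out)], 5), collapse = ", "))
  out
}

check_columns <- function(df, needed, what) {
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop(sprintf("schema error in %s table: missing column(s) %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Read and cross-validate a camera-trap dataset
#'
#' Reads the three delimited input tables (comma-separated, UTF-8,
#' ISO-8601 dates/timestamps) and validates them against each other:
#' every detection must fall inside an active deployment interval of its
#' site, every site must have covariates, camera brands and vegetation
#' classes must come from their closed sets, and malfunction intervals
#' must lie within active intervals.
#'
#' Expected columns:
#' * detections: `site_id, species_id, timestamp, individual_id`
#'   (`individual_id` may be empty);
#' * deployments: `site_id, camera_brand, interval_type, start_date,
#'   end_date` with one row per interval and `interval_type` in
#'   `{active, malfunction}`;
#' * covariates: `site_id, x, y, dist_settlement_m, dist_water_m,
#'   elevation_m, slope_deg, solar_radiation, vegetation`.
#'
#' @param detections_path,deployments_path,covariates_path file paths.
#' @return a list of class `camtrap_dataset` with elements `records`,
#'   `deployments`, `covariates`.
#' @export
load_dataset <- function(detections_path, deployments_path, covariates_path) {
  for (p in c(detections_path, deployments_path, covariates_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  records <- read.csv(detections_path, stringsAsFactors = FALSE,
                      colClasses = "character")
  deployments <- read.csv(deployments_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  covariates <- read.csv(covariates_path, stringsAsFactors = FALSE)
  validate_dataset(records, deployments, covariates)
}

#' Validate in-memory camera-trap tables
#'
#' Same checks as [load_dataset()] for tables already in R.
#' @param records,deployments,covariates data frames (see
#'   [load_dataset()] for columns).
#' @return a `camtrap_dataset` list with typed columns.
#' @export
validate_dataset <- function(records, deployments, covariates) {
  check_columns(records, setdiff(DETECTION_COLS, "individual_id"), "detections")
  check_columns(deployments, DEPLOYMENT_COLS, "deployments")
  check_columns(covariates, COVARIATE_COLS, "covariates")

  if (!nrow(records)) stop("validation error: empty detections table")

  records$timestamp <- parse_timestamp(records$timestamp)
  if (is.null(records$individual_id)) records$individual_id <- NA_character_
  records$individual_id[records$individual_id %in% c("", "NA")] <- NA_character_

  bad_brand <- setdiff(unique(deployments$camera_brand), CAMERA_BRANDS)
  if (length(bad_brand))
    stop("schema error: unknown camera_brand ", paste(bad_brand, collapse = ", "),
         " (expected one of ", paste(CAMERA_BRANDS, collapse = ", "), ")")
  bad_type <- setdiff(unique(deployments$interval_type), c("active", "malfunction"))
  if (length(bad_type))
    stop("schema error: unknown interval_type ", paste(bad_type, collapse = ", "))
  deployments$start_date <- as.Date(deployments$start_date)
  deployments$end_date <- as.Date(deployments$end_date)
  if (anyNA(deployments$start_date) || anyNA(deployments$end_date))
    stop("schema error: unparseable deployment dates")
  if (any(deployments$end_date < deployments$start_date))
    stop("validation error: deployment interval with end before start")

  bad_veg <- setdiff(unique(covariates$vegetation), VEGETATION_CLASSES)
  if (length(bad_veg))
    stop("schema error: unknown vegetation class ", paste(bad_veg, collapse = ", "))
  if (anyDuplicated(covariates$site_id))
    stop("validation error: duplicated site_id in covariates")
  num_cols <- c("dist_settlement_m", "dist_water_m")
  for (cc in num_cols)
    if (any(!is.finite(covariates[[cc]]) | covariates[[cc]] < 0))
      stop("validation error: ", cc, " must be finite and non-negative")

  no_dep <- setdiff(unique(records$site_id), unique(deployments$site_id))
  if (length(no_dep))
    stop("validation error: detection site(s) without deployment: ",
         paste(no_dep, collapse = ", "))
  no_cov <- setdiff(unique(records$site_id), covariates$site_id)
  if (length(no_cov))
    stop("validation error: detection site(s) without covariates: ",
         paste(no_cov, collapse = ", "))

  # malfunction days must be a subset of active days, per site
  for (s in unique(deployments$site_id)) {
    d <- deployments[deployments$site_id == s, ]
    act <- interval_days(d[d$interval_type == "active", ])
    mal <- interval_days(d[d$interval_type == "malfunction", ])
    if (length(setdiff(mal, act)))
      stop("validation error: malfunction interval outside active interval at site ", s)
  }

  # every record inside some active interval of its site
  rec_day <- as.Date(records$timestamp)
  ok <- vapply(seq_len(nrow(records)), function(r) {
    d <- deployments[deployments$site_id == records$site_id[r] &
                       deployments$interval_type == "active", ]
    any(rec_day[r] >= d$start_date & rec_day[r] <= d$end_date)
  }, logical(1))
  if (any(!ok))
    stop("validation error: detection(s) outside any active deployment interval, rows: ",
         paste(which(!ok), collapse = ", "))

  structure(list(records = records, deployments = deployments,
                 covariates = covariates),
            class = "camtrap_dataset")
}

# all calendar days covered by a set of intervals (Date vector, unique)
interval_days <- function(intervals) {
  if (!nrow(intervals)) return(as.Date(character(0)))
  unique(do.call(c, lapply(seq_len(nrow(intervals)), function(i)
    seq(intervals$start_date[i], intervals$end_date[i], by = "day"))))
}

#' Write a validated dataset back to delimited text
#'
#' Inverse of [load_dataset()]: the three tables are written as CSV so
#' that reloading yields an identical dataset (round-trip property).
#'
#' @param dataset a `camtrap_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "camtrap_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- dataset$records
  rec$timestamp <- format(rec$timestamp, "%Y-%m-%dT%H:%M:%S")
  paths <- file.path(dir, c("detections.csv", "deployments.csv", "covariates.csv"))
  write.csv(rec, paths[1], row.names = FALSE)
  write.csv(dataset$deployments, paths[2], row.names = FALSE)
  write.csv(dataset$covariates, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Distance to the nearest settlement point
#'
#' Minimum Euclidean distance from a site to a set of settlement
#' points, all in a common projected CRS in meters. Settlement geometry
#' is reduced to representative points; over a park-scale extent the
#' projection error of planar distance is negligible.
#'
#' @param site_xy numeric length-2 `(x, y)` in meters.
#' @param settlement_points numeric matrix (n x 2) of point coordinates.
#' @return distance in meters (>= 0).
#' @export
nearest_settlement_distance <- function(site_xy, settlement_points) {
  pts <- rbind(settlement_points)
  if (!nrow(pts)) stop("empty settlement point set")
  if (ncol(pts) != 2 || length(site_xy) != 2)
    stop("coordinates must be 2-column (x, y)")
  min(sqrt((pts[, 1] - site_xy[1])^2 + (pts[, 2] - site_xy[2])^2))
}
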