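# Phase I of the pipeline: attach (country, region) names and climate
# covariates to point events, dropping anything that cannot be resolved.

#' Offline reverse geocoding against a rectangular atlas
#'
#' Maps coordinates to the unique atlas cell containing them under the
#' half-open convention `[min, max)` per axis, so a point on a shared edge
#' belongs to the higher-min cell. Points outside every cell map to `NA`
#' (absence is a value, not an error).
#'
#' @param atlas a `region_atlas`.
#' @param lat,lon numeric vectors of equal length, finite decimal degrees.
#' @return Data frame with character columns `country`, `region` (`NA` when
#'   no cell contains the point).
#' @export
reverse_geocode <- function(atlas, lat, lon) {
  stopifnot(length(lat) == length(lon))
  if (length(lat) == 0L)
    return(data.frame(country = character(), region = character(),
                      stringsAsFactors = FALSE))
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop("coordinates must be finite")
  hit_cell <- function(la, lo) {
    i <- which(la >= atlas$lat_min & la < atlas$lat_max &
                 lo >= atlas$lon_min & lo < atlas$lon_max)
    if (length(i)) i[1] else NA_integer_
  }
  idx <- mapply(hit_cell, lat, lon)
  data.frame(country = atlas$country[idx], region = atlas$region[idx],
             stringsAsFactors = FALSE)
}

# Nearest axis index for each query value; which.min ties go to the smaller
# index. NA when the query sits farther than one grid step outside the axis.
.nearest_index <- function(axis, x) {
  step <- if (length(axis) > 1L) axis[2] - axis[1] else Inf
  i <- vapply(x, function(v) which.min(abs(axis - v)), integer(1))
  i[x < axis[1] - step | x > axis[length(axis)] + step] <- NA_integer_
  i
}

# Time-axis positions of (year, month) queries; NA when outside the span.
.time_index <- function(grid, year, month) {
  match(paste(year, month), paste(grid$time$year, grid$time$month))
}

#' Extract climate covariates at points and months
#'
#' Returns the values of the grid cell whose centre is nearest in `(lat,
#' lon)` under Euclidean degree distance (on a rectangular grid the per-axis
#' nearest node is the joint minimizer); exact ties break toward the smaller
#' axis index. The year-month join is exact, with no lagging.
#'
#' @param grid a `climate_grid`.
#' @param lat,lon,year,month equal-length query vectors.
#' @return Data frame with columns `precipitation`, `max_temperature`,
#'   `soil_moisture`.
#' @export
sample_climate <- function(grid, lat, lon, year, month) {
  stopifnot(inherits(grid, "climate_grid"))
  n <- length(lat)
  stopifnot(length(lon) == n, length(year) == n, length(month) == n)
  ti <- .time_index(grid, year, month)
  if (anyNA(ti))
    stop("temporal coverage error: (year, month) outside the climate span: ",
         paste(unique(paste0(year[is.na(ti)], "-", month[is.na(ti)])),
               collapse = ", "))
  ilat <- .nearest_index(grid$lat, lat)
  ilon <- .nearest_index(grid$lon, lon)
  if (anyNA(ilat) || anyNA(ilon))
    stop("spatial coverage error: point(s) farther than one grid step ",
         "outside the climate bounding box")
  at <- cbind(ti, ilat, ilon)
  data.frame(
    precipitation = grid$ppt[at],
    max_temperature = grid$tmax[at],
    soil_moisture = grid$soil[at]
  )
}

# TRUE where an event is resolvable: inside the atlas, inside the climate
# span and within one grid step of the climate box.
.event_resolvable <- function(events, grid, atlas) {
  geo_ok <- !is.na(reverse_geocode(atlas, events$lat, events$lon)$country)
  t_ok <- !is.na(.time_index(grid, events$start_year, events$start_month))
  s_ok <- !is.na(.nearest_index(grid$lat, events$lat)) &
    !is.na(.nearest_index(grid$lon, events$lon))
  geo_ok & t_ok & s_ok
}

#' Build the positive-class table from sighting events
#'
#' One labelled row per geocodable event: reverse-geocoded `(country,
#' region)`, climate covariates sampled at the event's coordinates for its
#' start year-month, and `locust_present = "yes"` (sighting feeds only report
#' presences). Events that fall outside the atlas or the climate coverage are
#' dropped and counted — the null-dropping rule is total, so no emitted row
#' has a missing covariate.
#'
#' @param events event data frame (`lat`, `lon`, `start_year`,
#'   `start_month`).
#' @param grid a `climate_grid`.
#' @param atlas a `region_atlas`.
#' @param collapse if `TRUE`, keep one row per (region, year, month); by
#'   default every event yields its own row.
#' @return Labelled data frame in schema column order with a `provenance`
#'   attribute (`rows_read`, `rows_dropped`, `positives`, `negatives`).
#' @export
build_positive_rows <- function(events, grid, atlas, collapse = FALSE) {
  n_in <- nrow(events)
  keep <- .event_resolvable(events, grid, atlas)
  ev <- events[keep, , drop = FALSE]
  if (nrow(ev) == 0L)
    stop("no events survived geocoding and covariate sampling")
  geo <- reverse_geocode(atlas, ev$lat, ev$lon)
  clim <- sample_climate(grid, ev$lat, ev$lon, ev$start_year, ev$start_month)
  rows <- data.frame(
    start_month = as.integer(ev$start_month),
    start_year = as.integer(ev$start_year),
    country = geo$country,
    region = geo$region,
    soil_moisture = clim$soil_moisture,
    precipitation = clim$precipitation,
    max_temperature = clim$max_temperature,
    locust_present = "yes",
    stringsAsFactors = FALSE
  )
  if (collapse)
    rows <- rows[!duplicated(rows[c("country", "region", "start_year",
                                    "start_month")]), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "provenance") <- list(rows_read = n_in,
                                   rows_dropped = n_in - sum(keep),
                                   positives = nrow(rows), negatives = 0L)
  rows
}
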