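# File formats: CSV (UTF-8, header row) for events, atlases and labelled
# tables; netCDF with dims (time, lat, lon) and variables ppt/tmax/soil for
# climate. Time is encoded as integer YYYYMM so the year-month axis
# round-trips exactly.

#' Validate a climate grid's structural invariants
#'
#' Checks strictly increasing axes, matching `(time, lat, lon)` array shapes,
#' a gap-free monthly time axis, and non-negative precipitation and soil
#' moisture.
#'
#' @param grid a `climate_grid`.
#' @return The grid, invisibly classed, or an error.
#' @export
validate_climate <- function(grid) {
  for (ax in c("lat", "lon"))
    if (length(grid[[ax]]) < 1L || is.unsorted(grid[[ax]], strictly = TRUE))
      stop("climate grid ", ax, " axis must be strictly increasing")
  tm <- grid$time
  if (!all(c("year", "month") %in% names(tm)) || nrow(tm) < 1L)
    stop("climate grid time axis must have year and month columns")
  if (any(tm$month < 1L | tm$month > 12L))
    stop("climate grid months must lie in 1..12")
  idx <- tm$year * 12L + (tm$month - 1L)
  if (nrow(tm) > 1L && any(diff(idx) != 1L))
    stop("climate grid time axis has gaps: consecutive entries must differ ",
         "by one calendar month")
  want <- c(nrow(tm), length(grid$lat), length(grid$lon))
  for (v in c("ppt", "tmax", "soil")) {
    if (is.null(grid[[v]]))
      stop("climate grid is missing variable '", v, "'")
    if (!identical(dim(grid[[v]]), as.integer(want)))
      stop("climate variable '", v, "' shape does not match (time, lat, lon)")
  }
  if (any(grid$ppt < 0)) stop("precipitation must be non-negative")
  if (any(grid$soil < 0)) stop("soil moisture must be non-negative")
  class(grid) <- "climate_grid"
  invisible(grid)
}

#' Write a climate grid to netCDF
#'
#' @param grid a `climate_grid`.
#' @param path output `.nc` path.
#' @return `path`, invisibly.
#' @export
write_climate <- function(grid, path) {
  validate_climate(grid)
  dim_t <- ncdf4::ncdim_def("time", "year-month as YYYYMM",
                            as.integer(grid$time$year * 100L + grid$time$month))
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", grid$lat)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", grid$lon)
  units <- c(ppt = "mm", tmax = "degC", soil = "VWC")
  vars <- lapply(names(units), function(v)
    ncdf4::ncvar_def(v, units[[v]], list(dim_t, dim_lat, dim_lon),
                     missval = NA_real_, prec = "double"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  for (i in seq_along(vars))
    ncdf4::ncvar_put(nc, vars[[i]], grid[[names(units)[i]]])
  invisible(path)
}

#' Read a climate grid from netCDF
#'
#' Expects dimensions `time` (YYYYMM integers), `lat`, `lon` and variables
#' `ppt`, `tmax`, `soil`; errors name whatever is missing.
#'
#' @param path `.nc` file path.
#' @return A validated `climate_grid`.
#' @export
read_climate <- function(path) {
  if (!file.exists(path)) stop("climate file not found: ", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  for (d in c("time", "lat", "lon"))
    if (!d %in% names(nc$dim))
      stop("climate file lacks required dimension '", d, "'")
  for (v in c("ppt", "tmax", "soil"))
    if (!v %in% names(nc$var))
      stop("climate file lacks required variable '", v, "'")
  tcode <- as.integer(nc$dim$time$vals)
  grid <- list(
    lat = as.numeric(nc$dim$lat$vals),
    lon = as.numeric(nc$dim$lon$vals),
    time = data.frame(year = tcode %/% 100L, month = tcode %% 100L)
  )
  for (v in c("ppt", "tmax", "soil")) {
    arr <- ncdf4::ncvar_get(nc, v, collapse_degen = FALSE)
    dim(arr) <- c(nrow(grid$time), length(grid$lat), length(grid$lon))
    grid[[v]] <- arr
  }
  grid <- validate_climate(grid)
  grid
}

#' @rdname read_atlas
#' @export
write_atlas <- function(atlas, path) {
  utils::write.csv(as.data.frame(atlas)[, c("country", "region", "lat_min",
                                            "lat_max", "lon_min", "lon_max")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read/write region atlases and event tables as CSV
#'
#' @param atlas a `region_atlas` data frame.
#' @param events an event data frame (`lat`, `lon`, `start_year`,
#'   `start_month`).
#' @param path CSV path.
#' @return Readers return the parsed, validated table; writers the path.
#' @export
read_atlas <- function(path) {
  atlas <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "region", "lat_min", "lat_max", "lon_min", "lon_max")
  miss <- setdiff(need, names(atlas))
  if (length(miss)) stop("atlas file lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(atlas$lat_min >= atlas$lat_max) || any(atlas$lon_min >= atlas$lon_max))
    stop("atlas cells must have lat_min < lat_max and lon_min < lon_max")
  if (any(!nzchar(atlas$country)) || any(!nzchar(atlas$region)))
    stop("atlas country and region names must be non-empty")
  class(atlas) <- c("region_atlas", "data.frame")
  atlas
}

#' @rdname read_atlas
#' @export
write_events <- function(events, path) {
  utils::write.csv(events[, c("lat", "lon", "start_year", "start_month")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_atlas
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lat", "lon", "start_year", "start_month")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("event file lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(ev$lat)) || any(!is.finite(ev$lon)))
    stop("event coordinates must be finite")
  if (any(ev$start_month < 1L | ev$start_month > 12L))
    stop("event start_month must lie in 1..12")
  ev
}

# Canonical labelled-table column order (schema of the fused dataset).
.glad_cols <- c("start_month", "start_year", "country", "region",
                "soil_moisture", "precipitation", "max_temperature",
                "locust_present")

#' Read/write labelled presence/absence tables as CSV
#'
#' Columns, in order: `start_month`, `start_year`, `country`, `region`,
#' `soil_moisture`, `precipitation`, `max_temperature`, `locust_present`
#' (`"yes"`/`"no"`).
#'
#' @param rows a labelled data frame with the eight schema columns.
#' @param path CSV path.
#' @return Readers return the validated table; writers the path.
#' @export
write_glad <- function(rows, path) {
  utils::write.csv(rows[, .glad_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_glad
#' @export
read_glad <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.glad_cols, names(rows))
  if (length(miss)) stop("dataset file lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(rows$locust_present %in% c("yes", "no")))
    stop("locust_present must be 'yes' or 'no'")
  rows[, .glad_cols]
}
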