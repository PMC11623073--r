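# Variable ranges (mm/month, deg C, volumetric water content) that generated
# climate is clipped into; these are the observed extremes of the three
# TerraClimate-style covariates over the 1985-2020 study window.
.var_ranges <- list(
  ppt  = c(0.00, 906.70),
  tmax = c(2.10, 46.71),
  soil = c(0.00, 582.60)
)

# Seasonal template parameters per variable: annual mean level, amplitude of
# the seasonal cycle, and a mild north-south gradient per degree latitude.
.var_season <- list(
  ppt  = c(mid = 80, amp = 70, grad = 2.0),
  tmax = c(mid = 30, amp = 8,  grad = -0.3),
  soil = c(mid = 40, amp = 35, grad = 1.0)
)

#' Configuration for the synthetic locust/climate generator
#'
#' Bundles every knob of the synthetic study system: a rectangular atlas of
#' `n_countries * regions_per_country` region cells, a monthly climate grid,
#' and swarm events whose region-month occurrence probability follows a
#' country-specific logistic model in the (standardized) climate covariates.
#'
#' The default coefficients plant opposite-sign climate responses in
#' alternating countries (slope magnitude 2 on the standardized scale, on all
#' three covariates), so that a country-partitioned classifier has structure
#' to recover that a single global fit cannot. `base_rate` sets the attack
#' probability at average climate via the logistic intercept.
#'
#' @param seed integer master seed; all atlas/climate/event randomness derives
#'   from it through per-stage sub-seeds.
#' @param n_countries,regions_per_country atlas tiling (countries are
#'   latitude strips, regions longitude strips within each country).
#' @param grid_step climate grid spacing in degrees.
#' @param lat_bounds,lon_bounds bounding box, degrees, `c(min, max)`.
#' @param year_span inclusive `c(first, last)` study years.
#' @param base_rate attack probability at average climate, in (0, 1).
#' @param country_coefficients numeric matrix with one row per country and
#'   columns `(b0, b_ppt, b_tmax, b_soil)`; `NULL` for the planted default.
#' @param events_per_attack sighting records emitted per attacked
#'   region-month.
#' @param noise_sd named numeric vector `c(ppt=, tmax=, soil=)` of Gaussian
#'   noise SDs added to the seasonal climate template (0 = deterministic).
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, year_span = c(2001, 2004))
#' atlas <- make_atlas(cfg)
#' @export
sim_config <- function(seed = 1L,
                       n_countries = 3L,
                       regions_per_country = 2L,
                       grid_step = 0.5,
                       lat_bounds = c(0, 12),
                       lon_bounds = c(0, 12),
                       year_span = c(1985L, 2020L),
                       base_rate = 0.5,
                       country_coefficients = NULL,
                       events_per_attack = 1L,
                       noise_sd = c(ppt = 10, tmax = 1.5, soil = 8)) {
  n_countries <- as.integer(n_countries)
  regions_per_country <- as.integer(regions_per_country)
  year_span <- as.integer(year_span)
  if (n_countries < 1L || regions_per_country < 1L)
    stop("n_countries and regions_per_country must be >= 1")
  if (!is.numeric(grid_step) || grid_step <= 0)
    stop("grid_step must be > 0")
  if (length(lat_bounds) != 2L || diff(lat_bounds) <= 0 ||
      length(lon_bounds) != 2L || diff(lon_bounds) <= 0)
    stop("lat_bounds and lon_bounds must be increasing c(min, max) pairs")
  if (length(year_span) != 2L || year_span[1] > year_span[2])
    stop("year_span start must not exceed its end")
  if (!is.numeric(base_rate) || base_rate <= 0 || base_rate >= 1)
    stop("base_rate must lie strictly in (0, 1)")
  if (events_per_attack < 1L)
    stop("events_per_attack must be >= 1")
  noise_sd <- noise_sd[c("ppt", "tmax", "soil")]
  if (anyNA(noise_sd) || any(noise_sd < 0))
    stop("noise_sd must supply non-negative ppt, tmax and soil entries")

  if (is.null(country_coefficients)) {
    sgn <- rep_len(c(1, -1), n_countries)
    country_coefficients <- cbind(
      b0 = rep(stats::qlogis(base_rate), n_countries),
      b_ppt = 2 * sgn, b_tmax = 2 * sgn, b_soil = 2 * sgn
    )
  }
  country_coefficients <- as.matrix(country_coefficients)
  if (nrow(country_coefficients) != n_countries ||
      ncol(country_coefficients) != 4L)
    stop("country_coefficients must be an n_countries x 4 matrix ",
         "(b0, b_ppt, b_tmax, b_soil)")
  colnames(country_coefficients) <- c("b0", "b_ppt", "b_tmax", "b_soil")

  structure(list(
    seed = as.integer(seed),
    n_countries = n_countries,
    regions_per_country = regions_per_country,
    grid_step = grid_step,
    lat_bounds = as.numeric(lat_bounds),
    lon_bounds = as.numeric(lon_bounds),
    year_span = year_span,
    base_rate = base_rate,
    country_coefficients = country_coefficients,
    events_per_attack = as.integer(events_per_attack),
    noise_sd = noise_sd
  ), class = "sim_config")
}

# Derive a per-stage sub-seed from the master seed so atlas/climate/event
# randomness is decoupled; kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  ch <- utf8ToInt(stage)
  h <- sum(ch * seq_along(ch))
  as.integer((abs(as.double(seed)) * 7919 + h) %% 2147483629)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Tile the bounding box into named country/region cells
#'
#' Countries are latitude strips and regions longitude strips within each
#' country, enumerated row-major (all regions of country 1, then country 2,
#' ...). Cells follow the half-open convention `[min, max)` so every interior
#' point belongs to exactly one cell. Names are deterministic: `"C01"`,
#' `"C01-R02"`, ...
#'
#' @param config a [sim_config()].
#' @return A `region_atlas`: a data frame with columns `country`, `region`,
#'   `lat_min`, `lat_max`, `lon_min`, `lon_max`.
#' @export
make_atlas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dlat <- diff(config$lat_bounds) / config$n_countries
  dlon <- diff(config$lon_bounds) / config$regions_per_country
  if (dlat < config$grid_step || dlon < config$grid_step)
    stop("bounding box too small: each region cell must span at least one ",
         "grid_step (", config$grid_step, " deg) in both axes")
  ci <- rep(seq_len(config$n_countries), each = config$regions_per_country)
  ri <- rep(seq_len(config$regions_per_country), times = config$n_countries)
  atlas <- data.frame(
    country = sprintf("C%02d", ci),
    region = sprintf("C%02d-R%02d", ci, ri),
    lat_min = config$lat_bounds[1] + (ci - 1) * dlat,
    lat_max = config$lat_bounds[1] + ci * dlat,
    lon_min = config$lon_bounds[1] + (ri - 1) * dlon,
    lon_max = config$lon_bounds[1] + ri * dlon,
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("region_atlas", "data.frame")
  atlas
}

# All (year, month) pairs of an inclusive year span, in calendar order.
month_seq <- function(span) {
  years <- span[1]:span[2]
  data.frame(year = rep(years, each = 12L), month = rep(1:12, length(years)))
}

#' Deterministic seasonal climate template
#'
#' The noise-free part of [make_climate()]: for each variable, an annual
#' sinusoid peaking in a country-specific month, plus a mild latitudinal
#' gradient, clipped into the observed variable ranges. Grid nodes outside
#' every atlas cell use a default mid-year peak.
#'
#' @inheritParams make_atlas
#' @param atlas a `region_atlas` within the config bounds.
#' @return A `climate_grid` (see [make_climate()]) with zero noise.
#' @export
climate_template <- function(config, atlas) {
  stopifnot(inherits(config, "sim_config"))
  step <- config$grid_step
  n_lat <- floor(diff(config$lat_bounds) / step + 1e-9)
  n_lon <- floor(diff(config$lon_bounds) / step + 1e-9)
  lat <- config$lat_bounds[1] + step * (seq_len(n_lat) - 0.5)
  lon <- config$lon_bounds[1] + step * (seq_len(n_lon) - 0.5)
  tm <- month_seq(config$year_span)
  nt <- nrow(tm)

  nodes <- expand.grid(lat = lat, lon = lon) # lat varies fastest
  geo <- reverse_geocode(atlas, nodes$lat, nodes$lon)
  cidx <- match(geo$country, unique(atlas$country))
  # peak month per country, spread around the calendar; month 7 off-atlas
  peaks <- ifelse(is.na(cidx), 7, 1 + ((cidx - 1) * 5) %% 12)
  latc <- mean(config$lat_bounds)

  grid <- list(lat = lat, lon = lon, time = tm)
  for (v in names(.var_season)) {
    par <- .var_season[[v]]
    seasonal <- par[["amp"]] *
      cospi(2 * outer(tm$month, peaks, "-") / 12) # nt x nodes
    arr <- par[["mid"]] + seasonal +
      rep(par[["grad"]] * (nodes$lat - latc), each = nt)
    rng <- .var_ranges[[v]]
    arr <- pmin(pmax(arr, rng[1]), rng[2])
    dim(arr) <- c(nt, n_lat, n_lon)
    grid[[v]] <- arr
  }
  class(grid) <- "climate_grid"
  grid
}

#' Generate a monthly synthetic climate grid
#'
#' Adds seeded Gaussian noise (per-variable SDs from `config$noise_sd`) to the
#' seasonal [climate_template()] and clips each variable back into its
#' observed range, so `ppt` and `soil` stay non-negative and `tmax` stays
#' within its recorded extremes.
#'
#' @inheritParams climate_template
#' @return A `climate_grid`: list with strictly increasing `lat`/`lon` degree
#'   axes, a gap-free `time` data frame (`year`, `month`), and `(time, lat,
#'   lon)` arrays `ppt` (mm), `tmax` (deg C), `soil` (volumetric water
#'   content).
#' @export
make_climate <- function(config, atlas) {
  grid <- climate_template(config, atlas)
  if (any(atlas$lat_min < config$lat_bounds[1] - 1e-9) ||
      any(atlas$lat_max > config$lat_bounds[2] + 1e-9) ||
      any(atlas$lon_min < config$lon_bounds[1] - 1e-9) ||
      any(atlas$lon_max > config$lon_bounds[2] + 1e-9))
    stop("atlas extends outside the configured bounds")
  with_seed(stage_seed(config$seed, "climate"), {
    for (v in names(.var_ranges)) {
      sd_v <- config$noise_sd[[v]]
      if (sd_v > 0) {
        arr <- grid[[v]] + stats::rnorm(length(grid[[v]]), sd = sd_v)
        rng <- .var_ranges[[v]]
        grid[[v]] <- array(pmin(pmax(arr, rng[1]), rng[2]), dim(grid[[v]]))
      }
    }
  })
  validate_climate(grid)
}

#' Simulate swarm sighting events with planted climate signal
#'
#' For every (region, year, month) an attack indicator is drawn with
#' probability `plogis(b0 + b . z)`, where `z` are the three climate
#' covariates at the region centroid, standardized per variable over the whole
#' grid, and the coefficient row is the region's country's. Each attacked
#' region-month emits `events_per_attack` sighting records at uniform random
#' points strictly inside the region cell. Fully reproducible from
#' `config$seed`.
#'
#' @inheritParams climate_template
#' @param grid a `climate_grid` covering the atlas and year span.
#' @return Event data frame with columns `lat`, `lon`, `start_year`,
#'   `start_month`, carrying attributes `n_attacks` and `n_region_months`.
#' @export
simulate_events <- function(config, atlas, grid) {
  stopifnot(inherits(config, "sim_config"), inherits(grid, "climate_grid"))
  tm <- grid$time
  need <- month_seq(config$year_span)
  if (!all(paste(need$year, need$month) %in% paste(tm$year, tm$month)))
    stop("climate grid does not cover the configured year span")
  keep <- paste(tm$year, tm$month) %in% paste(need$year, need$month)

  zstat <- lapply(grid[c("ppt", "tmax", "soil")], function(a) {
    s <- stats::sd(a)
    c(mean = mean(a), sd = if (s > 0) s else 1)
  })
  countries <- unique(atlas$country)

  events <- vector("list", nrow(atlas))
  n_attacks <- 0L
  with_seed(stage_seed(config$seed, "events"), {
    for (i in seq_len(nrow(atlas))) {
      cell <- atlas[i, ]
      beta <- config$country_coefficients[match(cell$country, countries), ]
      clat <- (cell$lat_min + cell$lat_max) / 2
      clon <- (cell$lon_min + cell$lon_max) / 2
      ilat <- which.min(abs(grid$lat - clat))
      ilon <- which.min(abs(grid$lon - clon))
      z <- vapply(c("ppt", "tmax", "soil"), function(v) {
        (grid[[v]][keep, ilat, ilon] - zstat[[v]][["mean"]]) /
          zstat[[v]][["sd"]]
      }, numeric(sum(keep)))
      p <- stats::plogis(beta[["b0"]] + z %*% beta[c("b_ppt", "b_tmax", "b_soil")])
      hit <- stats::runif(length(p)) < p
      n_attacks <- n_attacks + sum(hit)
      if (any(hit)) {
        ne <- sum(hit) * config$events_per_attack
        hit_tm <- need[hit, , drop = FALSE]
        events[[i]] <- data.frame(
          lat = stats::runif(ne, cell$lat_min, cell$lat_max),
          lon = stats::runif(ne, cell$lon_min, cell$lon_max),
          start_year = rep(hit_tm$year, each = config$events_per_attack),
          start_month = rep(hit_tm$month, each = config$events_per_attack)
        )
      }
    }
  })
  out <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(lat = numeric(), lon = numeric(),
                      start_year = integer(), start_month = integer())
  rownames(out) <- NULL
  attr(out, "n_attacks") <- n_attacks
  attr(out, "n_region_months") <- nrow(atlas) * nrow(need)
  out
}

#' One-call synthetic study system
#'
#' Convenience wrapper returning the atlas, climate grid and event table for a
#' configuration.
#'
#' @inheritParams make_atlas
#' @return `list(atlas, climate, events)`.
#' @export
simulate_glad <- function(config = sim_config()) {
  atlas <- make_atlas(config)
  climate <- make_climate(config, atlas)
  events <- simulate_events(config, atlas, climate)
  list(atlas = atlas, climate = climate, events = events)
}
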