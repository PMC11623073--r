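# Operational-emissions accounting for the compute phases:
# emissions (gCO2eq) = energy (kWh) x regional carbon intensity (gCO2eq/kWh).
# The power model mirrors a hosted-notebook CPU environment: constant CPU
# wattage plus RAM wattage proportional to installed gigabytes.

#' Constant power model for energy accounting
#'
#' Defaults describe the hosted CPU runtime the method was profiled on:
#' 42.5 W total CPU power and 12.678 GB RAM. RAM draws
#' `ram_watts_per_gb` per gigabyte (default 3 W per 8 GB, the convention of
#' common code-emissions trackers). `sample_interval_s` is the metering
#' interval; with a constant power model the integrated energy reduces to
#' duration x power, but the interval is kept for API compatibility with
#' variable-power metering.
#'
#' @param cpu_watts total CPU power draw, W.
#' @param ram_gigabytes installed RAM, GB.
#' @param ram_watts_per_gb RAM power per GB, W.
#' @param sample_interval_s metering interval, seconds.
#' @return Object of class `power_model`.
#' @export
power_model <- function(cpu_watts = 42.5, ram_gigabytes = 12.678,
                        ram_watts_per_gb = 3 / 8, sample_interval_s = 15) {
  vals <- c(cpu_watts, ram_gigabytes, ram_watts_per_gb, sample_interval_s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all power model parameters must be positive")
  structure(list(cpu_watts = cpu_watts, ram_gigabytes = ram_gigabytes,
                 ram_watts_per_gb = ram_watts_per_gb,
                 sample_interval_s = sample_interval_s),
            class = "power_model")
}

#' Energy drawn by a phase
#'
#' Integrates constant CPU and RAM power over the duration, sampled at the
#' model's metering interval (any trailing partial interval is included
#' exactly): `cpu_kwh = cpu_watts * duration / 3.6e6` and `ram_kwh =
#' ram_gigabytes * ram_watts_per_gb * duration / 3.6e6`.
#'
#' @param duration_s phase duration, seconds, `>= 0`.
#' @param power a [power_model()].
#' @return Named numeric vector `c(ram_kwh, cpu_kwh)`.
#' @export
estimate_energy <- function(duration_s, power = power_model()) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L ||
      !is.finite(duration_s) || duration_s < 0)
    stop("duration must be a single non-negative number")
  c(ram_kwh = power$ram_gigabytes * power$ram_watts_per_gb * duration_s / 3.6e6,
    cpu_kwh = power$cpu_watts * duration_s / 3.6e6)
}

#' Emissions of an energy amount
#'
#' The exact product of energy and regional carbon intensity.
#'
#' @param energy_kwh energy, kWh, `>= 0`.
#' @param intensity_g_per_kwh regional carbon intensity, gCO2eq/kWh, `>= 0`.
#' @return Emissions in gCO2eq.
#' @export
estimate_emissions <- function(energy_kwh, intensity_g_per_kwh) {
  if (any(energy_kwh < 0) || any(intensity_g_per_kwh < 0))
    stop("energy and intensity must be non-negative")
  energy_kwh * intensity_g_per_kwh
}

#' Regional carbon intensity lookup
#'
#' Reads the small bundled region-to-intensity table (representative
#' grid-mix values in gCO2eq/kWh; no network lookups). Supply `table` to
#' override with your own CSV (`region`, `g_co2_per_kwh`).
#'
#' @param region region code, e.g. `"US"`.
#' @param table optional path to a replacement intensity CSV.
#' @return Intensity in gCO2eq/kWh.
#' @export
carbon_intensity <- function(region = "US", table = NULL) {
  path <- if (is.null(table))
    system.file("extdata", "carbon_intensity.csv", package = "locustlens",
                mustWork = TRUE) else table
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  i <- match(region, tab$region)
  if (is.na(i)) stop("unknown region '", region, "'; available: ",
                     paste(tab$region, collapse = ", "))
  tab$g_co2_per_kwh[i]
}

#' Per-phase energy/carbon ledger
#'
#' One row per phase with its RAM energy, CPU energy and emissions
#' (`(ram_kwh + cpu_kwh) * intensity`, exactly), plus totals.
#'
#' @param phases named numeric vector of durations (seconds), or a data
#'   frame with columns `name`, `duration_s`.
#' @param power a [power_model()].
#' @param intensity carbon intensity in gCO2eq/kWh (see
#'   [carbon_intensity()]).
#' @param region optional region tag recorded on the ledger; when given and
#'   `intensity` is missing, the bundled table supplies it.
#' @return Object of class `carbon_ledger`: the per-phase data frame with
#'   `intensity`, `region` and `total` attributes.
#' @export
carbon_ledger <- function(phases, power = power_model(),
                          intensity = carbon_intensity(region),
                          region = "US") {
  if (!is.data.frame(phases)) {
    if (is.null(names(phases))) stop("phase durations must be named")
    phases <- data.frame(name = names(phases), duration_s = as.numeric(phases),
                         stringsAsFactors = FALSE)
  }
  if (nrow(phases) == 0L) stop("ledger requires at least one phase")
  if (any(phases$duration_s < 0)) stop("durations must be non-negative")
  en <- t(vapply(phases$duration_s, estimate_energy, numeric(2),
                 power = power))
  led <- data.frame(
    phase = phases$name,
    duration_s = phases$duration_s,
    ram_kwh = en[, "ram_kwh"],
    cpu_kwh = en[, "cpu_kwh"],
    emissions_g = estimate_emissions(en[, "ram_kwh"] + en[, "cpu_kwh"],
                                     intensity),
    stringsAsFactors = FALSE
  )
  structure(led, class = c("carbon_ledger", "data.frame"),
            intensity = intensity, region = region,
            total = c(ram_kwh = sum(led$ram_kwh), cpu_kwh = sum(led$cpu_kwh),
                      emissions_g = sum(led$emissions_g)))
}

#' @export
print.carbon_ledger <- function(x, ...) {
  cat(sprintf("Carbon ledger (region %s, %.2f gCO2eq/kWh)\n",
              attr(x, "region"), attr(x, "intensity")))
  print.data.frame(x, row.names = FALSE)
  tot <- attr(x, "total")
  cat(sprintf("total: %.6g kWh RAM, %.6g kWh CPU, %.4g gCO2eq\n",
              tot[["ram_kwh"]], tot[["cpu_kwh"]], tot[["emissions_g"]]))
  invisible(x)
}

#' Read/write a carbon ledger as JSON
#'
#' @param ledger a [carbon_ledger()].
#' @param path JSON path.
#' @return `write_carbon_ledger` returns the path; `read_carbon_ledger` the
#'   reconstructed ledger.
#' @export
write_carbon_ledger <- function(ledger, path, power = power_model()) {
  jsonlite::write_json(list(
    region = attr(ledger, "region"),
    intensity = attr(ledger, "intensity"),
    power = unclass(power),
    phases = as.data.frame(ledger)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_carbon_ledger
#' @export
read_carbon_ledger <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  phases <- stats::setNames(obj$phases[, c("phase", "duration_s")],
                            c("name", "duration_s"))
  carbon_ledger(phases, power = do.call(power_model, obj$power),
                intensity = obj$intensity, region = obj$region)
}
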