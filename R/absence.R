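# Pseudo-absence generation: the negative class is the calendar complement of
# reported attacks. For every region of every country with at least one
# recorded attack, each study-span month with no attack on record becomes one
# "no" row, with climate attached at the region-cell centroid.

#' Attacked region-months of a positive table
#'
#' @param positives labelled rows, all `"yes"`.
#' @return An `attack_calendar`: data frame `country`, `region`, `year`,
#'   `month`, one row per distinct attacked region-month, in canonical
#'   (country, region, year, month) order so downstream output is invariant
#'   to positive-row ordering.
#' @export
attack_calendar <- function(positives) {
  if (is.null(positives) || nrow(positives) == 0L)
    stop("attack_calendar requires a non-empty positive table")
  if (!all(positives$locust_present == "yes"))
    stop("attack_calendar input must contain only positive ('yes') rows")
  cal <- unique(data.frame(
    country = positives$country, region = positives$region,
    year = as.integer(positives$start_year),
    month = as.integer(positives$start_month),
    stringsAsFactors = FALSE
  ))
  if (any(cal$month < 1L | cal$month > 12L))
    stop("calendar months must lie in 1..12")
  cal <- cal[order(cal$country, cal$region, cal$year, cal$month), ,
             drop = FALSE]
  rownames(cal) <- NULL
  class(cal) <- c("attack_calendar", "data.frame")
  cal
}

#' Generate the negative (pseudo-absence) class
#'
#' For each region in the universe (by default, every atlas region of each
#' country appearing in the calendar — known regions count even if never
#' attacked), and for each (year, month) of `span` not in that region's
#' attack set, emits one `"no"` row with covariates sampled at the region-cell
#' centroid. Per region, negatives + distinct attacked months always equal
#' the number of span months.
#'
#' @param calendar an [attack_calendar()].
#' @param atlas a `region_atlas` containing every calendar region.
#' @param grid a `climate_grid` covering `span`.
#' @param span inclusive `c(first, last)` years; defaults to the grid's.
#' @param universe `"country"` (all regions of attacked countries) or
#'   `"attacked"` (only regions with at least one historical attack).
#' @return Labelled data frame of `"no"` rows with a `provenance` attribute.
#' @export
generate_negatives <- function(calendar, atlas, grid,
                               span = range(grid$time$year),
                               universe = c("country", "attacked")) {
  universe <- match.arg(universe)
  stopifnot(inherits(grid, "climate_grid"))
  missing_r <- setdiff(calendar$region, atlas$region)
  if (length(missing_r))
    stop("calendar region(s) missing from atlas: ",
         paste(missing_r, collapse = ", "))
  months <- month_seq(as.integer(span))
  if (anyNA(.time_index(grid, months$year, months$month)))
    stop("span extends outside the climate grid's time axis")

  cells <- if (universe == "country") {
    atlas[atlas$country %in% unique(calendar$country), , drop = FALSE]
  } else {
    atlas[atlas$region %in% unique(calendar$region), , drop = FALSE]
  }
  cal_key <- paste(calendar$region, calendar$year, calendar$month)

  out <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    free <- !(paste(cell$region, months$year, months$month) %in% cal_key)
    if (!any(free)) return(NULL)
    mm <- months[free, , drop = FALSE]
    clim <- sample_climate(grid,
                           rep((cell$lat_min + cell$lat_max) / 2, nrow(mm)),
                           rep((cell$lon_min + cell$lon_max) / 2, nrow(mm)),
                           mm$year, mm$month)
    data.frame(
      start_month = mm$month, start_year = mm$year,
      country = cell$country, region = cell$region,
      soil_moisture = clim$soil_moisture,
      precipitation = clim$precipitation,
      max_temperature = clim$max_temperature,
      locust_present = "no",
      stringsAsFactors = FALSE
    )
  })
  negs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(negs))
    negs <- utils::read.csv(text = paste(.glad_cols, collapse = ","))
  rownames(negs) <- NULL
  attr(negs, "provenance") <- list(rows_read = 0L, rows_dropped = 0L,
                                   positives = 0L, negatives = nrow(negs))
  negs
}

#' Assemble the final labelled dataset
#'
#' Concatenates the positive and negative tables, checks that no region-month
#' carries both labels, and records provenance counters and per-country class
#' counts.
#'
#' @param positives,negatives labelled tables from [build_positive_rows()]
#'   and [generate_negatives()].
#' @param quiet suppress the per-country class-count message.
#' @return The combined table with `provenance` and `class_counts`
#'   attributes.
#' @export
assemble_dataset <- function(positives, negatives, quiet = FALSE) {
  if (is.null(negatives) || nrow(negatives) == 0L)
    stop("negative class is empty: the classifier needs both labels")
  if (is.null(positives) || nrow(positives) == 0L)
    stop("positive class is empty")
  key <- function(d) paste(d$country, d$region, d$start_year, d$start_month)
  clash <- intersect(unique(key(positives)), unique(key(negatives)))
  if (length(clash))
    stop("label collision: region-month(s) labelled both yes and no: ",
         paste(utils::head(clash, 3L), collapse = "; "))
  out <- rbind(positives[, .glad_cols], negatives[, .glad_cols])
  rownames(out) <- NULL
  prov_p <- attr(positives, "provenance")
  attr(out, "provenance") <- list(
    rows_read = if (is.null(prov_p)) nrow(positives) else prov_p$rows_read,
    rows_dropped = if (is.null(prov_p)) 0L else prov_p$rows_dropped,
    positives = nrow(positives), negatives = nrow(negatives)
  )
  counts <- table(out$country, out$locust_present)
  attr(out, "class_counts") <- counts
  if (!quiet)
    message("assembled dataset: ", nrow(positives), " positive / ",
            nrow(negatives), " negative rows across ",
            nrow(counts), " countries")
  out
}
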