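# Shared fixtures and independent oracles, all built in code at test time.

# Default test-scale study system: 3 countries x 2 regions, 4 years.
test_config <- function(seed = 42L, n_countries = 3L, ...) {
  sim_config(seed = seed, n_countries = n_countries,
             year_span = c(1990L, 1993L), ...)
}

make_test_glad <- function(config = test_config()) {
  sim <- simulate_glad(config)
  pos <- build_positive_rows(sim$events, sim$climate, sim$atlas)
  neg <- generate_negatives(attack_calendar(pos), sim$atlas, sim$climate,
                            span = config$year_span)
  assemble_dataset(pos, neg, quiet = TRUE)
}

# Small handmade climate grid with distinct, position-coded values so any
# sampling mistake is visible: value = 1000*t + 10*ilat + ilon (+ offset).
grid_fixture <- function(nlat = 5L, nlon = 5L, years = 1990L,
                         lat0 = 0.5, lon0 = 0.5, step = 1) {
  tm <- do.call(rbind, lapply(years, function(y)
    data.frame(year = y, month = 1:12)))
  nt <- nrow(tm)
  base <- outer(seq_len(nt) * 1000, outer(10 * seq_len(nlat),
                                          seq_len(nlon), "+"), "+")
  dim(base) <- c(nt, nlat, nlon)
  validate_climate(list(
    lat = lat0 + step * (seq_len(nlat) - 1),
    lon = lon0 + step * (seq_len(nlon) - 1),
    time = tm, ppt = base, tmax = base / 1000, soil = base + 0.5
  ))
}

# Atlas of one country with n rectangular regions side by side (1 deg wide).
atlas_fixture <- function(n_regions = 6L, country = "C01") {
  a <- data.frame(
    country = country,
    region = sprintf("%s-R%02d", country, seq_len(n_regions)),
    lat_min = 0, lat_max = 5,
    lon_min = seq_len(n_regions) - 1, lon_max = seq_len(n_regions),
    stringsAsFactors = FALSE
  )
  class(a) <- c("region_atlas", "data.frame")
  a
}

# Positive rows written out directly (schema order), label "yes".
positive_rows <- function(region, country, year, month) {
  data.frame(start_month = month, start_year = year, country = country,
             region = region, soil_moisture = 1, precipitation = 2,
             max_temperature = 3, locust_present = "yes",
             stringsAsFactors = FALSE)
}

# --- Independent brute-force K-NN oracle -----------------------------------
# Deliberately naive: explicit loops, its own scaling and vote logic, sharing
# only the documented contracts (z-score with unit spread for constants,
# neighbour ties to the smaller index, class ties to the nearest neighbour,
# zero-distance dominance in distance mode).
brute_scale <- function(xtr) {
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, sd)
  sdv[is.na(sdv) | sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

brute_nn <- function(xtr, q, k, p = 1) {
  sc <- brute_scale(xtr)
  d <- numeric(nrow(xtr))
  for (i in seq_len(nrow(xtr))) {
    s <- 0
    for (j in seq_len(ncol(xtr)))
      s <- s + abs((q[j] - sc$mu[j]) / sc$sd[j] -
                     (xtr[i, j] - sc$mu[j]) / sc$sd[j])^p
    d[i] <- s^(1 / p)
  }
  ord <- order(d, seq_along(d))
  list(index = ord[seq_len(k)], distance = d[ord[seq_len(k)]])
}

brute_predict <- function(xtr, ytr, q, k, weights = "uniform", p = 1) {
  nn <- brute_nn(xtr, q, k, p)
  labs <- ytr[nn$index]
  ds <- nn$distance
  if (weights == "uniform") {
    score <- sum(labs == 1) / length(labs)
  } else if (any(ds == 0)) {
    score <- sum(labs[ds == 0] == 1) / sum(ds == 0)
  } else {
    score <- sum((1 / ds)[labs == 1]) / sum(1 / ds)
  }
  label <- if (score > 0.5) 1L else if (score < 0.5) 0L else labs[1]
  list(label = label, score = score)
}

# Random raw feature matrices for oracle comparisons.
random_train <- function(n, d = 5L) {
  matrix(rnorm(n * d, sd = rep(c(1, 5, 10, 0.1, 2), length.out = d)),
         n, d)
}
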