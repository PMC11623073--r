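# From-scratch K-nearest-neighbour classifier: weighted Minkowski distances
# (Manhattan by default), a majority / inverse-distance vote, z-score
# feature scaling frozen at fit time, and fully deterministic tie handling.

.feature_cols <- c("start_year", "start_month", "precipitation",
                   "max_temperature", "soil_moisture")

#' Encode labelled rows as a numeric feature matrix
#'
#' Feature order is fixed: start year, start month, precipitation, maximum
#' temperature, soil moisture. Labels map `"yes"` to 1 and `"no"` to 0.
#'
#' @param rows labelled data frame in the fused-table schema.
#' @return `list(x, y, feature_names)` with `x` an `n x 5` matrix and `y` an
#'   integer 0/1 vector.
#' @export
encode_features <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0L) stop("cannot encode an empty table")
  miss <- setdiff(c(.feature_cols, "locust_present"), names(rows))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(rows$start_month < 1 | rows$start_month > 12))
    stop("start_month must lie in 1..12")
  bad <- setdiff(unique(as.character(rows$locust_present)), c("yes", "no"))
  if (length(bad))
    stop("unknown label value(s): ", paste(bad, collapse = ", "))
  x <- as.matrix(rows[, .feature_cols])
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("features must be finite")
  list(x = x, y = as.integer(rows$locust_present == "yes"),
       feature_names = .feature_cols)
}

#' Weighted Minkowski distance between two feature vectors
#'
#' `minkowski_distance` computes `(sum_r w_r |x_r - z_r|^p)^(1/p)`;
#' `manhattan_distance` is the `p = 1` case, `sum_r w_r |x_r - z_r|`, the
#' classifier's default metric (all weights 1).
#'
#' @param x,z equal-length numeric vectors.
#' @param w non-negative feature weights, recycled scalar or length-d.
#' @param p Minkowski order, `>= 1`.
#' @return Non-negative scalar.
#' @export
minkowski_distance <- function(x, z, w = 1, p = 1) {
  if (length(x) != length(z)) stop("dimension mismatch between x and z")
  if (length(w) == 1L) w <- rep(w, length(x))
  if (length(w) != length(x)) stop("feature weights must match dimension")
  if (p < 1) stop("Minkowski order p must be >= 1")
  sum(w * abs(x - z)^p)^(1 / p)
}

#' @rdname minkowski_distance
#' @export
manhattan_distance <- function(x, z, w = 1) minkowski_distance(x, z, w, p = 1)

# Distances from one scaled query to all scaled training rows, vectorized.
.dists_to_train <- function(xs, q, w, p) {
  d <- abs(xs - rep(q, each = nrow(xs)))^p %*% w
  as.vector(d)^(1 / p)
}

.metric_p <- function(metric, p) {
  switch(metric,
         manhattan = 1,
         euclidean = 2,
         minkowski = {
           if (is.null(p)) stop("metric 'minkowski' requires p")
           if (p < 1) stop("Minkowski order p must be >= 1")
           p
         })
}

#' Fit the K-nearest-neighbour classifier
#'
#' A lazy learner: fitting freezes the standardized training matrix (z-score
#' using the fitted rows' statistics only; constant features get unit spread
#' so no division by zero occurs), the 0/1 labels and the hyperparameters.
#' All computation happens at query time.
#'
#' @param x labelled data frame in the fused-table schema, or a numeric
#'   feature matrix (then `y` is required).
#' @param y integer/logical 0-1 labels when `x` is a matrix.
#' @param k neighbours consulted per prediction (default 7, the tuned
#'   value).
#' @param weights `"uniform"` (majority vote, the tuned value) or
#'   `"distance"` (inverse-distance vote).
#' @param metric `"manhattan"` (tuned value), `"euclidean"` or
#'   `"minkowski"` (with order `p`).
#' @param p Minkowski order when `metric = "minkowski"`.
#' @param feature_weights non-negative per-feature weights in Eq. form
#'   `sum w_r |x_r - z_r|`; default all 1.
#' @param scaling optional `list(centre, spread)` overriding the fit-set
#'   statistics (used to reproduce pre-split scaling).
#' @return Object of class `glad_knn`.
#' @seealso [predict.glad_knn()], [nearest_neighbours()], [knn_vote()]
#' @export
glad_knn <- function(x, y = NULL, k = 7L,
                     weights = c("uniform", "distance"),
                     metric = c("manhattan", "euclidean", "minkowski"),
                     p = NULL, feature_weights = NULL, scaling = NULL) {
  weights <- match.arg(weights)
  metric <- match.arg(metric)
  if (is.data.frame(x)) {
    enc <- encode_features(x)
    x <- enc$x
    y <- enc$y
  } else {
    x <- as.matrix(x)
    if (is.null(y)) stop("y is required when x is a matrix")
    y <- as.integer(y)
  }
  if (nrow(x) < 1L) stop("cannot fit on an empty sample")
  if (length(y) != nrow(x)) stop("label length must match rows of x")
  if (!all(y %in% 0:1)) stop("labels must be binary 0/1")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  d <- ncol(x)
  if (is.null(feature_weights)) feature_weights <- rep(1, d)
  if (length(feature_weights) != d || any(feature_weights < 0))
    stop("feature_weights must be ", d, " non-negative values")
  pp <- .metric_p(metric, p)

  if (is.null(scaling)) {
    centre <- colMeans(x)
    spread <- apply(x, 2, stats::sd)
    spread[!is.finite(spread) | spread == 0] <- 1
  } else {
    centre <- scaling$centre
    spread <- scaling$spread
  }
  xs <- sweep(sweep(x, 2, centre), 2, spread, "/")

  structure(list(
    xs = xs, y = y, centre = centre, spread = spread,
    config = list(k = k, weights = weights, metric = metric, p = pp,
                  feature_weights = feature_weights),
    feature_names = colnames(x)
  ), class = "glad_knn")
}

#' @export
print.glad_knn <- function(x, ...) {
  cat("K-nearest-neighbour classifier (lazy learner)\n")
  cat(sprintf("  n = %d training samples, d = %d features\n",
              nrow(x$xs), ncol(x$xs)))
  cat(sprintf("  k = %d, weights = %s, metric = %s (p = %g)\n",
              x$config$k, x$config$weights, x$config$metric, x$config$p))
  cat(sprintf("  class balance: %d positive / %d negative\n",
              sum(x$y == 1L), sum(x$y == 0L)))
  invisible(x)
}

#' The k nearest training samples to a query
#'
#' Distances use the model's metric on the standardized scale; the query is
#' standardized with the frozen fit statistics. Exact distance ties break
#' toward the smaller training index.
#'
#' @param model a fitted [glad_knn()].
#' @param x one query: numeric feature vector on the raw scale.
#' @param k how many neighbours; must not exceed the training size.
#' @return Data frame `index`, `distance`, ascending by distance.
#' @export
nearest_neighbours <- function(model, x, k = model$config$k) {
  stopifnot(inherits(model, "glad_knn"))
  n <- nrow(model$xs)
  if (k > n) stop("k = ", k, " exceeds the ", n, " training samples")
  q <- (as.numeric(x) - model$centre) / model$spread
  if (length(q) != ncol(model$xs)) stop("query dimension mismatch")
  dist <- .dists_to_train(model$xs, q, model$config$feature_weights,
                          model$config$p)
  ord <- order(dist, seq_along(dist))[seq_len(k)]
  data.frame(index = ord, distance = dist[ord])
}

#' Neighbour vote
#'
#' Uniform mode assigns the class occurring most frequently among the
#' neighbours, with the positive score the fraction of positive neighbours;
#' a tied vote goes to the class of the single nearest neighbour. Distance
#' mode weights each neighbour by `1/d`; if any neighbour sits at distance
#' exactly 0 the vote is restricted to those (they dominate), avoiding
#' division by zero.
#'
#' @param labels 0/1 neighbour labels, in ascending-distance order.
#' @param distances matching non-negative distances.
#' @param weights `"uniform"` or `"distance"`.
#' @return `list(label, score)` with `label` in 0/1 and `score` the
#'   (weighted) positive fraction in `[0, 1]`.
#' @export
knn_vote <- function(labels, distances = NULL,
                     weights = c("uniform", "distance")) {
  weights <- match.arg(weights)
  if (length(labels) < 1L) stop("vote requires at least one neighbour")
  if (weights == "uniform") {
    score <- mean(labels == 1L)
  } else {
    if (is.null(distances) || length(distances) != length(labels))
      stop("distance weighting requires matching distances")
    zero <- distances == 0
    if (any(zero)) {
      score <- mean(labels[zero] == 1L)
    } else {
      w <- 1 / distances
      score <- sum(w[labels == 1L]) / sum(w)
    }
  }
  label <- if (score > 0.5) 1L else if (score < 0.5) 0L else labels[1L]
  list(label = label, score = score)
}

#' Predict from a fitted K-NN
#'
#' Composes scaling, neighbour search (`k` capped at the training size) and
#' the vote, per query row.
#'
#' @param object a fitted [glad_knn()].
#' @param newdata labelled data frame (schema columns) or numeric feature
#'   matrix / vector on the raw scale.
#' @param type `"record"` for a data frame of labels and positive scores,
#'   `"class"` for `"yes"`/`"no"`, `"score"` for the numeric score.
#' @param ... unused.
#' @return Per `type`; labels are `"yes"`/`"no"` characters.
#' @export
predict.glad_knn <- function(object, newdata,
                             type = c("record", "class", "score"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    nd <- newdata
    nd$locust_present <- "yes" # placeholder; labels unused for encoding x
    newdata <- encode_features(nd)$x
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  k <- min(object$config$k, nrow(object$xs))
  res <- vapply(seq_len(nrow(newdata)), function(i) {
    nn <- nearest_neighbours(object, newdata[i, ], k)
    v <- knn_vote(object$y[nn$index], nn$distance, object$config$weights)
    c(v$label, v$score)
  }, numeric(2))
  label <- c("no", "yes")[res[1, ] + 1L]
  score <- res[2, ]
  switch(type,
         record = data.frame(pred = label, score = score,
                             stringsAsFactors = FALSE),
         class = label,
         score = score)
}
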