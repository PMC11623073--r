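# The country-partitioned classifier: for each test sample, a K-NN is fitted
# on the training rows of that sample's country only (cached per country),
# which lets countries with opposite climate-attack relationships coexist.
# scope = "global" gives the single-fit baseline on the identical surface.

#' Stratified k-fold assignment
#'
#' Assigns each row to one of `n_splits` folds so that per-fold class
#' proportions stay within one sample of the global ratio (per-class
#' round-robin after an optional seeded shuffle).
#'
#' @param labels class labels, one per row.
#' @param n_splits number of folds (default 5).
#' @param shuffle shuffle within class before assignment.
#' @param seed integer seed for the shuffle.
#' @return Integer fold id per row, in `1..n_splits`.
#' @export
stratified_folds <- function(labels, n_splits = 5L, shuffle = TRUE,
                             seed = 1L) {
  n_splits <- as.integer(n_splits)
  if (n_splits < 2L) stop("n_splits must be >= 2")
  counts <- table(labels)
  if (any(counts < n_splits))
    stop("stratification error: class '",
         names(counts)[which.min(counts)], "' has fewer than ", n_splits,
         " members")
  fold <- integer(length(labels))
  with_seed(stage_seed(seed, "folds"), {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      if (shuffle) idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(n_splits), length(idx))
    }
  })
  fold
}

.knn_args <- function(k, weights, metric, p, feature_weights) {
  list(k = k, weights = weights, metric = metric, p = p,
       feature_weights = feature_weights)
}

#' Fit the country-partitioned locust-presence classifier
#'
#' The fitting function of the package. Training rows are grouped by
#' country and one K-NN ([glad_knn()]) is fitted per country (plus one global
#' model used both as the `scope = "global"` baseline and as the fallback for
#' test countries unseen in training). `k` is capped at each subset's size;
#' a single-class subset simply predicts that class with score 0/1.
#'
#' @param data labelled data frame in the fused-table schema, containing both
#'   classes.
#' @param k,weights,metric,p,feature_weights passed to [glad_knn()]; defaults
#'   are the tuned configuration (k = 7, uniform, Manhattan).
#' @param scope `"country"` (the partitioned model) or `"global"` (one fit on
#'   all rows — the baseline).
#' @param scaling optional pre-computed `list(centre, spread)` applied to all
#'   subsets, reproducing pre-split ("leaky") scaling; default scales within
#'   each fitted subset.
#' @return Object of class `locustlens` with `predict`, `print` and
#'   `summary` methods.
#' @examples
#' sim <- simulate_glad(sim_config(seed = 7, year_span = c(2001, 2002)))
#' glad <- assemble_dataset(
#'   pos <- build_positive_rows(sim$events, sim$climate, sim$atlas),
#'   generate_negatives(attack_calendar(pos), sim$atlas, sim$climate),
#'   quiet = TRUE)
#' fit <- locustlens(glad)
#' head(predict(fit, glad))
#' @export
locustlens <- function(data, k = 7L, weights = "uniform",
                       metric = "manhattan", p = NULL,
                       feature_weights = NULL,
                       scope = c("country", "global"), scaling = NULL) {
  scope <- match.arg(scope)
  if (length(unique(data$locust_present)) < 2L)
    stop("training data must contain both classes")
  cfg <- .knn_args(k, weights, metric, p, feature_weights)

  fit_one <- function(rows) {
    t0 <- proc.time()[["elapsed"]]
    m <- glad_knn(rows, k = min(cfg$k, nrow(rows)), weights = cfg$weights,
                  metric = cfg$metric, p = cfg$p,
                  feature_weights = cfg$feature_weights, scaling = scaling)
    attr(m, "fit_seconds") <- proc.time()[["elapsed"]] - t0
    m
  }

  global <- fit_one(data)
  models <- list()
  if (scope == "country") {
    for (cn in unique(data$country))
      models[[cn]] <- fit_one(data[data$country == cn, , drop = FALSE])
  }
  structure(list(
    models = models, global = global, scope = scope, config = cfg,
    n_train = nrow(data), countries = unique(data$country),
    class_counts = table(data$country, data$locust_present)
  ), class = "locustlens")
}

#' @export
print.locustlens <- function(x, ...) {
  cat("LocustLens", if (x$scope == "global") "(global baseline)" else
    "country-partitioned", "K-NN classifier\n")
  cat(sprintf("  %d training rows, %d countries\n",
              x$n_train, length(x$countries)))
  cat(sprintf("  k = %d, weights = %s, metric = %s\n",
              x$config$k, x$config$weights, x$config$metric))
  invisible(x)
}

#' @export
summary.locustlens <- function(object, ...) {
  print(object)
  cat("\nPer-country class counts:\n")
  print(object$class_counts)
  invisible(object$class_counts)
}

#' Predict locust presence for new rows
#'
#' Each test row is scored by the K-NN of its own country (scope
#' `"country"`); rows from countries unseen in training fall back to the
#' global model and are flagged. Wall-clock fit and predict durations are
#' carried per record (fit time of the model used; predict time measured per
#' country batch and attributed evenly to its rows).
#'
#' @param object a fitted [locustlens()].
#' @param newdata labelled or unlabelled rows in the fused-table schema.
#' @param fold optional fold id stamped onto the records.
#' @param ... unused.
#' @return One prediction record per input row, input order preserved:
#'   `truth` (NA when unlabelled), `pred`, `score`, `country`, `fit_s`,
#'   `predict_s`, `fallback`, `fold`.
#' @export
predict.locustlens <- function(object, newdata, fold = NA_integer_, ...) {
  stopifnot(inherits(object, "locustlens"))
  n <- nrow(newdata)
  truth <- if ("locust_present" %in% names(newdata))
    as.character(newdata$locust_present) else rep(NA_character_, n)
  pred <- character(n); score <- numeric(n)
  fit_s <- numeric(n); pred_s <- numeric(n); fallback <- logical(n)

  for (cn in unique(newdata$country)) {
    rows <- which(newdata$country == cn)
    model <- if (object$scope == "country") object$models[[cn]] else
      object$global
    fb <- is.null(model)
    if (fb) model <- object$global
    t0 <- proc.time()[["elapsed"]]
    rec <- predict(model, newdata[rows, , drop = FALSE], type = "record")
    dt <- proc.time()[["elapsed"]] - t0
    pred[rows] <- rec$pred
    score[rows] <- rec$score
    fit_s[rows] <- attr(model, "fit_seconds")
    pred_s[rows] <- dt / length(rows)
    fallback[rows] <- fb
  }
  data.frame(truth = truth, pred = pred, score = score,
             country = as.character(newdata$country),
             fit_s = fit_s, predict_s = pred_s,
             fallback = fallback, fold = fold,
             stringsAsFactors = FALSE)
}

#' Stratified cross-validated predictions
#'
#' Splits the dataset into stratified folds, fits on each training portion
#' and predicts the held-out portion, concatenating the prediction records.
#' `scope = "global"` runs the single-fit baseline under identical folds.
#'
#' @inheritParams locustlens
#' @param folds number of stratified CV folds (default 5).
#' @param shuffle,seed fold construction controls.
#' @param scale_before_split if `TRUE`, feature scaling statistics are
#'   computed once on the full dataset before splitting (reproduces a
#'   pre-split scaling pipeline, which leaks test statistics into training);
#'   default scales within each fitted subset only.
#' @return All out-of-fold prediction records (see [predict.locustlens()]).
#' @export
locustlens_cv <- function(data, k = 7L, weights = "uniform",
                          metric = "manhattan", p = NULL,
                          feature_weights = NULL,
                          scope = c("country", "global"),
                          folds = 5L, shuffle = TRUE, seed = 1L,
                          scale_before_split = FALSE) {
  scope <- match.arg(scope)
  fold <- stratified_folds(data$locust_present, folds, shuffle, seed)
  scaling <- NULL
  if (scale_before_split) {
    x <- encode_features(data)$x
    spread <- apply(x, 2, stats::sd)
    spread[!is.finite(spread) | spread == 0] <- 1
    scaling <- list(centre = colMeans(x), spread = spread)
  }
  recs <- lapply(sort(unique(fold)), function(f) {
    fit <- locustlens(data[fold != f, , drop = FALSE], k = k,
                      weights = weights, metric = metric, p = p,
                      feature_weights = feature_weights, scope = scope,
                      scaling = scaling)
    predict(fit, data[fold == f, , drop = FALSE], fold = f)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Randomized hyperparameter search
#'
#' Samples `n_iter` configurations uniformly with replacement from the
#' candidate sets and scores each by mean stratified-CV accuracy of the
#' country-partitioned classifier under a fixed fold seed; ties go to the
#' first configuration reaching the maximum.
#'
#' @param data labelled dataset.
#' @param space named list of candidate sets `k`, `weights`, `metric` (and
#'   optionally `p` for Minkowski entries).
#' @param n_iter configurations to draw (default 10).
#' @param folds,seed CV protocol; `seed` also drives the sampling.
#' @return `list(best, results)`: the best configuration and the scored
#'   table (one row per iteration).
#' @export
random_search <- function(data,
                          space = list(k = c(3L, 5L, 7L, 11L),
                                       weights = c("uniform", "distance"),
                                       metric = c("manhattan", "euclidean")),
                          n_iter = 10L, folds = 5L, seed = 1L) {
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (any(lengths(space[c("k", "weights", "metric")]) == 0))
    stop("candidate sets must be non-empty")
  pick <- function(set) set[sample.int(length(set), n_iter, replace = TRUE)]
  draw <- with_seed(stage_seed(seed, "search"), {
    data.frame(
      k = pick(space$k),
      weights = pick(space$weights),
      metric = pick(space$metric),
      stringsAsFactors = FALSE
    )
  })
  p_mink <- if (is.null(space$p)) 2 else space$p[1]
  acc <- vapply(seq_len(n_iter), function(i) {
    rec <- locustlens_cv(data, k = draw$k[i], weights = draw$weights[i],
                         metric = draw$metric[i],
                         p = if (draw$metric[i] == "minkowski") p_mink,
                         folds = folds, seed = seed)
    mean(rec$pred == rec$truth)
  }, numeric(1))
  results <- cbind(draw, accuracy = acc)
  best <- results[which.max(acc), , drop = FALSE]
  list(best = as.list(best[, c("k", "weights", "metric", "accuracy")]),
       results = results)
}
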