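test_that("confusion counts enumerate and conserve", {
  cc <- confusion_counts(c("yes", "yes", "no", "no"),
                         c("yes", "no", "yes", "no"))
  expect_equal(unclass(cc)[c("TP", "FN", "FP", "TN")],
               list(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
  perfect <- confusion_counts(c("yes", "no"), c("yes", "no"))
  expect_equal(perfect$FP + perfect$FN, 0L)
  set.seed(2)
  t <- sample(c("yes", "no"), 30, replace = TRUE)
  p <- sample(c("yes", "no"), 30, replace = TRUE)
  cc2 <- confusion_counts(t, p)
  expect_equal(cc2$TP + cc2$TN + cc2$FP + cc2$FN, 30L)
  expect_error(confusion_counts(character(0), character(0)), "at least one")
})

test_that("scalar metrics match hand-computed values and conventions", {
  m <- classification_metrics(list(TP = 8, FN = 2, FP = 1, TN = 9))
  expect_equal(m[["accuracy"]], 0.85)
  expect_equal(m[["precision"]], 8 / 9)
  expect_equal(m[["recall"]], 0.8)
  expect_equal(m[["f1"]], 16 / 19)
  expect_equal(m[["f1"]], 0.8421, tolerance = 1e-4)
  # all-negative truth with no positive predictions: zero-denominator rule
  d <- suppressWarnings(classification_metrics(
    list(TP = 0, FN = 0, FP = 0, TN = 10)))
  expect_equal(unname(d), c(1, 0, 0, 0))
  w <- capture_warnings(classification_metrics(
    list(TP = 0, FN = 0, FP = 0, TN = 10)))
  expect_true(all(grepl("zero denominator", w)) && length(w) == 2L)
  expect_error(classification_metrics(list(TP = 0, FN = 0, FP = 0, TN = 0)),
               "empty")
})

test_that("F1 equals the harmonic-mean identity on random counts", {
  set.seed(8)
  for (i in 1:50) {
    cc <- as.list(setNames(rpois(4, 10) + 1, c("TP", "FN", "FP", "TN")))
    m <- classification_metrics(cc)
    P <- cc$TP / (cc$TP + cc$FP)
    R <- cc$TP / (cc$TP + cc$FN)
    expect_equal(m[["f1"]], 2 * P * R / (P + R))
  }
})

test_that("AUC matches exhaustive pairwise enumeration", {
  expect_equal(auc_score(c("yes", "yes", "no", "no"),
                         c(0.9, 0.8, 0.7, 0.4)), 1.0)
  expect_equal(auc_score(c("yes", "yes", "no", "no"),
                         c(0.9, 0.6, 0.6, 0.2)), 0.875) # 3 wins + 1 tie
  expect_equal(auc_score(c("yes", "no", "yes", "no"), rep(0.3, 4)), 0.5)
  expect_error(auc_score(c("yes", "yes"), c(0.1, 0.2)), "undefined")

  # pairwise enumeration oracle on random score lists
  set.seed(31)
  for (i in 1:10) {
    n <- sample(6:40, 1)
    truth <- c("yes", "no", sample(c("yes", "no"), n - 2, replace = TRUE))
    score <- round(runif(n), 2) # rounding forces ties
    pos <- score[truth == "yes"]; neg <- score[truth == "no"]
    wins <- 0
    for (a in pos) for (b in neg)
      wins <- wins + (a > b) + 0.5 * (a == b)
    expect_equal(auc_score(truth, score), wins / (length(pos) * length(neg)))
  }
})

test_that("AUC is invariant under monotone score transforms and calibrated on noise", {
  set.seed(12)
  truth <- sample(c("yes", "no"), 100, replace = TRUE)
  score <- runif(100)
  a0 <- auc_score(truth, score)
  expect_equal(auc_score(truth, exp(3 * score)), a0)
  expect_equal(auc_score(truth, rank(score)), a0)

  set.seed(99)
  big_truth <- sample(c("yes", "no"), 1000, replace = TRUE)
  expect_lt(abs(auc_score(big_truth, runif(1000)) - 0.5), 0.05)

  perfect <- auc_score(rep(c("yes", "no"), each = 20),
                       c(runif(20, 0.6, 1), runif(20, 0, 0.4)))
  expect_equal(perfect, 1)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  truth <- sample(c("yes", "no"), 200, replace = TRUE)
  score <- runif(200) + 0.3 * (truth == "yes")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = score, levels = c("no", "yes"),
    direction = "<", quiet = TRUE)))
  expect_equal(auc_score(truth, score), ref)
})

test_that("per-country reports pool back to the global counts", {
  set.seed(6)
  rec <- data.frame(
    truth = sample(c("yes", "no"), 120, replace = TRUE),
    score = runif(120),
    country = sample(c("C01", "C02", "C03"), 120, replace = TRUE),
    stringsAsFactors = FALSE
  )
  rec$pred <- ifelse(rec$score > 0.5, "yes", "no")
  ev <- suppressWarnings(evaluate_predictions(rec))
  expect_equal(nrow(ev$per_country), 3L)
  expect_equal(sum(ev$per_country$n * ev$per_country$accuracy) / ev$n,
               ev$metrics[["accuracy"]])

  # single-country input: the per-country entry equals the global report
  one <- rec[rec$country == "C01", ]
  ev1 <- suppressWarnings(evaluate_predictions(one))
  mcols <- c("accuracy", "precision", "recall", "f1", "auc")
  expect_equal(as.numeric(ev1$per_country[1, mcols]),
               unname(ev1$metrics[mcols]))

  # a country with one truth class gets an undefined (NA) AUC, not 0
  rec2 <- rec
  rec2$truth[rec2$country == "C02"] <- "yes"
  ev2 <- suppressWarnings(evaluate_predictions(rec2))
  expect_true(is.na(ev2$per_country$auc[ev2$per_country$country == "C02"]))

  # macro averaging class-averages the asymmetric metrics
  evm <- suppressWarnings(evaluate_predictions(rec, average = "macro"))
  cc <- ev$counts
  rec_yes <- cc$TP / (cc$TP + cc$FN)
  rec_no <- cc$TN / (cc$TN + cc$FP)
  expect_equal(evm$metrics[["recall"]], (rec_yes + rec_no) / 2)
  expect_equal(evm$metrics[["accuracy"]], ev$metrics[["accuracy"]])
})
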