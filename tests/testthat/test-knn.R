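test_that("distance formulas match hand arithmetic", {
  expect_equal(manhattan_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(manhattan_distance(c(1, 2), c(4, 6)), 7)
  expect_equal(manhattan_distance(c(1, 2), c(4, 6), w = c(2, 1)), 10)
  expect_equal(minkowski_distance(c(0, 0), c(3, 4), p = 2), 5)
  expect_error(manhattan_distance(1:2, 1:3), "dimension")
  expect_error(minkowski_distance(1:2, 2:3, p = 0.5), ">= 1")
})

test_that("manhattan distance is a metric on sampled triples", {
  set.seed(3)
  for (i in 1:50) {
    x <- rnorm(5); y <- rnorm(5); z <- rnorm(5)
    dxy <- manhattan_distance(x, y)
    expect_gte(dxy, 0)
    expect_equal(dxy, manhattan_distance(y, x))
    expect_lte(dxy, manhattan_distance(x, z) + manhattan_distance(z, y) + 1e-12)
  }
})

test_that("feature encoding fixes order and binarizes labels", {
  rows <- rbind(positive_rows("R", "C", 1990L, 5L),
                positive_rows("R", "C", 1991L, 6L),
                positive_rows("R", "C", 1992L, 7L))
  rows$locust_present <- c("yes", "no", "yes")
  enc <- encode_features(rows)
  expect_equal(colnames(enc$x),
               c("start_year", "start_month", "precipitation",
                 "max_temperature", "soil_moisture"))
  expect_equal(enc$x[1, ], c(start_year = 1990, start_month = 5,
                             precipitation = 2, max_temperature = 3,
                             soil_moisture = 1))
  expect_equal(enc$y, c(1L, 0L, 1L))
  rows$start_month[1] <- 13L
  expect_error(encode_features(rows), "1..12")
  rows$start_month[1] <- 5L
  rows$locust_present[1] <- "maybe"
  expect_error(encode_features(rows), "unknown label")
})

test_that("fitting freezes scaling and handles degenerate spreads", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5))
  m <- glad_knn(x, c(1L, 0L, 1L, 0L), k = 1)
  expect_equal(m$spread[["b"]], 1) # constant feature keeps unit spread
  expect_identical(glad_knn(x, c(1L, 0L, 1L, 0L), k = 1)[c("xs", "y")],
                   m[c("xs", "y")])
  # k = 1 self-prediction returns the training label
  for (i in 1:4)
    expect_equal(predict(m, x[i, ], type = "class"),
                 c("no", "yes")[c(1L, 0L, 1L, 0L)[i] + 1L])
  expect_error(glad_knn(x[0, , drop = FALSE], integer(0)), "empty")
})

test_that("neighbour search orders by distance with index tie-breaks", {
  x <- matrix(c(0, 1, 2, 3), ncol = 1)
  m <- glad_knn(x, c(0L, 0L, 1L, 1L), k = 2)
  nn <- nearest_neighbours(m, 1.6, k = 2)
  expect_equal(nn$index, c(3L, 2L)) # 2 then 1 on the raw line
  tie <- nearest_neighbours(m, 1.5, k = 1)
  expect_equal(tie$index, 2L) # equidistant to 1 and 2: earlier-stored wins
  expect_error(nearest_neighbours(m, 0, k = 9), "exceeds")
})

test_that("the vote follows majority, dominance and nearest-tie rules", {
  v <- knn_vote(c(1L, 1L, 0L), weights = "uniform")
  expect_equal(v$label, 1L)
  expect_equal(v$score, 2 / 3)
  # zero-distance neighbours dominate in distance mode
  v0 <- knn_vote(c(1L, 0L, 0L, 0L), c(0, 5, 5, 5), weights = "distance")
  expect_equal(v0$label, 1L)
  # 50/50 uniform vote goes to the nearest neighbour's class
  vt <- knn_vote(c(0L, 1L), weights = "uniform")
  expect_equal(vt$label, 0L)
  expect_error(knn_vote(integer(0)), "at least one")
})

test_that("predictions agree with the brute-force oracle across settings", {
  set.seed(101)
  xtr <- random_train(50, 5)
  ytr <- rbinom(50, 1, 0.5)
  m_args <- expand.grid(k = c(1L, 3L, 7L),
                        weights = c("uniform", "distance"),
                        metric = c("manhattan", "euclidean"),
                        stringsAsFactors = FALSE)
  queries <- random_train(40, 5)
  for (a in seq_len(nrow(m_args))) {
    p <- if (m_args$metric[a] == "manhattan") 1 else 2
    m <- glad_knn(xtr, ytr, k = m_args$k[a], weights = m_args$weights[a],
                  metric = m_args$metric[a])
    for (q in seq_len(nrow(queries))) {
      nn <- nearest_neighbours(m, queries[q, ], m_args$k[a])
      ref <- brute_nn(xtr, queries[q, ], m_args$k[a], p)
      expect_equal(nn$index, ref$index)
      expect_equal(nn$distance, ref$distance)
      got <- predict(m, queries[q, ], type = "record")
      want <- brute_predict(xtr, ytr, queries[q, ], m_args$k[a],
                            m_args$weights[a], p)
      expect_equal(got$pred, c("no", "yes")[want$label + 1L])
      expect_equal(got$score, want$score)
    }
  }
})

test_that("uniform vote equals the label mode when the mode is unique", {
  set.seed(5)
  for (i in 1:30) {
    labs <- rbinom(7, 1, 0.5)
    if (sum(labs) == 3.5) next
    v <- knn_vote(labs, weights = "uniform")
    if (sum(labs == 1) != sum(labs == 0))
      expect_equal(v$label, as.integer(sum(labs == 1) > sum(labs == 0)))
  }
})

test_that("predictions are invariant to per-feature affine rescaling", {
  set.seed(77)
  xtr <- random_train(60, 5)
  ytr <- rbinom(60, 1, 0.5)
  queries <- random_train(15, 5)
  base <- predict(glad_knn(xtr, ytr, k = 7), queries, type = "record")
  for (i in 1:20) {
    a <- runif(5, 0.1, 10)
    b <- rnorm(5, sd = 50)
    tx <- sweep(sweep(xtr, 2, a, "*"), 2, b, "+")
    tq <- sweep(sweep(queries, 2, a, "*"), 2, b, "+")
    got <- predict(glad_knn(tx, ytr, k = 7), tq, type = "record")
    expect_equal(got$pred, base$pred)
    expect_equal(got$score, base$score)
  }
})

test_that("separable classes are classified perfectly; single-class data is degenerate", {
  set.seed(9)
  x <- rbind(matrix(rnorm(100 * 5), ncol = 5),
             matrix(rnorm(100 * 5, mean = 30), ncol = 5))
  y <- rep(c(0L, 1L), each = 100)
  m <- glad_knn(x, y, k = 7)
  expect_equal(predict(m, x, type = "class"), c("no", "yes")[y + 1L])

  ones <- glad_knn(matrix(rnorm(15), ncol = 5), rep(1L, 3), k = 7)
  rec <- predict(ones, matrix(rnorm(10), ncol = 5), type = "record")
  expect_true(all(rec$pred == "yes"))
  expect_true(all(rec$score == 1))
})
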