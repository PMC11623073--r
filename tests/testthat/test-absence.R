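test_that("the attack calendar is the distinct set of attacked region-months", {
  pos <- rbind(positive_rows("R1", "C01", 1990L, 10L),
               positive_rows("R1", "C01", 1990L, 11L),
               positive_rows("R1", "C01", 1990L, 11L)) # duplicate month
  cal <- attack_calendar(pos)
  expect_equal(nrow(cal), 2L)
  expect_equal(cal$month, c(10L, 11L))
  expect_error(attack_calendar(pos[0, ]), "non-empty")
  neg <- pos
  neg$locust_present <- "no"
  expect_error(attack_calendar(neg), "positive")
})

test_that("negatives are the monthly complement of attacks", {
  atlas <- atlas_fixture(1)
  g <- grid_fixture(nlat = 5, nlon = 1) # covers the single cell, 1990
  pos <- rbind(positive_rows("C01-R01", "C01", 1990L, 3L),
               positive_rows("C01-R01", "C01", 1990L, 7L))
  neg <- generate_negatives(attack_calendar(pos), atlas, g,
                            span = c(1990, 1990))
  expect_equal(nrow(neg), 10L) # 12 - 2
  expect_true(all(neg$locust_present == "no"))
  expect_false(any(neg$start_month %in% c(3L, 7L)))
})

test_that("six regions, two attacked months in one region, one year: 70 negatives", {
  atlas <- atlas_fixture(6)
  g <- grid_fixture(nlat = 5, nlon = 6)
  pos <- rbind(positive_rows("C01-R01", "C01", 1990L, 10L),
               positive_rows("C01-R01", "C01", 1990L, 11L))
  neg <- generate_negatives(attack_calendar(pos), atlas, g,
                            span = c(1990, 1990))
  expect_equal(nrow(neg), 6L * 12L - 2L)
  # all six known regions of the country appear, not just the attacked one
  expect_setequal(unique(neg$region), atlas$region)
  # the attacked region contributes exactly the 10 attack-free months
  expect_equal(sum(neg$region == "C01-R01"), 10L)
  # restricting the universe to historically attacked regions
  neg_att <- generate_negatives(attack_calendar(pos), atlas, g,
                                span = c(1990, 1990), universe = "attacked")
  expect_equal(nrow(neg_att), 10L)
})

test_that("a region attacked every span month yields no negatives", {
  atlas <- atlas_fixture(1)
  g <- grid_fixture(nlat = 5, nlon = 1)
  pos <- do.call(rbind, lapply(1:12, function(m)
    positive_rows("C01-R01", "C01", 1990L, m)))
  neg <- generate_negatives(attack_calendar(pos), atlas, g,
                            span = c(1990, 1990))
  expect_equal(nrow(neg), 0L)
})

test_that("negative generation validates regions and span", {
  atlas <- atlas_fixture(2)
  g <- grid_fixture(nlat = 5, nlon = 2)
  cal <- attack_calendar(positive_rows("GHOST", "C01", 1990L, 1L))
  expect_error(generate_negatives(cal, atlas, g, span = c(1990, 1990)),
               "GHOST")
  cal2 <- attack_calendar(positive_rows("C01-R01", "C01", 1990L, 1L))
  expect_error(generate_negatives(cal2, atlas, g, span = c(1990, 1991)),
               "outside")
})

test_that("assembly conserves counts and rejects inconsistencies", {
  atlas <- atlas_fixture(6)
  g <- grid_fixture(nlat = 5, nlon = 6)
  pos <- rbind(positive_rows("C01-R01", "C01", 1990L, 10L),
               positive_rows("C01-R01", "C01", 1990L, 11L),
               positive_rows("C01-R02", "C01", 1990L, 1L),
               positive_rows("C01-R02", "C01", 1990L, 1L))
  neg <- generate_negatives(attack_calendar(pos), atlas, g,
                            span = c(1990, 1990))
  glad <- assemble_dataset(pos, neg, quiet = TRUE)
  prov <- attr(glad, "provenance")
  expect_equal(nrow(glad), nrow(pos) + nrow(neg))
  expect_equal(prov$positives, 4L)
  expect_equal(prov$negatives, nrow(neg))

  # conservation identity per region over the whole universe
  cal <- attack_calendar(pos)
  for (r in atlas$region) {
    attacked <- sum(cal$region == r)
    expect_equal(sum(neg$region == r) + attacked, 12L)
  }

  # no negative row's region-month is in the calendar
  expect_length(intersect(paste(neg$region, neg$start_year, neg$start_month),
                          paste(cal$region, cal$year, cal$month)), 0)

  # invariant to positive-row ordering
  neg2 <- generate_negatives(attack_calendar(pos[sample(nrow(pos)), ]),
                             atlas, g, span = c(1990, 1990))
  expect_identical(neg, neg2)

  # collisions and empty classes are rejected
  bad <- neg[1, ]
  bad$locust_present <- "yes"
  expect_error(assemble_dataset(rbind(pos, bad), neg, quiet = TRUE),
               "collision")
  expect_error(assemble_dataset(pos, neg[0, ], quiet = TRUE), "empty")
})
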