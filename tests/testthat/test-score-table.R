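test_that("raw score is the log of count over 0.1% of the corpus total", {
  expect_equal(raw_score(0.001 * 500, 500), 0)       # log(1)
  expect_equal(raw_score(0.01 * 500, 500), log(10))  # ln(10) ~ 2.3026
  expect_error(raw_score(2, 0), "positive")
  # monotone in the count
  cts <- sort(runif(50, 1.01, 100))
  expect_true(all(diff(raw_score(cts, 1000)) > 0))
})

test_that("tables are min-max scaled onto [-3, 3] with rare counts excluded", {
  b <- new_fragment_counts(
    counts = c("10" = 0.5, "11" = 2, "12" = 8),
    radii = c("10" = 2L, "11" = 2L, "12" = 2L),
    total = 100, source = "building_blocks", n_records = 3L
  )
  r <- new_fragment_counts(
    counts = c("20" = 1, "21" = 3, "22" = 5, "23" = 9),
    radii = c("20" = 2L, "21" = 2L, "22" = 2L, "23" = 2L),
    total = 50, source = "reactions", n_records = 4L
  )
  tab <- build_score_table(b, r)
  # counts <= 1 are dropped entirely
  expect_false("10" %in% names(tab$bscores))
  expect_false("20" %in% names(tab$rscores))
  # extremes map exactly onto the band edges, independently per table
  expect_equal(unname(tab$bscores[c("11", "12")]), c(-3, 3))
  expect_equal(min(tab$rscores), -3)
  expect_equal(max(tab$rscores), 3)
  # linearity: the middle entry sits at the log-interpolated position
  raw <- log(c(3, 5, 9) / (0.001 * 50))
  expect_equal(
    unname(tab$rscores["22"]),
    -3 + 6 * (raw[2] - raw[1]) / (raw[3] - raw[1])
  )
})

test_that("degenerate and empty tables are handled explicitly", {
  b1 <- new_fragment_counts(c("1" = 4), c("1" = 2L), 10, "building_blocks", 1L)
  r1 <- new_fragment_counts(c("2" = 4, "3" = 4), c("2" = 2L, "3" = 2L), 10, "reactions", 1L)
  tab <- build_score_table(b1, r1)
  expect_equal(unname(tab$bscores), 0)     # constant table maps to 0
  expect_equal(unname(tab$rscores), c(0, 0))

  empty_b <- new_fragment_counts(c("1" = 0.4), c("1" = 2L), 10, "building_blocks", 1L)
  expect_error(build_score_table(empty_b, r1), "building-block")
})

test_that("lookup applies the max-merge rule with a -6 floor", {
  tab <- build_score_table(
    new_fragment_counts(c("1" = 2, "2" = 8), c("1" = 2L, "2" = 2L), 100, "building_blocks", 2L),
    new_fragment_counts(c("2" = 2, "3" = 9), c("2" = 2L, "3" = 2L), 100, "reactions", 2L)
  )
  # fragment known to both: the higher of BScore (+3) and RScore (-3)
  expect_equal(lookup_score(tab, 2), 3)
  # single-table fragments pass through
  expect_equal(lookup_score(tab, 1), unname(tab$bscores["1"]))
  expect_equal(lookup_score(tab, 3), unname(tab$rscores["3"]))
  # absent fragment: exactly -6
  expect_identical(lookup_score(tab, 987654321), -6)
  # vectorized and always in [-3,3] or -6
  vals <- lookup_score(tab, c(1, 2, 3, 42, 4242))
  expect_true(all(vals %in% c(-6) | (vals >= -3 & vals <= 3)))
})

test_that("the fixture score table stays in band and round-trips bit-stably", {
  fx <- seed7_fixture()
  tab <- fx$table
  expect_true(all(tab$bscores >= -3 & tab$bscores <= 3))
  expect_true(all(tab$rscores >= -3 & tab$rscores <= 3))
  expect_equal(max(tab$bscores), 3)
  expect_equal(max(tab$rscores), 3)

  path <- withr::local_tempfile(fileext = ".json")
  write_score_table(tab, path)
  back <- read_score_table(path)
  stored <- as.numeric(union(names(tab$bscores), names(tab$rscores)))
  set.seed(42)
  absent <- sample.int(2^31 - 1, 1000)
  absent <- setdiff(absent, stored)
  probe <- c(stored, absent)
  expect_identical(lookup_score(back, probe), lookup_score(tab, probe))

  # identical corpora -> byte-identical serialization
  path2 <- withr::local_tempfile(fileext = ".json")
  write_score_table(build_score_table(fx$bcounts, fx$rcounts), path2)
  expect_identical(readLines(path), readLines(path2))
})
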