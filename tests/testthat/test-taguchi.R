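test_that("the L9 array is balanced and pairwise orthogonal", {
  d <- l9_design()
  expect_equal(unname(d$array[4, ]), c(2L, 1L, 2L))
  for (col in 1:3) {
    expect_equal(as.integer(table(d$array[, col])), rep(3L, 3))
  }
  # brute force: every ordered column pair covers all 9 level pairs once
  for (a in 1:3) for (b in 1:3) {
    if (a == b) next
    pairs <- table(paste(d$array[, a], d$array[, b]))
    expect_length(pairs, 9L)
    expect_true(all(pairs == 1L))
  }
  expect_equal(design_run_values(d, 4),
               list(slo_ratio = 0.5, filter_width = 3L, filter_height = 5L))
})

test_that("experiments run in array order with verbatim responses", {
  seen <- list()
  ev <- function(slo_ratio, filter_width, filter_height, seed) {
    seen[[length(seen) + 1]] <<- c(slo_ratio, filter_width, filter_height)
    c(train = 90, test = 85, val = 80)
  }
  tab <- run_taguchi_experiments(l9_design(), ev, seed = 3)
  expect_equal(nrow(tab), 9L)
  expect_true(all(tab$train == 90 & tab$test == 85 & tab$val == 80))
  d <- l9_design()
  expect_equal(length(seen), 9L)
  for (i in 1:9) {
    v <- design_run_values(d, i)
    expect_equal(seen[[i]], c(v$slo_ratio, v$filter_width, v$filter_height))
  }
  # constant responses: all level averages equal
  expect_true(all(level_averages(tab, "val") == 80))

  failing <- function(...) stop("boom")
  warns <- capture_warnings(
    bad <- run_taguchi_experiments(l9_design(), failing))
  expect_length(warns, 9L)   # one warning per failed run
  expect_match(warns[1], "run 1 failed")
  expect_error(level_averages(bad, "val"), "incomplete")
})

test_that("level averages of a balanced design share the grand mean", {
  set.seed(8)
  tab <- taguchi_response_table(runif(9, 90, 100), runif(9, 80, 100),
                                runif(9, 70, 90))
  for (resp in c("train", "test", "val")) {
    avg <- level_averages(tab, resp)
    expect_equal(unname(rowMeans(avg)), rep(mean(tab[[resp]]), 3),
                 tolerance = 1e-9)
    expect_true(all(colnames(avg) == paste0("level", 1:3)))
  }
})

test_that("level-average analysis recovers a planted dominant level", {
  set.seed(9)
  d <- l9_design()
  for (trial in 1:20) {
    planted <- sample(1:3, 3, replace = TRUE)
    effects <- matrix(runif(9, 0, 2), 3, 3)
    for (f in 1:3) effects[f, planted[f]] <- 10 + runif(1)
    y <- vapply(1:9, function(i)
      60 + sum(effects[cbind(1:3, d$array[i, ])]) + rnorm(1, 0, 0.05),
      numeric(1))
    tab <- taguchi_response_table(y, y, y)
    expect_equal(unname(select_best(tab, "val")$best_levels), planted)
  }
})

test_that("the example response table reproduces its printed analysis", {
  tab <- example_response_table()
  avg <- level_averages(tab, "val")
  expect_equal(avg["slo_ratio", 1], (84.80 + 79.40 + 79.29) / 3,
               tolerance = 1e-9)
  best <- select_best(tab, "val")
  expect_equal(unname(best$best_levels), c(1L, 1L, 1L))
  expect_equal(best$run, 1L)
  expect_equal(best$best_values$slo_ratio, 0.3)
  # train column: filter_width levels 1 and 2 tie, broken to the lower index
  avg_tr <- level_averages(tab, "train")
  expect_equal(avg_tr["filter_width", 1], avg_tr["filter_width", 2],
               tolerance = 1e-9)
  expect_equal(unname(select_best(tab, "train")$best_levels[2]), 1L)
})

test_that("response tables survive the CSV round trip", {
  tab <- example_response_table()
  f <- withr::local_tempfile(fileext = ".csv")
  write_response_table(tab, f)
  back <- read_response_table(f)
  expect_equal(back$val, tab$val)
  expect_equal(attr(back, "design")$array, attr(tab, "design")$array)
})

test_that("the desk-scale evaluator yields the three accuracy responses", {
  ev <- desk_evaluator(duration_s = 6, n_subjects = 1L, max_windows = 400L,
                       val_duration_s = 4)
  r <- ev(slo_ratio = 0.3, filter_width = 3, filter_height = 3, seed = 4)
  expect_named(r, c("train", "test", "val"))
  expect_true(all(r >= 0 & r <= 100))
  # training windows from a single subject are near-separable
  expect_gt(r[["train"]], 80)
})

test_that("the larger-the-better S/N ratio rises with the response", {
  expect_equal(sn_larger_better(10), -10 * log10(1 / 100))
  expect_gt(sn_larger_better(c(99, 99)), sn_larger_better(c(80, 80)))
  expect_error(sn_larger_better(c(1, -1)), "positive")
})
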