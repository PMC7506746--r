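test_that("the overlap ratio derives the documented sample counts", {
  expect_equal(window_config(slo_ratio = 0.3)$r, 4L)
  expect_equal(window_config(slo_ratio = 0.5)$r, 7L)
  expect_equal(window_config(slo_ratio = 0.7)$r, 10L)
  expect_error(window_config(slo_ratio = 0), "slo_ratio")
  expect_error(window_config(width_samples = 0), "width")
})

test_that("the class merge relabels toe off as heel off and nothing else", {
  labs <- phase_code(c("FC", "HO", "TO", "TO", "SW"))
  expect_equal(phase_name(merge_phases(labs)),
               c("FC", "HO", "HO", "HO", "SW"))
  no_to <- phase_code(c("SW", "HS", "FC", "HO"))
  expect_identical(merge_phases(no_to), no_to)
  rand <- sample(unname(PHASES), 200, replace = TRUE)
  expect_false(PHASES[["TO"]] %in% merge_phases(rand))
})

test_that("window extraction has exact counts, overlap and stride timing", {
  n <- 1000L
  feats <- matrix(rnorm(n * 22), n, 22)
  labs <- rep(1L, n)
  wins <- extract_windows(feats, labs, window_config())
  expect_length(wins, 987L)
  expect_equal(dim(wins[[1]]$features), c(22L, 14L))
  # consecutive windows share width-1 samples
  expect_equal(wins[[1]]$features[, -1], wins[[2]]$features[, -14])
  # start-time deltas are all 10 ms at 100 Hz
  starts <- vapply(wins, `[[`, numeric(1), "start_ms")
  expect_true(all(diff(starts) == 10))
  expect_error(extract_windows(feats[1:10, ], labs[1:10], window_config()),
               "14")
})

test_that("window-label assignment follows the terminal-run rule", {
  expect_equal(assign_window_label(rep(PHASES[["HS"]], 14), r = 4),
               PHASES[["HS"]])
  fc_ho <- function(nf, nh) rep(phase_code(c("FC", "HO")), c(nf, nh))
  expect_equal(phase_name(assign_window_label(fc_ho(10, 4), r = 4)), "HO")
  expect_equal(phase_name(assign_window_label(fc_ho(12, 2), r = 4)), "FC")
  out3 <- rep(phase_code(c("SW", "HS", "FC")), c(5, 5, 4))
  expect_true(is.na(assign_window_label(out3, r = 4)))
  expect_error(assign_window_label(fc_ho(7, 7), r = 15), "r must")
})

test_that("vectorized assignment agrees with the single-window rule", {
  set.seed(42)
  for (i in 1:300) {
    w <- sample(4:20, 1)
    r <- sample(seq_len(w), 1)
    seqs <- matrix(sample(1:4, 5 * w, replace = TRUE), 5, w)
    vec <- assign_labels_matrix(seqs, r)
    ind <- apply(seqs, 1, assign_window_label, r = r)
    expect_identical(unname(vec), unname(as.integer(ind)))
  }
})

test_that("grayscale conversion maps the window range onto [0, 1]", {
  expect_equal(as.numeric(window_to_image(matrix(c(-2, 0, 2), 1))),
               c(0, 0.5, 1))
  already <- matrix(c(0, 0.25, 1, 0.5), 2)
  expect_equal(window_to_image(already), already)
  expect_equal(window_to_image(matrix(7, 3, 4)), array(0, c(3, 4)))
  expect_error(window_to_image(matrix(c(1, NA), 1)), "non-finite")
  set.seed(7)
  for (i in 1:200) {
    img <- window_to_image(matrix(rnorm(22 * 14), 22))
    expect_equal(range(img), c(0, 1))
  }
})

test_that("the dataset pipeline conserves window counts and classes", {
  rec <- simulate_walk(make_gait_profile(21, 1.0), 30)
  labs <- label_stream(rec)$right
  std <- apply_standardization(rec$features,
                               fit_standardization(rec$features))
  ds <- build_window_dataset(std, labs, window_config())
  expect_equal(ds$counts$extracted, nrow(std) - 14L + 1L)
  expect_equal(ds$counts$kept + ds$counts$dropped, ds$counts$extracted)
  expect_setequal(unique(ds$labels), phase_code(c("SW", "HS", "FC", "HO")))
  expect_equal(dim(ds$images)[1:2], c(22L, 14L))
  expect_equal(dim(ds$images)[3], ds$counts$kept)
  expect_true(all(ds$images >= 0 & ds$images <= 1))
  # deterministic rebuild
  expect_identical(ds, build_window_dataset(std, labs, window_config()))
})

test_that("a kept window's class is present in its own label sequence", {
  set.seed(11)
  labs <- inverse.rle(list(
    lengths = pmax(1L, rpois(200, 12)),
    values = sample(1:4, 200, replace = TRUE)))
  n <- length(labs)
  feats <- matrix(rnorm(n * 22), n, 22)
  cfg <- window_config(slo_ratio = 0.5)
  ds <- build_window_dataset(feats, labs, cfg, merge = FALSE)
  wins <- extract_windows(feats, labs, cfg)
  assigned <- vapply(wins, function(wn)
    assign_window_label(wn, cfg$r), integer(1))
  kept <- which(!is.na(assigned))
  expect_equal(ds$labels, assigned[kept])
  for (k in kept) {
    expect_true(assigned[k] %in% wins[[k]]$label_seq)
  }
})

test_that("an SLO dataset survives the CSV round trip", {
  ds <- small_dataset(31, duration_s = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_slo_dataset(ds, f)
  back <- read_slo_dataset(f)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$images, ds$images, tolerance = 1e-9)
  expect_equal(back$counts, ds$counts)
  expect_equal(back$config$r, ds$config$r)
})
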