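test_that("profile defaults encode the study conditions and validate input", {
  p <- make_gait_profile(seed = 1, speed_mps = 1.0)
  expect_s3_class(p, "gait_profile")
  expect_equal(p$phase_fractions[["TO"]], 0.016)
  expect_equal(sum(p$phase_fractions), 1.0, tolerance = 1e-12)
  expect_equal(p$n_feature_channels, 22L)

  expect_error(make_gait_profile(1, speed_mps = 1.6), "0.2.*1.5|1.5")
  expect_error(make_gait_profile(1, speed_mps = 0.1), "band")
  expect_error(make_gait_profile(1, overrides = list(bogus = 1)), "bogus")
  expect_error(make_gait_profile(1, overrides = list(
    phase_fractions = c(SW = 0.5, HS = 0.2, FC = 0.2, HO = 0.09,
                        TO = 0.02))), "sum to 1")
})

test_that("identical seeds give identical profiles, different seeds differ", {
  expect_identical(make_gait_profile(1), make_gait_profile(1))
  p1 <- make_gait_profile(1)
  p2 <- make_gait_profile(2)
  expect_false(isTRUE(all.equal(p1$subject_offset, p2$subject_offset)))
})

test_that("simulated recordings are deterministic with exact frame counts", {
  p <- make_gait_profile(3, 0.9)
  r1 <- simulate_walk(p, 10)
  r2 <- simulate_walk(p, 10)
  expect_identical(r1, r2)
  expect_equal(nrow(r1$features), 1000L)
  expect_equal(length(r1$truth_right), 1000L)
  expect_equal(nrow(r1$fsr_left), 1000L)
  expect_equal(unique(diff(r1$time_ms)), 10L)
  expect_error(simulate_walk(p, -1), "positive")
})

test_that("phase schedule follows cycle order with largest-remainder counts", {
  p <- make_gait_profile(1)
  s <- phase_schedule(p, 1, cycle_samples = 126)
  expect_equal(s$name, c("HS", "FC", "HO", "TO", "SW"))
  expect_equal(s$n_samples[s$name == "TO"], 2L)
  expect_equal(sum(s$n_samples), 126L)

  s3 <- phase_schedule(p, 3, cycle_samples = 126)
  expect_equal(sum(s3$n_samples), 3L * 126L)
  per_cycle <- tapply(s3$n_samples, list(s3$cycle, s3$name), identity)
  expect_true(all(per_cycle >= 1L))
  # every phase present in every cycle even at tiny cycle lengths
  tiny <- phase_schedule(p, 2, cycle_samples = 7)
  expect_true(all(tiny$n_samples >= 1L))
  expect_equal(sum(tiny$n_samples), 14L)
})

test_that("toe off occupies roughly 1.6% of samples over many cycles", {
  p <- make_gait_profile(5, 1.0)
  rec <- simulate_walk(p, 40)   # 40 cycles at cadence 2 steps/s
  frac <- mean(rec$truth_right == PHASES[["TO"]])
  expect_gt(frac, 0.016 - 0.005)
  expect_lt(frac, 0.016 + 0.005)
})

test_that("heel FSR exceeds threshold only in heel-bearing phases", {
  rec <- simulate_walk(make_gait_profile(7, 1.1), 30)
  heel_on <- rec$fsr_right[, "heel"] >= 0.5
  heel_phases <- phase_name(rec$truth_right[heel_on])
  expect_true(all(heel_phases %in% c("HS", "FC")))
  # and the heel is on for essentially all HS/FC samples
  in_hs_fc <- rec$truth_right %in% phase_code(c("HS", "FC"))
  expect_gt(mean(heel_on[in_hs_fc]), 0.99)
})

test_that("phase-conditional channel means are separable beyond the noise", {
  p <- make_gait_profile(11, 1.0)
  rec <- simulate_walk(p, 60)
  phases <- rec$truth_right
  pairs <- utils::combn(unname(PHASES), 2)
  for (k in seq_len(ncol(pairs))) {
    a <- rec$features[phases == pairs[1, k], , drop = FALSE]
    b <- rec$features[phases == pairs[2, k], , drop = FALSE]
    gap <- abs(colMeans(a) - colMeans(b))
    expect_gte(mean(gap >= 2 * p$noise_sigma), 0.5)
  }
})

test_that("FSR labeling recovers the generator's ground truth", {
  rec <- simulate_walk(make_gait_profile(13, 0.8), 60)
  labs <- label_stream(rec)
  expect_gte(mean(labs$right == rec$truth_right), 0.99)
  expect_gte(mean(labs$left == rec$truth_left), 0.99)
})
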