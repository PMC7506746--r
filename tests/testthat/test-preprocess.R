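test_that("signed-offset augmentation reproduces the amplitude rule", {
  out <- augment_series(c(1, 2, 3),
                        augmentation_spec(noise_kind = "signed-offset",
                                          n_copies = 2))
  # amplitude a = (max|S| - |mean|) * 0.1 = (3 - 2) * 0.1 = 0.1
  expect_equal(out[[1]], c(1.1, 2.1, 3.1))
  expect_equal(out[[2]], c(0.9, 1.9, 2.9))

  const <- augment_series(c(4, 4, 4),
                          augmentation_spec(noise_kind = "signed-offset",
                                            n_copies = 1))
  expect_equal(const[[1]], c(4, 4, 4))
  expect_error(augment_series(numeric(0)), "non-empty")
})

test_that("every augmented copy stays within the amplitude bound", {
  spec <- augmentation_spec(n_copies = 25, seed = 42)
  for (rep in 1:5) {
    S <- matrix(rnorm(60 * 3, sd = rep), 60, 3)
    a <- apply(S, 2, function(col) (max(abs(col)) - abs(mean(col))) * 0.1)
    copies <- augment_series(S, spec)
    expect_length(copies, 25L)
    for (cp in copies) {
      dev <- abs(cp - S)
      expect_true(all(dev <= rep(a, each = 60) + 1e-12))
    }
  }
  # n_copies copies + original = ~26x growth
  expect_length(augment_series(rnorm(10), augmentation_spec()), 25L)
})

test_that("standardization uses population moments and rejects degeneracy", {
  p <- fit_standardization(cbind(x = c(1, 2, 3)))
  expect_equal(unname(p$mean), 2)
  expect_equal(unname(p$sigma), sqrt(2 / 3))
  expect_equal(p$n_fit, 3L)

  z <- apply_standardization(cbind(c(1, 2, 3)), p)
  expect_equal(as.numeric(z), c(-sqrt(3 / 2), 0, sqrt(3 / 2)),
               tolerance = 1e-12)

  expect_error(fit_standardization(cbind(a = c(1, 2), b = c(5, 5))), "2")
  expect_error(fit_standardization(cbind(c(1, 2, 3))[1, , drop = FALSE]),
               "2 rows")
  expect_error(apply_standardization(matrix(1, 2, 3), p), "mismatch")
})

test_that("standardizing the fitting matrix yields zero mean unit sigma", {
  X <- matrix(rnorm(500 * 8, mean = 3, sd = 4), 500, 8)
  p <- fit_standardization(X)
  Z <- apply_standardization(X, p)
  expect_equal(unname(colMeans(Z)), rep(0, 8), tolerance = 1e-9)
  expect_equal(unname(sqrt(colMeans(sweep(Z, 2, colMeans(Z))^2))),
               rep(1, 8), tolerance = 1e-9)
  # round trip to the original scale
  expect_equal(invert_standardization(Z, p), X, tolerance = 1e-9)
  # already-standardized data is a fixed point
  p2 <- fit_standardization(Z)
  expect_equal(unname(p2$mean), rep(0, 8), tolerance = 1e-9)
  expect_equal(unname(p2$sigma), rep(1, 8), tolerance = 1e-9)
})

test_that("standardization parameters persist through JSON", {
  p <- fit_standardization(matrix(rnorm(40), 10, 4))
  f <- withr::local_tempfile(fileext = ".json")
  write_standardization(p, f)
  q <- read_standardization(f)
  expect_equal(unname(q$mean), unname(p$mean), tolerance = 1e-12)
  expect_equal(unname(q$sigma), unname(p$sigma), tolerance = 1e-12)
  expect_equal(q$n_fit, p$n_fit)
})

test_that("the split is disjoint, exhaustive and seeded", {
  s <- split_dataset(100, train_frac = 0.6, seed = 7)
  expect_length(s$train, 60L)
  expect_length(s$test, 40L)
  expect_length(intersect(s$train, s$test), 0L)
  expect_setequal(c(s$train, s$test), 1:100)
  expect_identical(s, split_dataset(100, train_frac = 0.6, seed = 7))
  expect_false(identical(s, split_dataset(100, train_frac = 0.6, seed = 8)))
  expect_error(split_dataset(0), "empty")
  expect_error(split_dataset(10, train_frac = 1), "between")

  y <- rep(c("a", "b"), c(80, 20))
  st <- split_dataset(100, 0.6, seed = 1, stratify = y)
  expect_equal(sum(st$train <= 80), 48L)   # 60% within each class
  expect_equal(sum(st$train > 80), 12L)
})
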