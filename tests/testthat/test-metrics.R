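test_that("rmse matches hand-derived values exactly", {
  expect_equal(rmse(c(6, 7, 8), c(6.5, 7, 7.5)), sqrt(1 / 6),
               tolerance = 1e-15)
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(5, 7), 2)
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("R-squared matches hand-derived values exactly", {
  expect_equal(rSquared(c(6, 7, 8), c(6.5, 7, 7.5)), 0.75,
               tolerance = 1e-15)
  expect_equal(rSquared(1:5, 1:5), 1)
  obs <- c(2, 4, 9, 1)
  expect_equal(rSquared(obs, rep(mean(obs), 4)), 0)
  expect_error(rSquared(c(3, 3, 3), c(1, 2, 3)), "constant")
})

test_that("metrics agree with brute-force recomputation from predictions", {
  set.seed(5)
  obs <- rnorm(200, 7); pred <- obs + rnorm(200, 0, 0.4)
  expect_equal(rmse(obs, pred), sqrt(sum((pred - obs)^2) / 200),
               tolerance = 1e-12)
  expect_equal(rSquared(obs, pred),
               1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2),
               tolerance = 1e-12)
})

test_that("k-fold assignments are balanced, complete and seeded", {
  f10 <- kfoldSplit(10, 10, seed = 1)
  expect_setequal(f10, 1:10)               # ten singletons
  f23 <- kfoldSplit(23, 10, seed = 1)
  sizes <- as.integer(table(f23))
  expect_equal(sort(sizes), c(rep(2L, 7), rep(3L, 3)))
  expect_identical(kfoldSplit(100, 10, seed = 4), kfoldSplit(100, 10, seed = 4))
  expect_false(identical(kfoldSplit(100, 10, 4), kfoldSplit(100, 10, 5)))
  expect_error(kfoldSplit(5, 10), "at least")
  # balance property across random cases
  set.seed(8)
  for (i in 1:20) {
    n <- sample(12:200, 1); k <- sample(2:10, 1)
    sz <- as.integer(table(kfoldSplit(n, k, seed = i)))
    expect_lte(max(sz) - min(sz), 1L)
    expect_equal(sum(sz), n)
  }
})
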