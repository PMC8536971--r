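test_that("the SMILES library is valid, distinct, and seed-reproducible", {
  lib <- genSmilesLibrary(1000, seed = 3)
  expect_length(lib, 1000L)
  expect_equal(anyDuplicated(lib), 0L)
  # every element is its own canonical key (self-canonical)
  sub <- lib[seq(1, 1000, by = 97)]
  expect_identical(canonicalKey(sub), sub)
  # all parse in the native reader
  expect_true(all(vapply(sub, function(s) {
    nrow(parseSmiles(s)$atoms) > 0
  }, logical(1))))
  expect_identical(genSmilesLibrary(50, seed = 9), genSmilesLibrary(50, seed = 9))
  expect_false(identical(genSmilesLibrary(50, seed = 9),
                         genSmilesLibrary(50, seed = 10)))
})

test_that("generated source pairs honor overlap and discordance counts", {
  lib <- sprintf("K%03d", 1:200)
  src <- genSources(100, 50, 20, 5, threshold = 0.1, seed = 5, smiles = lib)
  expect_equal(length(src$a), 100L)
  expect_equal(length(src$b), 50L)
  p <- findCrossPairs(src$a, src$b)
  expect_equal(nrow(p), 20L)
  expect_equal(sum(p$delta_pKi > 0.1), 5L)
  expect_true(all(p$delta_pKi <= 4.46 + 1e-9))
  expect_equal(src$truth$expected_final, 125L)
  expect_error(genSources(10, 5, 8, 0, smiles = lib), "nShared")
  expect_error(genSources(10, 5, 3, 4, smiles = lib), "nDiscordant")
})

test_that("pKi values stay inside the configured clip range", {
  lib <- sprintf("K%03d", 1:150)
  src <- genSources(80, 60, 10, 0, seed = 2, smiles = lib)
  pk <- c(records(src$a)$pKi, records(src$b)$pKi)
  expect_true(all(pk >= 4.2 - 1e-9 & pk <= 11 + 1e-9))
})

test_that("regression benchmarks carry exact ground truth", {
  clean <- genQsarDataset(200, 10, 3, noiseSd = 0, seed = 4)
  expect_equal(clean$y, clean$truth$y_noiseless)
  noisy <- genQsarDataset(200, 10, 3, noiseSd = 0.5, seed = 4)
  expect_true(all(noisy$y >= 4.2 & noisy$y <= 11))
  expect_identical(genQsarDataset(50, 5, 2, seed = 1)$X,
                   genQsarDataset(50, 5, 2, seed = 1)$X)
})

test_that("OLS on the true features of a linear benchmark recovers beta", {
  bench <- genQsarDataset(400, 8, 3, form = "linear", noiseSd = 0.3,
                          seed = 12)
  # the response is standardized before clipping; recover on that scale
  df <- data.frame(y = bench$y, bench$X[, bench$truth$informative])
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)$coefficients
  # rescaled true coefficients: beta / sd of the raw signal
  bsc <- bench$truth$beta
  est <- sm[-1, "Estimate"]; se <- sm[-1, "Std. Error"]
  scale <- as.numeric(stats::coef(stats::lm(est ~ 0 + bsc)))
  expect_true(all(abs(est - scale * bsc) <= 3 * se))
})
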