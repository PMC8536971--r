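bg3 <- local({
  set.seed(41)
  matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
})

test_that("a constant model gets zero attributions and its own base value", {
  f <- function(X) rep(3.5, nrow(X))
  s <- shapValues(f, bg3, bg3[1:3, , drop = FALSE], method = "exact")
  expect_equal(unname(shapPhi(s)), matrix(0, 3, 3), tolerance = 1e-12)
  expect_equal(baseValue(s), 3.5)
})

test_that("exact attributions of a linear model follow the closed form", {
  f <- function(X) 2 * X[, 1] - X[, 2] + 0 * X[, 3]
  x <- matrix(c(1, 1, 0.3), 1, dimnames = list(NULL, colnames(bg3)))
  s <- shapValues(f, bg3, x, method = "exact")
  expect_equal(unname(shapPhi(s)[1, ]),
               c(2 * (1 - mean(bg3[, 1])), -(1 - mean(bg3[, 2])), 0),
               tolerance = 1e-10)
  expect_equal(baseValue(s), mean(f(bg3)), tolerance = 1e-12)
})

test_that("exact enumeration satisfies local accuracy on a nonlinear model", {
  g <- function(X) sin(X[, 1]) * X[, 2] + X[, 3]^2
  xe <- matrix(rnorm(15, sd = 1.3), 5, 3,
               dimnames = list(NULL, colnames(bg3)))
  s <- shapValues(g, bg3, xe, method = "exact")
  err <- abs(baseValue(s) + rowSums(shapPhi(s)) - g(xe))
  expect_lte(max(err), 1e-9)
})

test_that("exact enumeration refuses too many features with guidance", {
  wide <- matrix(rnorm(26), 2, 13)
  colnames(wide) <- sprintf("v%d", 1:13)
  expect_error(shapValues(function(X) rowSums(X), wide, method = "exact"),
               "12 features")
  expect_error(shapValues(function(X) rowSums(X), bg3[0, , drop = FALSE]),
               "empty background")
})

test_that("sampling converges to the exact values on a 3-feature toy model", {
  h <- function(X) ifelse(X[, 1] > 0, 2, -1) + X[, 2] * X[, 3]
  xe <- bg3[1:3, , drop = FALSE]
  ex <- shapValues(h, bg3, xe, method = "exact")
  sm <- shapValues(h, bg3, xe, method = "sampling", nSamples = 5000,
                   seed = 6)
  rg <- diff(range(h(bg3)))
  expect_lte(max(abs(shapPhi(ex) - shapPhi(sm))), 0.02 * rg)
})

test_that("the sampling estimator is unbiased across seeded reruns", {
  h <- function(X) X[, 1] * X[, 2] + 0.5 * X[, 3]
  xe <- bg3[2, , drop = FALSE]
  exact <- shapPhi(shapValues(h, bg3, xe, method = "exact"))[1, ]
  reruns <- t(vapply(1:50, function(s) {
    shapPhi(shapValues(h, bg3, xe, method = "sampling", nSamples = 150,
                       seed = s))[1, ]
  }, numeric(3)))
  se <- apply(reruns, 2, sd) / sqrt(nrow(reruns))
  expect_true(all(abs(colMeans(reruns) - exact) <= 3 * se + 1e-12))
})

test_that("symmetric features receive equal attributions", {
  f <- function(X) X[, 1] + X[, 2]
  bgSym <- matrix(rep(c(0.2, -0.1), each = 8), 8, 2,
                  dimnames = list(NULL, c("a", "b")))
  bgSym[, 2] <- bgSym[, 1]                    # identical backgrounds
  x <- matrix(c(1, 1), 1, dimnames = list(NULL, c("a", "b")))
  s <- shapValues(f, bgSym, x, method = "exact")
  expect_equal(unname(shapPhi(s)[1, "a"]), unname(shapPhi(s)[1, "b"]),
               tolerance = 1e-12)
})

test_that("exact attributions are additive across models", {
  f <- function(X) X[, 1]^2
  g <- function(X) 2 * X[, 2] - X[, 3]
  fg <- function(X) f(X) + g(X)
  xe <- bg3[4:6, , drop = FALSE]
  expect_equal(shapPhi(shapValues(fg, bg3, xe, method = "exact")),
               shapPhi(shapValues(f, bg3, xe, method = "exact")) +
                 shapPhi(shapValues(g, bg3, xe, method = "exact")),
               tolerance = 1e-10)
})

test_that("importance ranking orders by mean |phi| with lexical ties", {
  f <- function(X) 3 * X[, 3]                # only f3 matters
  s <- shapValues(f, bg3, method = "exact")
  imp <- aggregateImportance(s)
  expect_equal(imp$feature[1], "f3")
  expect_equal(imp$mean_abs_shap[2:3], c(0, 0))
  expect_equal(imp$feature[2:3], c("f1", "f2"))  # lexical tie-break
  expect_true(all(imp$frac_positive >= 0 & imp$frac_positive <= 1))
})

test_that("dependence profiles expose monotone relationships", {
  f <- function(X) -2 * X[, 1]               # decreasing in f1
  s <- shapValues(f, bg3, method = "exact")
  dp <- dependenceProfile(s, "f1")
  expect_equal(nrow(dp), nrow(bg3))
  expect_lte(suppressWarnings(cor(dp$value, dp$phi, method = "spearman")), 0)
  expect_false(is.unsorted(dp$value))
  const <- shapValues(function(X) rep(1, nrow(X)), bg3, method = "exact")
  expect_equal(dependenceProfile(const, "f2")$phi, rep(0, nrow(bg3)),
               tolerance = 1e-12)
  expect_error(dependenceProfile(s, "nope"), "unknown feature")
})
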