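test_that("rule-of-five and Veber flags follow the stated inequalities", {
  allOk <- lipinskiVeber(300, 2.0, 1, 4, 80, 4)
  expect_true(all(unlist(allOk)))
  # boundaries: MW and logP strict; donors/acceptors/PSA inclusive;
  # rotatable bonds strict
  edge <- lipinskiVeber(499.9, 4.9, 5, 10, 140, 9)
  expect_true(all(unlist(edge)))
  expect_false(lipinskiVeber(500, 2, 1, 4, 80, 4)$mw_ok)
  expect_false(lipinskiVeber(300, 5, 1, 4, 80, 4)$logp_ok)
  expect_false(lipinskiVeber(300, 2, 6, 4, 80, 4)$hbd_ok)
  expect_false(lipinskiVeber(300, 2, 1, 11, 80, 4)$hba_ok)
  expect_false(lipinskiVeber(300, 2, 1, 4, 140.1, 4)$psa_ok)
  expect_false(lipinskiVeber(300, 2, 1, 4, 80, 10)$rot_ok)
  # a heavy ergoline-like compound fails only the weight rule
  big <- lipinskiVeber(654.6, 4.2, 3, 9, 118, 8)
  expect_false(big$lipinski_ok)
  expect_false(big$mw_ok)
  expect_true(big$logp_ok && big$hbd_ok && big$hba_ok)
  # completeness: lipinski_ok implies all four components
  set.seed(2)
  r <- lipinskiVeber(runif(50, 100, 700), runif(50, -1, 7),
                     sample(0:8, 50, TRUE), sample(0:14, 50, TRUE),
                     runif(50, 0, 200), sample(0:14, 50, TRUE))
  expect_true(all(!r$lipinski_ok |
                    (r$mw_ok & r$logp_ok & r$hbd_ok & r$hba_ok)))
})

test_that("Tanimoto similarity follows the set-overlap formula", {
  expect_equal(tanimoto(c(1, 5, 9), c(1, 5, 9)), 1)
  expect_equal(tanimoto(c(1, 2), c(3, 4)), 0)
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_error(tanimoto(integer(0), integer(0)), "undefined")
  # symmetry, bounds, identity-iff-equal on random bit sets
  set.seed(12)
  for (i in 1:50) {
    a <- sample(0:127, sample(1:40, 1))
    b <- sample(0:127, sample(1:40, 1))
    t1 <- tanimoto(a, b)
    expect_equal(t1, tanimoto(b, a))
    expect_gte(t1, 0); expect_lte(t1, 1)
    expect_equal(t1 == 1, setequal(a, b))
  }
})

test_that("similarity summaries are sane and seed-stable", {
  same <- rep("c1ccccc1O", 3)
  s <- similaritySummary(same)
  expect_equal(c(s$min, s$median, s$max), c(1, 1, 1))
  mix <- c("C", "c1ccc2ccccc2c1", "CCO", "c1ccccc1CCN")
  s2 <- similaritySummary(mix, seed = 5)
  expect_true(all(s2$values >= 0 & s2$values <= 1))
  expect_lte(s2$min, s2$median)
  expect_lte(s2$median, s2$max)
  expect_equal(sum(s2$histogram$count), length(s2$values))
  s3 <- similaritySummary(mix, seed = 5)
  expect_identical(s2$values, s3$values)
  expect_error(similaritySummary("CCO"), "at least two")
  # sampled mode is seeded-deterministic
  lib <- genSmilesLibrary(12, seed = 8)
  a <- similaritySummary(lib, exactLimit = 5, sampleSize = 200, seed = 3)
  b <- similaritySummary(lib, exactLimit = 5, sampleSize = 200, seed = 3)
  expect_identical(a$values, b$values)
})

test_that("morgan fingerprints distinguish structures and respect radius", {
  f1 <- morganFingerprint("c1ccccc1O")
  f2 <- morganFingerprint("Oc1ccccc1")
  expect_identical(f1, f2)                 # same molecule, same bits
  f3 <- morganFingerprint("CCCCCl")
  expect_lt(tanimoto(f1, f3), 0.3)
  expect_true(all(f1 >= 0 & f1 < 2048))
})

test_that("correlation matrices flag degenerate columns explicitly", {
  x <- c(1, 2, 3, 4)
  r <- correlationMatrix(data.frame(x = x, y = 2 * x + 1, z = -x))
  expect_equal(r["x", "y"], 1)
  expect_equal(r["x", "z"], -1)
  expect_equal(r, t(r))
  r2 <- correlationMatrix(data.frame(x = c(1, 2, 3), y = c(1, 3, 2)))
  expect_equal(r2["x", "y"], 0.5)
  rd <- correlationMatrix(data.frame(x = c(1, 2, 3), c = c(5, 5, 5)))
  expect_identical(attr(rd, "degenerate"), "c")
  expect_true(is.na(rd["x", "c"]))
  expect_error(correlationMatrix(data.frame(x = 1:2)), "length >= 3")
})

test_that("rule reports aggregate percentages from descriptor columns", {
  m <- computeDescriptors2D(c("CCO", "CC(=O)Nc1ccc(cc1)O",
                              "CC(C)Cc1ccc(cc1)C(C)C(=O)O"))
  rep <- ruleReport(m)
  expect_equal(nrow(rep$flags), 3L)
  expect_true(all(rep$summary$percent >= 0 & rep$summary$percent <= 100))
  # these three small drug-like molecules pass everything
  expect_equal(rep$summary$percent[rep$summary$rule ==
                                     "Complete Lipinski's rules"], 100)
  bad <- new("DescriptorMatrix",
             values = cbind(MW = c(300, 400)),
             compoundKeys = c("a", "b"), backend = "x", schema = "native")
  expect_error(ruleReport(bad), "missing rule columns")
})

test_that("pKi summaries report moments and histogram consistently", {
  set.seed(3)
  pk <- pmin(pmax(rnorm(500, 7), 4.2), 11)
  s <- pkiSummary(pk)
  expect_equal(s$n, 500L)
  expect_equal(sum(s$histogram$count), 500L)
  expect_gte(s$min, 4.2); expect_lte(s$max, 11)
})
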