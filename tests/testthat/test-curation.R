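test_that("within-source groups collapse to the mean or drop when discordant", {
  rs <- keyedSet(c("K1", "K1", "K2"), c(7.0, 7.05, 6.0), "A")
  d <- dedupeWithinSource(rs, threshold = 0.1)
  expect_equal(length(d), 2L)
  expect_equal(records(d)$pKi[records(d)$structure_key == "K1"], 7.025)

  wide <- keyedSet(c("K1", "K1"), c(7.0, 8.0), "A")
  expect_equal(length(dedupeWithinSource(wide, 0.1, "consistent")), 0L)
  med <- dedupeWithinSource(wide, 0.1, "median")
  expect_equal(records(med)$pKi, 7.5)

  uniq <- keyedSet(c("K1", "K2"), c(7, 6), "A")
  expect_identical(records(dedupeWithinSource(uniq, 0.1)), records(uniq))
})

test_that("cross-source pairs are found once per shared key with |delta|", {
  a <- keyedSet(c("K1", "K2"), c(7.5, 6.0), "A")
  b <- keyedSet(c("K2", "K3"), c(6.2, 8.0), "B")
  p <- findCrossPairs(a, b)
  expect_equal(nrow(p), 1L)
  expect_equal(p$structure_key, "K2")
  expect_equal(p$delta_pKi, 0.2)

  disjoint <- findCrossPairs(keyedSet("K1", 7, "A"), keyedSet("K9", 7, "B"))
  expect_equal(nrow(disjoint), 0L)

  p2 <- findCrossPairs(keyedSet("K1", 7.5, "A"), keyedSet("K1", 7.4, "B"))
  expect_equal(p2$delta_pKi, 0.1)

  dup <- keyedSet(c("K1", "K1"), c(7, 7), "A")
  expect_error(findCrossPairs(dup, b), "not deduplicated")
})

test_that("duplicate resolution follows the threshold rule on a hand fixture", {
  a <- keyedSet(c("K1", "K2", "K3"), c(7.00, 7.00, 6.5), "A")
  b <- keyedSet(c("K1", "K2", "K4"), c(7.05, 7.50, 8.0), "B")
  db <- resolveDuplicates(a, b, threshold = 0.1, priority = "A")
  ent <- entries(db)
  expect_setequal(ent$structure_key, c("K1", "K3", "K4"))
  expect_equal(ent$pKi[ent$structure_key == "K1"], 7.00)  # priority source
  expect_equal(ent$source[ent$structure_key == "K1"], "A")
  au <- auditCounts(db)
  expect_equal(au$pooled_total, 6L)
  expect_equal(au$pairs_total, 2L)
  expect_equal(au$pairs_discordant, 1L)
  expect_equal(au$final_uniques, 3L)
})

test_that("a pair at exactly the threshold difference is kept", {
  a <- keyedSet("K1", 7.5, "A")
  b <- keyedSet("K1", 7.4, "B")
  db <- resolveDuplicates(a, b, threshold = 0.1, priority = "A")
  expect_equal(length(db), 1L)
  expect_equal(entries(db)$pKi, 7.5)
})

test_that("disjoint sources concatenate and audit counts reconcile", {
  a <- keyedSet(c("K1", "K2"), c(7, 6), "A")
  b <- keyedSet(c("K3", "K4", "K5"), c(8, 5, 6), "B")
  db <- resolveDuplicates(a, b)
  expect_equal(length(db), 5L)
  expect_equal(auditCounts(db)$duplicate_records, 0L)
})

test_that("swapping priority changes surviving values, never the count", {
  set.seed(42)
  keys <- sprintf("K%02d", 1:20)
  a <- keyedSet(keys[1:12], rnorm(12, 7, 1), "A")
  b <- keyedSet(keys[5:20], rnorm(16, 7, 1), "B")
  dbA <- resolveDuplicates(a, b, priority = "A")
  dbB <- resolveDuplicates(a, b, priority = "B")
  expect_equal(length(dbA), length(dbB))
  pa <- duplicatePairs(dbA)
  conc <- pa$structure_key[!pa$discordant]
  entA <- entries(dbA); entB <- entries(dbB)
  expect_true(all(entA$source[entA$structure_key %in% conc] == "A"))
  expect_true(all(entB$source[entB$structure_key %in% conc] == "B"))
})

test_that("raising the threshold never decreases the final count", {
  set.seed(7)
  keys <- sprintf("K%02d", 1:30)
  a <- keyedSet(keys[1:20], rnorm(20, 7, 1), "A")
  b <- keyedSet(keys[10:30], rnorm(21, 7, 1), "B")
  counts <- vapply(c(0, 0.1, 0.5, 1, 2, 5),
                   function(th) length(resolveDuplicates(a, b, th)),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("curation count matches brute-force set arithmetic on random specs", {
  lib <- sprintf("K%03d", 1:120)   # plain keys; no chemistry needed
  set.seed(11)
  for (rep in 1:200) {
    nA <- sample(5:60, 1); nB <- sample(5:60, 1)
    nS <- sample(0:min(nA, nB), 1); nD <- if (nS > 0) sample(0:nS, 1) else 0L
    src <- genSources(nA, nB, nS, nD, threshold = 0.1,
                      seed = rep, smiles = lib)
    db <- resolveDuplicates(src$a, src$b, 0.1, priority = "ZINC")
    expect_equal(length(db), src$truth$expected_final)
    expect_equal(length(db), bruteForceCurationCount(src$a, src$b, 0.1))
    expect_equal(length(db), nA + nB - nS - nD)
  }
})
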