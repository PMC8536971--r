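# The descriptor engine is validated two ways: against a frozen reference
# table of standard-implementation values for six diverse molecules
# (spanning every implemented family), and against hand-derived values for
# simple graphs.

refMols <- c("CC(=O)Nc1ccc(cc1)O", "CC(=O)Oc1ccccc1C(=O)O",
             "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "Nc1ccc(cc1)S(=O)(=O)N",
             "[O-][N+](=O)c1ccc(cc1)Cl", "C1CC2CCC1C2")

test_that("engine reproduces the frozen reference descriptor values", {
  ref <- read.delim(test_path("descriptor-reference.tsv"), comment.char = "#")
  can <- canonicalKey(refMols)
  m <- computeDescriptors2D(can, keys = as.character(seq_along(can)))
  vals <- descriptorValues(m)
  ref <- ref[ref$descriptor %in% colnames(vals), ]
  got <- vals[cbind(ref$mol, match(ref$descriptor, colnames(vals)))]
  # logP/MR columns come from the reference Wildman-Crippen implementation
  isCrippen <- ref$descriptor %in% c("SLogP", "SMR", "Lipinski",
                                     "GhoseFilter")
  tol <- ifelse(isCrippen, 1e-4, 1e-6)
  ok <- abs(got - ref$value) <= pmax(tol, tol * abs(ref$value))
  if (!all(ok)) {
    bad <- head(ref[!ok, ], 10)
    fail(sprintf("descriptor mismatches: %s",
                 paste(bad$descriptor, collapse = ", ")))
  }
  expect_true(all(ok))
})

test_that("descriptor matrix follows the standard 2D schema of 1613 columns", {
  m <- computeDescriptors2D(c("CCO", "c1ccccc1"))
  expect_equal(ncol(m), 1613L)
  expect_identical(colnames(descriptorValues(m)), descriptorSchema())
})

test_that("hand-derived values hold on simple graphs", {
  m <- computeDescriptors2D(c("c1ccccc1", "CCO", "CCC"))
  v <- descriptorValues(m)
  # benzene
  expect_equal(unname(v[1, "nAromAtom"]), 6)
  expect_equal(unname(v[1, "nRing"]), 1)
  expect_equal(unname(v[1, "naRing"]), 1)
  expect_equal(unname(v[1, "nBondsA"]), 6)
  expect_equal(unname(v[1, "Zagreb1"]), 24)          # 6 atoms of degree 2
  expect_equal(unname(v[1, "ABC"]), 6 * sqrt(1 / 2)) # (2+2-2)/(2*2) per edge
  expect_equal(unname(v[1, "MW"]), 6 * 12 + 6 * 1.007825032, tolerance = 1e-9)
  expect_equal(unname(v[1, "WPath"]), 27)            # ring distance sum
  # ethanol: C-C-O
  expect_equal(unname(v[2, "nHeavyAtom"]), 3)
  expect_equal(unname(v[2, "nHBDon"]), 1)
  expect_equal(unname(v[2, "nHBAcc"]), 1)
  expect_equal(unname(v[2, "TopoPSA"]), 20.23)       # hydroxyl contribution
  expect_equal(unname(v[2, "WPath"]), 4)             # 1 + 1 + 2
  # propane: ABC = 2*sqrt((1+2-2)/2), ABCGG = 2*sqrt(1/2)
  expect_equal(unname(v[3, "ABC"]), 2 * sqrt(1 / 2))
  expect_equal(unname(v[3, "ABCGG"]), 2 * sqrt(1 / 2))
  # duplicate inputs give identical rows
  m2 <- computeDescriptors2D(c("CCO", "CCO"))
  v2 <- descriptorValues(m2)
  expect_identical(v2[1, ], v2[2, ])
})

test_that("preprocessing imputes, encodes and drops as specified", {
  vals <- cbind(a = c(1, NA, 3), b = c(5, 5, 5), c = c(NA, NA, NA),
                d = c(TRUE, FALSE, TRUE), e = c(0.1, 0.2, 0.3))
  m <- new("DescriptorMatrix", values = vals,
           compoundKeys = as.character(1:3), backend = "external",
           schema = "native")
  p <- preprocessDescriptors(m)
  pv <- descriptorValues(p)
  expect_equal(pv[, "a"], c(1, 2, 3))        # mean imputation
  expect_equal(pv[, "d"], c(1, 0, 1))        # boolean encoding
  expect_false("b" %in% colnames(pv))        # constant dropped
  expect_false("c" %in% colnames(pv))        # empty dropped
  prov <- provenance(p)
  expect_setequal(prov$dropped$column, c("b", "c"))
  expect_equal(prov$dropped$reason[prov$dropped$column == "b"], "constant")
  expect_equal(prov$dropped$reason[prov$dropped$column == "c"], "empty")
  # imputation preserves the observed-cell mean
  expect_equal(mean(pv[, "a"]), mean(c(1, 3, 2)))
  expect_error(preprocessDescriptors(
    new("DescriptorMatrix", values = cbind(x = c(2, 2, 2)),
        compoundKeys = as.character(1:3), backend = "external",
        schema = "native")), "all columns")
})

test_that("preprocessing is idempotent and never widens the matrix", {
  set.seed(31)
  vals <- matrix(rnorm(60), 10, 6,
                 dimnames = list(NULL, letters[1:6]))
  vals[sample(60, 8)] <- NA
  vals[, 6] <- 1
  m <- new("DescriptorMatrix", values = vals,
           compoundKeys = as.character(1:10), backend = "external",
           schema = "native")
  p1 <- preprocessDescriptors(m)
  p2 <- preprocessDescriptors(p1)
  expect_identical(descriptorValues(p1), descriptorValues(p2))
  expect_lte(ncol(p1), ncol(m))
  expect_equal(nrow(p1), nrow(m))
})

test_that("descriptor tables round-trip through the deposited layout", {
  m <- computeDescriptors2D(c("CCO", "CCN", "CCC"))
  pk <- c(7.1, 6.4, 5.2)
  f <- tempfile(fileext = ".txt")
  writeDescriptorTable(preprocessDescriptors(m), pk, f)
  back <- readDescriptorTable(f)
  expect_equal(back$pKi, pk)
  expect_equal(ncol(back$descriptors),
               ncol(preprocessDescriptors(m)))
})
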