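test_that("canonical keys identify molecules independently of atom order", {
  k <- canonicalKey(c("CCO", "OCC", "c1ccccc1O", "Oc1ccccc1", "CCN"))
  expect_identical(k[1], k[2])
  expect_identical(k[3], k[4])
  expect_false(k[1] == k[5])
  # idempotent under re-canonicalization
  expect_identical(canonicalKey(k[1]), k[1])
})

test_that("stereo-aware keys separate enantiomers; agnostic mode merges them", {
  ena <- c("C[C@H](N)O", "C[C@@H](N)O")
  expect_false(canonicalKey(ena[1]) == canonicalKey(ena[2]))
  agn <- canonicalKey(ena, stereo = FALSE)
  expect_identical(agn[1], agn[2])
})

test_that("salt stripping and neutralization normalize the key", {
  expect_identical(canonicalKey("CC(=O)[O-].[Na+]", neutralize = TRUE),
                   canonicalKey("CC(=O)O"))
  expect_identical(canonicalKey("c1ccccc1O.Cl"), canonicalKey("Oc1ccccc1"))
})

test_that("unparseable SMILES raise an error naming the offender", {
  expect_error(canonicalKey(c("CCO", "not_a_smiles!!")), "not_a_smiles")
  expect_identical(is.na(canonicalKey("][", onError = "na")), TRUE)
})

test_that("InChIKey mode gives the hashed-InChI identity", {
  k <- canonicalKey(c("CCO", "OCC", "CCN"), as = "inchikey")
  expect_identical(k[1], k[2])
  expect_false(k[1] == k[3])
  expect_match(k[1], "^[A-Z]{14}-[A-Z]{10}-[A-Z]$")
})

test_that("SMILES-format files load with trailing pKi column", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("CCO\tmol1\t7.2", "c1ccccc1\tmol2\t6.0", "CCN\t5.5"), f)
  rs <- loadRecords(f, "smi", sourceId = "SMI")
  expect_equal(length(rs), 3L)
  expect_setequal(records(rs)$pKi, c(7.2, 6.0, 5.5))
})

test_that("Ki converts to pKi on the molar scale", {
  expect_equal(kiToPKi(10, "nM"), 8)
  expect_equal(kiToPKi(1, "M"), 0)
  expect_equal(kiToPKi(1, "uM"), 6)
})

test_that("CSV loading keeps parseable rows and logs rejections", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("smiles,pKi", "CCO,7.1", "CCN,6.5", "c1ccccc1,5.9",
               "CCC,N/A", "@@bad@@,7.0"), f)
  rs <- loadRecords(f, "csv", sourceId = "T")
  expect_s4_class(rs, "BioactivitySet")
  expect_equal(length(rs), 3L)
  rej <- rejected(rs)
  expect_equal(nrow(rej), 2L)
  expect_true(any(grepl("non-numeric", rej$reason)))
  expect_true(any(grepl("unparseable", rej$reason)))

  empty <- tempfile(fileext = ".csv")
  writeLines("smiles,pKi", empty)
  expect_error(loadRecords(empty, "csv", sourceId = "T"), "no rows")
})

test_that("records round-trip through CSV at full precision", {
  rs <- keyedSet(c("CCO", "CCN", "CCC"), c(7.123456789012345, 6.5, 5.9), "S")
  f <- tempfile(fileext = ".csv")
  writeRecords(rs, f)
  back <- loadRecords(f, "csv", sourceId = "S")
  expect_equal(length(back), length(rs))
  expect_setequal(records(back)$structure_key, records(rs)$structure_key)
  expect_equal(sort(records(back)$pKi), sort(records(rs)$pKi),
               tolerance = 0)
})

test_that("implausible pKi values are flagged but never dropped", {
  expect_warning(rs <- keyedSet(c("CCO", "CCN"), c(7, 15.2), "S"),
                 "suspect")
  expect_equal(length(rs), 2L)
})

test_that("SDF input is readable with a pKi data field", {
  sdf <- ChemmineR::smiles2sdf(c(m1 = "CCO", m2 = "c1ccccc1"))
  ChemmineR::datablock(sdf) <- list(c(pKi = "7.2"), c(pKi = "6.1"))
  f <- tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(sdf, f)
  rs <- loadRecords(f, "sdf", sourceId = "SDF")
  expect_equal(length(rs), 2L)
  expect_setequal(records(rs)$pKi, c(7.2, 6.1))
})
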