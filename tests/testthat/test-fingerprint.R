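test_that("tanimoto matches hand-counted values and edge conventions", {
  fp <- fingerprint(c(1, 2, 3, 4))
  expect_identical(tanimoto(fp, fp), 1)
  expect_identical(tanimoto(fingerprint(0:3), fingerprint(10:13)), 0)
  # |{3,4}| / |{1..8}| = 2/8
  expect_identical(tanimoto(fingerprint(1:4), fingerprint(3:8)), 0.25)
  # empty-vs-empty is a convention, not a computation
  expect_identical(tanimoto(fingerprint(), fingerprint()), 0)
  expect_identical(tanimoto(fingerprint(), fingerprint(), empty = NA_real_),
                   NA_real_)
  expect_error(tanimoto(fingerprint(1, nbits = 64), fingerprint(1)),
               class = "ChemLinker_invalid_input")
})

test_that("popcount bound evaluates exactly and rejects negatives", {
  expect_identical(maxAttainableSimilarity(10, 10), 1)
  expect_equal(maxAttainableSimilarity(5, 15), 5 / 15)
  expect_identical(maxAttainableSimilarity(0, 7), 0)
  expect_identical(maxAttainableSimilarity(7, 0), 0)
  expect_error(maxAttainableSimilarity(-1, 5),
               class = "ChemLinker_invalid_input")
})

test_that("tanimoto never exceeds the popcount bound; equality at containment", {
  set.seed(11)
  for (i in 1:500) {
    fps <- randomFps(2, seed = i)
    s <- tanimoto(fps[[1]], fps[[2]])
    expect_lte(s, maxAttainableSimilarity(popcount(fps[[1]]),
                                          popcount(fps[[2]])))
    expect_gte(s, 0); expect_lte(s, 1)
    expect_identical(s, tanimoto(fps[[2]], fps[[1]]))
  }
  # containment attains the bound
  big <- fingerprint(0:49)
  small <- fingerprint(0:19)
  expect_identical(tanimoto(big, small),
                   maxAttainableSimilarity(50, 20))
})

test_that("hex serialization round-trips and flags malformed input", {
  fps <- c(list(fingerprint(), fingerprint(c(0, 7, 165)),
                fingerprint(0:165)),
           randomFps(20, seed = 3))
  for (fp in fps) {
    hex <- fpToHex(fp)
    expect_identical(nchar(hex), 42L)
    back <- hexToFp(hex)
    expect_identical(back@onBits, fp@onBits)
  }
  expect_error(hexToFp("zz"), class = "ChemLinker_invalid_input")
  expect_error(hexToFp(strrep("f", 42)), class = "ChemLinker_invalid_input")
})

test_that("hash fingerprinting is deterministic and rejects empty input", {
  a <- hashFingerprint("CC(=O)Oc1ccccc1C(=O)O")
  b <- hashFingerprint("CC(=O)Oc1ccccc1C(=O)O")
  expect_identical(a@onBits, b@onBits)
  expect_identical(a@nbits, 166L)
  expect_gt(popcount(a), 0L)
  expect_error(hashFingerprint(""), class = "ChemLinker_query_error")
})

test_that("bitcount index buckets by popcount, preserving input order", {
  expect_length(buildBitcountIndex(list())@buckets, 0L)
  fps <- list(x = fingerprint(0:3), y = fingerprint(10:13),
              z = fingerprint(0:6))
  idx <- buildBitcountIndex(fps)
  expect_named(idx@buckets, c("4", "7"))
  expect_identical(idx@buckets[["4"]], c(1L, 2L))
  expect_identical(idx@buckets[["7"]], 3L)
  expect_true(validObject(idx))
  # re-indexing is deterministic
  expect_identical(idx, buildBitcountIndex(fps))
  expect_error(buildBitcountIndex(list(a = fingerprint(1, nbits = 64),
                                       b = fingerprint(1))),
               class = "ChemLinker_invalid_input")
})
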