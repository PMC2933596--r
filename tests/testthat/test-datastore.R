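# Minimal hand-built store: two compounds, optionally extra tables.
writeTinyStore <- function(dir, extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp1 <- fingerprint(0:9); fp2 <- fingerprint(5:30)
  writeLines(c("compound_id\tsmiles\tfingerprint_hex\tpopcount",
               paste("c1", "CCO", fpToHex(fp1), popcount(fp1), sep = "\t"),
               paste("c2", "CCN", fpToHex(fp2), popcount(fp2), sep = "\t")),
             file.path(dir, "compounds.tsv"))
  for (nm in names(extra)) writeLines(extra[[nm]], file.path(dir, nm))
  dir
}

test_that("a generated fixture store loads with zero validation issues", {
  store <- loadStore(sharedStoreDir())
  expect_s4_class(store, "DataStore")
  expect_identical(nrow(validateStore(store)), 0L)
  expect_true(validObject(store@index))
})

test_that("a store with only compounds.tsv loads; relational tables are empty", {
  dir <- writeTinyStore(tempfile("tiny"))
  store <- loadStore(dir)
  expect_identical(nrow(store@compounds), 2L)
  expect_identical(nrow(store@assays), 0L)
  expect_identical(nrow(store@outcomes), 0L)
  expect_identical(nrow(store@drugs), 0L)
  expect_identical(length(store@conformers), 0L)
  expect_identical(length(store@geneDisease), 0L)
  expect_identical(nrow(validateStore(store)), 0L)
})

test_that("missing compounds.tsv is fatal", {
  dir <- tempfile("nostore"); dir.create(dir)
  expect_error(loadStore(dir), class = "ChemLinker_store_error")
})

test_that("dangling compound references are load errors naming the offender", {
  dir <- writeTinyStore(tempfile("dangling"), extra = list(
    "assays.tsv" = c("assay_id\tname\tdescription", "a1\tA\tdesc"),
    "outcomes.tsv" = c("assay_id\tcompound_id\toutcome\tscore",
                       "a1\tGHOST\tactive\t1")))
  expect_error(loadStore(dir), "GHOST", class = "ChemLinker_store_error")
})

test_that("unknown outcome words are rejected at load", {
  dir <- writeTinyStore(tempfile("vocab"), extra = list(
    "assays.tsv" = c("assay_id\tname\tdescription", "a1\tA\tdesc"),
    "outcomes.tsv" = c("assay_id\tcompound_id\toutcome\tscore",
                       "a1\tc1\tACTIVE-ISH\t1")))
  expect_error(loadStore(dir), "ACTIVE-ISH", class = "ChemLinker_store_error")
})

test_that("malformed rows are reported with file and line", {
  dir <- writeTinyStore(tempfile("malformed"), extra = list(
    "assays.tsv" = c("assay_id\tname\tdescription", "a1\tonly-two-fields")))
  expect_error(loadStore(dir), "assays.tsv:2", class = "ChemLinker_store_error")
})

test_that("validateStore reports planted inconsistencies as data, not errors", {
  store <- loadStore(sharedStoreDir())
  # out-of-range gene-disease score
  broken <- store
  broken@geneDisease[1, 1] <- 1.5
  iss <- validateStore(broken)
  expect_gt(nrow(iss), 0L)
  expect_true(any(grepl("1.5", iss$issue, fixed = TRUE)))
  expect_true(any(grepl(rownames(broken@geneDisease)[1], iss$issue)))
  # duplicate assay id
  broken2 <- store
  broken2@assays <- rbind(broken2@assays, broken2@assays[1, ])
  iss2 <- validateStore(broken2)
  expect_true(any(grepl(broken2@assays$assay_id[1], iss2$issue)))
})

test_that("conformers load equivalently from the TSV dialect and SDF", {
  skip_if_not_installed("ChemmineR")
  conf <- round(randomConformer(5, seed = 4), 4)
  tsv <- paste(apply(conf, 1, function(r) paste(r, collapse = ":")),
               collapse = ";")
  dirA <- writeTinyStore(tempfile("ctsv"), extra = list(
    "conformers.tsv" = c("compound_id\tcoords", paste0("c1\t", tsv))))
  # V2000 molfile with the compound id on the title line
  atoms <- apply(conf, 1, function(r)
    sprintf("%10.4f%10.4f%10.4f C   0  0  0  0  0  0  0  0  0  0  0  0",
            r[1], r[2], r[3]))
  sdf <- c("c1", "  synthetic", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", 5L, 1L),
           atoms, "  1  2  1  0  0  0  0", "M  END", "$$$$")
  dirB <- writeTinyStore(tempfile("csdf"), extra = list("conformers.sdf" = sdf))
  a <- loadStore(dirA); b <- loadStore(dirB)
  expect_equal(unname(a@conformers[["c1"]]), unname(b@conformers[["c1"]]),
               tolerance = 1e-8)
  expect_equal(a@shapes[, "c1"], b@shapes[, "c1"], tolerance = 1e-8)
})
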