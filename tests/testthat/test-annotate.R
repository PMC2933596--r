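test_that("GO extraction finds exact phrases with correct spans", {
  lex <- tinyLexicon()[1:2, ]
  text <- "Inhibitors of apoptosis in the cell cycle"
  m <- extractGOTerms(text, lex)
  expect_identical(m$go_id, c("GO:0006915", "GO:0007049"))
  expect_identical(m$matched_text, c("apoptosis", "cell cycle"))
  # spans are 0-based half-open and slice back to the matched text
  for (i in seq_len(nrow(m)))
    expect_identical(tolower(substr(text, m$start[i] + 1, m$end[i])),
                     tolower(m$matched_text[i]))
  expect_identical(nrow(extractGOTerms("", lex)), 0L)
  expect_identical(nrow(extractGOTerms("nothing relevant here", lex)), 0L)
})

test_that("overlaps resolve longest-first, then leftmost", {
  lex <- tinyLexicon()  # contains both "cell" and "cell cycle"
  m <- extractGOTerms("cell cycle arrest", lex)
  expect_identical(m$go_id, "GO:0007049")
  expect_identical(m$matched_text, "cell cycle")
  # a lone "cell" elsewhere still matches
  m2 <- extractGOTerms("the cell divides; cell cycle stops", lex)
  expect_identical(m2$go_id, c("GO:0008150", "GO:0007049"))
  expect_true(all(diff(m2$start) > 0))
})

test_that("matching is case-insensitive and respects word boundaries", {
  lex <- tinyLexicon()[1, , drop = FALSE]
  expect_identical(extractGOTerms("APOPTOSIS assay", lex)$go_id, "GO:0006915")
  # embedded in a longer word: no match
  expect_identical(nrow(extractGOTerms("antiapoptosism", lex)), 0L)
})

test_that("genesToDiseases filters, aggregates by max and sorts deterministically", {
  mat <- matrix(c(0.9, 0.3,
                  0.6, 0.2), nrow = 2, byrow = TRUE,
                dimnames = list(c("G1", "G2"), c("D1", "D2")))
  out <- genesToDiseases("G1", mat, 0.5)
  expect_identical(out$disease, "D1")
  expect_identical(out$score, 0.9)
  expect_identical(out$genes, "G1")
  expect_identical(nrow(genesToDiseases(character(0), mat, 0.5)), 0L)
  # max aggregation with the full supporting gene set
  mat2 <- matrix(c(0.6, 0.8), nrow = 2,
                 dimnames = list(c("G1", "G2"), "D1"))
  out2 <- genesToDiseases(c("G1", "G2"), mat2, 0.5)
  expect_identical(out2$score, 0.8)
  expect_setequal(strsplit(out2$genes, ",")[[1]], c("G1", "G2"))
  # unknown genes are skipped, case-insensitive lookup works
  expect_identical(genesToDiseases(c("g1", "NOPE"), mat, 0.5)$disease, "D1")
})

test_that("scores never exceed the matrix maximum; raising the floor only removes", {
  set.seed(17)
  mat <- matrix(runif(100), 10, 10,
                dimnames = list(sprintf("G%d", 1:10), sprintf("D%d", 1:10)))
  genes <- sprintf("G%d", c(2, 5, 9))
  prev <- NULL
  for (floor_ in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    out <- genesToDiseases(genes, mat, floor_)
    if (nrow(out))
      expect_true(all(out$score <= max(mat[genes, ])))
    if (!is.null(prev)) expect_true(all(out$disease %in% prev))
    prev <- out$disease
  }
})

test_that("assayToDiseases composes the full 4-link chain on a planted fixture", {
  store <- loadStore(sharedStoreDir())
  m <- readManifest(sharedStoreDir())
  ch <- m$chains[[1]]
  assay <- store@assays[store@assays$assay_id == ch$active_assay, ]
  ann <- assayToDiseases(assay, store)
  expect_gte(length(ann), 1L)
  hit <- Filter(function(a) a$disease == ch$disease, ann)
  expect_length(hit, 1L)
  expect_equal(hit[[1]]$score, ch$disease_score)
  expect_true(ch$gene %in% hit[[1]]$genes)
  chain <- hit[[1]]$provenance[[1]]
  expect_length(chain, 4L)
  expect_identical(vapply(chain, `[[`, character(1), "kind"),
                   c("assay", "go_term", "gene", "disease"))
  expect_identical(chain[[1]]$id, ch$active_assay)
  expect_identical(chain[[2]]$id, ch$go_id)
  expect_identical(chain[[4]]$id, ch$disease)
  # a description with no lexicon term yields nothing
  blank <- list(assay_id = "x", description = "entirely unrelated words")
  expect_length(assayToDiseases(blank, store), 0L)
})

test_that("masking a lexicon term removes exactly the chains through it", {
  store <- loadStore(sharedStoreDir())
  m <- readManifest(sharedStoreDir())
  ch <- m$chains[[1]]
  assay <- store@assays[store@assays$assay_id == ch$active_assay, ]
  before <- assayToDiseases(assay, store)
  masked <- store
  masked@goLexicon <- masked@goLexicon[masked@goLexicon$go_id != ch$go_id, ]
  after <- assayToDiseases(assay, masked)
  lostGo <- function(anns) unlist(lapply(anns, function(a)
    lapply(a$provenance, function(chain) chain[[2]]$id)))
  expect_true(ch$go_id %in% lostGo(before))
  expect_false(ch$go_id %in% lostGo(after))
})
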