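sharedReport <- local({
  rep <- NULL
  function() {
    if (is.null(rep)) {
      store <- loadStore(sharedStoreDir())
      m <- readManifest(sharedStoreDir())
      rep <<- runQuery(m$query_smiles, store, conformer = m$query_conformer)
    }
    rep
  }
})

test_that("outcome partitioning routes pairs by outcome and drops inconclusives", {
  hits <- data.frame(compound_id = c("c1", "c2"), similarity = c(0.9, 0.88),
                     stringsAsFactors = FALSE)
  outcomes <- data.frame(
    assay_id = c("A1", "A2", "A3"),
    compound_id = c("c1", "c1", "c2"),
    outcome = c("active", "inactive", "inconclusive"),
    score = c("10", "2", ""), stringsAsFactors = FALSE)
  parts <- partitionOutcomes(hits, outcomes)
  expect_identical(parts$active$compound_id, "c1")
  expect_identical(parts$active$assay_id, "A1")
  expect_identical(parts$inactive$assay_id, "A2")
  # c2 had only an inconclusive outcome: in neither partition
  expect_false("c2" %in% c(parts$active$compound_id,
                           parts$inactive$compound_id))
  empty <- partitionOutcomes(hits[0, ], outcomes)
  expect_identical(nrow(empty$active), 0L)
  expect_identical(nrow(empty$inactive), 0L)
})

test_that("a planted-chain query surfaces every planted finding in its section", {
  m <- readManifest(sharedStoreDir())
  rep <- sharedReport()
  s <- reportSections(rep)
  expect_identical(names(s), c("predictive_models", "active_similars",
                               "chemogenomics_similars", "systems_similars",
                               "literature_similars", "inactive_similars"))
  for (ch in m$chains) {
    act <- Filter(function(h) h$compound_id == ch$compound_id &&
                    h$assay_id == ch$active_assay, s$active_similars$assay_hits)
    expect_length(act, 1L)
    expect_equal(act[[1]]$similarity, ch$similarity)
    dis <- Filter(function(d) d$disease == ch$disease, act[[1]]$diseases)
    expect_length(dis, 1L)
    expect_equal(dis[[1]]$score, ch$disease_score)
    ina <- Filter(function(h) h$assay_id == ch$inactive_assay,
                  s$inactive_similars$assay_hits)
    expect_length(ina, 1L)
    expect_true(ch$drug_id %in% vapply(s$active_similars$drug_hits, `[[`,
                                       character(1), "drug_id"))
    expect_true(ch$compound_id %in%
                  vapply(s$chemogenomics_similars$hits, `[[`, character(1),
                         "compound_id"))
    expect_true(ch$pathway_id %in%
                  vapply(s$systems_similars$hits, `[[`, character(1),
                         "pathway_id"))
    expect_true(ch$paper_id %in%
                  vapply(s$literature_similars$hits, `[[`, character(1),
                         "paper_id"))
  }
  # 3D: planted rigid copy of the query conformer ranks first
  nb <- s$active_similars$neighbors3d
  expect_identical(nb$compound_id[1], m$planted_3d_neighbor)
  expect_lt(nb$distance[1], 1e-8)
  # no decoy below the threshold appears as a similarity hit (the 3D
  # neighbour list is k-nearest by shape, unconstrained by the threshold)
  doc <- xml2::read_xml(reportToXML(rep))
  hitIds <- xml2::xml_attr(
    xml2::xml_find_all(doc, "//*[@similarity and @compound_id]"),
    "compound_id")
  expect_false(any(grepl("^CDEC", hitIds)))
})

test_that("no reported similarity falls below the configured threshold", {
  rep <- sharedReport()
  th <- rep@metadata$config$similarity_threshold
  xml <- xml2::read_xml(reportToXML(rep))
  sims <- as.numeric(xml2::xml_attr(
    xml2::xml_find_all(xml, "//*[@similarity]"), "similarity"))
  expect_true(all(sims >= th))
})

test_that("a query dissimilar to the whole store yields six present, empty-hit sections", {
  dir <- file.path(tempdir(), "chemlinker-nochain-store")
  if (!dir.exists(dir))
    generateFixtureStore(fixtureSpec(seed = 9L, plantedChains = list()), dir)
  store <- loadStore(dir)
  m <- readManifest(dir)
  rep <- runQuery(m$query_smiles, store)
  s <- reportSections(rep)
  expect_length(s, 6L)
  expect_length(s$active_similars$assay_hits, 0L)
  expect_length(s$active_similars$drug_hits, 0L)
  expect_length(s$chemogenomics_similars$hits, 0L)
  expect_length(s$systems_similars$hits, 0L)
  expect_length(s$literature_similars$hits, 0L)
  expect_length(s$inactive_similars$assay_hits, 0L)
  # the predictor section is populated regardless
  expect_identical(nrow(s$predictive_models$predictions), 40L)
})

test_that("a query identical to a stored compound is reported at similarity 1.0", {
  m <- readManifest(sharedStoreDir())
  rep <- sharedReport()
  ch1 <- Filter(function(ch) ch$similarity == 1.0, m$chains)[[1]]
  hits <- reportSections(rep)$active_similars$assay_hits
  self <- Filter(function(h) h$compound_id == ch1$compound_id, hits)
  expect_gte(length(self), 1L)
  expect_identical(self[[1]]$similarity, 1)
})

test_that("XML has six section elements, is well-formed, and round-trips bytes", {
  rep <- sharedReport()
  txt <- reportToXML(rep)
  doc <- xml2::read_xml(txt)  # parse failure would throw
  kids <- xml2::xml_name(xml2::xml_children(doc))
  expect_identical(setdiff(kids, c("metadata", "query")),
                   c("predictive_models", "active_similars",
                     "chemogenomics_similars", "systems_similars",
                     "literature_similars", "inactive_similars"))
  expect_identical(as.character(doc), txt)
  # empty report round-trips too
  dir <- file.path(tempdir(), "chemlinker-nochain-store")
  if (!dir.exists(dir))
    generateFixtureStore(fixtureSpec(seed = 9L, plantedChains = list()), dir)
  m <- readManifest(dir)
  rep0 <- runQuery(m$query_smiles, loadStore(dir))
  txt0 <- reportToXML(rep0)
  expect_identical(as.character(xml2::read_xml(txt0)), txt0)
})

test_that("XML and JSON carry identical (section, compound, similarity) triples", {
  rep <- sharedReport()
  doc <- xml2::read_xml(reportToXML(rep))
  xmlTriples <- do.call(rbind, lapply(
    c("active_similars", "chemogenomics_similars", "systems_similars",
      "inactive_similars"),
    function(sec) {
      nodes <- xml2::xml_find_all(
        doc, sprintf("/report/%s/*[@compound_id and @similarity]", sec))
      if (!length(nodes)) return(NULL)
      data.frame(section = sec,
                 compound_id = xml2::xml_attr(nodes, "compound_id"),
                 similarity = as.numeric(xml2::xml_attr(nodes, "similarity")),
                 stringsAsFactors = FALSE)
    }))
  j <- jsonlite::fromJSON(reportToJSON(rep), simplifyVector = FALSE)
  fromList <- function(sec, entries) {
    if (!length(entries)) return(NULL)
    data.frame(section = sec,
               compound_id = vapply(entries, `[[`, character(1),
                                    "compound_id"),
               similarity = vapply(entries, `[[`, numeric(1), "similarity"),
               stringsAsFactors = FALSE)
  }
  js <- j$sections
  jsonTriples <- rbind(
    fromList("active_similars", c(js$active_similars$assay_hits,
                                  js$active_similars$drug_hits)),
    fromList("chemogenomics_similars", js$chemogenomics_similars),
    fromList("systems_similars", js$systems_similars),
    fromList("inactive_similars", c(js$inactive_similars$assay_hits,
                                    js$inactive_similars$drug_hits)))
  key <- function(df) sort(paste(df$section, df$compound_id,
                                 signif(df$similarity, 12)))
  expect_identical(key(xmlTriples), key(jsonTriples))
})

test_that("runQuery is deterministic for fixed store bytes, config and smiles", {
  store <- loadStore(sharedStoreDir())
  m <- readManifest(sharedStoreDir())
  r1 <- runQuery(m$query_smiles, store, conformer = m$query_conformer)
  r2 <- runQuery(m$query_smiles, store, conformer = m$query_conformer)
  expect_identical(reportToXML(r1), reportToXML(r2))
  expect_identical(reportToJSON(r1), reportToJSON(r2))
})

test_that("removing one table empties only its corresponding section", {
  src <- sharedStoreDir()
  dir <- tempfile("ablate")
  dir.create(dir)
  file.copy(list.files(src, full.names = TRUE), dir)
  unlink(file.path(dir, "pathways.tsv"))
  m <- readManifest(dir)
  full <- runQuery(m$query_smiles, loadStore(src))
  cut <- runQuery(m$query_smiles, loadStore(dir))
  jf <- jsonlite::fromJSON(reportToJSON(full), simplifyVector = FALSE)$sections
  jc <- jsonlite::fromJSON(reportToJSON(cut), simplifyVector = FALSE)$sections
  expect_length(jc$systems_similars, 0L)
  for (sec in setdiff(names(jf), "systems_similars"))
    expect_identical(jc[[sec]], jf[[sec]])
})

test_that("sections truncate to the configured cap by rank", {
  store <- loadStore(sharedStoreDir())
  m <- readManifest(sharedStoreDir())
  cfg <- engineConfig(maxHitsPerSection = 1L)
  rep <- runQuery(m$query_smiles, store, cfg)
  s <- reportSections(rep)
  expect_lte(length(s$chemogenomics_similars$hits), 1L)
  expect_lte(length(s$active_similars$assay_hits) +
               length(s$active_similars$drug_hits), 1L)
  # rank order: the kept assay hit is the top-similarity one
  if (length(s$active_similars$assay_hits))
    expect_equal(s$active_similars$assay_hits[[1]]$similarity, 1.0)
})

test_that("an unusable query SMILES raises a query error", {
  store <- loadStore(sharedStoreDir())
  expect_error(runQuery("", store), class = "ChemLinker_query_error")
})

test_that("config files round-trip through the flat key = value dialect", {
  path <- tempfile(fileext = ".conf")
  writeLines(c("# engine settings", "similarity_threshold = 0.7",
               "strict_threshold = true", "k_3d = 5",
               "predictor = reference"), path)
  cfg <- readEngineConfig(path)
  expect_identical(cfg@similarityThreshold, 0.7)
  expect_true(cfg@strictThreshold)
  expect_identical(cfg@k3d, 5L)
  expect_identical(cfg@redThreshold, 0.7)  # untouched default
  expect_error(readEngineConfig(tempfile()), class = "ChemLinker_store_error")
  writeLines("not_a_key = 1", path)
  expect_error(readEngineConfig(path), class = "ChemLinker_store_error")
})
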