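#' Route similarity hits through bioassay outcomes
#'
#' Joins 2D similarity hits to the outcome table: every (hit, assay) pair
#' is routed to the active or inactive partition by its recorded outcome;
#' inconclusive outcomes are excluded from both. Associations keep the hit
#' similarity and the assay linkage.
#'
#' @param hits Data frame from [search2D()] (\code{compound_id},
#'   \code{similarity}).
#' @param outcomes Outcome table (\code{assay_id}, \code{compound_id},
#'   \code{outcome}, \code{score}).
#' @return List with data frames \code{active} and \code{inactive}, each
#'   with columns \code{compound_id}, \code{similarity}, \code{assay_id},
#'   \code{outcome}, \code{score}.
#' @export
partitionOutcomes <- function(hits, outcomes) {
  empty <- data.frame(compound_id = character(0), similarity = numeric(0),
                      assay_id = character(0), outcome = character(0),
                      score = character(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L || nrow(outcomes) == 0L)
    return(list(active = empty, inactive = empty))
  joined <- merge(hits, outcomes, by = "compound_id")
  joined <- joined[joined$outcome %in% c("active", "inactive"), , drop = FALSE]
  joined <- joined[order(-joined$similarity, joined$compound_id,
                         joined$assay_id, method = "radix"), , drop = FALSE]
  rownames(joined) <- NULL
  cols <- c("compound_id", "similarity", "assay_id", "outcome", "score")
  list(active = joined[joined$outcome == "active", cols, drop = FALSE],
       inactive = joined[joined$outcome == "inactive", cols, drop = FALSE])
}

.assayHitEntries <- function(part, store, config) {
  if (nrow(part) == 0L) return(list())
  out <- vector("list", nrow(part))
  for (i in seq_len(nrow(part))) {
    aid <- part$assay_id[i]
    arow <- store@assays[store@assays$assay_id == aid, , drop = FALSE]
    diseases <- if (nrow(arow))
      assayToDiseases(arow[1L, ], store, config) else list()
    out[[i]] <- list(compound_id = part$compound_id[i],
                     similarity = part$similarity[i],
                     assay_id = aid,
                     assay_name = if (nrow(arow)) arow$name[1L] else "",
                     score = part$score[i],
                     diseases = diseases)
  }
  out
}

.drugHitEntries <- function(hits, store, config) {
  if (nrow(hits) == 0L || nrow(store@drugs) == 0L) return(list())
  joined <- merge(hits, store@drugs, by = "compound_id")
  if (nrow(joined) == 0L) return(list())
  joined <- joined[order(-joined$similarity, joined$drug_id,
                         method = "radix"), , drop = FALSE]
  out <- vector("list", nrow(joined))
  for (i in seq_len(nrow(joined))) {
    go <- extractGOTerms(joined$usage_description[i], store@goLexicon)
    diseases <- .textToDiseases("drug", joined$drug_id[i],
                                joined$usage_description[i], store, config)
    out[[i]] <- list(drug_id = joined$drug_id[i],
                     compound_id = joined$compound_id[i],
                     similarity = joined$similarity[i],
                     name = joined$name[i],
                     usage_description = joined$usage_description[i],
                     source = joined$source[i],
                     go_terms = go$go_id,
                     diseases = diseases)
  }
  out
}

.relationEntries <- function(hits, table, cols) {
  if (nrow(hits) == 0L || nrow(table) == 0L) return(list())
  joined <- merge(hits, table, by = "compound_id")
  if (nrow(joined) == 0L) return(list())
  joined <- joined[order(-joined$similarity, joined$compound_id,
                         method = "radix"), , drop = FALSE]
  lapply(seq_len(nrow(joined)), function(i)
    c(list(compound_id = joined$compound_id[i],
           similarity = joined$similarity[i]),
      as.list(joined[i, cols, drop = FALSE])))
}

.literatureEntries <- function(hits, store) {
  if (nrow(hits) == 0L || nrow(store@literature) == 0L) return(list())
  sims <- stats::setNames(hits$similarity, hits$compound_id)
  out <- list()
  for (i in seq_len(nrow(store@literature))) {
    row <- store@literature[i, ]
    cids <- strsplit(row$compound_ids, ";", fixed = TRUE)[[1]]
    cids <- intersect(cids, names(sims))
    if (length(cids) == 0L) next
    cids <- cids[order(-sims[cids], cids, method = "radix")]
    text <- paste(row$title, row$abstract)
    go <- extractGOTerms(text, store@goLexicon)
    out[[length(out) + 1L]] <-
      list(paper_id = row$paper_id, title = row$title,
           best_similarity = max(sims[cids]),
           compounds = data.frame(compound_id = cids,
                                  similarity = as.numeric(sims[cids]),
                                  stringsAsFactors = FALSE),
           go_terms = go$go_id)
  }
  if (length(out) == 0L) return(out)
  o <- order(-vapply(out, `[[`, numeric(1), "best_similarity"),
             vapply(out, `[[`, character(1), "paper_id"), method = "radix")
  out[o]
}

.capList <- function(x, cap, what) {
  if (length(x) > cap) {
    clNotice("%s truncated from %d to %d entries (rank order)",
             what, length(x), cap)
    x <- x[seq_len(cap)]
  }
  x
}

#' Run one query through the whole engine
#'
#' Fingerprints the query SMILES (with [hashFingerprint()] unless a
#' fingerprint is supplied), performs the bound-pruned 2D similarity
#' search over the compound table at the configured threshold, and
#' assembles the six-section aggregate report: the configured activity
#' predictor; active bioassay associations with assay -> GO -> gene ->
#' disease annotations, plus drug hits (usage descriptions GO-tagged and
#' disease-annotated the same way) and, when a query conformer is given,
#' the k nearest 3D shape neighbours; chemical-gene/disease relations;
#' pathway relations; literature hits (one entry per paper, its matching
#' compounds collapsed, titles/abstracts GO-tagged); and inactive bioassay
#' associations. All six sections are always present, possibly empty;
#' missing optional tables degrade to empty sections with logged notices.
#'
#' @param smiles Non-empty query SMILES string.
#' @param store A [DataStore-class].
#' @param config An [EngineConfig-class].
#' @param conformer Optional query conformer (n x 3 matrix) enabling the
#'   3D neighbour annotation; when absent the 3D part is omitted with a
#'   logged notice.
#' @param fp Optional precomputed query [Fingerprint-class] (a
#'   real-chemistry fingerprinting backend plugs in here).
#' @param timestamp Optional character timestamp recorded in the report
#'   metadata; empty by default so identical inputs give bit-identical
#'   reports.
#' @return An [AggregateReport-class].
#' @examples
#' \dontrun{
#' store <- loadStore("store")
#' rep <- runQuery("CC(=O)Oc1ccccc1C(=O)O", store)
#' }
#' @export
runQuery <- function(smiles, store, config = engineConfig(),
                     conformer = NULL, fp = NULL, timestamp = "") {
  stopifnot(is(store, "DataStore"), is(config, "EngineConfig"))
  if (is.null(fp)) fp <- hashFingerprint(smiles, config@fingerprintLength)
  hits <- search2D(fp, store@index, config@similarityThreshold,
                   strict = config@strictThreshold)
  cap <- config@maxHitsPerSection

  predictor <- getPredictor(config@predictor)
  predictions <- predictor$predict(smiles, fp, config)

  parts <- partitionOutcomes(hits, store@outcomes)
  activeAssay <- .assayHitEntries(parts$active, store, config)
  inactiveAssay <- .assayHitEntries(parts$inactive, store, config)
  drugHits <- .drugHitEntries(hits, store, config)

  neighbors3d <- NULL
  if (!is.null(conformer)) {
    neighbors3d <- search3D(conformer, store, config@k3d)
  } else {
    clNotice("no query conformer supplied; 3D neighbours omitted from the report")
  }

  activeAssay <- .capList(activeAssay, cap, "active assay hits")
  drugHits <- .capList(drugHits, max(0L, cap - length(activeAssay)),
                       "drug hits")
  inactiveAssay <- .capList(inactiveAssay, cap, "inactive assay hits")

  sections <- list(
    predictive_models = list(predictions = predictions),
    active_similars = list(assay_hits = activeAssay, drug_hits = drugHits,
                           neighbors3d = neighbors3d),
    chemogenomics_similars = list(
      hits = .capList(.relationEntries(hits, store@chemGene,
                                       c("target", "target_kind",
                                         "relation", "source")),
                      cap, "chemogenomics hits")),
    systems_similars = list(
      hits = .capList(.relationEntries(hits, store@pathways,
                                       c("pathway_id", "pathway_name",
                                         "enzyme")),
                      cap, "pathway hits")),
    literature_similars = list(
      hits = .capList(.literatureEntries(hits, store), cap,
                      "literature hits")),
    inactive_similars = list(assay_hits = inactiveAssay, drug_hits = list(),
                             neighbors3d = NULL))

  nTables <- c(compounds = nrow(store@compounds), assays = nrow(store@assays),
               outcomes = nrow(store@outcomes), drugs = nrow(store@drugs),
               literature = nrow(store@literature),
               chemgene = nrow(store@chemGene),
               pathways = nrow(store@pathways))
  metadata <- list(config = configSnapshot(config),
                   store = list(source = basename(store@sourceDir),
                                tables = as.list(nTables)),
                   timestamp = timestamp)
  new("AggregateReport",
      query = list(smiles = smiles, fingerprint = fp, conformer = conformer),
      sections = sections, metadata = metadata)
}
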