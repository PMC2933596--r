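.xmlDiseases <- function(parent, diseases) {
  for (d in diseases) {
    dn <- xml2::xml_add_child(parent, "disease", name = d$disease,
                              score = fmtNum(d$score),
                              genes = paste(d$genes, collapse = ","))
    prov <- xml2::xml_add_child(dn, "provenance")
    for (chain in d$provenance) {
      cn <- xml2::xml_add_child(prov, "chain")
      for (link in chain)
        xml2::xml_add_child(cn, "link", kind = link$kind, id = link$id)
    }
  }
}

.xmlAssayHits <- function(parent, entries) {
  for (h in entries) {
    hn <- xml2::xml_add_child(parent, "assay_hit",
                              compound_id = h$compound_id,
                              similarity = fmtNum(h$similarity),
                              assay_id = h$assay_id,
                              assay_name = h$assay_name,
                              score = as.character(h$score))
    .xmlDiseases(hn, h$diseases)
  }
}

#' Serialize a report as XML
#'
#' Produces a well-formed XML document with one element per report
#' section, in the fixed six-section order, preceded by metadata and
#' query elements. Every hit element carries \code{compound_id} and
#' \code{similarity} attributes; disease annotations nest their full
#' provenance chains. Serialization is deterministic and round-trips:
#' parsing the output and re-serializing reproduces the bytes.
#'
#' @param report An [AggregateReport-class].
#' @return Character scalar: the XML document text.
#' @seealso [reportToJSON()]
#' @export
reportToXML <- function(report) {
  doc <- xml2::xml_new_root("report")
  meta <- xml2::xml_add_child(doc, "metadata",
                              timestamp = report@metadata$timestamp)
  cfgAttrs <- lapply(report@metadata$config, function(v)
    if (is.numeric(v)) fmtNum(v) else as.character(v))
  do.call(xml2::xml_add_child, c(list(meta, "config"), cfgAttrs))
  storeAttrs <- c(list(source = report@metadata$store$source),
                  lapply(report@metadata$store$tables, as.character))
  do.call(xml2::xml_add_child, c(list(meta, "store"), storeAttrs))
  xml2::xml_add_child(doc, "query", smiles = report@query$smiles,
                      popcount = as.character(popcount(report@query$fingerprint)))

  s <- report@sections

  pm <- xml2::xml_add_child(doc, "predictive_models")
  pred <- s$predictive_models$predictions
  for (i in seq_len(nrow(pred)))
    xml2::xml_add_child(pm, "prediction",
                        target = pred$target_name[i], panel = pred$panel[i],
                        probability = fmtNum(pred$probability[i]),
                        color = pred$color[i],
                        sensitivity = fmtNum(pred$sensitivity[i]),
                        specificity = fmtNum(pred$specificity[i]))

  addActiveLike <- function(name, sec) {
    node <- xml2::xml_add_child(doc, name)
    .xmlAssayHits(node, sec$assay_hits)
    for (h in sec$drug_hits) {
      hn <- xml2::xml_add_child(node, "drug_hit", drug_id = h$drug_id,
                                compound_id = h$compound_id,
                                similarity = fmtNum(h$similarity),
                                name = h$name, source = h$source)
      xml2::xml_add_child(hn, "usage_description", h$usage_description)
      for (g in h$go_terms) xml2::xml_add_child(hn, "go_term", id = g)
      .xmlDiseases(hn, h$diseases)
    }
    if (!is.null(sec$neighbors3d))
      for (i in seq_len(nrow(sec$neighbors3d)))
        xml2::xml_add_child(node, "neighbor3d",
                            compound_id = sec$neighbors3d$compound_id[i],
                            distance = fmtNum(sec$neighbors3d$distance[i]))
    node
  }
  addActiveLike("active_similars", s$active_similars)

  cg <- xml2::xml_add_child(doc, "chemogenomics_similars")
  for (h in s$chemogenomics_similars$hits)
    xml2::xml_add_child(cg, "hit", compound_id = h$compound_id,
                        similarity = fmtNum(h$similarity), target = h$target,
                        target_kind = h$target_kind, relation = h$relation,
                        source = h$source)

  sy <- xml2::xml_add_child(doc, "systems_similars")
  for (h in s$systems_similars$hits)
    xml2::xml_add_child(sy, "hit", compound_id = h$compound_id,
                        similarity = fmtNum(h$similarity),
                        pathway_id = h$pathway_id,
                        pathway_name = h$pathway_name, enzyme = h$enzyme)

  li <- xml2::xml_add_child(doc, "literature_similars")
  for (h in s$literature_similars$hits) {
    pn <- xml2::xml_add_child(li, "paper", paper_id = h$paper_id,
                              best_similarity = fmtNum(h$best_similarity))
    xml2::xml_add_child(pn, "title", h$title)
    for (g in h$go_terms) xml2::xml_add_child(pn, "go_term", id = g)
    for (i in seq_len(nrow(h$compounds)))
      xml2::xml_add_child(pn, "compound",
                          compound_id = h$compounds$compound_id[i],
                          similarity = fmtNum(h$compounds$similarity[i]))
  }

  addActiveLike("inactive_similars", s$inactive_similars)

  as.character(doc)
}

.jsonDiseases <- function(diseases) {
  lapply(diseases, function(d)
    list(disease = d$disease, score = d$score,
         genes = as.list(d$genes),
         provenance = lapply(d$provenance, function(chain)
           lapply(chain, function(link) list(kind = link$kind, id = link$id)))))
}

.jsonAssayHits <- function(entries) {
  lapply(entries, function(h)
    list(compound_id = h$compound_id, similarity = h$similarity,
         assay_id = h$assay_id, assay_name = h$assay_name,
         score = h$score, diseases = .jsonDiseases(h$diseases)))
}

#' Serialize a report as JSON
#'
#' Same information content as [reportToXML()], with stable key order and
#' deterministic bytes for a fixed report.
#'
#' @param report An [AggregateReport-class].
#' @return Character scalar: the JSON text.
#' @export
reportToJSON <- function(report) {
  s <- report@sections
  pred <- s$predictive_models$predictions
  activeLike <- function(sec) {
    out <- list(assay_hits = .jsonAssayHits(sec$assay_hits),
                drug_hits = lapply(sec$drug_hits, function(h)
                  list(drug_id = h$drug_id, compound_id = h$compound_id,
                       similarity = h$similarity, name = h$name,
                       source = h$source,
                       usage_description = h$usage_description,
                       go_terms = as.list(h$go_terms),
                       diseases = .jsonDiseases(h$diseases))))
    out$neighbors3d <- if (is.null(sec$neighbors3d)) list()
    else lapply(seq_len(nrow(sec$neighbors3d)), function(i)
      list(compound_id = sec$neighbors3d$compound_id[i],
           distance = sec$neighbors3d$distance[i]))
    out
  }
  body <- list(
    metadata = report@metadata,
    query = list(smiles = report@query$smiles,
                 popcount = popcount(report@query$fingerprint)),
    sections = list(
      predictive_models = lapply(seq_len(nrow(pred)), function(i)
        list(target = pred$target_name[i], panel = pred$panel[i],
             probability = pred$probability[i], color = pred$color[i],
             sensitivity = pred$sensitivity[i],
             specificity = pred$specificity[i])),
      active_similars = activeLike(s$active_similars),
      chemogenomics_similars = lapply(s$chemogenomics_similars$hits,
                                      function(h)
        list(compound_id = h$compound_id, similarity = h$similarity,
             target = h$target, target_kind = h$target_kind,
             relation = h$relation, source = h$source)),
      systems_similars = lapply(s$systems_similars$hits, function(h)
        list(compound_id = h$compound_id, similarity = h$similarity,
             pathway_id = h$pathway_id, pathway_name = h$pathway_name,
             enzyme = h$enzyme)),
      literature_similars = lapply(s$literature_similars$hits, function(h)
        list(paper_id = h$paper_id, title = h$title,
             best_similarity = h$best_similarity,
             go_terms = as.list(h$go_terms),
             compounds = lapply(seq_len(nrow(h$compounds)), function(i)
               list(compound_id = h$compounds$compound_id[i],
                    similarity = h$compounds$similarity[i])))),
      inactive_similars = activeLike(s$inactive_similars)))
  as.character(jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE))
}
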