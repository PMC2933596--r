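#' Number of on bits in a fingerprint
#'
#' @param x A [Fingerprint-class] object.
#' @return Integer popcount.
#' @examples
#' popcount(fingerprint(c(0, 5, 9)))
#' @export
setGeneric("popcount", function(x) standardGeneric("popcount"))

#' @rdname popcount
#' @export
setMethod("popcount", "Fingerprint", function(x) length(x@onBits))

setMethod("show", "Fingerprint", function(object) {
  cat(sprintf("Fingerprint: %d bits, popcount %d\n",
              object@nbits, length(object@onBits)))
  if (length(object@onBits))
    cat("  on bits:", paste(utils::head(object@onBits, 12L), collapse = " "),
        if (length(object@onBits) > 12L) "..." else "", "\n")
})

setMethod("show", "BitcountIndex", function(object) {
  cat(sprintf("BitcountIndex: %d compounds, %d bits, %d popcount buckets\n",
              length(object@ids), object@nbits, length(object@buckets)))
})

setMethod("show", "EngineConfig", function(object) {
  cat("EngineConfig\n")
  cat(sprintf("  similarity threshold : %s%.2f\n",
              if (object@strictThreshold) "> " else ">= ",
              object@similarityThreshold))
  cat(sprintf("  colour cutoffs       : red >= %.2f, yellow >= %.2f\n",
              object@redThreshold, object@yellowThreshold))
  cat(sprintf("  disease min score    : %.2f\n", object@diseaseMinScore))
  cat(sprintf("  fingerprint length   : %d bits\n", object@fingerprintLength))
  cat(sprintf("  max hits / section   : %d, 3D neighbours: %d\n",
              object@maxHitsPerSection, object@k3d))
  cat(sprintf("  predictor            : %s (seed %d)\n",
              object@predictor, object@seed))
})

setMethod("show", "DataStore", function(object) {
  cat("DataStore", if (nzchar(object@sourceDir))
    sprintf("(loaded from %s)", object@sourceDir) else "(in memory)", "\n")
  cat(sprintf("  compounds : %d (indexed, %d buckets)\n",
              nrow(object@compounds), length(object@index@buckets)))
  cat(sprintf("  conformers: %d  assays: %d  outcomes: %d  drugs: %d\n",
              length(object@conformers), nrow(object@assays),
              nrow(object@outcomes), nrow(object@drugs)))
  cat(sprintf("  literature: %d  GO terms: %d  GO-gene: %d\n",
              nrow(object@literature), nrow(object@goLexicon),
              nrow(object@goGenes)))
  cat(sprintf("  gene x disease: %d x %d  chem-gene: %d  pathways: %d\n",
              nrow(object@geneDisease), ncol(object@geneDisease),
              nrow(object@chemGene), nrow(object@pathways)))
})

setMethod("show", "AggregateReport", function(object) {
  cat("AggregateReport for query:", object@query$smiles, "\n")
  for (nm in names(object@sections)) {
    n <- sectionSize(object, nm)
    cat(sprintf("  %-24s %d entries\n", nm, n))
  }
})

#' Accessors for report sections
#'
#' @param report An [AggregateReport-class].
#' @param name One of the six section names.
#' @return `reportSections` returns the named list of all six sections;
#'   `reportSection` returns one section; `sectionSize` its entry count.
#' @export
reportSections <- function(report) report@sections

#' @rdname reportSections
#' @export
reportSection <- function(report, name) {
  name <- match.arg(name, .SECTION_NAMES)
  report@sections[[name]]
}

#' @rdname reportSections
#' @export
sectionSize <- function(report, name) {
  s <- reportSection(report, name)
  if (name == "predictive_models") return(nrow(s$predictions))
  if (name == "active_similars" || name == "inactive_similars")
    return(length(s$assay_hits) + length(s$drug_hits))
  length(s$hits)
}
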