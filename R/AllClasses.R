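#' @import methods
NULL

#' Binary structural-key fingerprint
#'
#' A fixed-length binary fingerprint stored as the sorted set of its on-bit
#' positions (0-based). The default length of 166 follows the MACCS-style
#' structural key convention used throughout the package; any positive
#' length is accepted.
#'
#' @slot nbits Single positive integer, the fingerprint length.
#' @slot onBits Sorted integer vector of unique on-bit positions, each in
#'   \code{[0, nbits)}.
#'
#' @seealso [fingerprint()], [tanimoto()], [popcount()]
#' @exportClass Fingerprint
setClass("Fingerprint",
  representation(nbits = "integer", onBits = "integer"),
  prototype(nbits = 166L, onBits = integer(0))
)

setValidity("Fingerprint", function(object) {
  msg <- character(0)
  if (length(object@nbits) != 1L || is.na(object@nbits) || object@nbits < 1L)
    msg <- c(msg, "nbits must be a single positive integer")
  b <- object@onBits
  if (anyNA(b)) msg <- c(msg, "onBits must not contain NA")
  else {
    if (anyDuplicated(b)) msg <- c(msg, "onBits must be unique")
    if (is.unsorted(b)) msg <- c(msg, "onBits must be sorted")
    if (length(b) && (min(b) < 0L || max(b) >= object@nbits))
      msg <- c(msg, sprintf("onBits must lie in [0, %d)", object@nbits))
  }
  if (length(msg)) msg else TRUE
})

#' Popcount-bucketed fingerprint index
#'
#' An index over a set of identified fingerprints, bucketed by popcount
#' (number of on bits). The bucket structure supports the similarity
#' bound used by [search2D()]: for a query with popcount \eqn{a} and a
#' threshold \eqn{t}, any bucket with popcount \eqn{b} such that
#' \eqn{\min(a,b)/(a+b-\min(a,b)) < t} can be skipped entirely.
#'
#' Internally the fingerprints are also held as a dense logical matrix
#' (\code{nbits} rows, one column per compound) so that Tanimoto values
#' for a whole bucket are computed in one vectorised pass.
#'
#' @slot nbits Fingerprint length shared by all entries.
#' @slot ids Character vector of compound identifiers (column order).
#' @slot bits Logical matrix, \code{nbits} x \code{length(ids)}.
#' @slot popcounts Integer vector of per-column popcounts.
#' @slot buckets Named list mapping popcount (as character) to the integer
#'   column indices in that bucket, input order preserved.
#'
#' @seealso [buildBitcountIndex()], [search2D()]
#' @exportClass BitcountIndex
setClass("BitcountIndex",
  representation(nbits = "integer", ids = "character", bits = "matrix",
                 popcounts = "integer", buckets = "list"),
  prototype(nbits = 166L, ids = character(0),
            bits = matrix(logical(0), nrow = 166), popcounts = integer(0),
            buckets = list())
)

setValidity("BitcountIndex", function(object) {
  msg <- character(0)
  n <- length(object@ids)
  if (ncol(object@bits) != n) msg <- c(msg, "bits must have one column per id")
  if (nrow(object@bits) != object@nbits)
    msg <- c(msg, "bits must have nbits rows")
  if (length(object@popcounts) != n)
    msg <- c(msg, "popcounts must have one entry per id")
  idx <- sort(as.integer(unlist(object@buckets, use.names = FALSE)))
  if (!identical(idx, seq_len(n)))
    msg <- c(msg, "buckets must partition the column indices")
  for (nm in names(object@buckets)) {
    cols <- object@buckets[[nm]]
    if (any(object@popcounts[cols] != as.integer(nm))) {
      msg <- c(msg, sprintf("bucket %s contains a fingerprint with a different popcount", nm))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Engine configuration
#'
#' Tunable parameters of the aggregation engine. Defaults follow the
#' reference configuration: similarity threshold 0.85 (inclusive unless
#' \code{strictThreshold}), activity colour cutoffs 0.7 (red) and 0.6
#' (yellow), disease reporting floor 0.5, 166-bit fingerprints, at most
#' 100 hits per report section, and 10 nearest shape neighbours.
#'
#' @slot similarityThreshold Tanimoto threshold for 2D hits, in (0, 1].
#' @slot strictThreshold If TRUE, require similarity strictly above the
#'   threshold; default FALSE (at-or-above), so exact matches are kept.
#' @slot redThreshold,yellowThreshold Probability cutoffs for the
#'   red/yellow/grey activity colour coding.
#' @slot diseaseMinScore Minimum gene-disease score to report a disease.
#' @slot fingerprintLength Fingerprint length in bits.
#' @slot maxHitsPerSection Per-section hit cap (truncation by rank).
#' @slot k3d Number of nearest shape neighbours to report.
#' @slot predictor Name of the registered activity predictor.
#' @slot seed Integer seed forwarded to seeded components.
#'
#' @seealso [engineConfig()], [readEngineConfig()]
#' @exportClass EngineConfig
setClass("EngineConfig",
  representation(similarityThreshold = "numeric", strictThreshold = "logical",
                 redThreshold = "numeric", yellowThreshold = "numeric",
                 diseaseMinScore = "numeric", fingerprintLength = "integer",
                 maxHitsPerSection = "integer", k3d = "integer",
                 predictor = "character", seed = "integer"),
  prototype(similarityThreshold = 0.85, strictThreshold = FALSE,
            redThreshold = 0.7, yellowThreshold = 0.6,
            diseaseMinScore = 0.5, fingerprintLength = 166L,
            maxHitsPerSection = 100L, k3d = 10L,
            predictor = "reference", seed = 1L)
)

setValidity("EngineConfig", function(object) {
  msg <- character(0)
  if (!(object@similarityThreshold > 0 && object@similarityThreshold <= 1))
    msg <- c(msg, "similarityThreshold must be in (0, 1]")
  if (!(object@yellowThreshold > 0 && object@yellowThreshold <= object@redThreshold &&
        object@redThreshold <= 1))
    msg <- c(msg, "need 0 < yellowThreshold <= redThreshold <= 1")
  if (object@fingerprintLength < 1L) msg <- c(msg, "fingerprintLength must be positive")
  if (object@maxHitsPerSection < 1L) msg <- c(msg, "maxHitsPerSection must be positive")
  if (object@k3d < 1L) msg <- c(msg, "k3d must be positive")
  if (length(msg)) msg else TRUE
})

#' Loaded local data store
#'
#' The in-memory, indexed collection of the flat tables the engine
#' searches: compounds (with fingerprints and a popcount index),
#' conformers with precomputed shape descriptors, assays and outcomes,
#' drugs, literature links, a GO term lexicon, a GO-to-gene map, a
#' gene x disease score matrix, chemical-gene/disease relations and
#' pathway relations. All tables except \code{compounds} are optional;
#' absent tables are empty data frames and yield empty report sections.
#'
#' @slot compounds Data frame: compound_id, smiles, fingerprint_hex, popcount.
#' @slot index A [BitcountIndex-class] over the compound fingerprints.
#' @slot conformers Named list of n x 3 coordinate matrices (Angstrom).
#' @slot shapes Numeric matrix, 12 rows, one column per conformer.
#' @slot assays,outcomes,drugs,literature,goLexicon,goGenes,chemGene,pathways
#'   Data frames in the flat-file dialect (see [loadStore()]).
#' @slot geneDisease Numeric matrix, genes x diseases, scores in [0, 1].
#' @slot sourceDir Directory the store was loaded from ("" if built in code).
#'
#' @seealso [loadStore()], [validateStore()]
#' @exportClass DataStore
setClass("DataStore",
  representation(compounds = "data.frame", index = "BitcountIndex",
                 conformers = "list", shapes = "matrix",
                 assays = "data.frame", outcomes = "data.frame",
                 drugs = "data.frame", literature = "data.frame",
                 goLexicon = "data.frame", goGenes = "data.frame",
                 geneDisease = "matrix", chemGene = "data.frame",
                 pathways = "data.frame", sourceDir = "character")
)

#' Six-section aggregate report
#'
#' The result of [runQuery()]: the query (SMILES, fingerprint, optional
#' conformer) plus exactly six sections in fixed order --
#' \code{predictive_models}, \code{active_similars},
#' \code{chemogenomics_similars}, \code{systems_similars},
#' \code{literature_similars}, \code{inactive_similars} -- and metadata
#' (configuration snapshot, store identity, timestamp).
#'
#' @slot query List: smiles, fingerprint ([Fingerprint-class]), optional
#'   conformer matrix.
#' @slot sections Named list of exactly six sections, fixed order.
#' @slot metadata List: config snapshot, store identity, timestamp.
#'
#' @seealso [runQuery()], [reportToXML()], [reportToJSON()]
#' @exportClass AggregateReport
setClass("AggregateReport",
  representation(query = "list", sections = "list", metadata = "list")
)

.SECTION_NAMES <- c("predictive_models", "active_similars",
                    "chemogenomics_similars", "systems_similars",
                    "literature_similars", "inactive_similars")

setValidity("AggregateReport", function(object) {
  if (!identical(names(object@sections), .SECTION_NAMES))
    return("sections must be exactly the six named sections, in fixed order")
  TRUE
})
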