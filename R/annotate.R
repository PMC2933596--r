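#' Extract Gene Ontology terms from free text
#'
#' Dictionary phrase matching against a GO lexicon: case-insensitive,
#' word-boundary-respecting exact-phrase matches. Overlapping candidate
#' matches are resolved by longest match first, then leftmost; surviving
#' matches are returned ordered by span start. Spans are 0-based,
#' half-open, so \code{substr(text, start + 1, end)} recovers the matched
#' region.
#'
#' @param text Character scalar (may be empty).
#' @param lexicon Data frame with columns \code{go_id} (format
#'   \code{GO:} + 7 digits) and \code{term_text}.
#' @return Data frame with columns \code{go_id}, \code{matched_text},
#'   \code{start}, \code{end}.
#' @examples
#' lex <- data.frame(go_id = c("GO:0006915", "GO:0007049"),
#'                   term_text = c("apoptosis", "cell cycle"))
#' extractGOTerms("Inhibitors of apoptosis in the cell cycle", lex)
#' @export
extractGOTerms <- function(text, lexicon) {
  empty <- data.frame(go_id = character(0), matched_text = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(text) || is.na(text) || !nzchar(text) || nrow(lexicon) == 0L)
    return(empty)
  cand <- list()
  for (i in seq_len(nrow(lexicon))) {
    term <- lexicon$term_text[i]
    if (!nzchar(term)) next
    pat <- paste0("\\b", .escapeRegex(term), "\\b")
    m <- gregexpr(pat, text, ignore.case = TRUE, perl = TRUE)[[1]]
    if (m[1L] == -1L) next
    len <- attr(m, "match.length")
    for (k in seq_along(m)) {
      cand[[length(cand) + 1L]] <- list(go_id = lexicon$go_id[i],
                                        start = as.integer(m[k]) - 1L,
                                        len = as.integer(len[k]))
    }
  }
  if (length(cand) == 0L) return(empty)
  st <- vapply(cand, `[[`, integer(1), "start")
  ln <- vapply(cand, `[[`, integer(1), "len")
  # longest first, then leftmost; greedy non-overlapping selection
  o <- order(-ln, st)
  chosen <- logical(length(cand))
  covered <- rep(FALSE, nchar(text))
  for (j in o) {
    span <- (st[j] + 1L):(st[j] + ln[j])
    if (!any(covered[span])) {
      chosen[j] <- TRUE
      covered[span] <- TRUE
    }
  }
  keep <- which(chosen)
  keep <- keep[order(st[keep])]
  data.frame(go_id = vapply(cand[keep], `[[`, character(1), "go_id"),
             matched_text = substring(text, st[keep] + 1L, st[keep] + ln[keep]),
             start = st[keep], end = st[keep] + ln[keep],
             stringsAsFactors = FALSE)
}

.escapeRegex <- function(s) gsub("([\\^$.|?*+()\\[\\]{}\\\\])", "\\\\\\1", s, perl = TRUE)

#' Map genes to diseases through the gene x disease score matrix
#'
#' For each disease, the reported score is the maximum score over the
#' given genes (the most-supported signal); diseases scoring at least
#' \code{minScore} are returned, sorted by score descending then disease
#' name ascending. Each annotation lists every gene that itself reaches
#' \code{minScore} for that disease. Gene symbols are compared
#' case-insensitively; genes absent from the matrix are skipped with a
#' logged notice.
#'
#' @param genes Character vector of gene symbols.
#' @param matrix Numeric gene x disease matrix with dimnames.
#' @param minScore Reporting floor in [0, 1].
#' @return Data frame with columns \code{disease}, \code{score},
#'   \code{genes} (comma-separated supporting genes).
#' @export
genesToDiseases <- function(genes, matrix, minScore = 0.5) {
  empty <- data.frame(disease = character(0), score = numeric(0),
                      genes = character(0), stringsAsFactors = FALSE)
  if (length(genes) == 0L || length(matrix) == 0L) return(empty)
  rows <- match(toupper(genes), toupper(rownames(matrix)))
  if (anyNA(rows)) {
    clNotice("genes absent from the gene-disease matrix: %s",
             paste(unique(genes[is.na(rows)]), collapse = ", "))
  }
  genes <- genes[!is.na(rows)]; rows <- rows[!is.na(rows)]
  if (length(rows) == 0L) return(empty)
  sub <- matrix[rows, , drop = FALSE]
  best <- apply(sub, 2L, max)
  keep <- which(best >= minScore)
  if (length(keep) == 0L) return(empty)
  out <- data.frame(disease = colnames(matrix)[keep],
                    score = as.numeric(best[keep]),
                    genes = vapply(keep, function(j) {
                      g <- rownames(matrix)[rows[sub[, j] >= minScore]]
                      paste(unique(g), collapse = ",")
                    }, character(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$disease, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer diseases from a bioassay description
#'
#' The inference chain: GO terms are extracted from the assay description
#' with [extractGOTerms()], mapped to genes through the GO-to-gene table,
#' and the genes scored against the gene x disease matrix with
#' [genesToDiseases()]. Each returned annotation carries its full
#' provenance: one chain per (GO term, gene) pair that supports the
#' disease, each chain the ordered links assay -> GO term -> gene ->
#' disease. Two GO terms converging on one disease yield a single
#' annotation whose provenance lists both chains. Missing lexicon,
#' GO-gene or matrix tables degrade to an empty result with a notice.
#'
#' @param assay One-row data frame (or list) with \code{assay_id} and
#'   \code{description}.
#' @param store A [DataStore-class].
#' @param config An [EngineConfig-class]; \code{diseaseMinScore} applies.
#' @return List of disease annotations, each a list with \code{disease},
#'   \code{score}, \code{genes} (character vector) and \code{provenance}
#'   (list of chains; a chain is a list of \code{(kind, id)} links).
#' @export
assayToDiseases <- function(assay, store, config = engineConfig()) {
  .textToDiseases(sourceKind = "assay", sourceId = assay$assay_id,
                  text = assay$description, store = store, config = config)
}

# Shared GO -> gene -> disease chain for any text-bearing record (assay
# descriptions, drug usage descriptions, paper titles/abstracts).
.textToDiseases <- function(sourceKind, sourceId, text, store, config) {
  if (nrow(store@goLexicon) == 0L || nrow(store@goGenes) == 0L ||
      length(store@geneDisease) == 0L) {
    clNotice("disease annotation skipped for %s '%s': lexicon, GO-gene map or gene-disease matrix missing",
             sourceKind, sourceId)
    return(list())
  }
  matches <- extractGOTerms(text, store@goLexicon)
  if (nrow(matches) == 0L) return(list())
  goIds <- unique(matches$go_id)
  pairs <- store@goGenes[store@goGenes$go_id %in% goIds, , drop = FALSE]
  if (nrow(pairs) == 0L) return(list())
  ann <- genesToDiseases(unique(pairs$gene), store@geneDisease,
                         config@diseaseMinScore)
  if (nrow(ann) == 0L) return(list())
  out <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    genes <- strsplit(ann$genes[i], ",", fixed = TRUE)[[1]]
    chains <- list()
    for (g in genes) {
      gos <- pairs$go_id[toupper(pairs$gene) == toupper(g)]
      for (go in unique(gos)) {
        chains[[length(chains) + 1L]] <-
          list(list(kind = sourceKind, id = as.character(sourceId)),
               list(kind = "go_term", id = go),
               list(kind = "gene", id = g),
               list(kind = "disease", id = ann$disease[i]))
      }
    }
    out[[i]] <- list(disease = ann$disease[i], score = ann$score[i],
                     genes = genes, provenance = chains)
  }
  out
}
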