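#' Build a popcount-bucketed index over identified fingerprints
#'
#' @param fps Named list of [Fingerprint-class] objects (names are compound
#'   identifiers), all of one length.
#' @return A [BitcountIndex-class].
#' @examples
#' idx <- buildBitcountIndex(list(c1 = fingerprint(1:4), c2 = fingerprint(2:8)))
#' @export
buildBitcountIndex <- function(fps) {
  if (length(fps) == 0L)
    return(new("BitcountIndex"))
  if (is.null(names(fps)) || any(!nzchar(names(fps))))
    clStop("fingerprints must be named by compound id",
           class = "ChemLinker_invalid_input")
  nbits <- unique(vapply(fps, function(f) f@nbits, integer(1)))
  if (length(nbits) != 1L)
    clStop("mixed fingerprint lengths: %s", paste(nbits, collapse = ", "),
           class = "ChemLinker_invalid_input")
  n <- length(fps)
  bits <- matrix(FALSE, nrow = nbits, ncol = n)
  pc <- integer(n)
  for (j in seq_len(n)) {
    on <- fps[[j]]@onBits
    bits[on + 1L, j] <- TRUE
    pc[j] <- length(on)
  }
  buckets <- split(seq_len(n), pc)   # input order preserved within buckets
  new("BitcountIndex", nbits = nbits, ids = names(fps), bits = bits,
      popcounts = pc, buckets = buckets)
}

# Vectorised Tanimoto of one query against index columns `cols`.
.tanimotoCols <- function(query, index, cols) {
  qv <- logical(index@nbits)
  qv[query@onBits + 1L] <- TRUE
  a <- length(query@onBits)
  sub <- index@bits[, cols, drop = FALSE]
  inter <- colSums(sub & qv)
  uni <- a + index@popcounts[cols] - inter
  sim <- ifelse(uni == 0, 0, inter / uni)   # both empty -> 0 by convention
  as.numeric(sim)
}

.orderHits <- function(ids, sims) {
  o <- order(-sims, ids, method = "radix")
  data.frame(compound_id = ids[o], similarity = sims[o],
             stringsAsFactors = FALSE)
}

#' Bound-pruned exact 2D similarity search
#'
#' Returns every indexed compound whose Tanimoto similarity to the query
#' is at (or, with \code{strict}, strictly above) the threshold. Popcount
#' buckets whose [maxAttainableSimilarity()] falls below the threshold are
#' skipped without scanning; the result is provably identical to an
#' exhaustive scan. Hits are ordered by similarity descending, ties broken
#' by compound id ascending.
#'
#' @param query A [Fingerprint-class] matching the indexed length.
#' @param index A [BitcountIndex-class].
#' @param threshold Similarity threshold in (0, 1].
#' @param strict Use strictly-greater comparison instead of at-or-above.
#' @return Data frame with columns \code{compound_id}, \code{similarity},
#'   plus attribute \code{"bucketsScanned"} / \code{"bucketsSkipped"}.
#' @examples
#' idx <- buildBitcountIndex(list(a = fingerprint(1:8), b = fingerprint(1:4)))
#' search2D(fingerprint(1:8), idx, 0.5)
#' @export
search2D <- function(query, index, threshold, strict = FALSE) {
  stopifnot(is(query, "Fingerprint"), is(index, "BitcountIndex"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    clStop("threshold must lie in (0, 1]", class = "ChemLinker_invalid_input")
  empty <- .orderHits(character(0), numeric(0))
  if (length(index@ids) == 0L) {
    attr(empty, "bucketsScanned") <- 0L
    attr(empty, "bucketsSkipped") <- 0L
    return(empty)
  }
  if (query@nbits != index@nbits)
    clStop("query fingerprint length %d does not match indexed length %d",
           query@nbits, index@nbits, class = "ChemLinker_invalid_input")
  a <- length(query@onBits)
  pcs <- as.integer(names(index@buckets))
  keep <- maxAttainableSimilarity(a, pcs) >= threshold
  scanned <- 0L
  ids <- character(0); sims <- numeric(0)
  for (i in which(keep)) {
    cols <- index@buckets[[i]]
    s <- .tanimotoCols(query, index, cols)
    ok <- if (strict) s > threshold else s >= threshold
    if (any(ok)) {
      ids <- c(ids, index@ids[cols[ok]])
      sims <- c(sims, s[ok])
    }
    scanned <- scanned + 1L
  }
  out <- .orderHits(ids, sims)
  attr(out, "bucketsScanned") <- scanned
  attr(out, "bucketsSkipped") <- length(pcs) - scanned
  out
}

#' Exhaustive 2D scan (reference path)
#'
#' Linear scan over every indexed compound, used as the unpruned reference
#' against which [search2D()] is checked. Same ordering and threshold
#' semantics.
#'
#' @inheritParams search2D
#' @return Data frame with columns \code{compound_id}, \code{similarity}.
#' @export
scan2D <- function(query, index, threshold, strict = FALSE) {
  stopifnot(is(query, "Fingerprint"), is(index, "BitcountIndex"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    clStop("threshold must lie in (0, 1]", class = "ChemLinker_invalid_input")
  if (length(index@ids) == 0L) return(.orderHits(character(0), numeric(0)))
  s <- .tanimotoCols(query, index, seq_along(index@ids))
  ok <- if (strict) s > threshold else s >= threshold
  .orderHits(index@ids[ok], s[ok])
}
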