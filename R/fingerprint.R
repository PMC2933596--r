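#' Construct a fingerprint
#'
#' @param onBits Integer vector of on-bit positions, 0-based, in
#'   \code{[0, nbits)}. Duplicates are an error.
#' @param nbits Fingerprint length in bits (default 166, the structural-key
#'   convention used across the package).
#' @return A [Fingerprint-class] object.
#' @examples
#' fp <- fingerprint(c(1, 2, 3, 4))
#' popcount(fp)
#' @export
fingerprint <- function(onBits = integer(0), nbits = 166L) {
  nbits <- as.integer(nbits)
  onBits <- as.integer(onBits)
  if (anyDuplicated(onBits)) clStop("duplicate on-bit positions")
  new("Fingerprint", nbits = nbits, onBits = sort(onBits))
}

#' Tanimoto similarity between two fingerprints
#'
#' Computes \eqn{|A \cap B| / |A \cup B|} over the on bits of two
#' fingerprints of equal length. The similarity between two empty
#' fingerprints is defined as \code{empty} (default 0): two structureless
#' bit vectors carry no evidence of similarity.
#'
#' @param fpA,fpB [Fingerprint-class] objects of equal length.
#' @param empty Value returned when both fingerprints are empty.
#' @return Similarity in \code{[0, 1]}.
#' @examples
#' tanimoto(fingerprint(c(1, 2, 3, 4)), fingerprint(3:8))  # 2/8
#' @export
tanimoto <- function(fpA, fpB, empty = 0) {
  stopifnot(is(fpA, "Fingerprint"), is(fpB, "Fingerprint"))
  if (fpA@nbits != fpB@nbits)
    clStop("fingerprint length mismatch (%d vs %d)", fpA@nbits, fpB@nbits,
           class = "ChemLinker_invalid_input")
  a <- length(fpA@onBits); b <- length(fpB@onBits)
  if (a == 0L && b == 0L) return(empty)
  inter <- length(intersect(fpA@onBits, fpB@onBits))
  inter / (a + b - inter)
}

#' Upper bound on Tanimoto similarity from popcounts alone
#'
#' For fingerprints with \code{a} and \code{b} bits set, no pair can exceed
#' \eqn{\min(a,b)/(a+b-\min(a,b))} (attained when the smaller bit set is
#' contained in the larger). This is the pruning bound used by
#' [search2D()] to skip whole popcount buckets.
#'
#' @param a,b Non-negative integer popcounts (vectorised over \code{b}).
#' @return Bound in \code{[0, 1]}; 0 when either popcount is 0.
#' @examples
#' maxAttainableSimilarity(5, 15)  # 1/3
#' @export
maxAttainableSimilarity <- function(a, b) {
  if (any(a < 0) || any(b < 0))
    clStop("popcounts must be non-negative", class = "ChemLinker_invalid_input")
  m <- pmin(a, b)
  out <- ifelse(m == 0, 0, m / (a + b - m))
  as.numeric(out)
}

#' Serialize / parse fingerprints as hexadecimal strings
#'
#' The table dialect stores a fingerprint as a big-endian hex string of
#' \code{ceiling(nbits/4)} digits, with bit 0 the least-significant bit of
#' the last hex digit.
#'
#' @param fp A [Fingerprint-class].
#' @param hex Hex string as written by `fpToHex`.
#' @param nbits Fingerprint length the hex string encodes.
#' @return `fpToHex` a character scalar; `hexToFp` a [Fingerprint-class].
#' @examples
#' hexToFp(fpToHex(fingerprint(c(0, 7, 165))))
#' @export
fpToHex <- function(fp) {
  stopifnot(is(fp, "Fingerprint"))
  ndigits <- ceiling(fp@nbits / 4)
  vals <- integer(ndigits)
  if (length(fp@onBits)) {
    digit <- fp@onBits %/% 4L          # 0 = least significant digit
    within <- bitwShiftL(1L, fp@onBits %% 4L)
    for (i in seq_along(digit))
      vals[digit[i] + 1L] <- vals[digit[i] + 1L] + within[i]
  }
  paste(rev(sprintf("%x", vals)), collapse = "")
}

#' @rdname fpToHex
#' @export
hexToFp <- function(hex, nbits = 166L) {
  nbits <- as.integer(nbits)
  ndigits <- ceiling(nbits / 4)
  if (!grepl("^[0-9a-fA-F]+$", hex) || nchar(hex) != ndigits)
    clStop("malformed fingerprint hex '%s' (want %d hex digits)", hex, ndigits,
           class = "ChemLinker_invalid_input")
  vals <- strtoi(rev(strsplit(hex, "")[[1]]), base = 16L)
  on <- integer(0)
  for (d in seq_along(vals)) {
    v <- vals[d]
    if (v > 0L) {
      for (k in 0:3) if (bitwAnd(v, bitwShiftL(1L, k)) != 0L)
        on <- c(on, (d - 1L) * 4L + k)
    }
  }
  if (length(on) && max(on) >= nbits)
    clStop("hex string sets a bit beyond fingerprint length %d", nbits,
           class = "ChemLinker_invalid_input")
  fingerprint(on, nbits)
}

#' Deterministic hash fingerprint for a SMILES string
#'
#' Maps a SMILES string to a fingerprint by hashing its character n-grams
#' (lengths 1-3) onto bit positions with a fixed polynomial hash. This is
#' the bundled self-consistent fingerprinting backend: it makes the engine
#' and its fixtures testable without a chemistry toolkit, and identical
#' strings always map to identical fingerprints. It makes no claim of
#' bit-compatibility with MACCS or any other key catalogue; a
#' real-chemistry backend can be substituted wherever a
#' [Fingerprint-class] is accepted.
#'
#' @param smiles Non-empty SMILES (or any) string.
#' @param nbits Fingerprint length (default 166).
#' @return A [Fingerprint-class].
#' @examples
#' hashFingerprint("CC(=O)Oc1ccccc1C(=O)O")
#' @export
hashFingerprint <- function(smiles, nbits = 166L) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    clStop("query SMILES must be a single non-empty string",
           class = "ChemLinker_query_error")
  nbits <- as.integer(nbits)
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  bits <- integer(0)
  for (len in 1:3) {
    if (n < len) break
    for (i in seq_len(n - len + 1L)) {
      gram <- paste(chars[i:(i + len - 1L)], collapse = "")
      bits <- c(bits, .stringHash(gram) %% nbits)
    }
  }
  fingerprint(unique(bits), nbits)
}
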