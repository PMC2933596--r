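options(ChemLinker.quiet = TRUE)

# Seeded random fingerprints with popcounts drawn from pcRange.
randomFps <- function(n, seed, nbits = 166L, pcRange = c(10L, 120L)) {
  set.seed(seed)
  fps <- vector("list", n)
  for (j in seq_len(n)) {
    pc <- sample(pcRange[1]:pcRange[2], 1L)
    fps[[j]] <- fingerprint(sort(sample.int(nbits, pc) - 1L), nbits)
  }
  names(fps) <- sprintf("C%05d", seq_len(n))
  fps
}

# Independent reference for search2D built from the scalar tanimoto()
# path: per-pair set arithmetic, filtered and ordered by hand.
bruteForce2D <- function(query, fps, threshold, strict = FALSE) {
  sims <- vapply(fps, function(f) tanimoto(query, f), numeric(1))
  keep <- if (strict) sims > threshold else sims >= threshold
  ids <- names(fps)[keep]
  sims <- unname(sims[keep])
  o <- order(-sims, ids, method = "radix")
  data.frame(compound_id = ids[o], similarity = sims[o],
             stringsAsFactors = FALSE)
}

tinyLexicon <- function() {
  data.frame(go_id = c("GO:0006915", "GO:0007049", "GO:0008150"),
             term_text = c("apoptosis", "cell cycle", "cell"),
             stringsAsFactors = FALSE)
}

# A generated store shared across test files (one build per test run).
sharedStoreDir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "chemlinker-shared-store")
      if (!dir.exists(dir)) generateFixtureStore(fixtureSpec(seed = 42L), dir)
    }
    dir
  }
})
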