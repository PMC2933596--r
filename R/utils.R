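.onLoad <- function(libname, pkgname) {
  .registerBuiltinPredictors()
}

# Internal logging: notices are emitted with message() and can be silenced
# via options(ChemLinker.quiet = TRUE).
clNotice <- function(...) {
  if (!isTRUE(getOption("ChemLinker.quiet", FALSE)))
    message("[ChemLinker] ", sprintf(...))
  invisible(NULL)
}

clStop <- function(..., class = "ChemLinker_error") {
  stop(errorCondition(sprintf(...), class = c(class, "error", "condition")))
}

# Deterministic 32-bit polynomial rolling hash of a string (pure R, no
# dependence on the session RNG or locale).
.stringHash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  h
}

# Seeded evaluation that restores the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647), kind = "Mersenne-Twister")
  expr
}

# Format a numeric scalar for serialization: up to 15 significant digits,
# no scientific notation surprises, deterministic.
fmtNum <- function(x) {
  if (is.na(x)) return("")
  s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  s
}
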