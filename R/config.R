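.CONFIG_KEYS <- c(similarity_threshold = "similarityThreshold",
                  strict_threshold = "strictThreshold",
                  red_threshold = "redThreshold",
                  yellow_threshold = "yellowThreshold",
                  disease_min_score = "diseaseMinScore",
                  fingerprint_length = "fingerprintLength",
                  max_hits_per_section = "maxHitsPerSection",
                  k_3d = "k3d",
                  predictor = "predictor",
                  seed = "seed")

#' Create an engine configuration
#'
#' All arguments default to the reference configuration (see
#' [EngineConfig-class]); pass only what you want to change.
#'
#' @param similarityThreshold Tanimoto threshold in (0, 1]; default 0.85.
#' @param strictThreshold Strictly-greater comparison; default FALSE.
#' @param redThreshold,yellowThreshold Colour cutoffs; defaults 0.7, 0.6.
#' @param diseaseMinScore Disease reporting floor; default 0.5.
#' @param fingerprintLength Bits per fingerprint; default 166.
#' @param maxHitsPerSection Per-section cap; default 100.
#' @param k3d Shape neighbours reported; default 10.
#' @param predictor Registered predictor name; default "reference".
#' @param seed Seed forwarded to seeded components; default 1.
#' @return A validated [EngineConfig-class].
#' @examples
#' engineConfig(similarityThreshold = 0.7)
#' @export
engineConfig <- function(similarityThreshold = 0.85, strictThreshold = FALSE,
                         redThreshold = 0.7, yellowThreshold = 0.6,
                         diseaseMinScore = 0.5, fingerprintLength = 166L,
                         maxHitsPerSection = 100L, k3d = 10L,
                         predictor = "reference", seed = 1L) {
  new("EngineConfig",
      similarityThreshold = as.numeric(similarityThreshold),
      strictThreshold = isTRUE(as.logical(strictThreshold)),
      redThreshold = as.numeric(redThreshold),
      yellowThreshold = as.numeric(yellowThreshold),
      diseaseMinScore = as.numeric(diseaseMinScore),
      fingerprintLength = as.integer(fingerprintLength),
      maxHitsPerSection = as.integer(maxHitsPerSection),
      k3d = as.integer(k3d),
      predictor = as.character(predictor),
      seed = as.integer(seed))
}

#' Read a flat key = value configuration file
#'
#' Lines of the form \code{key = value}; blank lines and lines starting
#' with \code{#} are ignored. Keys use the file dialect
#' (\code{similarity_threshold}, \code{strict_threshold},
#' \code{red_threshold}, \code{yellow_threshold}, \code{disease_min_score},
#' \code{fingerprint_length}, \code{max_hits_per_section}, \code{k_3d},
#' \code{predictor}, \code{seed}). Unknown keys are an error.
#'
#' @param path Path to the config file.
#' @return A validated [EngineConfig-class].
#' @export
readEngineConfig <- function(path) {
  if (!file.exists(path))
    clStop("config file not found: %s", path, class = "ChemLinker_store_error")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      clStop("malformed config line: '%s'", ln, class = "ChemLinker_store_error")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(.CONFIG_KEYS))
      clStop("unknown config key: '%s'", key, class = "ChemLinker_store_error")
    slot <- .CONFIG_KEYS[[key]]
    args[[slot]] <- switch(slot,
      predictor = val,
      strictThreshold = tolower(val) %in% c("true", "yes", "1", "on"),
      as.numeric(val))
  }
  do.call(engineConfig, args)
}

# Ordered plain-list snapshot of a config (used in report metadata).
configSnapshot <- function(config) {
  list(similarity_threshold = config@similarityThreshold,
       strict_threshold = config@strictThreshold,
       red_threshold = config@redThreshold,
       yellow_threshold = config@yellowThreshold,
       disease_min_score = config@diseaseMinScore,
       fingerprint_length = config@fingerprintLength,
       max_hits_per_section = config@maxHitsPerSection,
       k_3d = config@k3d,
       predictor = config@predictor,
       seed = config@seed)
}
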