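#' Colour-code an activity probability
#'
#' The display convention for predicted activity probabilities: red for
#' probabilities at or above the red cutoff (default 0.7), yellow at or
#' above the yellow cutoff but below red (default 0.6), grey below.
#'
#' @param probability Probability in [0, 1] (vectorised).
#' @param config An [EngineConfig-class] supplying the cutoffs.
#' @return Character vector over \{"red", "yellow", "grey"\}.
#' @examples
#' colorCode(c(0.70, 0.60, 0.59))
#' @export
colorCode <- function(probability, config = engineConfig()) {
  if (any(!is.finite(probability)) || any(probability < 0 | probability > 1))
    clStop("probability must lie in [0, 1]",
           class = "ChemLinker_invalid_input")
  ifelse(probability >= config@redThreshold, "red",
         ifelse(probability >= config@yellowThreshold, "yellow", "grey"))
}

#' Default tumor-cell-line target panel
#'
#' Forty pseudo cell-line targets spread over the usual tumor panels
#' (renal, non-small cell lung, breast, colon, melanoma, leukemia,
#' ovarian, prostate, CNS), with fixed illustrative confusion metrics.
#' These name the rows of the reference predictor's output so report
#' layout matches a cell-line activity panel; they are synthetic labels,
#' not trained models.
#'
#' @return Data frame: \code{target_name}, \code{panel},
#'   \code{sensitivity}, \code{specificity} (40 rows).
#' @export
defaultTargetPanel <- function() {
  panels <- c("renal", "non-small cell lung", "breast", "colon", "melanoma",
              "leukemia", "ovarian", "prostate", "cns")
  prefix <- c("RXF", "HOP", "MCF", "HCT", "MEL", "HL", "OVC", "PC", "SNB")
  rows <- list()
  for (i in seq_len(40L)) {
    p <- ((i - 1L) %% length(panels)) + 1L
    rows[[i]] <- data.frame(
      target_name = sprintf("%s-%02d", prefix[p], i),
      panel = panels[p],
      sensitivity = round(0.70 + 0.25 * ((i * 7L) %% 11L) / 10, 3),
      specificity = round(0.70 + 0.25 * ((i * 5L) %% 11L) / 10, 3),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Read predictor metadata (confusion metrics) from TSV
#'
#' Columns \code{target_name, panel, sensitivity, specificity}. Metrics
#' are pass-through metadata attached to predictions so model validity can
#' be judged; they are never recomputed.
#'
#' @param path TSV path with a header row.
#' @return Data frame with the four columns.
#' @export
readPredictorMetadata <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", sep = "\t",
                          quote = "", stringsAsFactors = FALSE)
  need <- c("target_name", "panel", "sensitivity", "specificity")
  if (!identical(names(df), need))
    clStop("%s: bad header (want: %s)", path, paste(need, collapse = ", "),
           class = "ChemLinker_store_error")
  df$sensitivity <- as.numeric(df$sensitivity)
  df$specificity <- as.numeric(df$specificity)
  df
}

#' Deterministic reference activity predictor
#'
#' A self-contained stand-in predictor satisfying the plug-in contract:
#' for each target it derives a fixed pseudo-random bit mask from the
#' predictor seed and the target name, and scores a fingerprint by the
#' fraction of mask bits it sets: \eqn{|fp \cap M_t| / |M_t|}. The output
#' is deterministic for a fixed seed, spans [0, 1], and respects the
#' colour-coding invariant. It encodes no chemistry; real models can be
#' registered under the same contract via [registerPredictor()].
#'
#' @param fp A [Fingerprint-class].
#' @param predictorSeed Integer seed for the per-target masks.
#' @param targets Data frame as from [defaultTargetPanel()] (or a
#'   character vector of target names).
#' @param config An [EngineConfig-class] for the colour cutoffs.
#' @return Data frame: \code{target_name}, \code{panel},
#'   \code{probability}, \code{color}, \code{sensitivity},
#'   \code{specificity}.
#' @export
referencePredict <- function(fp, predictorSeed = 1L,
                             targets = defaultTargetPanel(),
                             config = engineConfig()) {
  stopifnot(is(fp, "Fingerprint"))
  if (is.character(targets))
    targets <- data.frame(target_name = targets,
                          panel = character(length(targets)),
                          sensitivity = rep(NA_real_, length(targets)),
                          specificity = rep(NA_real_, length(targets)),
                          stringsAsFactors = FALSE)
  if (nrow(targets) == 0L)
    return(data.frame(target_name = character(0), panel = character(0),
                      probability = numeric(0), color = character(0),
                      sensitivity = numeric(0), specificity = numeric(0),
                      stringsAsFactors = FALSE))
  nbits <- fp@nbits
  probs <- numeric(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    mseed <- (as.numeric(predictorSeed) * 1000003 +
              .stringHash(targets$target_name[i])) %% 2147483647
    mask <- withSeed(mseed, {
      msize <- sample(8:48, 1L)
      sort(sample.int(nbits, msize) - 1L)
    })
    probs[i] <- length(intersect(fp@onBits, mask)) / length(mask)
  }
  data.frame(target_name = targets$target_name, panel = targets$panel,
             probability = probs, color = colorCode(probs, config),
             sensitivity = targets$sensitivity,
             specificity = targets$specificity, stringsAsFactors = FALSE)
}

# Predictor registry: a predictor is a list(name, predict, metadata) where
# predict(smiles, fp, config) returns the referencePredict() column layout.
.predictorRegistry <- new.env(parent = emptyenv())

#' Register / fetch an activity predictor
#'
#' @param name Predictor name (the config's \code{predictor} field).
#' @param predict Function \code{(smiles, fp, config)} returning a data
#'   frame in the [referencePredict()] column layout; must be
#'   deterministic for fixed inputs.
#' @param metadata Free-form description (confusion metrics etc.).
#' @return `registerPredictor` the registered contract (invisibly);
#'   `getPredictor` the contract registered under \code{name}.
#' @export
registerPredictor <- function(name, predict, metadata = list()) {
  stopifnot(is.character(name), is.function(predict))
  contract <- list(name = name, predict = predict, metadata = metadata)
  assign(name, contract, envir = .predictorRegistry)
  invisible(contract)
}

#' @rdname registerPredictor
#' @export
getPredictor <- function(name) {
  if (!exists(name, envir = .predictorRegistry, inherits = FALSE))
    clStop("no predictor registered under '%s'", name,
           class = "ChemLinker_invalid_input")
  get(name, envir = .predictorRegistry, inherits = FALSE)
}

.registerBuiltinPredictors <- function() {
  registerPredictor("reference",
    function(smiles, fp, config)
      referencePredict(fp, predictorSeed = config@seed, config = config),
    metadata = list(description = "seeded bit-mask reference predictor"))
}
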