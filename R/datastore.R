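.OUTCOME_VOCAB <- c("active", "inactive", "inconclusive")

.TABLE_COLUMNS <- list(
  compounds = c("compound_id", "smiles", "fingerprint_hex", "popcount"),
  assays = c("assay_id", "name", "description"),
  outcomes = c("assay_id", "compound_id", "outcome", "score"),
  drugs = c("drug_id", "compound_id", "name", "usage_description", "source"),
  literature = c("paper_id", "title", "abstract", "compound_ids"),
  go_lexicon = c("go_id", "term_text"),
  go_genes = c("go_id", "gene"),
  chemgene = c("compound_id", "target", "target_kind", "relation", "source"),
  pathways = c("compound_id", "pathway_id", "pathway_name", "enzyme"),
  conformers = c("compound_id", "coords")
)

.emptyTable <- function(name) {
  cols <- .TABLE_COLUMNS[[name]]
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  df
}

# Strict TSV reader for the store dialect: header must match exactly,
# every row must have the header's field count; errors name file + line.
.readTable <- function(path, name) {
  cols <- .TABLE_COLUMNS[[name]]
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L)
    clStop("%s: empty file (missing header)", path,
           class = "ChemLinker_store_error")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  if (!identical(header, cols))
    clStop("%s:1: bad header (want: %s)", path, paste(cols, collapse = ", "),
           class = "ChemLinker_store_error")
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) return(.emptyTable(name))
  # field count from the raw tab count (strsplit drops trailing empties)
  ntab <- lengths(gregexpr("\t", body, fixed = TRUE))
  ntab[!grepl("\t", body, fixed = TRUE)] <- 0L
  if (any(ntab + 1L != length(cols))) {
    bad <- which(ntab + 1L != length(cols))[1L]
    clStop("%s:%d: expected %d tab-separated fields, found %d",
           path, bad + 1L, length(cols), ntab[bad] + 1L,
           class = "ChemLinker_store_error")
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  parts <- lapply(parts, function(p) c(p, rep("", length(cols) - length(p))))
  m <- do.call(rbind, parts)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- cols
  rownames(df) <- NULL
  df
}

.readGeneDisease <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L)
    clStop("%s: empty file", path, class = "ChemLinker_store_error")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1L] != "gene")
    clStop("%s:1: first column must be 'gene' followed by disease columns",
           path, class = "ChemLinker_store_error")
  diseases <- header[-1L]
  body <- lines[-1L]; body <- body[nzchar(body)]
  if (length(body) == 0L)
    return(matrix(numeric(0), nrow = 0, ncol = length(diseases),
                  dimnames = list(character(0), diseases)))
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1L]
    clStop("%s:%d: expected %d fields, found %d", path, bad + 1L,
           length(header), nf[bad], class = "ChemLinker_store_error")
  }
  genes <- vapply(parts, `[[`, character(1), 1L)
  vals <- matrix(suppressWarnings(as.numeric(
    unlist(lapply(parts, `[`, -1L)))), ncol = length(diseases), byrow = TRUE)
  if (anyNA(vals))
    clStop("%s: non-numeric score", path, class = "ChemLinker_store_error")
  dimnames(vals) <- list(genes, diseases)
  vals
}

.parseConformerTSV <- function(df, path) {
  confs <- list()
  for (i in seq_len(nrow(df))) {
    trips <- strsplit(df$coords[i], ";", fixed = TRUE)[[1]]
    xyz <- strsplit(trips, ":", fixed = TRUE)
    if (any(lengths(xyz) != 3L))
      clStop("%s:%d: coordinates must be x:y:z triples separated by ';'",
             path, i + 1L, class = "ChemLinker_store_error")
    m <- do.call(rbind, lapply(xyz, as.numeric))
    if (anyNA(m))
      clStop("%s:%d: non-numeric coordinate", path, i + 1L,
             class = "ChemLinker_store_error")
    confs[[df$compound_id[i]]] <- m
  }
  confs
}

# SDF/MOL V2000 conformers via ChemmineR; compound id taken from the
# molecule title line.
.readConformersSDF <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    clStop("reading conformers.sdf requires the ChemmineR package",
           class = "ChemLinker_store_error")
  sdf <- ChemmineR::read.SDFset(path)
  ids <- as.character(ChemmineR::sdfid(sdf))
  confs <- list()
  for (i in seq_along(ids)) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    confs[[ids[i]]] <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
  }
  confs
}

#' Load and index a local data store
#'
#' Reads the flat-file store dialect from a directory: \code{compounds.tsv}
#' (required) plus the optional tables \code{assays.tsv},
#' \code{outcomes.tsv}, \code{drugs.tsv}, \code{literature.tsv},
#' \code{go_lexicon.tsv}, \code{go_genes.tsv}, \code{gene_disease.tsv},
#' \code{chemgene.tsv}, \code{pathways.tsv} and conformers as
#' \code{conformers.tsv} (\code{compound_id<TAB>x:y:z;x:y:z;...}) or
#' \code{conformers.sdf} (V2000, id from the title line). All identifiers
#' are case-sensitive. Cross-references are validated at load: any table
#' row naming a compound absent from the compound table is a fatal
#' validation error listing the offenders. Unknown bioassay outcome words
#' are a load error. Missing optional tables are logged and yield empty
#' report sections downstream. The popcount index and the 12-moment shape
#' descriptors are built during the load.
#'
#' @param storeDir Directory containing the tables.
#' @param config An [EngineConfig-class]; its \code{fingerprintLength}
#'   governs fingerprint parsing.
#' @return A [DataStore-class].
#' @seealso [validateStore()], [generateFixtureStore()]
#' @export
loadStore <- function(storeDir, config = engineConfig()) {
  if (!dir.exists(storeDir))
    clStop("store directory not found: %s", storeDir,
           class = "ChemLinker_store_error")
  cpath <- file.path(storeDir, "compounds.tsv")
  if (!file.exists(cpath))
    clStop("%s is missing compounds.tsv", storeDir,
           class = "ChemLinker_store_error")
  compounds <- .readTable(cpath, "compounds")
  nbits <- config@fingerprintLength
  fps <- lapply(compounds$fingerprint_hex, hexToFp, nbits = nbits)
  names(fps) <- compounds$compound_id
  pc <- suppressWarnings(as.integer(compounds$popcount))
  actual <- vapply(fps, popcount, integer(1))
  if (anyNA(pc) || any(pc != actual)) {
    bad <- which(is.na(pc) | pc != actual)[1L]
    clStop("%s:%d: popcount column disagrees with fingerprint_hex for '%s'",
           cpath, bad + 1L, compounds$compound_id[bad],
           class = "ChemLinker_store_error")
  }
  if (anyDuplicated(compounds$compound_id))
    clStop("%s: duplicate compound_id '%s'", cpath,
           compounds$compound_id[anyDuplicated(compounds$compound_id)],
           class = "ChemLinker_store_error")
  index <- buildBitcountIndex(fps)

  opt <- function(file, name) {
    p <- file.path(storeDir, file)
    if (file.exists(p)) .readTable(p, name)
    else {
      clNotice("optional table %s absent; the matching report section will be empty", file)
      .emptyTable(name)
    }
  }
  assays <- opt("assays.tsv", "assays")
  outcomes <- opt("outcomes.tsv", "outcomes")
  drugs <- opt("drugs.tsv", "drugs")
  literature <- opt("literature.tsv", "literature")
  goLexicon <- opt("go_lexicon.tsv", "go_lexicon")
  goGenes <- opt("go_genes.tsv", "go_genes")
  chemGene <- opt("chemgene.tsv", "chemgene")
  pathways <- opt("pathways.tsv", "pathways")

  gdPath <- file.path(storeDir, "gene_disease.tsv")
  geneDisease <- if (file.exists(gdPath)) .readGeneDisease(gdPath)
  else {
    clNotice("optional table gene_disease.tsv absent; disease annotation disabled")
    matrix(numeric(0), 0, 0)
  }

  confs <- list()
  tsvPath <- file.path(storeDir, "conformers.tsv")
  sdfPath <- file.path(storeDir, "conformers.sdf")
  if (file.exists(tsvPath))
    confs <- .parseConformerTSV(.readTable(tsvPath, "conformers"), tsvPath)
  else if (file.exists(sdfPath))
    confs <- .readConformersSDF(sdfPath)
  else clNotice("no conformer table; 3D search disabled")

  bad <- !outcomes$outcome %in% .OUTCOME_VOCAB
  if (any(bad))
    clStop("outcomes.tsv: unknown outcome '%s' (allowed: %s)",
           outcomes$outcome[which(bad)[1L]],
           paste(.OUTCOME_VOCAB, collapse = ", "),
           class = "ChemLinker_store_error")
  dupPair <- duplicated(outcomes[, c("assay_id", "compound_id")])
  if (any(dupPair))
    clNotice("outcomes.tsv: %d repeated (assay, compound) pairs", sum(dupPair))

  known <- compounds$compound_id
  checkRefs <- function(ids, label) {
    ids <- ids[nzchar(ids)]
    missing <- setdiff(unique(ids), known)
    if (length(missing))
      clStop("%s references unknown compound_id(s): %s", label,
             paste(missing, collapse = ", "),
             class = "ChemLinker_store_error")
  }
  checkRefs(outcomes$compound_id, "outcomes.tsv")
  checkRefs(drugs$compound_id, "drugs.tsv")
  checkRefs(chemGene$compound_id, "chemgene.tsv")
  checkRefs(pathways$compound_id, "pathways.tsv")
  checkRefs(unlist(strsplit(literature$compound_ids, ";", fixed = TRUE)),
            "literature.tsv")
  checkRefs(names(confs), "conformers")
  missingAssay <- setdiff(unique(outcomes$assay_id), assays$assay_id)
  if (length(missingAssay))
    clStop("outcomes.tsv references unknown assay_id(s): %s",
           paste(missingAssay, collapse = ", "),
           class = "ChemLinker_store_error")

  shapes <- if (length(confs)) {
    s <- vapply(confs, usrDescriptor, numeric(12))
    if (is.null(dim(s))) s <- matrix(s, nrow = 12,
                                     dimnames = list(NULL, names(confs)))
    s
  } else matrix(numeric(0), nrow = 12, ncol = 0)

  new("DataStore", compounds = compounds, index = index, conformers = confs,
      shapes = shapes, assays = assays, outcomes = outcomes, drugs = drugs,
      literature = literature, goLexicon = goLexicon, goGenes = goGenes,
      geneDisease = geneDisease, chemGene = chemGene, pathways = pathways,
      sourceDir = normalizePath(storeDir))
}

#' Re-check every store invariant
#'
#' Unlike the fail-fast checks inside [loadStore()], this returns issues
#' as data rather than raising: one row per problem, empty when the store
#' is internally consistent.
#'
#' @param store A [DataStore-class].
#' @return Data frame with columns \code{table}, \code{issue}.
#' @export
validateStore <- function(store) {
  issues <- list()
  add <- function(table, issue)
    issues[[length(issues) + 1L]] <<- data.frame(table = table, issue = issue,
                                                 stringsAsFactors = FALSE)
  known <- store@compounds$compound_id
  dup <- unique(known[duplicated(known)])
  for (d in dup) add("compounds", sprintf("duplicate compound_id '%s'", d))

  for (i in seq_len(nrow(store@compounds))) {
    fp <- tryCatch(hexToFp(store@compounds$fingerprint_hex[i],
                           store@index@nbits), error = function(e) NULL)
    if (is.null(fp)) {
      add("compounds", sprintf("row %d: malformed fingerprint_hex", i))
    } else if (popcount(fp) != as.integer(store@compounds$popcount[i]))
      add("compounds", sprintf("row %d ('%s'): popcount mismatch", i,
                               store@compounds$compound_id[i]))
  }

  dupA <- unique(store@assays$assay_id[duplicated(store@assays$assay_id)])
  for (d in dupA) add("assays", sprintf("duplicate assay_id '%s'", d))

  badOut <- !store@outcomes$outcome %in% .OUTCOME_VOCAB
  for (i in which(badOut))
    add("outcomes", sprintf("row %d: unknown outcome '%s'", i,
                            store@outcomes$outcome[i]))

  refCheck <- function(ids, table) {
    for (m in setdiff(unique(ids[nzchar(ids)]), known))
      add(table, sprintf("unknown compound_id '%s'", m))
  }
  refCheck(store@outcomes$compound_id, "outcomes")
  refCheck(store@drugs$compound_id, "drugs")
  refCheck(store@chemGene$compound_id, "chemgene")
  refCheck(store@pathways$compound_id, "pathways")
  refCheck(unlist(strsplit(store@literature$compound_ids, ";", fixed = TRUE)),
           "literature")
  refCheck(names(store@conformers), "conformers")
  for (m in setdiff(unique(store@outcomes$assay_id), store@assays$assay_id))
    add("outcomes", sprintf("unknown assay_id '%s'", m))

  gd <- store@geneDisease
  if (length(gd)) {
    dupG <- unique(rownames(gd)[duplicated(rownames(gd))])
    for (d in dupG) add("gene_disease", sprintf("duplicate gene '%s'", d))
    dupD <- unique(colnames(gd)[duplicated(colnames(gd))])
    for (d in dupD) add("gene_disease", sprintf("duplicate disease '%s'", d))
    bad <- which(gd < 0 | gd > 1, arr.ind = TRUE)
    for (i in seq_len(nrow(bad)))
      add("gene_disease",
          sprintf("score %g out of [0,1] at gene '%s', disease '%s'",
                  gd[bad[i, 1L], bad[i, 2L]],
                  rownames(gd)[bad[i, 1L]], colnames(gd)[bad[i, 2L]]))
  }

  badGo <- !grepl("^GO:[0-9]{7}$", store@goLexicon$go_id)
  for (i in which(badGo))
    add("go_lexicon", sprintf("row %d: malformed go_id '%s'", i,
                              store@goLexicon$go_id[i]))
  for (i in which(!nzchar(store@goLexicon$term_text)))
    add("go_lexicon", sprintf("row %d: empty term_text", i))

  if (length(issues)) do.call(rbind, issues)
  else data.frame(table = character(0), issue = character(0),
                  stringsAsFactors = FALSE)
}
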