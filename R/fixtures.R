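#' Describe a synthetic fixture store
#'
#' A fixture spec fixes the size and the planted content of a generated
#' store. Each planted chain describes one compound at an exact target
#' similarity to the designated query, wired end-to-end through every
#' table: an active assay whose description embeds a GO lexicon term, an
#' inactive assay, a drug, a chemical-gene relation, a pathway row, a
#' literature row, and a gene-disease matrix entry completing the
#' assay -> GO term -> gene -> disease chain.
#'
#' @param seed Integer seed; the whole store is a pure function of the spec.
#' @param nCompounds,nAssays,nDrugs,nPapers,nGenes,nDiseases Decoy table
#'   sizes (positive).
#' @param plantedChains List of chains, each a list with
#'   \code{similarity} in (0, 1], \code{goTerm} (lexicon phrase),
#'   \code{gene}, \code{disease}, \code{diseaseScore} in [0, 1].
#' @param threshold Similarity threshold the decoys must stay clear of
#'   (decoys are kept at or below \code{threshold - margin}).
#' @param margin Decoy safety margin below the threshold (default 0.05).
#' @return A \code{FixtureSpec} list.
#' @seealso [generateFixtureStore()]
#' @export
fixtureSpec <- function(seed = 1L, nCompounds = 300L, nAssays = 30L,
                        nDrugs = 20L, nPapers = 25L, nGenes = 30L,
                        nDiseases = 12L,
                        plantedChains = list(
                          list(similarity = 0.9, goTerm = "apoptosis",
                               gene = "BCL2", disease = "lymphoma",
                               diseaseScore = 0.9),
                          list(similarity = 1.0, goTerm = "cell cycle",
                               gene = "TP53", disease = "breast carcinoma",
                               diseaseScore = 0.8)),
                        threshold = 0.85, margin = 0.05) {
  counts <- c(nCompounds, nAssays, nDrugs, nPapers, nGenes, nDiseases)
  if (any(counts < 1L))
    clStop("fixture counts must be positive", class = "ChemLinker_invalid_input")
  for (ch in plantedChains) {
    if (ch$similarity <= 0 || ch$similarity > 1)
      clStop("planted similarity must lie in (0, 1]",
             class = "ChemLinker_invalid_input")
  }
  structure(list(seed = as.integer(seed), nCompounds = as.integer(nCompounds),
                 nAssays = as.integer(nAssays), nDrugs = as.integer(nDrugs),
                 nPapers = as.integer(nPapers), nGenes = as.integer(nGenes),
                 nDiseases = as.integer(nDiseases),
                 plantedChains = plantedChains,
                 threshold = threshold, margin = margin),
            class = "FixtureSpec")
}

# Exact rational representation p/q of a similarity target (q <= 200).
.asRational <- function(t) {
  for (q in 1:200) {
    p <- round(t * q)
    if (p >= 1 && abs(t * q - p) < 1e-9) {
      g <- .gcd(p, q)
      return(c(p = p / g, q = q / g))
    }
  }
  clStop("similarity %g has no small exact rational form", t,
         class = "ChemLinker_generation_error")
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

# Integer (intersection c, popcount b) achieving Tanimoto exactly p/q
# against a query with popcount a, within nbits; NULL if infeasible.
.solvePlant <- function(a, p, q, nbits) {
  p <- unname(p); q <- unname(q)
  lo <- ceiling(a / q)
  hi <- min(floor(a / p), floor(nbits / q))
  if (lo > hi) return(NULL)
  k <- hi                     # largest feasible k: biggest shared bit set
  c(inter = p * k, b = q * k + p * k - a)
}

#' Seeded random conformer
#'
#' Uniform atom coordinates in the cube \eqn{[-5, 5]^3} Angstrom;
#' deterministic for a fixed seed.
#'
#' @param nAtoms Number of atoms (>= 1).
#' @param seed Integer seed.
#' @return Numeric nAtoms x 3 matrix.
#' @export
randomConformer <- function(nAtoms, seed = 1L) {
  if (!is.numeric(nAtoms) || length(nAtoms) != 1L || nAtoms < 1)
    clStop("nAtoms must be a positive integer",
           class = "ChemLinker_invalid_input")
  withSeed(seed, matrix(stats::runif(as.integer(nAtoms) * 3L, -5, 5),
                        ncol = 3L))
}

#' Random rigid motion
#'
#' `randomRotation` draws a proper rotation matrix (via QR of a Gaussian
#' matrix, determinant forced to +1); `applyRigid` applies
#' \code{coords %*% t(R) + tr}. Used to plant 3D neighbours and to test
#' rigid-motion invariance of the shape descriptor.
#'
#' @param seed Integer seed.
#' @param coords n x 3 coordinate matrix.
#' @param R 3 x 3 rotation matrix.
#' @param tr Length-3 translation vector.
#' @return `randomRotation` a 3 x 3 matrix; `applyRigid` the transformed
#'   coordinates.
#' @export
randomRotation <- function(seed = 1L) {
  withSeed(seed, {
    qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1L] <- -R[, 1L]
    R
  })
}

#' @rdname randomRotation
#' @export
applyRigid <- function(coords, R, tr = c(0, 0, 0)) {
  sweep(coords %*% t(R), 2L, -tr)
}

.fmtCoord <- function(m) {
  paste(apply(m, 1L, function(r)
    paste(sprintf("%.10g", r), collapse = ":")), collapse = ";")
}

.writeTSV <- function(path, header, rows) {
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, function(r) paste(r, collapse = "\t"), character(1)))
  writeLines(lines, path, useBytes = TRUE)
}

.SMILES_FRAGMENTS <- c("C", "N", "O", "S", "Cl", "F", "CC", "C=C", "C#N",
                       "c1ccccc1", "C(=O)O", "C(=O)N", "CO", "CN", "c1ccncc1",
                       "C1CCCCC1", "OC", "N(C)C", "C(F)(F)F", "S(=O)(=O)N")

.randomSmiles <- function() {
  n <- sample(3:8, 1L)
  paste(sample(.SMILES_FRAGMENTS, n, replace = TRUE), collapse = "")
}

.GO_PHRASES <- c("apoptosis", "cell cycle", "signal transduction",
                 "DNA repair", "oxidative stress response",
                 "protein folding", "lipid metabolism", "immune response",
                 "angiogenesis", "chromatin remodeling")

#' Generate a complete synthetic fixture store
#'
#' Writes every table of the store dialect into \code{outDir}: a compound
#' table whose planted entries achieve their target Tanimoto similarity
#' to the designated query exactly (integer-constructed fingerprints),
#' decoy compounds guaranteed at least \code{margin} below the threshold,
#' referentially intact assay/outcome/drug/literature/GO/gene-disease/
#' chemical-gene/pathway tables wiring each planted chain end-to-end, and
#' conformers including a rigidly transformed copy of the query conformer
#' assigned to the first planted compound. The same spec always produces
#' byte-identical directories. A manifest (also written to
#' \code{manifest.json}) records the query and every expected finding.
#'
#' @param spec A [fixtureSpec()].
#' @param outDir Output directory (created if needed).
#' @return The manifest, invisibly a list: \code{query_smiles},
#'   \code{query_conformer}, \code{chains} (per-chain expected ids),
#'   \code{decoy_compounds}.
#' @export
generateFixtureStore <- function(spec, outDir) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  nbits <- 166L
  nChain <- length(spec$plantedChains)

  withSeed(spec$seed, {
    # -- designated query: retry until every planted similarity is exactly
    #    achievable against its hash fingerprint
    query <- NULL
    for (attempt in 1:200) {
      cand <- .randomSmiles()
      fp <- hashFingerprint(cand, nbits)
      a <- popcount(fp)
      sol <- lapply(spec$plantedChains, function(ch) {
        pq <- .asRational(ch$similarity)
        .solvePlant(a, pq["p"], pq["q"], nbits)
      })
      if (a >= 20L && !any(vapply(sol, is.null, logical(1)))) {
        query <- list(smiles = cand, fp = fp, sol = sol)
        break
      }
    }
    if (is.null(query))
      clStop("no query admits the planted similarity targets exactly",
             class = "ChemLinker_generation_error")
    qBits <- query$fp@onBits
    qOff <- setdiff(0:(nbits - 1L), qBits)
    a <- length(qBits)

    # -- planted compounds
    plantIds <- sprintf("CPLANT%03d", seq_len(nChain))
    plantFps <- vector("list", nChain)
    for (i in seq_len(nChain)) {
      s <- query$sol[[i]]
      inter <- qBits[seq_len(s["inter"])]
      extra <- if (s["b"] > s["inter"])
        qOff[seq_len(s["b"] - s["inter"])] else integer(0)
      plantFps[[i]] <- fingerprint(c(inter, extra), nbits)
    }

    # -- decoy compounds, kept clear of the threshold
    nDecoy <- spec$nCompounds
    decoyIds <- sprintf("CDEC%04d", seq_len(nDecoy))
    decoyFps <- vector("list", nDecoy)
    lim <- spec$threshold - spec$margin
    for (i in seq_len(nDecoy)) {
      repeat {
        pc <- sample(15:80, 1L)
        f <- fingerprint(sort(sample.int(nbits, pc) - 1L), nbits)
        if (tanimoto(f, query$fp) <= lim) { decoyFps[[i]] <- f; break }
      }
    }

    ids <- c(plantIds, decoyIds)
    fps <- c(plantFps, decoyFps)
    smiles <- c(vapply(seq_len(nChain), function(i) .randomSmiles(),
                       character(1)),
                vapply(seq_len(nDecoy), function(i) .randomSmiles(),
                       character(1)))
    .writeTSV(file.path(outDir, "compounds.tsv"),
              c("compound_id", "smiles", "fingerprint_hex", "popcount"),
              lapply(seq_along(ids), function(i)
                c(ids[i], smiles[i], fpToHex(fps[[i]]),
                  popcount(fps[[i]]))))

    # -- GO lexicon: planted phrases first, then decoy phrases
    phrases <- unique(c(vapply(spec$plantedChains, `[[`, character(1),
                               "goTerm"),
                        .GO_PHRASES))
    goIds <- sprintf("GO:%07d", 6900000L + seq_along(phrases))
    names(goIds) <- phrases
    .writeTSV(file.path(outDir, "go_lexicon.tsv"), c("go_id", "term_text"),
              lapply(seq_along(phrases), function(i)
                c(goIds[i], phrases[i])))

    # -- genes / diseases
    genes <- unique(c(vapply(spec$plantedChains, `[[`, character(1), "gene"),
                      sprintf("GENE%03d", seq_len(spec$nGenes))))
    diseases <- unique(c(vapply(spec$plantedChains, `[[`, character(1),
                                "disease"),
                         sprintf("disease_%02d", seq_len(spec$nDiseases))))
    gd <- matrix(round(stats::runif(length(genes) * length(diseases),
                                    0.05, 0.45), 3),
                 nrow = length(genes), dimnames = list(genes, diseases))
    goGeneRows <- list()
    for (i in seq_len(nChain)) {
      ch <- spec$plantedChains[[i]]
      gd[ch$gene, ch$disease] <- ch$diseaseScore
      goGeneRows[[length(goGeneRows) + 1L]] <- c(goIds[ch$goTerm], ch$gene)
    }
    # decoy GO->gene links from decoy phrases to decoy genes
    decoyPhr <- setdiff(phrases, vapply(spec$plantedChains, `[[`,
                                        character(1), "goTerm"))
    for (i in seq_along(decoyPhr)) {
      g <- sprintf("GENE%03d", ((i - 1L) %% spec$nGenes) + 1L)
      goGeneRows[[length(goGeneRows) + 1L]] <- c(goIds[decoyPhr[i]], g)
    }
    .writeTSV(file.path(outDir, "go_genes.tsv"), c("go_id", "gene"),
              goGeneRows)
    .writeTSV(file.path(outDir, "gene_disease.tsv"),
              c("gene", diseases),
              lapply(seq_along(genes), function(i)
                c(genes[i], sprintf("%.3f", gd[i, ]))))

    # -- assays + outcomes: one active and one inactive assay per chain
    assayRows <- list(); outcomeRows <- list()
    chainAssays <- list()
    for (i in seq_len(nChain)) {
      ch <- spec$plantedChains[[i]]
      actId <- sprintf("APLANTACT%02d", i)
      inaId <- sprintf("APLANTINA%02d", i)
      assayRows[[length(assayRows) + 1L]] <-
        c(actId, sprintf("planted active assay %d", i),
          sprintf("Screen for modulators of %s in tumor cells", ch$goTerm))
      assayRows[[length(assayRows) + 1L]] <-
        c(inaId, sprintf("planted inactive assay %d", i),
          sprintf("Counter-screen measuring %s related readout", ch$goTerm))
      outcomeRows[[length(outcomeRows) + 1L]] <-
        c(actId, plantIds[i], "active", "95")
      outcomeRows[[length(outcomeRows) + 1L]] <-
        c(inaId, plantIds[i], "inactive", "5")
      chainAssays[[i]] <- list(active = actId, inactive = inaId)
    }
    for (i in seq_len(spec$nAssays)) {
      aid <- sprintf("ADEC%03d", i)
      phr <- decoyPhr[((i - 1L) %% max(1L, length(decoyPhr))) + 1L]
      assayRows[[length(assayRows) + 1L]] <-
        c(aid, sprintf("decoy assay %d", i),
          sprintf("Assay %d probing %s", i, phr))
      cid <- decoyIds[((i - 1L) %% nDecoy) + 1L]
      outcomeRows[[length(outcomeRows) + 1L]] <-
        c(aid, cid, c("active", "inactive", "inconclusive")[(i %% 3L) + 1L],
          as.character(i))
    }
    .writeTSV(file.path(outDir, "assays.tsv"),
              c("assay_id", "name", "description"), assayRows)
    .writeTSV(file.path(outDir, "outcomes.tsv"),
              c("assay_id", "compound_id", "outcome", "score"), outcomeRows)

    # -- drugs
    drugRows <- list()
    for (i in seq_len(nChain)) {
      ch <- spec$plantedChains[[i]]
      drugRows[[length(drugRows) + 1L]] <-
        c(sprintf("DRPLANT%02d", i), plantIds[i],
          sprintf("planteddrug%d", i),
          sprintf("Used against disorders of %s regulation", ch$goTerm),
          "drugbank-like")
    }
    for (i in seq_len(spec$nDrugs))
      drugRows[[length(drugRows) + 1L]] <-
        c(sprintf("DRDEC%03d", i), decoyIds[((i - 1L) %% nDecoy) + 1L],
          sprintf("decoydrug%d", i), sprintf("Decoy indication %d", i),
          c("drugbank-like", "mrtd-like")[(i %% 2L) + 1L])
    .writeTSV(file.path(outDir, "drugs.tsv"),
              c("drug_id", "compound_id", "name", "usage_description",
                "source"), drugRows)

    # -- literature
    paperRows <- list()
    for (i in seq_len(nChain)) {
      ch <- spec$plantedChains[[i]]
      paperRows[[length(paperRows) + 1L]] <-
        c(sprintf("PMPLANT%02d", i),
          sprintf("Planted paper %d on %s modulation", i, ch$goTerm),
          sprintf("We study %s in disease models.", ch$goTerm),
          plantIds[i])
    }
    for (i in seq_len(spec$nPapers))
      paperRows[[length(paperRows) + 1L]] <-
        c(sprintf("PMDEC%03d", i), sprintf("Decoy paper %d", i),
          sprintf("Abstract of decoy paper %d.", i),
          decoyIds[((i - 1L) %% nDecoy) + 1L])
    .writeTSV(file.path(outDir, "literature.tsv"),
              c("paper_id", "title", "abstract", "compound_ids"), paperRows)

    # -- chemical-gene relations and pathways
    cgRows <- list(); pwRows <- list()
    for (i in seq_len(nChain)) {
      ch <- spec$plantedChains[[i]]
      cgRows[[length(cgRows) + 1L]] <-
        c(plantIds[i], ch$gene, "gene", "increases-expression", "ctd-like")
      pwRows[[length(pwRows) + 1L]] <-
        c(plantIds[i], sprintf("PWPLANT%02d", i),
          sprintf("planted pathway %d", i), sprintf("enzyme%d", i))
    }
    for (i in seq_len(spec$nAssays)) {
      cid <- decoyIds[((i - 1L) %% nDecoy) + 1L]
      cgRows[[length(cgRows) + 1L]] <-
        c(cid, sprintf("GENE%03d", ((i - 1L) %% spec$nGenes) + 1L),
          c("gene", "disease", "enzyme-activity")[(i %% 3L) + 1L],
          "decreases-activity", c("ctd-like", "chembl-like")[(i %% 2L) + 1L])
      pwRows[[length(pwRows) + 1L]] <-
        c(cid, sprintf("PWDEC%03d", i), sprintf("decoy pathway %d", i), "")
    }
    .writeTSV(file.path(outDir, "chemgene.tsv"),
              c("compound_id", "target", "target_kind", "relation", "source"),
              cgRows)
    .writeTSV(file.path(outDir, "pathways.tsv"),
              c("compound_id", "pathway_id", "pathway_name", "enzyme"),
              pwRows)

    # -- conformers: random decoys plus a rigid copy of the query conformer
    #    planted on the first chain compound
    queryConf <- matrix(stats::runif(3L * 12L, -5, 5), ncol = 3L)
    R <- qr.Q(qr(matrix(stats::rnorm(9L), 3L, 3L)))
    if (det(R) < 0) R[, 1L] <- -R[, 1L]
    tr <- stats::runif(3L, -3, 3)
    confRows <- list()
    if (nChain >= 1L)
      confRows[[1L]] <- c(plantIds[1L],
                          .fmtCoord(applyRigid(queryConf, R, tr)))
    nConf <- min(40L, nDecoy)
    for (i in seq_len(nConf))
      confRows[[length(confRows) + 1L]] <-
        c(decoyIds[i],
          .fmtCoord(matrix(stats::runif(3L * sample(8:20, 1L), -5, 5),
                           ncol = 3L)))
    .writeTSV(file.path(outDir, "conformers.tsv"),
              c("compound_id", "coords"), confRows)

    manifest <- list(
      query_smiles = query$smiles,
      query_popcount = a,
      query_conformer = unname(apply(queryConf, 1L, function(r)
        as.list(r), simplify = FALSE)),
      threshold = spec$threshold,
      chains = lapply(seq_len(nChain), function(i) {
        ch <- spec$plantedChains[[i]]
        list(compound_id = plantIds[i],
             similarity = ch$similarity,
             active_assay = chainAssays[[i]]$active,
             inactive_assay = chainAssays[[i]]$inactive,
             go_id = unname(goIds[ch$goTerm]), go_term = ch$goTerm,
             gene = ch$gene, disease = ch$disease,
             disease_score = ch$diseaseScore,
             drug_id = sprintf("DRPLANT%02d", i),
             paper_id = sprintf("PMPLANT%02d", i),
             pathway_id = sprintf("PWPLANT%02d", i))
      }),
      planted_3d_neighbor = if (nChain >= 1L) plantIds[1L] else NULL,
      decoy_compounds = decoyIds)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  })
}

#' Read a fixture manifest back
#'
#' @param storeDir Directory written by [generateFixtureStore()].
#' @return The manifest list; \code{query_conformer} as a numeric matrix.
#' @export
readManifest <- function(storeDir) {
  m <- jsonlite::read_json(file.path(storeDir, "manifest.json"),
                           simplifyVector = FALSE)
  m$query_conformer <- do.call(rbind, lapply(m$query_conformer,
                                             function(r) unlist(r)))
  m
}
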