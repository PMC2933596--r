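---
title: "Similarity-based evidence aggregation: models, parameters and design choices"
author: "ChemLinker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-based evidence aggregation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChemLinker)
options(ChemLinker.quiet = TRUE)
```

ChemLinker answers one question: *what does a local knowledge store say
about molecules similar to this one?* The answer is assembled from two
similarity searches (2D fingerprints, 3D shape), a text-mining chain
that turns assay and drug descriptions into disease hypotheses, and a
pluggable activity predictor, all serialized into a fixed six-section
report. This vignette explains each model, the parameters that matter,
and the decisions taken where the design was genuinely open.

## 2D similarity and the pruning bound

Compounds are represented by fixed-length binary structural-key
fingerprints (166 bits by default, the classic structural-key length).
Similarity is the Tanimoto coefficient over on bits,
$T(A,B) = |A \cap B| / |A \cup B|$, and a search returns all compounds
with $T \ge t$ for threshold $t$ (default 0.85 — a conventional "very
similar" cutoff under the similar-property principle that structurally
similar molecules tend to share biological properties).

The search is exact but pruned. For popcounts $a$ and $b$, the largest
achievable Tanimoto is
$$T_{\max}(a,b) = \frac{\min(a,b)}{a + b - \min(a,b)},$$
attained exactly when the smaller bit set is contained in the larger.
The store is therefore indexed into popcount buckets, and a bucket is
scanned only if $T_{\max}(a,b) \ge t$. Because the bound is an upper
bound, pruning can never discard a true hit; the test suite and the
acceptance script verify set- and order-identity against an exhaustive
scan at scale (10,000 fingerprints × 50 queries × thresholds
{0.70, 0.85, 0.95}).

Decisions worth recording:

* **Threshold comparison.** The default is *at-or-above* ($\ge t$), with
  a `strictThreshold` switch for strictly-above. Inclusive comparison is
  the default because exact-equality hits — including a stored copy of
  the query itself at similarity 1.0 — must be representable.
* **Empty fingerprints.** $T(\emptyset,\emptyset)$ is defined as 0:
  two structureless bit vectors carry no evidence of similarity. The
  value is an argument (`empty=`) for callers who prefer `NA`.
* **Tie-breaks.** Hits are ordered by similarity descending, then
  compound id ascending (radix order), so reports are byte-deterministic.
* **Serialization.** Fingerprints travel in tables as big-endian hex
  strings, bit 0 the least-significant bit of the last digit — fixed
  here because a flat-file store needs one canonical form.
* **Query fingerprinting is a contract, not a chemistry claim.** The
  bundled `hashFingerprint()` maps character n-grams of the SMILES onto
  bit positions with a fixed polynomial hash. It is deterministic and
  self-consistent, which is all the engine and its fixtures need; it
  makes no claim of bit-compatibility with MACCS-style key catalogues.
  A real-chemistry backend plugs in wherever a `Fingerprint` is
  accepted (`runQuery(fp = ...)`).

## 3D shape descriptors

A conformer is summarised by the 12-value ultrafast shape recognition
signature: for each of four reference points — centroid, atom closest to
the centroid, atom farthest from the centroid, atom farthest from that
atom — the distance set from all atoms is reduced to (mean, standard
deviation, signed cube root of the third central moment). Ranking is by
Euclidean distance between signatures, ascending, ties by compound id.

Numerical choices, stated so tests can be exact:

* **Population moments** (divide by $n$, not $n-1$): the descriptor of a
  two-atom conformer at distance 2 is then exactly
  `[1,0,0, 1,1,0, 1,1,0, 1,1,0]`, which the tests assert to 1e-12.
* **Signed cube root** $\mathrm{sign}(m_3)\,|m_3|^{1/3}$ preserves skew
  direction for negative third moments.
* **Reference-atom ties** break to the lowest atom index; atom-order
  invariance therefore holds whenever reference distances are unique,
  and is tested only on such conformers.
* **Degenerate inputs**: a single atom (or any fully coincident set)
  yields the all-zero descriptor; empty coordinate sets are an error.
* **All atoms present in a record are used** — no element filtering —
  because input conformer tables are taken at face value.
* **Distance, not similarity**, is reported; any similarity transform of
  Euclidean distance is monotone, so ranking carries all information and
  callers may rescale as they wish.

Rigid-motion invariance is a mathematical property of the construction;
the suite checks it to a relative tolerance of 1e-8 over 100 random
conformers × 10 random rotations/translations (observed error is at
machine-precision level, ~1e-13).

## Text-to-disease chaining

Assay descriptions, drug usage descriptions and paper titles/abstracts
all pass through the same path:

1. **GO tagging** by dictionary phrase matching against the store's
   lexicon: case-insensitive, word-boundary-respecting exact phrases;
   overlapping candidates resolve longest-first, then leftmost. This
   was chosen over stemming or statistical concept recognition because
   it is deterministic, dependency-free and exactly testable; the cost
   is that inflected or paraphrased mentions are missed.
2. **GO → genes** through an explicit two-column table. An explicit
   table was preferred to ontology traversal: inputs stay inspectable
   and the chain is reproducible without an ontology snapshot.
3. **Genes → diseases** through a gene × disease score matrix in
   [0, 1]. A disease's score is the **maximum** over the contributing
   genes — the most-supported signal — with every gene reaching the
   floor retained as support. Mean-aggregation was rejected because one
   strong gene–disease link should not be diluted by weak co-mentions.
4. **Reporting floor** `diseaseMinScore = 0.5`: the midpoint of the
   score range, i.e. better-than-chance association; it is a
   configuration field, and raising it provably only removes diseases
   (tested across a grid).

Every reported disease carries its complete provenance — one chain per
supporting (GO term, gene) pair, each chain the ordered links
assay/drug/paper → GO term → gene → disease — so a reader can audit any
annotation. Gene symbols compare case-insensitively only inside this
annotation step; identifiers elsewhere are case-sensitive.

## Predictors and colour coding

Activity prediction is a plug-in contract: a registered predictor maps
(smiles, fingerprint, config) to a per-target table of probabilities.
Probabilities are colour-coded red ($p \ge 0.7$), yellow
($0.6 \le p < 0.7$), grey ($p < 0.6$); both cutoffs are configuration
fields, and the coding is a monotone step function by construction.
Confusion metrics (sensitivity/specificity) are pass-through metadata so
a reader can judge a model's validity; they are never recomputed.

The shipped `reference` predictor scores a fingerprint by its overlap
with a seeded pseudo-random bit mask per target,
$|fp \cap M_t|/|M_t|$, over a default panel of 40 synthetic tumor
cell-line targets spread across the usual panels (renal, non-small cell
lung, breast, colon, ...). It exists to exercise the contract and the
report layout deterministically — it encodes no chemistry, and is
documented as such.

## The aggregate report

The report always contains exactly six sections, in fixed order:
`predictive_models`, `active_similars`, `chemogenomics_similars`,
`systems_similars`, `literature_similars`, `inactive_similars`.
Missing optional tables yield empty sections (with a logged notice),
never a missing element. Drug hits live inside `active_similars`, next
to the bioassay actives, because both answer "what is known to *work*
for molecules like this"; the inactive section mirrors the active one
for inactive outcomes. Inconclusive outcomes appear in neither.
Literature hits are collapsed to one entry per paper with all matching
compounds attached, avoiding one row per (paper, compound) pair.

Ordering is fully specified (similarity descending, ids ascending;
literature by best compound similarity then paper id), each section is
truncated to `maxHitsPerSection` (default 100) by rank with a logged
notice, and XML serialization round-trips byte-identically
(serialize → parse → serialize). The report's metadata records the
configuration snapshot and store identity; its timestamp field is left
empty unless the caller supplies one, so that identical inputs always
produce byte-identical reports — determinism was judged more valuable
as a default than wall-clock stamping, which remains available
(`runQuery(timestamp = ...)`, used by the CLI).

## What the fixture generator emulates — and what it does not

`generateFixtureStore()` builds a complete store from a seed: decoy
compounds, assays, drugs, papers, GO lexicon, GO→gene map, gene×disease
matrix, relations, pathways, conformers — referentially intact for any
seed, and byte-identical across runs of the same spec.

Its planted chains are the load-bearing part. Each chain plants a
compound whose fingerprint achieves its target similarity **exactly**,
by solving $c/(a+b-c) = p/q$ in integers (intersection $c$, planted
popcount $b$) against the query's popcount $a$; candidate queries are
drawn until all targets are exactly representable. Default targets are
0.9 and 1.0: one clearly-above-threshold neighbour and one stored copy
of the query, exercising the inclusive-threshold edge. Decoys are
rejection-sampled to at least 0.05 below the search threshold, so no
floating-point boundary can flip them into the hit set. A rigidly
transformed copy of the query conformer is planted as the expected
3D nearest neighbour.

Default sizes (300 decoy compounds; 120 in the repeated end-to-end
runs; 10,000 fingerprints for the pruning checks; 100 conformers × 10
transforms for invariance) were chosen as the smallest scales at which
the pruning and bucketing machinery is genuinely exercised — dozens of
populated popcount buckets, both pruned and scanned paths taken.

What passing on these fixtures shows: the search, chaining and
serialization machinery is exact, deterministic and complete. What it
does not show: anything about real chemical space. Fixture SMILES are
syntactically plausible but chemically arbitrary; fingerprints are hash-
derived, not substructure keys; GO/gene/disease content is synthetic.
Conclusions about retrieval quality on real databases require real
tables, which the store dialect is designed to accept unchanged.

## Known limitations

* Dictionary GO tagging misses paraphrase and inflection; it will also
  happily tag a phrase used in a negated context.
* Disease scores are only as good as the supplied gene–disease matrix;
  the max-aggregation rule reports support, not statistical confidence.
* The hash fingerprint is not a chemical fingerprint; with it, 2D
  similarity reflects string similarity of SMILES. Attach a real
  backend for chemical conclusions.
* Substructure search, fingerprint folding, conformer generation and
  ontology-aware term expansion are out of scope by design.
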