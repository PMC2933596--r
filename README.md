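# ChemLinker

ChemLinker is an offline engine for similarity-based aggregation of
chemical and biological evidence about a query compound. Given a SMILES
string, it searches local tables of compounds, bioassay outcomes, drugs,
chemical–gene/disease relations, pathway links and literature references
for structurally similar molecules, chains bioassay text through Gene
Ontology terms and genes to candidate diseases, and emits a single
six-section report as XML or JSON. It is aimed at early drug-discovery
triage: given one structure, collect in one place everything a local
knowledge store can say about molecules like it.

## The methods at its core

**2D similarity with bound pruning.** Compounds carry 166-bit binary
structural-key fingerprints. Similarity between fingerprints A and B is
the Tanimoto coefficient

```
T(A, B) = |A ∩ B| / |A ∪ B|
```

Hits are compounds with `T ≥ t` (default threshold `t = 0.85`). The
search is exact but avoids scanning most of the store: for popcounts
`a = |A|`, `b = |B|`, no pair can exceed

```
Tmax(a, b) = min(a, b) / (a + b − min(a, b))
```

so the store is bucketed by popcount and any bucket with
`Tmax(a, b) < t` is skipped whole. Pruned and exhaustive search provably
return identical results.

**3D shape similarity.** Each conformer is summarised by the 12-value
ultrafast shape recognition (USR) signature: for four reference points
(centroid; atom closest to it; atom farthest from it; atom farthest from
that one), the distances from all atoms are reduced to their mean,
population standard deviation, and signed cube root of the third central
moment. Shape similarity is the Euclidean distance between signatures,
and nearest neighbours are reported; the signature is invariant under
rotation and translation.

**Evidence chaining.** Free text on assays, drug usage descriptions and
paper titles/abstracts is tagged with Gene Ontology identifiers by exact
dictionary phrase matching (case-insensitive, word boundaries, longest
match wins, then leftmost). GO terms map to genes through an explicit
GO→gene table, and genes map to diseases through a gene × disease score
matrix; a disease is reported when its best gene score reaches 0.5, with
the full provenance chain assay → GO term → gene → disease attached.

**The six report sections**, in fixed order: predictive models (a
pluggable per-target activity predictor with red ≥ 0.7 / yellow ≥ 0.6 /
grey colour coding), activities of similar compounds (bioassay actives,
drug hits, 3D neighbours, disease annotations), chemogenomics relations,
pathway/enzyme relations, literature, and inactivities of similar
compounds.

A seeded fixture generator builds complete synthetic stores with planted
relationship chains at exact target similarities, so everything above is
testable end-to-end with no external database.

## Worked example

```r
library(ChemLinker)

# a complete synthetic store with two planted evidence chains
generateFixtureStore(fixtureSpec(seed = 7), "store7")
store <- loadStore("store7")
m <- readManifest("store7")

rep <- runQuery(m$query_smiles, store, conformer = m$query_conformer)
rep
#> AggregateReport for query: C1CCCCC1SC(=O)OFNSFC(=O)O
#>   predictive_models        40 entries
#>   active_similars          4 entries
#>   chemogenomics_similars   2 entries
#>   systems_similars         2 entries
#>   literature_similars      2 entries
#>   inactive_similars        2 entries

hit <- reportSections(rep)$active_similars$assay_hits[[2]]
hit$compound_id    #> "CPLANT001"  — planted at Tanimoto exactly 0.9
hit$similarity     #> 0.9
hit$diseases[[1]]$disease  #> "lymphoma", score 0.9, via BCL2
writeLines(reportToXML(rep), "report.xml")
```

The two `active_similars` assay hits are the planted compounds (at
similarities 1.0 and 0.9); each carries a disease annotation whose
provenance chain runs assay → GO term → gene → disease. The planted 3D
neighbour — a rigidly transformed copy of the query conformer — ranks
first in the 3D list at distance ~4e-10.

A thin command-line front end ships in `inst/scripts/chemlinker`
(`query`, `validate`, `fixtures` subcommands; exit codes 0/2/3).

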