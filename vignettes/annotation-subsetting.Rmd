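---
title: "Annotation-driven subsetting and ranking of compound knowledge bases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-driven subsetting and ranking of compound knowledge bases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annolite)
library(dplyr)
```

## The problem

Non-target small-molecule identification by high-resolution mass
spectrometry retrieves candidate structures from a compound database by
exact mass (within a ppm window) or molecular formula, then ranks them with
whatever evidence is available: in-silico fragmentation scores, spectral
library similarity, and metadata such as literature and patent counts. With
knowledge bases now holding over a hundred million structures, a single
query can return tens of thousands of candidates, most of them vendor
library entries that will never be observed in an environmental or
biological sample. Ranking quality and throughput both suffer.

`annolite` implements the alternative: build a compact candidate database
*up front* from the knowledge base's annotation content, so that only
compounds with evidence of real-world relevance (agrochemical, drug, food,
pharmacological, safety, toxicity or use annotation) are searched at all,
and expose the annotation itself as ranking signal.

## The annotation fingerprint and category selections

Each compound record carries a *fingerprint*: a bitset over a category
index describing the knowledge base's classification of annotation content.
The index has one bit per top-level category and per subcategory (one
nesting level; deeper trees are flattened). The package ships a frozen
reference index of the ten relevant top categories with plausible
subcategory sets (3–6 each) — a synthetic stand-in, since real
classification trees change over time. The index is an input everywhere;
nothing about it is hard-coded.

Three built-in selections name the top categories a build uses:

* `tier0` — the seven "environmental" categories: AgroChemInfo,
  DrugMedicInfo, FoodRelated, PharmacoInfo, SafetyInfo, ToxicityInfo,
  KnownUse;
* `tier1` — tier0 plus BioPathway (biological pathway context);
* `exposomics` — tier1 plus Identification and DisorderDisease.

The selections are nested, and everything downstream respects that
nesting: the database built under tier0 is a subset (by InChIKey first
block) of the one built under tier1, which is a subset of exposomics.

Two derived quantities turn fingerprints into scores. The **category
score** of a top category is 0 when the category is absent and otherwise
1 plus the number of its subcategories present — so a compound with the
agrochemical top bit and four agrochemical subcategory bits scores 5. The
**total annotation count** (`AnnoTypeCount`) counts selected top
categories present, with maxima 7/8/10 for tier0/tier1/exposomics. One
normalisation is applied once, at dump reading: a subcategory bit implies
its top-category bit. The upstream convention is unstated, and rolling up
is the conservative reading — a record annotated only in a subcategory is
certainly annotated in its parent category.

## The construction rules

`build_lite()` turns raw records into the compact database with six rules,
in order:

1. keep records whose fingerprint intersects the selected categories;
2. map records to their parent compound (the neutral form), imputing the
   child's fingerprint (union) and literature/patent counts (sum) to the
   parent; parent chains resolve transitively, cycles are an error, and a
   referenced parent with no record of its own is materialised as a stub
   from its lowest-CID child;
3. collapse by InChIKey first block (IKFB, the structural skeleton),
   since fragmentation data rarely distinguishes stereoisomers: one entry
   per block, keeping the "best" CID and listing all members in
   `RelatedCIDs`;
4. eliminate entries whose formula contains a blacklisted element (65
   mostly metallic, rare-earth and synthetic elements — species that
   in-silico fragmentation cannot usefully process);
5. eliminate disconnected structures and mixtures (a `.` component
   separator outside brackets in SMILES, or in the InChI formula layer) —
   these cannot be observed at the neutral query mass; splitting and
   re-merging mixture components is deliberately out of scope;
6. neutralise charged molecular formulas (notation only: the charge token
   is stripped, element counts and structure strings untouched).

Rules 4–5 run *after* collapsing so that the elimination accounting is per
IKFB, and the report satisfies the identity
`kept + eliminated = total` exactly. "Best" CID is defined as the record
with the most fingerprint bits within the active selection, ties broken
towards the lowest CID; the upstream convention defines neither the metric
nor the tie-break, so the package fixes both and documents them.
Literature and patent counts are *summed* over merged entries (reading
"total counts calculated over the merged entries" as summation; a maximum
would discard the accumulation of evidence across stereoisomers).
Isotopically labelled members of a collapsed group receive no special
handling; their presence can in principle attach a group to a mass it
would not otherwise match.

```{r, eval = FALSE}
idx <- default_category_index()
rec <- read_compound_dump("compounds.tsv", "counts.tsv", "toc.tsv", idx)
b   <- build_lite(rec, "tier0", idx)
glance(b)                      # accounting report
write_lite_csv(tidy(b), b$selection, "pubchemlite_tier0.csv")
```

## Formula handling

Formulas are parsed from Hill-convention strings with an optional
sign-first charge token (`+`, `-`, `+2`, `-3`). The magnitude-before-sign
form (`2+`) is *not* used because it is ambiguous against a trailing
element count: `C9H13N2+` must mean N₂ with charge +1. Monoisotopic masses
are summed from a versioned most-abundant-isotope table shipped as a
plain-text file, so results are reproducible across environments. The
electron mass is ignored — a sub-ppm effect, irrelevant inside the 5 ppm
retrieval windows used here — and whether the upstream masses included it
is not guessed. Multi-component detection is purely lexical (dot
scanning); no structure-perception library is involved, which is exactly
as strong as the filters require.

## Retrieval, scoring and ranking

`candidates_by_mass()` retrieves entries within a symmetric ppm window
(default 5 ppm, the common instrument tolerance);
`candidates_by_formula()` matches neutralised formulas by element counts.
`score_candidates()` implements weighted max-normalised scoring: each
term's raw values (a database column such as `pubmed_count`, or an
external per-candidate table keyed by IKFB, e.g. spectral similarity) are
divided by the maximum within the candidate set, and the combined score is
the weighted sum. Consequences worth knowing:

* normalised scores lie in [0, 1] and the combined score in
  [0, Σ weights];
* rescaling any one term by a positive constant cannot change ranks;
* a term that is zero for every candidate contributes nothing;
* terms already bounded in [0, 1] are still normalised within the set,
  for uniformity.

Ties share the best rank by default (`1 + number strictly better`); a
pessimistic mode is available because the upstream convention is unstated.
Default term weights are 1; published combined scores depend on weight
configurations that are not public, so only orderings — not combined
values — are treated as reproducible.

## Benchmarking and gap analysis

`run_benchmark()` executes the retrieval–scoring–ranking loop over a
benchmark table and buckets the rank of each true compound into
`1`, `2–3`, `4–10`, `>10` and `missing` (the compound's IKFB was not
retrieved at all). The edges are configurable; the defaults express how
such evaluations are usually reported ("ranked first", "worst rank was
third"). De-duplication of multiple spectra per compound is the caller's
responsibility; the runner treats rows independently.
`subset_benchmark_by_category()` restricts an evaluation to compounds
carrying a given annotation type, `gap_report()` partitions a suspect list
by database presence, and `transformation_statements()` renders
predecessor/successor mappings as annotation sentences (serial comma from
three items; the two-item form joins with a bare "and" — the two-item case
has no printed precedent, so the package fixes it).

## The synthetic fixture generator

Real knowledge-base dumps are huge, versioned and unavailable offline, so
`generate_fixture()` produces dumps with known ground truth. It emulates
precisely the features the rules act on: stereoisomer groups sharing an
IKFB (group sizes from random assignment of compounds to groups),
sparse multi-category annotation (default density 0.35 per top category,
0.35 per subcategory, with a 10% chance of a subcategory-without-top bit
to exercise the roll-up), heavy-tailed literature/patent counts
(discretised log-normal, meanlog 2/sdlog 2 — producing the orders-of-
magnitude spread seen in real patent counts), parent–child CID relations
within a group, and configurable fractions of disconnected (0.10),
blacklisted-element (0.08) and charged (0.10) records. Formulas are drawn
from a small pool (default one per eight IKFB groups, minimum eight) so
that exact-mass windows contain several candidates, as real isobaric
queries do.

What it does **not** emulate: real InChIKeys (generated keys are
valid-pattern random strings, not structure hashes), chemically meaningful
SMILES/InChI beyond the properties the filters inspect, isotope
distributions, adducts, or real annotation co-occurrence structure.
Passing tests therefore demonstrate the correctness of the rules, the
accounting and the ranking machinery — not performance claims about any
real database.

Ground truth comes from `oracle_build()`, a straight-line, loop-based
reimplementation of the six rules that shares no code with the builder; the
test suite requires the two to agree exactly on fixtures up to 200
records. `generate_benchmark()` fabricates an external scoring term whose
informativeness is controlled: with probability *p* the correct candidate
receives the strict maximum (1.0 versus competitors below 0.9), otherwise
all candidates draw iid uniform scores. The observed rank-1 fraction is
then *p* plus a chance-win excess of (1 − *p*)·mean(1/k) over candidate
set sizes *k* — small by design because of the shared formula pool.

## Numerical and design choices

* Masses are compared to 1e-6 Da in round-trip tests; retrieval windows
  are relative (ppm), so no absolute mass tolerance enters the method.
* `RelatedCIDs` are sorted ascending and joined with `;`; CSV output is
  RFC 4180, UTF-8, `.` decimal point.
* Degenerate inputs: empty record sets build to an empty database with an
  all-zero report; an empty candidate set scores to an empty table; a
  benchmark entry with no candidates in the window is `missing`.
* All randomness (fixtures, benchmarks) flows through a single integer
  seed; identical seeds give byte-identical fixture files.
* Problem sizes used by the tests and the acceptance script — fixtures of
  40–450 compounds, benchmarks of up to 200 queries — were chosen as the
  smallest sizes at which the statistical properties (accounting, oracle
  equivalence, binomial recovery of informativeness) are sharp.

## Known limitations

* The reference category index is synthetic; building against a real
  classification tree requires exporting it to the documented TSV dialect.
* Mixtures are discarded, not split into components.
* Isotopically labelled entries inside collapsed groups are not treated
  specially.
* The package consumes fragmentation and spectral-similarity scores; it
  does not compute them.
* XLogP-style partitioning columns are not included by default.
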