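---
title: "Methods: consensus orthology, pseudoduplicates, and the naming cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus orthology, pseudoduplicates, and the naming cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echinoname)
```

## Scope and model

`echinoname` assigns standardized gene identifiers (a machine-readable
lower-case *symbol* plus a descriptive *full name*) to echinoderm
protein-coding genes on the basis of consensus orthology with the human
gene set. It consumes the *outputs* of orthology-inference tools as
normalized tab-separated tables; it does not run the tools themselves, and
it does not talk to any external database. All parsing of external formats
(GFF3, FASTA, BLAST tabular, the various tables) is isolated in the IO
layer; every downstream stage works on plain data frames.

## Consensus voting

An orthologous relationship is accepted when at least `min_tools` (default
**3**, inclusive) *distinct* tools report the same (query, subject) pair.
A tool reporting a pair twice contributes one vote — tool tables are
deduplicated on read, and the tally counts distinct tool names, never rows.
Unsupported edges are discarded *before* topology classification: a pair
seen by only two tools can neither name a gene nor merge two orthology
groups. The supported bipartite graph is cut into connected components and
each component is labeled purely by the sizes of its two sides: (1,1)
one:one, (1,>1) one:many, (>1,1) many:one, (>1,>1) many:many. Genes with no
supported edge become singleton *orphan* groups, so every gene flows
through the cascade exactly once.

Topology is evaluated **per species and per reference-taxon stratum**:
when two echinoderm species both hit one human gene, each species' stratum
sees its own many:one (or one:one) relationship. This is what makes
cross-species suffix coordination (below) well defined, and it mirrors the
fact that nameability categories are taxon-stratified.

## Nameability categories and a deliberate simplification

For reporting, genes are bucketed with the precedence human one:one >
other-vertebrate one:one > invertebrate/non-animal > unnameable. The
category vocabulary is closed, which leaves genes whose only human
relationships are *not* one:one (e.g. members of many:one expansions)
without a category of their own; they fall through the precedence chain
(usually to `unnameable`) **for reporting purposes only** — the naming
cascade still assigns them symbols through the paralog rules. This mirrors
the published observation that, within the tool subset the category counts
were derived from, all counted nameable genes were one:one orthologies.
Current policy is also that only *human* orthologs inform symbols:
vertebrate- and invertebrate-only genes are categorized for the report but
named by LOC fallback, with the orthology retained in provenance columns.
Cross-species echinoderm–echinoderm links travel the same call tables with
taxon `invertebrate` (echinoderms are invertebrates); the categorizer is
told to ignore subjects that are themselves cohort genes so internal links
are not mistaken for reference orthologs.

## Pseudoduplicates: the 90/90 rule

Echinoderms are broadcast spawners with highly polymorphic genomes;
assemblies can retain both haplotypes of a locus as two gene models
(under-collapsed heterozygosity). Gene models — introns included, plus
`flank_bp` (default **1000**) bases up- and downstream, clipped at contig
bounds with a warning — are compared all-vs-all. A hit passes when

* percent identity ≥ `identity_threshold` (default **90**, inclusive), and
* alignment length ≥ `coverage_threshold` percent (default **90**,
  inclusive) of the **longer** model's full length.

Identity follows the BLAST `pident` convention (computed over the
alignment), since the source of hits is a BLAST-style tabular file and the
rule's identity basis is otherwise underdetermined. When a tabular file
carries several HSPs for an ordered pair, the single best HSP decides
(longest alignment, ties broken by identity) — conservative and
deterministic. A pair passes if *either* orientation's hit passes, and
clusters are *connected components* of the passing-pair graph, not
cliques: chained pairs reflect one under-collapsed locus. Components of
size ≥ 2 are pseudoduplicate clusters; their members take letter suffixes
(`base.a`, `base.b`, … continuing `aa` after `z`) ordered by gene id,
because the letters deliberately carry no orthology meaning and are
independent between species. For fixture-scale inputs with no precomputed
BLAST file, an internal local-alignment fallback
(`compute_similarity_hits()`, built on `Biostrings::pairwiseAlignment`)
emits hits in the same columns, so no external aligner binary is ever
required by the tests. Membership is computed genome-wide once; a gene in
a cluster is suffixed regardless of its orthology topology, provided the
cluster can resolve a human base symbol at all — a cluster with no
supported human edge falls through to the ordinary cascade (typically LOC
fallback), since there is no human identifier to letter.

## The naming cascade

Per gene, in order:

1. **Pseudoduplicate cluster member** → letter-suffixed cluster symbol.
2. **one:one** → the human identifier, normalized.
3. **one:many** → tie-break cascade: (a) unique most-tools candidate;
   (b) on a tie, if *all* tied candidates share one family stem and no
   member of that family has a supported edge to a gene of another input
   echinoderm species, the stem itself; (c) curator override; (d) first
   tied candidate in byte order of normalized symbols. The stem source is
   the reference table's `stem` column when present, else the normalized
   symbol with trailing digits stripped. The all-candidates reading of the
   stem condition is a deliberate choice where the rule's scope was open;
   partial-stem ties fall to (c)/(d).
4. **many:one / many:many** → numeric suffixes `base.1, base.2, …` on the
   single human ortholog (many:one) or on the base resolved through the
   one:many cascade using each candidate's best supported edge
   (many:many). Species are processed in sorted order; a member holding a
   supported one:one cross-species link to an already-suffixed ortholog
   with the same base inherits that number, remaining members take the
   lowest unused numbers in gene-id order, and conflicting claims both
   fall back to fresh numbers with a logged message. Numbering is global
   per base symbol (never restarted per chromosome or subfamily).
5. **Orphan / non-human-only** → `loc` + Entrez ID, full name from the
   annotation's predicted product; the uppercase `LOC…` form and all
   legacy identifiers become synonyms.

Curator overrides sit between the stem rule and the alphanumeric
fallback — exactly where curatorial examination is described — and are
modeled opaquely as a lookup table, since what evidence curators may use
is undefined.

Species-wide symbol uniqueness is enforced at the end with deterministic
numeric disambiguation (`symbol-2`, `symbol-3`, … in gene-id order) plus a
logged message; the writer re-checks uniqueness as a last line of defense.

## Symbol normalization

`normalize_symbol()` lowercases; transliterates Greek letters to single
Latin letters (HGNC-style: α→a, β→b, …, ψ→y, ω→w; the full table ships in
the code); maps whitespace and disallowed characters to `-`; converts a
*trailing standalone* Roman-numeral token (canonical forms I–XX only, so
`IIII` does not convert) to Arabic digits and a trailing spelled-out Greek
token (`alpha` …) to its letter, joining either directly to the preceding
token (`Pax VI → pax6`); and preserves `.` so suffixes survive
re-normalization. The function is idempotent, and every emitted symbol
satisfies `normalize_symbol(s) == s` and the pattern
`^[a-z0-9][a-z0-9.-]*$`. "Alphanumerically first" is byte order on the
normalized form (radix sort), which is locale-independent and
reproducible.

## Percentage formatting

Published share tables mix 0-, 1- and 2-decimal precision, so precision is
a per-call parameter and the report emits all three renderings plus the
raw fraction. Rounding is **half-up**, computed in exact integer
arithmetic (`floor((2a + b) / 2b)` on scaled integers) rather than
floating-point `round()`, whose half-even ties would disagree at the
printed digit (e.g. 12.5% must print as 13%, not 12%).

## The synthetic-data generator

`generate_cohort()` plants every cascade branch with a known expected
symbol, rule, category, cluster and suffix: supported pairs are drawn in
`min_tools`…panel-size tools, most-tools winners get strictly more votes
than their runners-up, stem ties share an explicit stem, curator branches
carry an override row, noise pairs appear in fewer than `min_tools` tools,
and two-species cohorts add shared paralog families with supported
cross-species links whose suffix agreement is checked exactly.
`generate_pseudodup_sequences()` creates allele clusters by copying a
gene-model window (model + flanks) and substituting bases at a per-site
rate *d*; divergence is substitution-only (no indels), so true identity is
analytic (≈ 1 − d) and the emitted hits — alignment length equal to the
window, identity equal to the realized match fraction — reproduce the
planted cluster labels by construction. Defaults (gene models of 0.4–1.2
kb on one contig per species, 1 kb flanks, six tool labels, divergences
0.02 for in-cluster and 0.15 for out-of-cluster pairs) were chosen once as
plausible desk-scale values and are not tuned to tests.

What the generator does **not** emulate: real exon–intron architecture,
indel divergence, alignment noise, incomplete tool sensitivity, conflicting
taxon annotations, or genome-scale cohort sizes. A green end-to-end test
therefore establishes that the cascade implements its stated rules exactly
on inputs that obey the stated conventions — not that the published
genome-scale category counts would be reproduced from raw proteomes, which
would require the actual six tools and the *S. purpuratus* annotation and
is out of scope by design.

## Numerical and degenerate-input choices

* Coordinates are GFF3 1-based inclusive everywhere; conversion happens
  only inside sequence extraction (and the BED writer's 0-based starts).
* Thresholds are inclusive at exactly 90.0/90.0 and at exactly 3 tools.
* Empty call tables warn and return empty; empty hit files are valid;
  an empty edge set classifies to an empty group list.
* Conflicting subject taxa, duplicate reference symbols within a taxon,
  hits naming unknown genes, exons outside their gene span, genes off
  contig ends, missing Entrez IDs at LOC fallback, and malformed hits
  (alignment longer than the longer sequence) are hard errors.
* All orderings use radix (byte) sort, so outputs are byte-identical
  across platforms and reruns; the only timestamp lives in the run
  manifest.

## Known limitations

* Stems are only as good as the reference table; the digit-stripping
  fallback can manufacture stems for symbol families that are not gene
  families.
* Pseudoduplicate detection consumes precomputed similarity hits at scale;
  the internal aligner is quadratic and intended for fixtures and demos.
* The reporting category set cannot represent "named through many:*"
  genes as nameable (see above); their counts are recoverable from the
  assignment table's `rule_fired` column instead.
* Suffix inheritance considers only members with exactly one supported
  cross-species link to an already-assigned paralog of the same base;
  more elaborate reconciliation (e.g. global matching) is future work.
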