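---
title: "Stage-indexed anatomy ontologies: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-indexed anatomy ontologies: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stageont)
```

## The two-sided model

Developmental anatomy nomenclatures face a representational tension.
Annotation of embryo data is naturally *stage-specific*: an expression
pattern is observed in the midgut epithelium of a Theiler-stage-14
embryo, and that observation should attach to a stage-14 instance of the
structure with its own stable accession. Curation, on the other hand, is
naturally *stage-independent*: the midgut epithelium is one anatomical
entity, and maintaining twenty-odd copies of it (one per stage) invites
inconsistency.

`stageont` implements both sides and the derivations between them:

* An **abstract ontology** (`AbstractOntology`): one term per anatomical
  entity, annotated with the first and last stage at which the entity is
  considered present, connected by typed edges — `part_of` (the
  partonomy), `is_a` (subsumption) and `develops_from` (lineage; modeled
  but never traversed as a parent link). The graph over `part_of`/`is_a`
  is a rooted DAG; multiple parents are allowed, so brain can be part of
  head and of the central nervous system at once.
* A family of **timed ontologies** (`TimedOntology`), one per stage:
  the subgraph of entities present at that stage, each instance bearing
  its own timed accession.
* A **mapping table** (`MappingTable`) tying each timed accession
  permanently to its (abstract accession, stage) pair.

`instantiateAll()` derives the timed family from the abstract side;
`deriveAbstract()` reconstructs the abstract side as the union of timed
graphs, with each term's range being the first and last stage of
occurrence. On any valid abstract ontology with contiguous ranges the
two are mutually inverse — the central correctness property of the
package, exercised over hundreds of seeded fixtures in the test suite.

### Assumptions and what the interval model cannot say

A stage range is a **closed, contiguous interval**. An entity that is
present, disappears, and reappears cannot be captured by one term; it
must be modeled as two terms. Correspondingly, `deriveAbstract()` treats
non-contiguous occurrence as an error in strict mode and as a warning
plus hull interval (`[first, last]`) in permissive mode — the hull is
the only representable approximation.

Stage numbers are unitless ordinals over a configurable inclusive
domain, default `1..28` after the Theiler staging of the mouse; nothing
in the package is specific to the mouse or to that bound, and the
accession prefixes (`EMAPA`/`EMAP` by default) are configuration too.

## Instantiation semantics

At stage *s*, the timed node set is exactly the set of non-obsolete
terms whose interval contains *s*. An edge is included iff **both**
endpoints are present — instantiation is a pure graph restriction, and a
child present at a stage where its parent is not simply lacks that edge
there. Two designs were possible for such orphaned nodes: drop them, or
keep them and report. We keep them, for two reasons. First, the
conservation identity

> sum over stages of per-stage node counts
> = sum over terms of (end − start + 1)

then holds for *every* input, not only for well-nested ones, which makes
it usable as an invariant check on real data. Second, silently dropping
a term at some of its declared stages would hide exactly the curation
defect one wants surfaced; the `orphan_at_stage` warning (an error under
`strict`) names the term and stage instead. A stage at which the *root*
is absent is outside the ontology's coverage and is always an error for
single-stage instantiation.

`is_a` edges are carried into timed graphs alongside `part_of` by
default (`includeIsa = FALSE` restricts timed graphs to the original
strict-partonomy style); parent-coverage checks treat both types
equally. Whether subsumption should constrain stage ranges differently
from partonomy is a genuinely open modeling question; validating both
identically is the simplest consistent reading, and a term whose range
escapes its `is_a` parents is flagged the same way as one escaping its
`part_of` parents.

## Persistent identifiers

Annotation databases reference timed accessions, so those accessions
must never change meaning. `instantiateAll()` takes the previous
release's mapping table and:

* keeps every surviving (abstract accession, stage) row byte-identical;
* allocates fresh accessions only for genuinely new pairs, in
  (stage, abstract local id) order from a monotonically increasing
  counter — so a rerun on unchanged input is the identity, and output
  order is deterministic across runs;
* moves rows whose pair vanished (term retired, range shrunk) to a
  *retired* set from which accessions are never re-issued.

The retired set and the counter are part of the table's serialized form
(as `#`-prefixed bookkeeping lines above the three tab-separated data
columns), so persistence survives the file round trip.

## Naming

Term labels in anatomy are chronically ambiguous — "epithelium" may
label dozens of structures. Two display forms resolve this:

* the **full path name**, `TS14/mouse/organ system/visceral organ/
  alimentary system/gut/midgut/epithelium`: exact but unwieldy, and no
  longer unique once multiple parentage makes several root-to-term
  paths possible (`fullPathNames()` returns all of them);
* the **print name**, `TS14;midgut epithelium`: the zero-padded stage
  token plus a globally unique term name, semicolon-separated with no
  spaces.

Print names presuppose unique term names, which `uniquifyNames()`
enforces: every colliding term is renamed
`"<disambiguating ancestor name> <original name>"`, the ancestor being
the nearest `part_of` ancestor (breadth-first; depth-1 parents in
relation order, deeper ties broken by lexicographically smallest name)
whose prefix yields an unused name. The original short label is kept as
a `RELATED` synonym, so no previously valid search term is lost, and
the operation never touches accessions, ranges or topology — it is pure
relabeling, and idempotent.

Deliberate non-goals of the renaming pass: multi-segment path prefixes
("gut midgut epithelium") are never constructed, and holders that are
structurally indistinguishable — identical ancestor-name multisets, as
with two same-named siblings under one parent — are *reported* as
residual collisions rather than forced apart by an arbitrary choice.
Those cases need a curator, not an algorithm.

## Validation and versioning

`validateOntology()` aggregates the check suite; each check is also
callable alone and returns a machine-readable `ValidationReport`:

| check | severity | what it catches |
|---|---|---|
| `checkAcyclic` | ERROR | cycles over `part_of`/`is_a`, one witness per strongly connected component (`develops_from` cycles warn) |
| single root | ERROR | zero or several parentless terms |
| `checkStageConsistency` | ERROR / WARNING | inverted or out-of-domain ranges; orphan-at-stage coverage gaps |
| `checkNamesUnique` | WARNING | duplicated non-obsolete labels |
| `checkMapping` | ERROR | stale, dangling or missing mapping rows |

Orphan-at-stage is a warning by default because legacy files predate
the constraint and must still load; `strict` promotes it. Cycle
reporting emits one witness cycle per strongly connected component
rather than enumerating all cycles, which can be combinatorially many.

`diffVersions()` categorizes changes between releases (added, retired,
renamed, reranged, edges added/removed) and applies a deliberately
*heuristic* identifier-reuse alarm: an accession whose name changed
while none of its former labels (name or synonyms) survives is flagged
ERROR. There is no formal identity criterion across versions, so this
is documented as a heuristic in the finding itself; keeping the old
name as a synonym — good editorial practice anyway — suppresses it.

## The synthetic-fixture generator

Everything above is tested without downloading any curated resource.
`generateFixture()` produces EMAPA-shaped ontologies: a root spanning
the whole domain, children attached under a uniformly chosen parent
with their range nested in the primary parent's range (start uniform,
length `1 + Geometric` with mean a quarter of the domain span — a mix
of short- and long-lived structures, a testing choice rather than an
empirical claim), an adjustable fraction of `is_a` edges and of second
parents, and anatomy-vocabulary labels with duplicates at exactly the
requested rate. Second parents are drawn only among range-overlapping
terms: a relation between structures that never co-exist would be
instantiated at no stage (and is anatomically vacuous), which would
also make the union derivation unable to recover it.

Determinism is bit-for-bit: every term and every injected defect draws
from its own derived seed, so adding a parameter never shifts earlier
draws, and the same `FixtureSpec` always serializes to identical bytes.
Ground truth — per-stage node and edge counts, the duplicate-name
multiset, defect inventories, version-pair edit scripts — is computed
arithmetically from the term tables during generation, independently of
the staging and validation code under test.

What the generator does *not* emulate, and hence what green tests do
not show about real data: biologically meaningful topology or labels,
obsolete-term history, `develops_from` lineage content, the scale of
the curated resource (thousands of terms), or hand-edited OBO quirks
beyond the two stage-annotation dialects.

## Numerical and format choices

* **Stage tokens** are `TS` plus a zero-padded two-digit number
  (`TS05`); parsers accept unpadded and bare-integer forms. One token
  grammar serves print names, path names, OBO stage tags and mapping
  files.
* **Stage dialects**: ranges are written either as
  `relationship: starts_at TS12` / `ends_at TS14` (default) or as
  `property_value: starts_at "12"`; both are always parsed, the config
  chooses which is written. A term missing its annotation gets the
  domain bound and a warning (error under `strict`).
* **Canonical serialization**: UTF-8, LF newlines, no trailing
  whitespace; stanzas sorted by accession local part, tags in fixed
  order, synonyms and relation targets sorted. Two serializations of
  equal ontologies are byte-identical, so releases can be diffed under
  version control. Unrecognized tags round-trip verbatim at document
  level.
* **Tie-breaks** are always lexicographic in byte order (radix sort),
  never locale-dependent.
* Problem sizes in the shipped tests — fixtures of roughly 10–200
  terms, 100 seeds per property, 50 version pairs — were chosen so the
  whole suite explores each property broadly while remaining quick on a
  single CPU.

## Worked example

```{r example}
nm <- c("mouse", "organ system", "visceral organ", "alimentary system",
        "gut", "midgut", "epithelium", "skin", "epithelium")
acc <- paste0("EMAPA:", seq_along(nm))
onto <- abstractOntology(
  terms = data.frame(accession = acc, name = nm,
                     start = c(1L, rep(10L, 8)), end = 28L),
  relations = data.frame(from = acc[2:9], type = "part_of",
                         to = acc[c(1:6, 1, 8)]))

res <- instantiateAll(onto)
fullPathNames(timedOntologies(res)[["TS14"]], "EMAPA:7")

u <- uniquifyNames(onto)
printName(u$ontology, "EMAPA:7", 14)
u$report@renames
```

## Known limitations

* Discontinuous presence requires term splitting by the curator; the
  package can only detect and hull it.
* The renaming convention is one concrete realization of compound
  naming; a curation group may prefer organ-level prefixes over
  nearest-ancestor prefixes in specific regions.
* Identifier-reuse detection across versions is heuristic.
* No OWL semantics, reasoner classification, or cross-species bridging;
  OBO coverage is the 1.2-style subset (other constructs are preserved
  verbatim, not interpreted).
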