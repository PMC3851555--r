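# stageont

Tools for building and maintaining **stage-indexed developmental-anatomy
ontologies**: the two-sided model in which a single *abstract* ontology
(one term per anatomical entity, annotated with the first and last
developmental stage of its presence, organized as a rooted multi-parent
DAG of `part_of` / `is_a` / `develops_from` relations) generates a
family of *timed* per-stage ontologies, each instance carrying its own
persistent accession.

The package is aimed at ontology editors and database curators who need
to release per-stage anatomy files, keep timed identifiers stable
across releases, and gate releases on automated consistency checks.

## What it implements

* **Core model** — S4 classes `AbstractOntology`, `TimedOntology`,
  `MappingTable`, `OboDocument`, `ValidationReport`, `DiffReport`, with
  accessors (`parentsAt()`, `termStages()`, `stageRange()`, ...).
  Stage ranges are closed contiguous intervals over a configurable
  domain (default Theiler stages 1–28).
* **Staging** — `instantiateStage()` / `instantiateAll()` restrict the
  abstract DAG to each stage *s* (nodes: terms with
  `start ≤ s ≤ end`; edges: both endpoints present);
  `deriveAbstract()` reconstructs the abstract ontology as the union of
  timed graphs, each range being `[first occurrence, last occurrence]`.
  The two derivations are mutually inverse on valid input.
* **Persistent identifiers** — `instantiateAll()` maintains the
  timed↔abstract mapping table: surviving rows are preserved
  byte-identically, fresh accessions are allocated monotonically in
  (stage, local id) order, and retired accessions are never reused.
* **Naming** — `uniquifyNames()` resolves duplicated labels into
  compound names using the nearest disambiguating `part_of` ancestor
  (an "epithelium" under the midgut becomes "midgut epithelium", the
  short label kept as a synonym); `printName()` renders the
  `TS14;midgut epithelium` display form, `fullPathNames()` the
  `TS14/mouse/.../epithelium` path form.
* **Validation & versioning** — acyclicity (one witness cycle per
  strongly connected component), single root, stage-range sanity,
  per-stage parent coverage, name uniqueness, mapping consistency;
  `diffVersions()` categorizes release-to-release changes and flags
  suspected identifier reuse.
* **OBO I/O** — lossless parse/write of the OBO 1.2-style dialect with
  two stage-annotation encodings (`relationship: starts_at TS12` and
  `property_value: starts_at "12"`), deterministic canonical
  serialization (byte-identical reruns), and the three-column
  tab-separated mapping file.
* **Synthetic fixtures** — `generateFixture()` /
  `generateVersionPair()` produce seeded, bit-reproducible
  anatomy-shaped ontologies with recorded ground truth and injectable
  defects (cycles, inverted ranges, duplicate names, orphans, stale
  mapping rows), so everything above is testable offline.

## Worked example

```r
library(stageont)

nm  <- c("mouse", "organ system", "visceral organ", "alimentary system",
         "gut", "midgut", "epithelium", "skin", "epithelium")
acc <- paste0("EMAPA:", seq_along(nm))
onto <- abstractOntology(
  terms     = data.frame(accession = acc, name = nm,
                         start = c(1L, rep(10L, 8)), end = 28L),
  relations = data.frame(from = acc[2:9], type = "part_of",
                         to = acc[c(1:6, 1, 8)]))

res <- instantiateAll(onto)
res@mapping
#> MappingTable: 180 rows, 0 retired, next local id 181

fullPathNames(timedOntologies(res)[["TS14"]], "EMAPA:7")
#> [1] "TS14/mouse/organ system/visceral organ/alimentary system/gut/midgut/epithelium"

u <- uniquifyNames(onto)
u$report@renames
#>   accession        old               new ancestor
#> 1   EMAPA:7 epithelium midgut epithelium  EMAPA:6
#> 2   EMAPA:9 epithelium   skin epithelium  EMAPA:8

printName(u$ontology, "EMAPA:7", 14)
#> [1] "TS14;midgut epithelium"
```

The mapping holds 180 rows because the root spans stages 1–28 and the
eight other terms span 10–28 each (28 + 8×19). The two colliding
"epithelium" labels are disambiguated by their nearest `part_of`
ancestors, and the print name pairs the zero-padded stage token with
the now-unique name.

A command-line wrapper ships in `inst/scripts/stageont`:

```sh
stageont validate --obo emapa.obo --strict --report findings.tsv
stageont instantiate --obo emapa.obo --mapping prev.tsv --out-dir timed/
stageont derive-abstract --in-dir timed/ --out rebuilt.obo
stageont diff --old v1.obo --new v2.obo --report diff.tsv
stageont synth --spec spec.yaml --out fixture.obo --truth truth.json
```

Exit codes: `0` clean, `1` validation errors found, `2` usage/parse
failure — usable directly as a CI gate for ontology releases.

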