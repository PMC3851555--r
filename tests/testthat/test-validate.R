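test_that("multiple parents are not mistaken for cycles", {
  onto <- mkOnto(c("mouse", "head", "central nervous system", "brain"),
                 start = 1L, end = 28L,
                 edges = c("head -> mouse", "central nervous system -> mouse",
                           "brain -> head",
                           "brain -> central nervous system"))
  expect_equal(nrow(findings(checkAcyclic(onto))), 0L)
  expect_equal(nrow(findings(checkAcyclic(abstractOntology()))), 0L)
})

test_that("injected cycles are detected once per strongly connected component", {
  for (seed in 1:30) {
    k <- 1L + seed %% 3L
    fx <- generateFixture(fixtureSpec(
      seed = seed, nTerms = 25, maxDepth = 6,
      defects = rep(list(list(kind = "cycle", count = 1)), k)))
    rep <- checkAcyclic(fx$ontology)
    f <- findings(rep)
    hier <- relations(fx$ontology)
    hier <- hier[hier$type %in% c("part_of", "is_a"), ]
    expect_equal(sum(f$severity == "ERROR" & f$check == "acyclic"),
                 oracleCycleClassCount(hier))
    expect_true(all(grepl("cycle:", f$message)))
  }
})

test_that("develops_from cycles are warnings, not errors", {
  acc <- paste0("EMAPA:", 1:3)
  onto <- abstractOntology(
    terms = data.frame(accession = acc, name = c("mouse", "a", "b"),
                       start = 1L, end = 28L, stringsAsFactors = FALSE),
    relations = data.frame(
      from = c(acc[2], acc[3], acc[2], acc[3]),
      type = c("part_of", "part_of", "develops_from", "develops_from"),
      to = c(acc[1], acc[1], acc[3], acc[2]), stringsAsFactors = FALSE))
  f <- findings(checkAcyclic(onto))
  expect_equal(f$severity, "WARNING")
  expect_equal(f$check, "acyclic_develops_from")
})

test_that("stage-consistency flags inverted ranges and per-stage orphans", {
  # child [10,16] under a sole parent [12,14]: orphaned at 10, 11, 15, 16
  onto <- mkOnto(c("mouse", "gut", "epithelium"),
                 start = c(1L, 12L, 10L), end = c(28L, 14L, 16L),
                 edges = c("gut -> mouse", "epithelium -> gut"))
  f <- findings(checkStageConsistency(onto))
  orphan <- f[f$check == "orphan_at_stage", ]
  expect_equal(nrow(orphan), 4L)
  expect_true(all(orphan$accessions == "EMAPA:3"))
  expect_setequal(as.integer(sub(".*stage (\\d+).*", "\\1", orphan$message)),
                  c(10L, 11L, 15L, 16L))
  # nested ranges produce no findings
  nested <- mkOnto(c("mouse", "gut", "epithelium"),
                   start = c(1L, 10L, 12L), end = c(28L, 20L, 14L),
                   edges = c("gut -> mouse", "epithelium -> gut"))
  expect_equal(nrow(findings(checkStageConsistency(nested))), 0L)
  # inverted range is an error
  inv <- generateFixture(fixtureSpec(
    seed = 3, nTerms = 20,
    defects = list(list(kind = "inverted_range", count = 1))))
  f2 <- findings(checkStageConsistency(inv$ontology))
  expect_equal(sum(f2$severity == "ERROR" & f2$check == "inverted_range"), 1L)
  expect_equal(f2$accessions[f2$check == "inverted_range"],
               inv$truth$defects[[1]]$accessions)
})

test_that("orphan warnings equal the stage-by-stage oracle on fixtures", {
  for (seed in 1:20) {
    fx <- generateFixture(fixtureSpec(
      seed = seed, nTerms = 25,
      defects = list(list(kind = "orphan", count = 1))))
    f <- findings(checkStageConsistency(fx$ontology))
    got <- f[f$check == "orphan_at_stage", ]
    want <- oracleOrphans(fx$ontology)
    expect_equal(nrow(got), length(want))
    gotPairs <- paste(got$accessions,
                      sub(".*stage (\\d+).*", "\\1", got$message))
    expect_setequal(gotPairs, want)
  }
})

test_that("duplicate names yield one warning per name, none when unique", {
  onto <- midgutChainWithCollision()
  f <- findings(checkNamesUnique(onto))
  expect_equal(nrow(f), 1L)
  expect_equal(f$accessions, "EMAPA:7,EMAPA:9")
  expect_equal(nrow(findings(checkNamesUnique(midgutChain()))), 0L)
  for (seed in 1:20) {
    fx <- generateFixture(fixtureSpec(seed = seed, nTerms = 30,
                                      duplicateLabelFraction = 0.3))
    f <- findings(checkNamesUnique(fx$ontology))
    expect_equal(nrow(f), length(oracleDupNames(fx$ontology)))
  }
})

test_that("mapping checks catch stale rows, unknown terms and missing pairs", {
  onto <- mkOnto(c("mouse", "heart"), start = c(1L, 15L), end = c(28L, 20L),
                 edges = "heart -> mouse")
  full <- instantiateAll(onto)@mapping
  expect_equal(nrow(findings(checkMapping(onto, full))), 0L)
  # a row at TS14 for a term whose range is [15,20]
  shrunkRow <- mappingTable(rbind(
    mappingRows(full),
    data.frame(timed = "EMAP:999", abstract = "EMAPA:2", stage = 14L)))
  f <- findings(checkMapping(onto, shrunkRow))
  expect_equal(sum(f$check == "mapping_stale_stage"), 1L)
  # unknown abstract accession
  ghost <- mappingTable(rbind(
    mappingRows(full),
    data.frame(timed = "EMAP:998", abstract = "EMAPA:42", stage = 16L)))
  f2 <- findings(checkMapping(onto, ghost))
  expect_equal(sum(f2$check == "mapping_unknown_abstract"), 1L)
  # missing rows counted by brute-force pair enumeration
  for (seed in 1:10) {
    fx <- generateFixture(fixtureSpec(seed = seed, nTerms = 15))
    m <- instantiateAll(fx$ontology)@mapping
    rows <- mappingRows(m)
    drop <- sample(nrow(rows), 3)
    partial <- mappingTable(rows[-drop, ], nextLocalId = nextLocalId(m))
    f3 <- findings(checkMapping(fx$ontology, partial))
    expect_equal(sum(f3$check == "mapping_missing_row"), 3L)
  }
})

test_that("defect-free fixtures pass every error-level check", {
  for (seed in 1:20) {
    fx <- generateFixture(fixtureSpec(seed = seed, nTerms = 40,
                                      multiParentFraction = 0.3,
                                      duplicateLabelFraction = 0.2))
    rep <- validateOntology(fx$ontology,
                            mapping = instantiateAll(fx$ontology)@mapping)
    expect_false(hasErrors(rep))
  }
})

test_that("each injected defect is caught by its intended check only", {
  kinds <- c(cycle = "acyclic", inverted_range = "inverted_range",
             duplicate_name = "names_unique")
  for (seed in 1:10) {
    for (kind in names(kinds)) {
      fx <- generateFixture(fixtureSpec(
        seed = seed, nTerms = 25, duplicateLabelFraction = 0,
        defects = list(list(kind = kind, count = 1))))
      rep <- validateOntology(fx$ontology)
      f <- findings(rep)
      bad <- f[f$severity == "ERROR" | f$check == "names_unique", ]
      expect_true(all(bad$check == kinds[[kind]]),
                  info = paste(kind, seed, toString(unique(bad$check))))
      expect_gte(nrow(bad), 1L)
    }
    # stale mapping rows trip only the mapping check
    fx <- generateFixture(fixtureSpec(
      seed = seed, nTerms = 25, duplicateLabelFraction = 0,
      defects = list(list(kind = "stale_mapping", count = 1))))
    m <- instantiateAll(fx$ontology)@mapping
    bad <- mappingTable(rbind(mappingRows(m), fx$truth$staleMappingRows),
                        nextLocalId = nextLocalId(m))
    rep <- validateOntology(fx$ontology, mapping = bad)
    f <- findings(rep)
    expect_true(all(f$check[f$severity == "ERROR"] ==
                      "mapping_unknown_abstract"))
    expect_gte(sum(f$severity == "ERROR"), 1L)
  }
})

test_that("version diffs are empty on identical inputs and track additions", {
  onto <- midgutChain()
  d <- diffVersions(onto, onto)
  expect_length(d@added, 0L)
  expect_length(d@retired, 0L)
  expect_equal(nrow(d@renamed), 0L)
  expect_equal(nrow(d@rangeChanged), 0L)
  bigger <- onto
  bigger@terms <- rbind(bigger@terms, data.frame(
    accession = "EMAPA:8", name = "lumen", start = 12L, end = 20L,
    obsolete = FALSE, stringsAsFactors = FALSE))
  d2 <- diffVersions(onto, bigger)
  expect_equal(d2@added, "EMAPA:8")
  # antisymmetry under argument swap
  d3 <- diffVersions(bigger, onto)
  expect_equal(d3@retired, "EMAPA:8")
  expect_length(d3@added, 0L)
})

test_that("random edit scripts are reconstructed exactly by the diff", {
  for (seed in 1:25) {
    vp <- generateVersionPair(
      fixtureSpec(seed = seed, nTerms = 25),
      edits = list(add = 1 + seed %% 3, retire = 1, rename = 1,
                   rerange = 1))
    d <- diffVersions(vp$old, vp$new)
    expect_setequal(d@added, vp$truth$added)
    expect_setequal(d@retired, vp$truth$retired)
    expect_equal(d@renamed[order(d@renamed$accession), ],
                 vp$truth$renamed[order(vp$truth$renamed$accession), ],
                 ignore_attr = TRUE)
    expect_equal(d@rangeChanged[order(d@rangeChanged$accession), ],
                 vp$truth$rangeChanged[order(vp$truth$rangeChanged$accession), ],
                 ignore_attr = TRUE)
    ekey <- function(e) sort(paste(e$from, e$type, e$to))
    expect_equal(ekey(d@edgesAdded), ekey(vp$truth$edgesAdded))
    expect_equal(ekey(d@edgesRemoved), ekey(vp$truth$edgesRemoved))
  }
})

test_that("suspected identifier reuse is flagged by the label heuristic", {
  onto <- midgutChain()
  reused <- onto
  reused@terms$name[7] <- "mesothelium"  # no shared labels remain
  d <- diffVersions(onto, reused)
  expect_true(any(d@findings$check == "id_reuse_suspected"))
  # keeping the old label as a synonym suppresses the flag
  kept <- reused
  kept@synonyms <- rbind(kept@synonyms, data.frame(
    accession = "EMAPA:7", synonym = "epithelium", scope = "RELATED",
    stringsAsFactors = FALSE))
  d2 <- diffVersions(onto, kept)
  expect_equal(nrow(d2@findings), 0L)
})
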