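test_that("instantiation reproduces the worked-example chains", {
  onto <- midgutChain()
  t14 <- instantiateStage(onto, 14)
  expect_equal(nrow(terms(t14)), 7L)
  expect_equal(nrow(edges(t14)), 6L)
  expect_equal(fullPathNames(t14, "EMAPA:7"),
               paste0("TS14/mouse/organ system/visceral organ/",
                      "alimentary system/gut/midgut/epithelium"))
  # limb > forelimb > handplate > digit 1 > mesenchyme at TS20
  limb <- mkOnto(c("mouse", "limb", "forelimb", "handplate", "digit 1",
                   "mesenchyme"),
                 start = c(1L, rep(17L, 5)), end = 28L,
                 edges = c("limb -> mouse", "forelimb -> limb",
                           "handplate -> forelimb", "digit 1 -> handplate",
                           "mesenchyme -> digit 1"))
  t20 <- instantiateStage(limb, 20)
  expect_equal(nrow(terms(t20)), 6L)
  expect_equal(nrow(edges(t20)), 5L)
  expect_equal(fullPathNames(t20, "EMAPA:6"),
               "TS20/mouse/limb/forelimb/handplate/digit 1/mesenchyme")
})

test_that("interval membership decides presence at a stage", {
  onto <- mkOnto(c("mouse", "otocyst"), start = c(1L, 10L),
                 end = c(28L, 12L), edges = "otocyst -> mouse")
  expect_true("EMAPA:2" %in% terms(instantiateStage(onto, 12))$abstract)
  expect_false("EMAPA:2" %in% terms(instantiateStage(onto, 13))$abstract)
  # root absent at the requested stage is outside coverage
  small <- mkOnto(c("mouse", "gut"), start = c(5L, 6L), end = c(20L, 10L),
                  edges = "gut -> mouse")
  expect_error(instantiateStage(small, 2), "outside ontology coverage")
})

test_that("node counts match the brute-force interval oracle per stage", {
  for (seed in 1:30) {
    fx <- generateFixture(fixtureSpec(seed = seed, nTerms = 40))
    res <- instantiateAll(fx$ontology)
    for (s in seq(1, 28, by = 4)) {
      to <- timedOntologies(res)[[sprintf("TS%02d", s)]]
      expect_equal(nrow(terms(to)), oracleNodeCount(fx$ontology, s))
    }
  }
})

test_that("every timed edge joins two present endpoints", {
  for (seed in 1:10) {
    fx <- generateFixture(fixtureSpec(seed = seed, nTerms = 40,
                                      multiParentFraction = 0.4))
    res <- instantiateAll(fx$ontology)
    for (to in timedOntologies(res)) {
      ed <- edges(to)
      expect_true(all(ed$from %in% terms(to)$accession))
      expect_true(all(ed$to %in% terms(to)$accession))
    }
  }
})

test_that("orphaned-at-stage terms are instantiated and reported", {
  # child outlives its only parent
  onto <- mkOnto(c("mouse", "gut", "epithelium"),
                 start = c(1L, 12L, 12L), end = c(28L, 14L, 16L),
                 edges = c("gut -> mouse", "epithelium -> gut"))
  t15 <- instantiateStage(onto, 15)
  expect_true("EMAPA:3" %in% terms(t15)$abstract)
  f <- findings(t15@report)
  expect_true(any(f$check == "orphan_at_stage" &
                    grepl("EMAPA:3", f$accessions)))
  expect_error(instantiateStage(onto, 15, strict = TRUE), "unreachable")
})

test_that("cold-start allocation is complete, ordered and deterministic", {
  fx <- generateFixture(fixtureSpec(seed = 5, nTerms = 25))
  tm <- terms(fx$ontology)
  res <- instantiateAll(fx$ontology)
  rows <- mappingRows(res@mapping)
  # one row per (term, stage-in-range) pair
  expect_equal(nrow(rows), sum(tm$end - tm$start + 1L))
  # allocation follows (stage, abstract local id) order monotonically
  ord <- order(rows$stage, as.integer(sub(".*:", "", rows$abstract)))
  ids <- as.integer(sub(".*:", "", rows$timed[ord]))
  expect_equal(ids, seq_along(ids))
  # rerun is byte-identical
  res2 <- instantiateAll(fx$ontology)
  expect_identical(formatMapping(res2@mapping), formatMapping(res@mapping))
})

test_that("rerunning against the previous mapping is the identity", {
  fx <- generateFixture(fixtureSpec(seed = 9, nTerms = 30))
  m1 <- instantiateAll(fx$ontology)@mapping
  m2 <- instantiateAll(fx$ontology, previous = m1)@mapping
  expect_identical(formatMapping(m2), formatMapping(m1))
})

test_that("extending a range allocates exactly one fresh, larger id", {
  onto <- mkOnto(c("mouse", "heart"), start = c(1L, 10L), end = c(28L, 12L),
                 edges = "heart -> mouse")
  m1 <- instantiateAll(onto)@mapping
  wider <- onto
  wider@terms$end[2] <- 13L
  m2 <- instantiateAll(wider, previous = m1)@mapping
  r1 <- mappingRows(m1); r2 <- mappingRows(m2)
  expect_true(all(paste(r1$timed, r1$abstract, r1$stage) %in%
                    paste(r2$timed, r2$abstract, r2$stage)))
  fresh <- r2[!(r2$timed %in% r1$timed), ]
  expect_equal(nrow(fresh), 1L)
  expect_equal(fresh$stage, 13L)
  expect_gt(as.integer(sub(".*:", "", fresh$timed)),
            max(as.integer(sub(".*:", "", r1$timed))))
})

test_that("stale mapping rows are retired with a warning, never reused", {
  onto <- mkOnto(c("mouse", "heart"), start = c(1L, 10L), end = c(28L, 12L),
                 edges = "heart -> mouse")
  m1 <- instantiateAll(onto)@mapping
  # shrink the range: the TS12 row becomes stale
  shrunk <- onto
  shrunk@terms$end[2] <- 11L
  res <- instantiateAll(shrunk, previous = m1)
  staleAcc <- mappingRows(m1)$timed[mappingRows(m1)$stage == 12 &
                                      mappingRows(m1)$abstract == "EMAPA:2"]
  expect_true(staleAcc %in% retiredAccessions(res@mapping))
  expect_false(staleAcc %in% mappingRows(res@mapping)$timed)
  expect_true(any(findings(res@report)$check == "mapping_stale_stage"))
  # re-extend: the pair gets a brand-new accession, not the retired one
  res2 <- instantiateAll(onto, previous = res@mapping)
  readd <- mappingRows(res2@mapping)
  acc2 <- readd$timed[readd$stage == 12 & readd$abstract == "EMAPA:2"]
  expect_false(acc2 == staleAcc)
  expect_true(staleAcc %in% retiredAccessions(res2@mapping))
  # a previous mapping naming an unknown term warns and retires
  ghost <- mappingTable(data.frame(timed = "EMAP:77", abstract = "EMAPA:99",
                                   stage = 5L))
  res3 <- instantiateAll(onto, previous = ghost)
  expect_true(any(findings(res3@report)$check == "mapping_unknown_abstract"))
  expect_true("EMAP:77" %in% retiredAccessions(res3@mapping))
})

test_that("the abstract ontology is the union of its timed graphs", {
  # occurrence at stages 12..14 only gives range [12, 14]
  onto <- mkOnto(c("mouse", "handplate"), start = c(1L, 12L),
                 end = c(28L, 14L), edges = "handplate -> mouse")
  res <- instantiateAll(onto)
  back <- deriveAbstract(timedOntologies(res))
  expect_equal(stageRange(back, "EMAPA:2"), c(12L, 14L))
  # a single input stage collapses every range to [s, s]
  one <- deriveAbstract(timedOntologies(res)["TS13"])
  tm <- terms(one)
  expect_true(all(tm$start == 13L & tm$end == 13L))
})

test_that("derive-abstract round-trips instantiation on random fixtures", {
  for (seed in 1:30) {
    fx <- generateFixture(fixtureSpec(seed = seed, nTerms = 50,
                                      multiParentFraction = 0.3,
                                      isaFraction = 0.25))
    res <- instantiateAll(fx$ontology)
    back <- deriveAbstract(timedOntologies(res))
    expect_true(ontologyIdentical(fx$ontology, back, checkSynonyms = FALSE))
  }
})

test_that("widening a stage range never removes nodes from any stage", {
  fx <- generateFixture(fixtureSpec(seed = 21, nTerms = 30))
  onto <- fx$ontology
  before <- instantiateAll(onto)
  pick <- accessions(onto)[5]
  i <- match(pick, onto@terms$accession)
  wider <- onto
  wider@terms$start[i] <- max(stageDomain(onto)[1], onto@terms$start[i] - 2L)
  wider@terms$end[i] <- min(stageDomain(onto)[2], onto@terms$end[i] + 2L)
  after <- instantiateAll(wider)
  for (tok in names(timedOntologies(before))) {
    a <- terms(timedOntologies(before)[[tok]])$abstract
    b <- terms(timedOntologies(after)[[tok]])$abstract
    expect_true(all(a %in% b))
  }
})

test_that("non-contiguous occurrence errors in strict mode, hulls otherwise", {
  onto <- mkOnto(c("mouse", "gland"), start = c(1L, 10L), end = c(28L, 12L),
                 edges = "gland -> mouse")
  res <- instantiateAll(onto)
  gappy <- timedOntologies(res)[c("TS10", "TS12")]  # drop TS11
  expect_error(deriveAbstract(gappy, strict = TRUE), "non-contiguously")
  hulled <- deriveAbstract(gappy)
  expect_equal(stageRange(hulled, "EMAPA:2"), c(10L, 12L))
  expect_true(any(findings(hulled@loadReport)$check ==
                    "non_contiguous_occurrence"))
})

test_that("legacy per-stage files without cross-references still unify", {
  onto <- midgutChain()
  res <- instantiateAll(onto)
  stripped <- lapply(timedOntologies(res)[paste0("TS", 10:28)], function(t) {
    t@terms$abstract <- NA_character_
    t
  })
  back <- deriveAbstract(stripped)
  expect_equal(nrow(terms(back)), 7L)
  tm <- terms(back)
  expect_equal(sort(tm$name), sort(terms(onto)$name))
  ep <- tm$accession[tm$name == "epithelium"]
  expect_equal(stageRange(back, ep), c(10L, 28L))
  # conflicting names for one accession are an error
  bad <- timedOntologies(res)[c("TS10", "TS11")]
  bad[[2]]@terms$name[bad[[2]]@terms$abstract == "EMAPA:7"] <- "lining"
  expect_error(deriveAbstract(bad), "conflicting names")
})

test_that("path counting matches the dynamic-programming oracle on DAGs", {
  for (seed in 1:15) {
    fx <- generateFixture(fixtureSpec(seed = seed, nTerms = 20,
                                      multiParentFraction = 0.5))
    t1 <- instantiateStage(fx$ontology, 1)
    for (a in terms(t1)$accession) {
      expect_length(fullPathNames(t1, a), oraclePathCount(t1, a))
    }
  }
  # root has the single zero-length path
  t1 <- instantiateStage(midgutChain(), 20)
  expect_equal(fullPathNames(t1, "EMAPA:1"), "TS20/mouse")
  expect_error(fullPathNames(t1, "EMAP:999"), "unknown accession")
})
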