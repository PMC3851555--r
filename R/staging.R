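#' @include obo-io.R
NULL

## All (abstract accession, stage) pairs to instantiate, in allocation
## order: stage ascending, then abstract local id ascending.
.instantiationPairs <- function(x) {
  live <- x@terms[!x@terms$obsolete, , drop = FALSE]
  live <- live[order(.localPart(live$accession)), , drop = FALSE]
  dom <- x@stageDomain
  n <- pmax(0L, live$end - live$start + 1L)
  pairs <- data.frame(
    abstract = rep(live$accession, n),
    stage = unlist(lapply(seq_len(nrow(live)),
                          function(i) seq.int(live$start[i], live$end[i])),
                   use.names = FALSE),
    stringsAsFactors = FALSE)
  pairs <- pairs[pairs$stage >= dom[1] & pairs$stage <= dom[2], , drop = FALSE]
  pairs[order(pairs$stage, .localPart(pairs$abstract)), , drop = FALSE]
}

## Persistent-identifier allocation. Rows of `previous` whose
## (abstract, stage) pair is still instantiated are kept byte-identically;
## pairs never seen before get fresh, monotonically increasing local ids;
## rows that no longer correspond to an instantiated pair are moved to the
## retired set and their accessions are never reallocated.
.allocateMapping <- function(x, previous = mappingTable(),
                             config = ontologyConfig()) {
  pairs <- .instantiationPairs(x)
  pairKey <- paste(pairs$abstract, pairs$stage)
  prev <- previous@rows
  prevKey <- paste(prev$abstract, prev$stage)
  surviving <- prevKey %in% pairKey
  find <- .emptyFindings()
  if (any(!surviving)) {
    stale <- prev[!surviving, , drop = FALSE]
    unknown <- !(stale$abstract %in% x@terms$accession)
    if (any(unknown))
      find <- rbind(find, .finding(
        "WARNING", "mapping_unknown_abstract",
        unique(stale$abstract[unknown]),
        "previous mapping references abstract accessions not in the ontology; rows retired"))
    if (any(!unknown))
      find <- rbind(find, .finding(
        "WARNING", "mapping_stale_stage",
        unique(stale$abstract[!unknown]),
        "previous mapping rows fall outside current stage ranges; rows retired"))
  }
  retired <- unique(c(previous@retired, prev$timed[!surviving]))
  keep <- prev[surviving, , drop = FALSE]
  idx <- match(pairKey, prevKey[surviving])
  timed <- keep$timed[idx]
  usedLocal <- c(.localPart(keep$timed), .localPart(retired))
  nextId <- max(previous@nextLocalId,
                if (length(usedLocal)) max(usedLocal, na.rm = TRUE) + 1L else 1L)
  fresh <- is.na(timed)
  nFresh <- sum(fresh)
  if (nFresh) {
    timed[fresh] <- paste0(config@timedPrefix, ":",
                           seq.int(nextId, length.out = nFresh))
    nextId <- nextId + nFresh
  }
  mapping <- mappingTable(
    data.frame(timed = timed, abstract = pairs$abstract, stage = pairs$stage,
               stringsAsFactors = FALSE),
    nextLocalId = nextId, retired = retired)
  list(mapping = mapping, findings = find)
}

.instantiateStageInternal <- function(x, stage, mapping, config,
                                      strict, requireRoot = TRUE) {
  stage <- as.integer(stage)
  dom <- x@stageDomain
  if (stage < dom[1] || stage > dom[2])
    stop("stage ", stage, " outside stage domain [", dom[1], ", ", dom[2],
         "]", call. = FALSE)
  live <- x@terms[!x@terms$obsolete, , drop = FALSE]
  present <- live[live$start <= stage & live$end >= stage, , drop = FALSE]
  roots <- .rootsOf(x)
  rootsHere <- intersect(roots, present$accession)
  if (requireRoot && !length(rootsHere))
    stop("stage outside ontology coverage: root absent at stage ", stage,
         call. = FALSE)
  rel <- .hierarchyEdges(x, includeIsa = config@includeIsa)
  rel <- rel[rel$from %in% present$accession & rel$to %in% present$accession,
             , drop = FALSE]
  find <- .emptyFindings()
  orphans <- setdiff(present$accession,
                     .reachableFrom(rootsHere, rel$from, rel$to))
  if (length(orphans)) {
    if (strict)
      stop("terms present but unreachable from the root at stage ", stage,
           ": ", paste(orphans, collapse = ", "), call. = FALSE)
    find <- rbind(find, .finding(
      "WARNING", "orphan_at_stage", orphans,
      paste0("present at stage ", stage,
             " with no parent reachable from the root")))
  }
  key <- paste(mapping@rows$abstract, mapping@rows$stage)
  idx <- match(paste(present$accession, stage), key)
  if (anyNA(idx))
    stop("mapping has no row for ", present$accession[which(is.na(idx))[1]],
         " at stage ", stage, call. = FALSE)
  timedAcc <- mapping@rows$timed[idx]
  remap <- stats::setNames(timedAcc, present$accession)
  edges <- data.frame(from = unname(remap[rel$from]), type = rel$type,
                      to = unname(remap[rel$to]), stringsAsFactors = FALSE)
  ord <- order(.localPart(present$accession))
  new("TimedOntology", stage = stage,
      terms = data.frame(accession = timedAcc[ord],
                         abstract = present$accession[ord],
                         name = present$name[ord], stringsAsFactors = FALSE),
      edges = edges, prefix = config@timedPrefix,
      report = validationReport(find))
}

#' Instantiate the timed ontology for one developmental stage
#'
#' Restricts the abstract ontology to the terms whose stage range contains
#' `stage`, keeping every `part_of`/`is_a` edge whose two endpoints are
#' both present (an edge with one absent endpoint is dropped, which is
#' what lets the stage-consistency check spot orphaned structures). Terms
#' that are present but unreachable from the root are still instantiated
#' and flagged with an `orphan_at_stage` WARNING in the result's report;
#' under `strict` they are an error. A stage at which the root itself is
#' absent is outside the ontology's coverage and always an error.
#'
#' Timed accessions come from `mapping`; when no mapping is given, a
#' cold-start allocation over the whole ontology is computed (identical to
#' `instantiateAll(x)` with an empty previous mapping), so accessions are
#' deterministic either way.
#'
#' @param x an [AbstractOntology-class].
#' @param stage integer stage within the stage domain.
#' @param mapping optional [MappingTable-class] supplying timed accessions.
#' @param config an [OntologyConfig-class].
#' @param strict promote orphan-at-stage warnings to errors.
#' @param ... unused.
#' @return A [TimedOntology-class]; findings in its `report`.
#' @export
setMethod("instantiateStage", "AbstractOntology",
          function(x, stage, mapping = NULL, config = ontologyConfig(),
                   strict = config@strict, ...) {
  config@stageDomain <- x@stageDomain
  if (is.null(mapping))
    mapping <- .allocateMapping(x, mappingTable(), config)$mapping
  .instantiateStageInternal(x, stage, mapping, config, strict,
                            requireRoot = TRUE)
})

#' Instantiate every stage and maintain the persistent identifier mapping
#'
#' Produces one [TimedOntology-class] per stage in the stage domain
#' together with an updated [MappingTable-class]. For every abstract term
#' and every stage in its range exactly one timed term is created. Timed
#' accessions are taken from `previous` wherever the (abstract accession,
#' stage) pair was already mapped — previously issued accessions never
#' change meaning — and freshly allocated otherwise, in (stage, abstract
#' local id) order with a monotonically increasing counter. Previous rows
#' that no longer correspond to an instantiated pair (unknown accession or
#' a shrunken stage range) are moved to the retired set with a WARNING and
#' their accessions are never reused.
#'
#' @param x an [AbstractOntology-class].
#' @param previous the [MappingTable-class] from the previous release
#'   (empty for a cold start).
#' @param config an [OntologyConfig-class].
#' @param ... unused.
#' @return An [InstantiationResult-class] with slots `timed` (list named
#'   by stage token), `mapping` and `report`.
#' @export
setMethod("instantiateAll", "AbstractOntology",
          function(x, previous = mappingTable(), config = ontologyConfig(),
                   ...) {
  config@stageDomain <- x@stageDomain
  alloc <- .allocateMapping(x, previous, config)
  dom <- x@stageDomain
  stages <- seq.int(dom[1], dom[2])
  timed <- vector("list", length(stages))
  names(timed) <- .stageToken(stages)
  reports <- list(alloc$findings)
  for (i in seq_along(stages)) {
    to <- .instantiateStageInternal(x, stages[i], alloc$mapping, config,
                                    strict = config@strict,
                                    requireRoot = FALSE)
    reports[[length(reports) + 1L]] <- to@report@findings
    timed[[i]] <- to
  }
  new("InstantiationResult", timed = timed, mapping = alloc$mapping,
      report = validationReport(do.call(.combineFindings, reports)))
})

#' @describeIn InstantiationResult-class list of per-stage timed ontologies.
#' @param x an `InstantiationResult`.
#' @export
timedOntologies <- function(x) x@timed

setMethod("show", "InstantiationResult", function(object) {
  cat("InstantiationResult: ", length(object@timed), " stages, ",
      nrow(object@mapping@rows), " mapping rows\n", sep = "")
})

## ---- union of timed graphs ---------------------------------------------

## Name-path fallback identity for legacy per-stage files lacking xrefs:
## a node is identified by (name, sorted set of parent names) within its
## stage; the same key at different stages is the same abstract entity.
.assignFallbackIds <- function(timedList, config) {
  keys <- character()
  for (j in seq_along(timedList)) {
    to <- timedList[[j]]
    tm <- to@terms
    need <- is.na(tm$abstract)
    if (!any(need)) next
    ed <- to@edges[to@edges$type %in% .HIERARCHY_TYPES, , drop = FALSE]
    nameOf <- stats::setNames(tm$name, tm$accession)
    nodeKey <- vapply(tm$accession, function(a) {
      ps <- .csort(unname(nameOf[ed$to[ed$from == a]]))
      paste(nameOf[[a]], paste(ps, collapse = "|"), sep = "\r")
    }, character(1))
    if (anyDuplicated(nodeKey[need]))
      stop("ambiguous name-path fallback at stage ", to@stage, ": key '",
           nodeKey[need][duplicated(nodeKey[need])][1],
           "' matches several nodes", call. = FALSE)
    for (k in which(need)) {
      key <- nodeKey[k]
      if (!key %in% keys) keys <- c(keys, key)
      tm$abstract[k] <- paste0(config@abstractPrefix, ":",
                               match(key, keys))
    }
    to@terms <- tm
    timedList[[j]] <- to
  }
  timedList
}

#' Derive the abstract ontology as the union of timed graphs
#'
#' Reconstructs the stage-independent ontology from a set of per-stage
#' ontologies: the node set is the union of nodes (identified by abstract
#' accession, or by exact (name, parent-name set) matching for legacy
#' inputs without cross-references), each term's stage range is the first
#' and last stage at which it occurs, and the edge set is the union of the
#' timed edge sets. Non-contiguous occurrence — present at two stages but
#' not in between — cannot be represented by the interval model; it is an
#' error under `strict` and a WARNING plus hull interval otherwise.
#' Conflicting names for one abstract accession are always an error.
#'
#' `deriveAbstract(timedOntologies(instantiateAll(x)))` recovers `x`
#' exactly (terms, stage ranges and hierarchy edges) for any valid
#' ontology with contiguous ranges.
#'
#' @param timedList list of [TimedOntology-class] objects.
#' @param config an [OntologyConfig-class]; supplies the stage domain and
#'   abstract prefix of the result.
#' @param strict error on non-contiguous occurrence.
#' @return An [AbstractOntology-class]; contiguity findings in
#'   `loadReport(x)`.
#' @export
deriveAbstract <- function(timedList, config = ontologyConfig(),
                           strict = config@strict) {
  if (!length(timedList))
    stop("deriveAbstract needs at least one timed ontology", call. = FALSE)
  timedList <- timedList[order(vapply(timedList, function(t) t@stage,
                                      integer(1)))]
  if (any(vapply(timedList, function(t) anyNA(t@terms$abstract), logical(1))))
    timedList <- .assignFallbackIds(timedList, config)
  nodes <- do.call(rbind, lapply(timedList, function(t)
    data.frame(abstract = t@terms$abstract, name = t@terms$name,
               stage = t@stage, stringsAsFactors = FALSE)))
  edgeTab <- do.call(rbind, lapply(timedList, function(t) {
    abs <- stats::setNames(t@terms$abstract, t@terms$accession)
    e <- t@edges
    data.frame(from = unname(abs[e$from]), type = e$type,
               to = unname(abs[e$to]), stringsAsFactors = FALSE)
  }))
  find <- .emptyFindings()
  accs <- unique(nodes$abstract)
  accs <- accs[order(.localPart(accs))]
  nm <- character(length(accs)); st <- integer(length(accs))
  en <- integer(length(accs))
  byAcc <- split(seq_len(nrow(nodes)), nodes$abstract)
  for (i in seq_along(accs)) {
    rows <- byAcc[[accs[i]]]
    nms <- unique(nodes$name[rows])
    if (length(nms) > 1)
      stop("conflicting names for ", accs[i], " across stages: ",
           paste(nms, collapse = " / "), call. = FALSE)
    nm[i] <- nms
    stages <- sort(unique(nodes$stage[rows]))
    st[i] <- stages[1]; en[i] <- stages[length(stages)]
    gaps <- setdiff(seq.int(st[i], en[i]), stages)
    if (length(gaps)) {
      msg <- paste0(accs[i], " occurs non-contiguously (absent at stage ",
                    paste(gaps, collapse = ", "),
                    "); hull interval [", st[i], ", ", en[i], "] used")
      if (strict) stop(msg, call. = FALSE)
      find <- rbind(find, .finding("WARNING", "non_contiguous_occurrence",
                                   accs[i], msg))
    }
  }
  edgeTab <- edgeTab[!duplicated(paste(edgeTab$from, edgeTab$type,
                                       edgeTab$to)), , drop = FALSE]
  edgeTab <- edgeTab[order(.localPart(edgeTab$from), edgeTab$type,
                           .localPart(edgeTab$to)), , drop = FALSE]
  onto <- abstractOntology(
    terms = data.frame(accession = accs, name = nm, start = st, end = en,
                       obsolete = FALSE, stringsAsFactors = FALSE),
    relations = edgeTab, stageDomain = config@stageDomain,
    prefix = config@abstractPrefix)
  onto@loadReport <- validationReport(find)
  onto
}

## ---- path names ---------------------------------------------------------

#' All full path names of a timed term
#'
#' A timed term in a tree is uniquely identified by its "full name": the
#' stage token followed by the ordered hierarchical path from the root,
#' e.g. `TS14/mouse/organ system/visceral organ/alimentary system/gut/`
#' `midgut/epithelium`. In a DAG a term can have several such paths; all
#' root-to-term paths over `part_of`/`is_a` edges are returned, sorted.
#'
#' @param x a [TimedOntology-class].
#' @param accession a timed accession, or an abstract accession carried by
#'   one of the timed terms.
#' @return Character vector of slash-delimited path strings.
#' @export
setMethod("fullPathNames", "TimedOntology", function(x, accession) {
  tm <- x@terms
  if (accession %in% tm$accession) {
    acc <- accession
  } else if (accession %in% tm$abstract) {
    acc <- tm$accession[match(accession, tm$abstract)]
  } else {
    stop("unknown accession: ", accession, call. = FALSE)
  }
  ed <- x@edges[x@edges$type %in% .HIERARCHY_TYPES, , drop = FALSE]
  nameOf <- stats::setNames(tm$name, tm$accession)
  pathsTo <- function(a, seen = character()) {
    if (a %in% seen) stop("cycle in timed graph at ", a, call. = FALSE)
    parents <- ed$to[ed$from == a]
    if (!length(parents)) return(list(a))
    out <- list()
    for (p in parents)
      for (pp in pathsTo(p, c(seen, a)))
        out[[length(out) + 1L]] <- c(pp, a)
    out
  }
  rendered <- vapply(pathsTo(acc), function(p)
    paste0(.stageToken(x@stage), "/",
           paste(unname(nameOf[p]), collapse = "/")), character(1))
  .csort(rendered)
})
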