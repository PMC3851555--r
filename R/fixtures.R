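#' @include validate.R
NULL

## Anatomy-flavored vocabulary for generated term labels. Reuse across
## terms is what exercises the naming machinery; biological realism of
## the topology is an explicit non-goal.
.anatomyVocab <- c(
  "epithelium", "mesenchyme", "gut", "midgut", "foregut", "hindgut",
  "brain", "head", "neck", "limb", "forelimb", "hindlimb", "handplate",
  "footplate", "digit", "heart", "atrium", "ventricle", "somite",
  "neural tube", "spinal cord", "liver", "lung", "kidney", "gonad",
  "tail", "trunk", "ectoderm", "endoderm", "mesoderm", "aorta", "artery",
  "vein", "ganglion", "nerve", "eye", "retina", "lens", "ear", "otocyst",
  "tongue", "mandible", "maxilla", "palate", "rib", "vertebra", "sternum",
  "skin", "dermis", "epidermis", "muscle", "cartilage", "bone", "blood",
  "plexus", "sinus", "duct", "gland", "follicle", "mucosa", "lumen",
  "cavity", "membrane", "septum", "valve", "node", "vessel", "cortex",
  "medulla", "stroma", "capsule", "papilla")

## Evaluate `expr` under a temporary, fully specified RNG state so that
## generation is reproducible bit-for-bit and never disturbs the caller's
## random stream.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old))
      rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  suppressWarnings(set.seed(seed, kind = "Mersenne-Twister",
                            normal.kind = "Inversion",
                            sample.kind = "Rejection"))
  expr
}

## Draws are namespaced per term / per defect: each unit gets its own
## derived seed, so adding a generator parameter never silently shifts
## the draws of earlier units.
.subSeed <- function(seed, i, salt = 0L) {
  (as.numeric(seed) * 48271 + i * 1000003 + salt * 7919) %% 2147483562 + 1
}

.truthFromTables <- function(terms, relations, dom) {
  stages <- seq.int(dom[1], dom[2])
  live <- terms[!terms$obsolete, , drop = FALSE]
  nodeCounts <- vapply(stages, function(s)
    sum(live$start <= s & live$end >= s), integer(1))
  hier <- relations[relations$type %in% .HIERARCHY_TYPES, , drop = FALSE]
  fi <- match(hier$from, live$accession); ti <- match(hier$to, live$accession)
  ok <- !is.na(fi) & !is.na(ti)
  fi <- fi[ok]; ti <- ti[ok]
  edgeCounts <- vapply(stages, function(s)
    sum(live$start[fi] <= s & live$end[fi] >= s &
          live$start[ti] <= s & live$end[ti] >= s), integer(1))
  names(nodeCounts) <- names(edgeCounts) <- .stageToken(stages)
  dupNames <- table(live$name)
  dupNames <- dupNames[dupNames > 1]
  list(perStageNodeCounts = nodeCounts, perStageEdgeCounts = edgeCounts,
       duplicateNames = data.frame(name = names(dupNames),
                                   count = as.integer(dupNames),
                                   stringsAsFactors = FALSE))
}

## First-parent depth of every term (root = 0); generation keeps the
## first hierarchy edge of each term as its primary parent.
.depths <- function(terms, relations) {
  hier <- relations[relations$type %in% .HIERARCHY_TYPES, , drop = FALSE]
  firstParent <- hier$to[match(terms$accession, hier$from)]
  depth <- stats::setNames(rep(NA_integer_, nrow(terms)), terms$accession)
  depth[is.na(firstParent)] <- 0L
  while (anyNA(depth)) {
    todo <- which(is.na(depth))
    resolved <- !is.na(depth[firstParent[todo]])
    if (!any(resolved)) break
    depth[todo[resolved]] <- depth[firstParent[todo[resolved]]] + 1L
  }
  depth
}

#' Generate a synthetic abstract ontology with recorded ground truth
#'
#' Produces a rooted multi-parent DAG shaped like a developmental-anatomy
#' ontology: a root spanning the whole stage domain, child stage ranges
#' sampled inside their primary parent's range (start uniform, length
#' geometric), a configurable fraction of `is_a` edges and of second
#' parents, and labels drawn from an anatomy vocabulary with duplicates
#' at the requested rate. Generation is fully deterministic: the same
#' [FixtureSpec-class] yields byte-identical serialized output.
#'
#' Ground truth (per-stage node/edge counts, the duplicate-name multiset,
#' the injected-defect inventory) is computed arithmetically from the
#' term and relation tables during generation, independently of the
#' staging and validation code it is used to test.
#'
#' Requested defects are injected after construction: `cycle` (a
#' back-edge from an ancestor), `inverted_range` (start/end swapped),
#' `duplicate_name` (a forced label collision), `orphan` (a child range
#' pushed outside its parents' coverage), `stale_mapping` (bogus mapping
#' rows recorded in `truth$staleMappingRows` for tests to append to a
#' mapping table).
#'
#' @param spec a [FixtureSpec-class].
#' @param config an [OntologyConfig-class] (prefixes).
#' @return A list with elements `ontology` ([AbstractOntology-class]) and
#'   `truth` (a list).
#' @export
generateFixture <- function(spec, config = ontologyConfig()) {
  n <- spec@nTerms
  dom <- spec@stageDomain
  if (spec@maxDepth < 2 && n > 1)
    stop("infeasible spec: maxDepth < 2 with more than one term",
         call. = FALSE)
  pfx <- config@abstractPrefix
  acc <- paste0(pfx, ":", seq_len(n))
  nm <- character(n); st <- integer(n); en <- integer(n)
  depth <- integer(n)
  nm[1] <- "mouse"; st[1] <- dom[1]; en[1] <- dom[2]; depth[1] <- 0L
  rel <- .emptyRelations()
  for (i in seq_len(n)[-1]) {
    .withSeed(.subSeed(spec@seed, i), {
      eligible <- which(depth[seq_len(i - 1)] < spec@maxDepth - 1L)
      p <- eligible[sample.int(length(eligible), 1L)]
      type <- if (stats::runif(1) < spec@isaFraction) "is_a" else "part_of"
      start <- st[p] + sample.int(en[p] - st[p] + 1L, 1L) - 1L
      len <- 1L + stats::rgeom(1, 1 / spec@rangeMeanLength)
      end <- min(start + len - 1L, en[p])
      ## duplicates occur at exactly the requested rate: fresh draws avoid
      ## labels already in use (numbered variants once the vocabulary is
      ## exhausted)
      nm[i] <- if (i > 2 && stats::runif(1) < spec@duplicateLabelFraction) {
        prior <- nm[2:(i - 1)]
        prior[sample.int(length(prior), 1L)]
      } else {
        unused <- setdiff(.anatomyVocab, nm[seq_len(i - 1)])
        if (length(unused)) {
          unused[sample.int(length(unused), 1L)]
        } else {
          base <- .anatomyVocab[sample.int(length(.anatomyVocab), 1L)]
          k <- 2L
          while (paste(base, k) %in% nm[seq_len(i - 1)]) k <- k + 1L
          paste(base, k)
        }
      }
      st[i] <- start; en[i] <- end; depth[i] <- depth[p] + 1L
      rel <- rbind(rel, data.frame(from = acc[i], type = type, to = acc[p],
                                   stringsAsFactors = FALSE))
      if (i > 2 && stats::runif(1) < spec@multiParentFraction) {
        ## second parent must co-occur with the child at some stage, or
        ## the relation would hold at no instantiation
        others <- setdiff(seq_len(i - 1), p)
        others <- others[st[others] <= en[i] & en[others] >= st[i]]
        if (length(others)) {
          q <- others[sample.int(length(others), 1L)]
          type2 <- if (stats::runif(1) < spec@isaFraction) "is_a" else "part_of"
          rel <- rbind(rel, data.frame(from = acc[i], type = type2,
                                       to = acc[q], stringsAsFactors = FALSE))
        }
      }
    })
  }
  terms <- data.frame(accession = acc, name = nm, start = st, end = en,
                      obsolete = FALSE, stringsAsFactors = FALSE)
  defectLog <- list()
  staleRows <- NULL
  for (di in seq_along(spec@defects)) {
    d <- spec@defects[[di]]
    count <- if (is.null(d$count)) 1L else as.integer(d$count)
    for (k in seq_len(count)) {
      .withSeed(.subSeed(spec@seed, 10000L + di * 100L + k, salt = 1L), {
        if (d$kind == "cycle") {
          ## back-edge from a non-root ancestor, so the defect breaks
          ## acyclicity without also de-rooting the ontology
          deep <- which(depth >= 3L)
          hier <- rel[rel$type %in% .HIERARCHY_TYPES, , drop = FALSE]
          if (length(deep)) {
            t <- deep[sample.int(length(deep), 1L)]
            p1 <- hier$to[match(acc[t], hier$from)]
            anc <- hier$to[match(p1, hier$from)]
          } else {
            deep <- which(depth >= 2L)
            if (!length(deep)) stop("cycle defect needs depth >= 2 terms")
            t <- deep[sample.int(length(deep), 1L)]
            anc <- hier$to[match(acc[t], hier$from)]
          }
          rel <- rbind(rel, data.frame(from = anc, type = "part_of",
                                       to = acc[t], stringsAsFactors = FALSE))
          defectLog[[length(defectLog) + 1L]] <-
            list(kind = "cycle", accessions = c(anc, acc[t]))
        } else if (d$kind == "inverted_range") {
          cand <- which(terms$end > terms$start & seq_len(n) > 1L)
          t <- cand[sample.int(length(cand), 1L)]
          tmp <- terms$start[t]
          terms$start[t] <- terms$end[t]; terms$end[t] <- tmp
          defectLog[[length(defectLog) + 1L]] <-
            list(kind = "inverted_range", accessions = terms$accession[t])
        } else if (d$kind == "duplicate_name") {
          cand <- which(!duplicated(terms$name) & seq_len(n) > 1L)
          if (length(cand) < 2) stop("duplicate_name defect needs 2 terms")
          ij <- cand[sample.int(length(cand), 2L)]
          terms$name[ij[2]] <- terms$name[ij[1]]
          defectLog[[length(defectLog) + 1L]] <-
            list(kind = "duplicate_name", accessions = terms$accession[ij],
                 name = terms$name[ij[1]])
        } else if (d$kind == "orphan") {
          ## push a term's range one stage past its parents' coverage
          hier <- rel[rel$type %in% .HIERARCHY_TYPES, , drop = FALSE]
          nonRoot <- terms$accession[-1]
          parentEnd <- vapply(nonRoot, function(a)
            max(terms$end[match(hier$to[hier$from == a],
                                terms$accession)]), integer(1))
          parentStart <- vapply(nonRoot, function(a)
            min(terms$start[match(hier$to[hier$from == a],
                                  terms$accession)]), integer(1))
          cand <- nonRoot[parentEnd < dom[2] | parentStart > dom[1]]
          if (!length(cand)) stop("no orphan candidate term")
          a <- cand[sample.int(length(cand), 1L)]
          t <- match(a, terms$accession)
          pe <- parentEnd[match(a, nonRoot)]
          ps <- parentStart[match(a, nonRoot)]
          if (pe < dom[2]) {
            terms$end[t] <- pe + 1L
            terms$start[t] <- min(terms$start[t], pe + 1L)
            orphanStage <- pe + 1L
          } else {
            terms$start[t] <- ps - 1L
            terms$end[t] <- max(terms$end[t], ps - 1L)
            orphanStage <- ps - 1L
          }
          defectLog[[length(defectLog) + 1L]] <-
            list(kind = "orphan", accessions = a, stage = orphanStage)
        } else if (d$kind == "stale_mapping") {
          t <- sample.int(n, 1L)
          staleRows <- rbind(staleRows, data.frame(
            timed = paste0(config@timedPrefix, ":",
                           900000L + di * 100L + k),
            abstract = paste0(pfx, ":", n + 1000L + k),
            stage = dom[1], stringsAsFactors = FALSE))
          defectLog[[length(defectLog) + 1L]] <-
            list(kind = "stale_mapping",
                 accessions = staleRows$timed[nrow(staleRows)])
        } else {
          stop("unknown defect kind: ", d$kind)
        }
      })
    }
  }
  onto <- abstractOntology(terms = terms, relations = rel,
                           stageDomain = dom, prefix = pfx)
  truth <- .truthFromTables(terms, rel, dom)
  truth$defects <- defectLog
  truth$staleMappingRows <- staleRows
  truth$depths <- depth
  list(ontology = onto, truth = truth)
}

#' Generate a version pair with a recorded edit script
#'
#' Builds a fixture ontology, then applies a random edit script of the
#' requested composition — `add` (new leaf under a random parent),
#' `retire` (remove a leaf), `rename` (new label, old label kept as
#' synonym), `rerange` (new stage subrange for a leaf) — producing a
#' successor version plus ground truth for the diff: exactly which
#' accessions were added and retired, every rename and range change, and
#' the edge changes implied. Ops target disjoint terms so the recorded
#' script equals the net difference.
#'
#' @param spec a [FixtureSpec-class] for the base version.
#' @param edits named list of op counts, e.g.
#'   `list(add = 2, retire = 1, rename = 1, rerange = 1)`.
#' @param config an [OntologyConfig-class].
#' @return A list with `old`, `new` ([AbstractOntology-class]) and
#'   `truth` (added, retired, renamed, rangeChanged, edgesAdded,
#'   edgesRemoved).
#' @export
generateVersionPair <- function(spec, edits = list(), config = ontologyConfig()) {
  base <- generateFixture(spec, config)
  old <- base$ontology
  terms <- old@terms; rel <- old@relations; syn <- old@synonyms
  pfx <- config@abstractPrefix
  used <- character()
  truth <- list(added = character(), retired = character(),
                renamed = data.frame(accession = character(),
                                     old = character(), new = character(),
                                     stringsAsFactors = FALSE),
                rangeChanged = data.frame(accession = character(),
                                          oldStart = integer(),
                                          oldEnd = integer(),
                                          newStart = integer(),
                                          newEnd = integer(),
                                          stringsAsFactors = FALSE),
                edgesAdded = .emptyRelations(),
                edgesRemoved = .emptyRelations())
  cnt <- function(op) if (is.null(edits[[op]])) 0L else as.integer(edits[[op]])
  opIndex <- 0L
  ## fresh accessions never collide with any old-version accession, even
  ## one retired earlier in the same script
  nextAbsId <- max(.localPart(terms$accession)) + 1L
  leafSet <- function() {
    hier <- rel[rel$type %in% .HIERARCHY_TYPES, , drop = FALSE]
    setdiff(terms$accession[-1], c(hier$to, used))
  }
  for (k in seq_len(cnt("retire"))) {
    opIndex <- opIndex + 1L
    .withSeed(.subSeed(spec@seed, opIndex, salt = 2L), {
      cand <- leafSet()
      if (!length(cand)) stop("no leaf available to retire", call. = FALSE)
      a <- cand[sample.int(length(cand), 1L)]
      gone <- rel[rel$from == a | rel$to == a, , drop = FALSE]
      truth$edgesRemoved <- rbind(truth$edgesRemoved, gone)
      truth$retired <- c(truth$retired, a)
      rel <- rel[rel$from != a & rel$to != a, , drop = FALSE]
      terms <- terms[terms$accession != a, , drop = FALSE]
      syn <- syn[syn$accession != a, , drop = FALSE]
      used <- c(used, a)
    })
  }
  for (k in seq_len(cnt("rerange"))) {
    opIndex <- opIndex + 1L
    .withSeed(.subSeed(spec@seed, opIndex, salt = 2L), {
      hier <- rel[rel$type %in% .HIERARCHY_TYPES, , drop = FALSE]
      ## a new range must stay inside the first parent's range, keep
      ## covering any children, and differ from the current one
      feasible <- function(a) {
        i <- match(a, terms$accession)
        p <- hier$to[hier$from == a][1]
        pi <- match(p, terms$accession)
        kids <- hier$from[hier$to == a]
        ki <- match(kids, terms$accession)
        loMax <- if (length(ki)) min(terms$start[ki]) else terms$end[pi]
        hiMin <- if (length(ki)) max(terms$end[ki]) else terms$start[pi]
        subs <- expand.grid(s = terms$start[pi]:terms$end[pi],
                            e = terms$start[pi]:terms$end[pi])
        subs[subs$s <= subs$e & subs$s <= loMax & subs$e >= hiMin &
               !(subs$s == terms$start[i] & subs$e == terms$end[i]), ,
             drop = FALSE]
      }
      cand <- setdiff(terms$accession[-1], used)
      cand <- cand[order(.localPart(cand))]
      cand <- cand[sample.int(length(cand))]
      a <- NULL
      for (cc in cand) {
        subs <- feasible(cc)
        if (nrow(subs)) { a <- cc; break }
      }
      if (is.null(a)) stop("no term available to rerange", call. = FALSE)
      i <- match(a, terms$accession)
      pick <- subs[sample.int(nrow(subs), 1L), ]
      truth$rangeChanged <- rbind(truth$rangeChanged, data.frame(
        accession = a, oldStart = terms$start[i], oldEnd = terms$end[i],
        newStart = pick$s, newEnd = pick$e, stringsAsFactors = FALSE))
      terms$start[i] <- pick$s; terms$end[i] <- pick$e
      used <- c(used, a)
    })
  }
  for (k in seq_len(cnt("rename"))) {
    opIndex <- opIndex + 1L
    .withSeed(.subSeed(spec@seed, opIndex, salt = 2L), {
      cand <- setdiff(terms$accession[-1], used)
      if (!length(cand)) stop("no term available to rename", call. = FALSE)
      a <- cand[sample.int(length(cand), 1L)]
      i <- match(a, terms$accession)
      oldName <- terms$name[i]
      prefixWord <- .anatomyVocab[sample.int(length(.anatomyVocab), 1L)]
      newName <- paste(prefixWord, oldName)
      truth$renamed <- rbind(truth$renamed, data.frame(
        accession = a, old = oldName, new = newName,
        stringsAsFactors = FALSE))
      terms$name[i] <- newName
      syn <- rbind(syn, data.frame(accession = a, synonym = oldName,
                                    scope = "RELATED",
                                    stringsAsFactors = FALSE))
      used <- c(used, a)
    })
  }
  for (k in seq_len(cnt("add"))) {
    opIndex <- opIndex + 1L
    .withSeed(.subSeed(spec@seed, opIndex, salt = 2L), {
      a <- paste0(pfx, ":", nextAbsId)
      nextAbsId <- nextAbsId + 1L
      cand <- setdiff(terms$accession, used)
      p <- cand[sample.int(length(cand), 1L)]
      i <- match(p, terms$accession)
      start <- terms$start[i] +
        sample.int(terms$end[i] - terms$start[i] + 1L, 1L) - 1L
      end <- min(start + stats::rgeom(1, 1 / spec@rangeMeanLength),
                 terms$end[i])
      nm <- .anatomyVocab[sample.int(length(.anatomyVocab), 1L)]
      terms <- rbind(terms, data.frame(
        accession = a, name = nm, start = start, end = end,
        obsolete = FALSE, stringsAsFactors = FALSE))
      edge <- data.frame(from = a, type = "part_of", to = p,
                         stringsAsFactors = FALSE)
      rel <- rbind(rel, edge)
      truth$edgesAdded <- rbind(truth$edgesAdded, edge)
      truth$added <- c(truth$added, a)
      used <- c(used, a)
    })
  }
  newOnto <- abstractOntology(terms = terms, relations = rel, synonyms = syn,
                              stageDomain = old@stageDomain, prefix = pfx,
                              metadata = old@metadata)
  list(old = old, new = newOnto, truth = truth)
}
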