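#' @include AllGenerics.R
NULL

## ---- internal graph helpers --------------------------------------------

## Hierarchy edges (part_of / is_a) among non-obsolete terms.
.hierarchyEdges <- function(x, includeIsa = TRUE) {
  keep <- if (includeIsa) .HIERARCHY_TYPES else "part_of"
  rel <- x@relations[x@relations$type %in% keep, , drop = FALSE]
  live <- x@terms$accession[!x@terms$obsolete]
  rel[rel$from %in% live & rel$to %in% live, , drop = FALSE]
}

## Non-obsolete terms with no hierarchy parents (candidate roots).
.rootsOf <- function(x) {
  live <- x@terms[!x@terms$obsolete, , drop = FALSE]
  rel <- .hierarchyEdges(x)
  setdiff(live$accession, rel$from)
}

## Accessions reachable downward from `roots` given child->parent edges.
.reachableFrom <- function(roots, edgeFrom, edgeTo) {
  reached <- roots
  frontier <- roots
  while (length(frontier)) {
    nxt <- unique(edgeFrom[edgeTo %in% frontier])
    frontier <- setdiff(nxt, reached)
    reached <- c(reached, frontier)
  }
  reached
}

.checkKnown <- function(x, accession) {
  if (!accession %in% x@terms$accession)
    stop("unknown accession: ", accession, call. = FALSE)
}

## ---- accessors ----------------------------------------------------------

#' Accessors for ontology objects
#'
#' @param x an [AbstractOntology-class], [TimedOntology-class] or other
#'   stageont object.
#' @param accession a single accession string.
#' @param ... unused.
#' @return `accessions()` the accession vector; `terms()`, `relations()`,
#'   `synonyms()`, `edges()` the underlying data frames; `stageDomain()`
#'   the inclusive `c(min, max)` stage bounds; `ontologyRoot()` the unique
#'   root accession; `term()` an [AbstractTerm-class]; `stageRange()` the
#'   term's `c(start, end)`.
#' @name ontology-accessors
NULL

#' @rdname ontology-accessors
#' @export
setMethod("accessions", "AbstractOntology", function(x, ...) x@terms$accession)

#' @rdname ontology-accessors
#' @export
setMethod("terms", "AbstractOntology", function(x, ...) x@terms)

#' @rdname ontology-accessors
#' @export
setMethod("relations", "AbstractOntology", function(x, ...) x@relations)

#' @rdname ontology-accessors
#' @export
setMethod("synonyms", "AbstractOntology", function(x, ...) x@synonyms)

#' @rdname ontology-accessors
#' @export
setMethod("stageDomain", "AbstractOntology", function(x) x@stageDomain)

#' @rdname ontology-accessors
#' @export
setMethod("ontologyRoot", "AbstractOntology", function(x) {
  roots <- .rootsOf(x)
  if (length(roots) != 1)
    stop("ontology does not have a unique root (found ", length(roots), ")",
         call. = FALSE)
  roots
})

#' @rdname ontology-accessors
#' @export
setMethod("term", "AbstractOntology", function(x, accession) {
  .checkKnown(x, accession)
  row <- x@terms[x@terms$accession == accession, ]
  rel <- x@relations[x@relations$from == accession, c("type", "to")]
  rownames(rel) <- NULL
  syn <- x@synonyms[x@synonyms$accession == accession,
                    c("synonym", "scope"), drop = FALSE]
  rownames(syn) <- NULL
  new("AbstractTerm", accession = accession, name = row$name,
      stageRange = c(row$start, row$end), synonyms = syn,
      relations = rel, obsolete = row$obsolete)
})

#' @rdname ontology-accessors
#' @export
setMethod("stageRange", "AbstractOntology", function(x, accession) {
  .checkKnown(x, accession)
  row <- x@terms[x@terms$accession == accession, ]
  c(row$start, row$end)
})

#' @rdname ontology-accessors
#' @export
setMethod("accessions", "TimedOntology", function(x, ...) x@terms$accession)

#' @rdname ontology-accessors
#' @export
setMethod("terms", "TimedOntology", function(x, ...) x@terms)

#' @rdname ontology-accessors
#' @export
setMethod("stage", "TimedOntology", function(x) x@stage)

#' @rdname ontology-accessors
#' @export
setMethod("edges", "TimedOntology", function(x) x@edges)

#' @describeIn ValidationReport-class the findings data frame.
#' @param x a `ValidationReport`.
#' @export
setMethod("findings", "ValidationReport", function(x) x@findings)

#' @describeIn ValidationReport-class `TRUE` if any ERROR-level finding.
#' @export
setMethod("hasErrors", "ValidationReport", function(x)
  any(x@findings$severity == "ERROR"))

#' @describeIn MappingTable-class the (timed, abstract, stage) rows.
#' @param x a `MappingTable`.
#' @export
setMethod("mappingRows", "MappingTable", function(x) x@rows)

#' @describeIn MappingTable-class timed accessions never to be reused.
#' @export
setMethod("retiredAccessions", "MappingTable", function(x) x@retired)

#' @describeIn MappingTable-class the fresh-allocation counter.
#' @export
setMethod("nextLocalId", "MappingTable", function(x) x@nextLocalId)

## ---- core operations ----------------------------------------------------

#' Parents of a term that are present at a given stage
#'
#' Returns the hierarchy parents (`part_of` and `is_a` targets, in
#' relation order) whose own stage range contains `stage`.
#' `develops_from` targets are never returned, and obsolete parents are
#' skipped. With multiple parentage a structure such as brain can be part
#' of both head and the central nervous system at once.
#'
#' @param x an [AbstractOntology-class].
#' @param accession the child term's accession.
#' @param stage integer stage within the ontology's stage domain.
#' @return data frame with columns `type` and `accession`.
#' @export
setMethod("parentsAt", "AbstractOntology", function(x, accession, stage) {
  .checkKnown(x, accession)
  stage <- as.integer(stage)
  dom <- x@stageDomain
  if (stage < dom[1] || stage > dom[2])
    stop("stage ", stage, " outside stage domain [", dom[1], ", ", dom[2], "]",
         call. = FALSE)
  rel <- x@relations[x@relations$from == accession &
                       x@relations$type %in% .HIERARCHY_TYPES, , drop = FALSE]
  if (!nrow(rel))
    return(data.frame(type = character(), accession = character(),
                      stringsAsFactors = FALSE))
  idx <- match(rel$to, x@terms$accession)
  ok <- !x@terms$obsolete[idx] &
    x@terms$start[idx] <= stage & x@terms$end[idx] >= stage
  out <- data.frame(type = rel$type[ok], accession = rel$to[ok],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
})

#' Every stage at which a term is present
#'
#' The stage range is a closed, contiguous interval: a term present first
#' at stage `start` and last at stage `end` is present at every stage in
#' between. Discontinuous presence cannot be represented by one term.
#'
#' @param x an [AbstractOntology-class].
#' @param accession term accession.
#' @return integer vector `start:end`.
#' @export
setMethod("termStages", "AbstractOntology", function(x, accession) {
  r <- stageRange(x, accession)
  seq.int(r[1], r[2])
})

## ---- comparison ---------------------------------------------------------

#' Compare two abstract ontologies for semantic identity
#'
#' Order-insensitive equality on terms (accession, name, stage range,
#' obsolete flag), hierarchy edges, and optionally synonyms. Used by the
#' round-trip properties (serialization may normalize ordering).
#'
#' @param a,b [AbstractOntology-class] objects.
#' @param checkSynonyms compare synonym sets too (default `TRUE`).
#' @param hierarchyOnly compare only `part_of`/`is_a` edges (default
#'   `FALSE`: all typed edges compared).
#' @return `TRUE` or `FALSE`.
#' @export
ontologyIdentical <- function(a, b, checkSynonyms = TRUE, hierarchyOnly = FALSE) {
  keyTerms <- function(x) {
    t <- x@terms
    sort(paste(t$accession, t$name, t$start, t$end, t$obsolete, sep = "\r"))
  }
  keyEdges <- function(x) {
    r <- x@relations
    if (hierarchyOnly) r <- r[r$type %in% .HIERARCHY_TYPES, , drop = FALSE]
    sort(paste(r$from, r$type, r$to, sep = "\r"))
  }
  keySyn <- function(x) {
    s <- x@synonyms
    sort(paste(s$accession, s$synonym, s$scope, sep = "\r"))
  }
  identical(keyTerms(a), keyTerms(b)) &&
    identical(keyEdges(a), keyEdges(b)) &&
    identical(a@stageDomain, b@stageDomain) &&
    (!checkSynonyms || identical(keySyn(a), keySyn(b)))
}

## ---- show methods -------------------------------------------------------

setMethod("show", "AbstractOntology", function(object) {
  n <- nrow(object@terms)
  live <- sum(!object@terms$obsolete)
  cat("AbstractOntology (", object@prefix, "): ", n, " terms (",
      live, " current), ", nrow(object@relations), " relations, stages ",
      object@stageDomain[1], "..", object@stageDomain[2], "\n", sep = "")
})

setMethod("show", "TimedOntology", function(object) {
  cat("TimedOntology at TS", sprintf("%02d", object@stage), ": ",
      nrow(object@terms), " terms, ", nrow(object@edges), " edges\n",
      sep = "")
})

setMethod("show", "MappingTable", function(object) {
  cat("MappingTable: ", nrow(object@rows), " rows, ",
      length(object@retired), " retired, next local id ",
      object@nextLocalId, "\n", sep = "")
})

setMethod("show", "ValidationReport", function(object) {
  f <- object@findings
  cat("ValidationReport: ", sum(f$severity == "ERROR"), " error(s), ",
      sum(f$severity == "WARNING"), " warning(s)\n", sep = "")
  if (nrow(f)) print(utils::head(f, 10))
})

setMethod("show", "OboDocument", function(object) {
  cat("OboDocument: ", nrow(object@header), " header line(s), ",
      length(object@stanzas), " stanza(s)\n", sep = "")
})

setMethod("show", "DiffReport", function(object) {
  cat("DiffReport: ", length(object@added), " added, ",
      length(object@retired), " retired, ", nrow(object@renamed),
      " renamed, ", nrow(object@rangeChanged), " reranged, ",
      nrow(object@edgesAdded), "/", nrow(object@edgesRemoved),
      " edges added/removed\n", sep = "")
})

setMethod("show", "NamingReport", function(object) {
  cat("NamingReport: ", nrow(object@renames), " rename(s), ",
      nrow(object@residualCollisions), " residual collision(s)\n", sep = "")
})

setMethod("show", "AbstractTerm", function(object) {
  cat(object@accession, " '", object@name, "' TS",
      sprintf("%02d", object@stageRange[1]), "..TS",
      sprintf("%02d", object@stageRange[2]),
      if (object@obsolete) " (obsolete)" else "", "\n", sep = "")
})
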