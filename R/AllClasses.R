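#' @import methods
NULL

## Relation-type vocabulary. develops_from is modeled (parsed, serialized,
## diffed) but excluded from hierarchy traversal and coverage checks.
.REL_TYPES <- c("part_of", "is_a", "develops_from")
.HIERARCHY_TYPES <- c("part_of", "is_a")

#' Relation types understood by the toolkit
#'
#' @return Character vector of relation-type tokens. `part_of` and `is_a`
#'   form the hierarchy; `develops_from` is accepted by parsers and
#'   serializers but never traversed as a parent link.
#' @export
relationTypes <- function() .REL_TYPES

.emptyTerms <- function() {
  data.frame(accession = character(), name = character(),
             start = integer(), end = integer(), obsolete = logical(),
             stringsAsFactors = FALSE)
}

.emptyRelations <- function() {
  data.frame(from = character(), type = character(), to = character(),
             stringsAsFactors = FALSE)
}

.emptySynonyms <- function() {
  data.frame(accession = character(), synonym = character(),
             scope = character(), stringsAsFactors = FALSE)
}

.emptyFindings <- function() {
  data.frame(severity = character(), check = character(),
             accessions = character(), message = character(),
             stringsAsFactors = FALSE)
}

## Numeric local part of "<PREFIX>:<n>" accessions; used for canonical sorting.
.localPart <- function(acc) {
  suppressWarnings(as.integer(sub("^.*:", "", acc)))
}

## Locale-independent (byte order) string sort, for deterministic output.
.csort <- function(x) sort(x, method = "radix")

#' ValidationReport: machine-readable findings from consistency checks
#'
#' Holds a data frame of findings with columns `severity` (`"ERROR"` or
#' `"WARNING"`), `check` (the check name), `accessions` (comma-joined
#' subject accessions) and `message`. An empty report means the subject
#' passed every enabled check.
#'
#' @aliases ValidationReport
#' @export
setClass("ValidationReport",
         representation(findings = "data.frame"),
         prototype(findings = .emptyFindings()),
         validity = function(object) {
           need <- c("severity", "check", "accessions", "message")
           if (!all(need %in% names(object@findings)))
             return("findings must have columns severity, check, accessions, message")
           bad <- setdiff(object@findings$severity, c("ERROR", "WARNING"))
           if (length(bad)) return(paste("unknown severity:", bad[1]))
           TRUE
         })

#' @rdname ValidationReport-class
#' @param findings data frame of findings (see class description).
#' @export
validationReport <- function(findings = .emptyFindings()) {
  new("ValidationReport", findings = findings)
}

.finding <- function(severity, check, accessions, message) {
  data.frame(severity = severity, check = check,
             accessions = paste(accessions, collapse = ","),
             message = message, stringsAsFactors = FALSE)
}

.combineFindings <- function(...) {
  parts <- Filter(function(d) nrow(d) > 0, list(...))
  if (!length(parts)) return(.emptyFindings())
  do.call(rbind, parts)
}

#' AbstractOntology: a stage-independent anatomy ontology
#'
#' The abstract (EMAPA-style) side of the model: every anatomical entity is
#' one term annotated with the first and last developmental stage at which
#' it is considered present, and terms are connected by typed edges
#' (`part_of`, `is_a`, `develops_from`) forming a rooted DAG in which
#' multiple parents are allowed.
#'
#' Slots store the term table (`accession`, `name`, `start`, `end`,
#' `obsolete`), the relation table (`from`, `type`, `to`; row order is
#' meaningful — it is the relation order used for naming tie-breaks), the
#' synonym table (`accession`, `synonym`, `scope`), the inclusive stage
#' domain, the accession prefix and ordered OBO header metadata.
#'
#' Validity enforces structural well-formedness only (unique accessions,
#' resolvable relation targets, known relation types). Acyclicity, the
#' single-root property and stage-range sanity are checked post-hoc by the
#' validation functions ([checkAcyclic()], [checkStageConsistency()]), so
#' that deliberately defective ontologies can be constructed for testing
#' the validators.
#'
#' @aliases AbstractOntology
#' @export
setClass("AbstractOntology",
         representation(terms = "data.frame",
                        relations = "data.frame",
                        synonyms = "data.frame",
                        stageDomain = "integer",
                        prefix = "character",
                        metadata = "character",
                        loadReport = "ValidationReport"),
         prototype(terms = .emptyTerms(),
                   relations = .emptyRelations(),
                   synonyms = .emptySynonyms(),
                   stageDomain = c(1L, 28L),
                   prefix = "EMAPA",
                   metadata = character(),
                   loadReport = new("ValidationReport")),
         validity = function(object) {
           tm <- object@terms
           if (!all(c("accession", "name", "start", "end", "obsolete") %in% names(tm)))
             return("terms must have columns accession, name, start, end, obsolete")
           if (anyDuplicated(tm$accession))
             return(paste("duplicate accession:",
                          tm$accession[duplicated(tm$accession)][1]))
           rel <- object@relations
           if (!all(c("from", "type", "to") %in% names(rel)))
             return("relations must have columns from, type, to")
           if (length(bad <- setdiff(rel$type, .REL_TYPES)))
             return(paste("unknown relation type:", bad[1]))
           unresolved <- setdiff(c(rel$from, rel$to), tm$accession)
           if (length(unresolved))
             return(paste("relation endpoint not in ontology:", unresolved[1]))
           if (length(object@stageDomain) != 2 ||
               object@stageDomain[1] > object@stageDomain[2])
             return("stageDomain must be c(min, max) with min <= max")
           TRUE
         })

#' Construct an AbstractOntology
#'
#' @param terms data frame with columns `accession`, `name`, `start`,
#'   `end` and optionally `obsolete` (default `FALSE`).
#' @param relations data frame with columns `from`, `type`, `to`; `type`
#'   one of [relationTypes()]. Row order is preserved.
#' @param synonyms data frame with columns `accession`, `synonym`, `scope`.
#' @param stageDomain inclusive integer stage domain, default `c(1, 28)`
#'   (Theiler stages); configurable so the toolkit is not mouse-specific.
#' @param prefix accession prefix for the abstract namespace.
#' @param metadata named character vector of OBO header tag/value pairs.
#' @return An [AbstractOntology-class] object.
#' @examples
#' onto <- abstractOntology(
#'   terms = data.frame(accession = c("EMAPA:1", "EMAPA:2"),
#'                      name = c("mouse", "head"),
#'                      start = c(1L, 10L), end = c(28L, 28L)),
#'   relations = data.frame(from = "EMAPA:2", type = "part_of", to = "EMAPA:1"))
#' onto
#' @export
abstractOntology <- function(terms = .emptyTerms(),
                             relations = .emptyRelations(),
                             synonyms = .emptySynonyms(),
                             stageDomain = c(1L, 28L),
                             prefix = "EMAPA",
                             metadata = character()) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  if (!nrow(terms) && !ncol(terms)) terms <- .emptyTerms()
  if (is.null(terms$obsolete)) terms$obsolete <- rep(FALSE, nrow(terms))
  terms$accession <- as.character(terms$accession)
  terms$name <- as.character(terms$name)
  terms$start <- as.integer(terms$start)
  terms$end <- as.integer(terms$end)
  terms$obsolete <- as.logical(terms$obsolete)
  rownames(terms) <- NULL
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  if (!nrow(relations)) relations <- .emptyRelations()
  relations$from <- as.character(relations$from)
  relations$type <- as.character(relations$type)
  relations$to <- as.character(relations$to)
  rownames(relations) <- NULL
  synonyms <- as.data.frame(synonyms, stringsAsFactors = FALSE)
  if (!nrow(synonyms)) synonyms <- .emptySynonyms()
  if (is.null(synonyms$scope)) synonyms$scope <- rep("RELATED", nrow(synonyms))
  rownames(synonyms) <- NULL
  new("AbstractOntology", terms = terms, relations = relations,
      synonyms = synonyms, stageDomain = as.integer(stageDomain),
      prefix = prefix, metadata = metadata)
}

#' AbstractTerm: one stage-independent anatomical entity
#'
#' A convenience view of a single row of an [AbstractOntology-class],
#' materialized on demand by [term()].
#'
#' @aliases AbstractTerm
#' @export
setClass("AbstractTerm",
         representation(accession = "character", name = "character",
                        stageRange = "integer", synonyms = "data.frame",
                        relations = "data.frame", obsolete = "logical"))

#' TimedOntology: the per-stage instantiation
#'
#' The timed (EMAP-style) side of the model: the subgraph of anatomical
#' entities present at one developmental stage, each instance bearing its
#' own timed accession. `terms` has columns `accession` (timed),
#' `abstract` (the abstract accession it instantiates) and `name`;
#' `edges` has columns `from`, `type`, `to` over timed accessions.
#'
#' @aliases TimedOntology
#' @export
setClass("TimedOntology",
         representation(stage = "integer", terms = "data.frame",
                        edges = "data.frame", prefix = "character",
                        report = "ValidationReport"),
         prototype(stage = 1L,
                   terms = data.frame(accession = character(),
                                      abstract = character(),
                                      name = character(),
                                      stringsAsFactors = FALSE),
                   edges = .emptyRelations(), prefix = "EMAP",
                   report = new("ValidationReport")),
         validity = function(object) {
           if (length(object@stage) != 1) return("stage must be a single integer")
           tm <- object@terms
           if (!all(c("accession", "abstract", "name") %in% names(tm)))
             return("terms must have columns accession, abstract, name")
           if (anyDuplicated(tm$accession))
             return("duplicate timed accession")
           ed <- object@edges
           unresolved <- setdiff(c(ed$from, ed$to), tm$accession)
           if (length(unresolved))
             return(paste("edge endpoint not instantiated:", unresolved[1]))
           TRUE
         })

#' MappingTable: persistent timed-to-abstract identifier mapping
#'
#' One row per instantiated (abstract accession, stage) pair, giving the
#' timed accession permanently assigned to it. `nextLocalId` is the
#' allocation counter for fresh timed accessions and `retired` the set of
#' timed accessions that must never be reused.
#'
#' @aliases MappingTable
#' @export
setClass("MappingTable",
         representation(rows = "data.frame", nextLocalId = "integer",
                        retired = "character"),
         prototype(rows = data.frame(timed = character(),
                                     abstract = character(),
                                     stage = integer(),
                                     stringsAsFactors = FALSE),
                   nextLocalId = 1L, retired = character()),
         validity = function(object) {
           r <- object@rows
           if (!all(c("timed", "abstract", "stage") %in% names(r)))
             return("rows must have columns timed, abstract, stage")
           if (anyDuplicated(r$timed)) return("duplicate timed accession in mapping")
           if (anyDuplicated(paste(r$abstract, r$stage)))
             return("duplicate (abstract, stage) pair in mapping")
           if (length(intersect(r$timed, object@retired)))
             return("mapping row uses a retired timed accession")
           TRUE
         })

#' @rdname MappingTable-class
#' @param rows data frame with columns `timed`, `abstract`, `stage`.
#' @param nextLocalId integer allocation counter; defaults to one past the
#'   largest local id seen in `rows` or `retired`.
#' @param retired character vector of timed accessions never to reuse.
#' @export
mappingTable <- function(rows = NULL, nextLocalId = NULL, retired = character()) {
  if (is.null(rows))
    rows <- data.frame(timed = character(), abstract = character(),
                       stage = integer(), stringsAsFactors = FALSE)
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  rows$timed <- as.character(rows$timed)
  rows$abstract <- as.character(rows$abstract)
  rows$stage <- as.integer(rows$stage)
  rownames(rows) <- NULL
  if (is.null(nextLocalId)) {
    used <- c(.localPart(rows$timed), .localPart(retired))
    nextLocalId <- if (length(used)) max(used, na.rm = TRUE) + 1L else 1L
  }
  new("MappingTable", rows = rows, nextLocalId = as.integer(nextLocalId),
      retired = as.character(retired))
}

#' OboDocument: lossless representation of an OBO flat file
#'
#' `header` is an ordered data frame of (tag, value) pairs; `stanzas` an
#' ordered list, each element a list with `type` (e.g. `"Term"`) and
#' `tags` (ordered data frame of tag/value pairs). Unrecognized tags are
#' preserved verbatim so that write(parse(text)) is byte-identical for
#' canonically formatted input.
#'
#' @aliases OboDocument
#' @export
setClass("OboDocument",
         representation(header = "data.frame", stanzas = "list"),
         prototype(header = data.frame(tag = character(), value = character(),
                                       stringsAsFactors = FALSE),
                   stanzas = list()))

#' DiffReport: categorized changes between two ontology versions
#'
#' @aliases DiffReport
#' @export
setClass("DiffReport",
         representation(added = "character", retired = "character",
                        renamed = "data.frame", rangeChanged = "data.frame",
                        edgesAdded = "data.frame", edgesRemoved = "data.frame",
                        findings = "data.frame"))

#' NamingReport: record of compound-name disambiguation
#'
#' `renames` has columns `accession`, `old`, `new`, `ancestor` (the
#' disambiguating ancestor's accession); `residualCollisions` has columns
#' `name`, `accessions` (comma-joined holders still ambiguous).
#'
#' @aliases NamingReport
#' @export
setClass("NamingReport",
         representation(renames = "data.frame", residualCollisions = "data.frame"))

#' InstantiationResult: output of instantiating every stage
#'
#' @aliases InstantiationResult
#' @export
setClass("InstantiationResult",
         representation(timed = "list", mapping = "MappingTable",
                        report = "ValidationReport"))

#' OntologyConfig: run configuration shared by I/O, staging and the CLI
#'
#' @aliases OntologyConfig
#' @export
setClass("OntologyConfig",
         representation(stageDomain = "integer", abstractPrefix = "character",
                        timedPrefix = "character", dialect = "character",
                        strict = "logical", includeIsa = "logical"),
         validity = function(object) {
           if (!object@dialect %in% c("relationship", "property_value"))
             return("dialect must be 'relationship' or 'property_value'")
           TRUE
         })

#' @rdname OntologyConfig-class
#' @param stageDomain inclusive integer stage domain.
#' @param abstractPrefix,timedPrefix accession prefixes for the abstract and
#'   timed namespaces.
#' @param dialect stage-annotation dialect used when writing OBO:
#'   `"relationship"` (`relationship: starts_at TS12`) or
#'   `"property_value"` (`property_value: starts_at "12"`). Both dialects
#'   always parse.
#' @param strict when `TRUE`, conditions that are warnings in permissive
#'   mode (missing stage annotations, orphans-at-stage, non-contiguous
#'   occurrence) become errors.
#' @param includeIsa include `is_a` edges in instantiated per-stage graphs
#'   (default `TRUE`); `FALSE` restricts timed graphs to the partonomy.
#' @export
ontologyConfig <- function(stageDomain = c(1L, 28L), abstractPrefix = "EMAPA",
                           timedPrefix = "EMAP", dialect = "relationship",
                           strict = FALSE, includeIsa = TRUE) {
  new("OntologyConfig", stageDomain = as.integer(stageDomain),
      abstractPrefix = abstractPrefix, timedPrefix = timedPrefix,
      dialect = dialect, strict = strict, includeIsa = includeIsa)
}

#' FixtureSpec: parameters for the synthetic-ontology generator
#'
#' @aliases FixtureSpec
#' @export
setClass("FixtureSpec",
         representation(seed = "integer", nTerms = "integer",
                        maxDepth = "integer", multiParentFraction = "numeric",
                        isaFraction = "numeric",
                        duplicateLabelFraction = "numeric",
                        stageDomain = "integer", rangeMeanLength = "numeric",
                        defects = "list"),
         validity = function(object) {
           if (object@nTerms < 1) return("nTerms must be >= 1")
           if (object@maxDepth < 1) return("maxDepth must be >= 1")
           for (p in c(object@multiParentFraction, object@isaFraction,
                       object@duplicateLabelFraction))
             if (p < 0 || p > 1) return("fractions must lie in [0, 1]")
           TRUE
         })

#' @rdname FixtureSpec-class
#' @param seed integer seed; the same spec always generates byte-identical
#'   output.
#' @param nTerms number of terms including the root.
#' @param maxDepth maximum hierarchy depth.
#' @param multiParentFraction fraction of non-root terms receiving a second
#'   parent.
#' @param isaFraction fraction of primary child-parent edges typed `is_a`
#'   rather than `part_of`.
#' @param duplicateLabelFraction fraction of non-root terms deliberately
#'   reusing an existing label (to exercise naming disambiguation).
#' @param stageDomain inclusive stage domain.
#' @param rangeMeanLength mean of the geometric stage-range length model;
#'   defaults to a quarter of the stage-domain span.
#' @param defects list of defect descriptors, each
#'   `list(kind = <"cycle"|"inverted_range"|"duplicate_name"|"orphan"|"stale_mapping">, count = n)`.
#' @export
fixtureSpec <- function(seed = 1L, nTerms = 30L, maxDepth = 6L,
                        multiParentFraction = 0.15, isaFraction = 0.15,
                        duplicateLabelFraction = 0.1,
                        stageDomain = c(1L, 28L),
                        rangeMeanLength = NULL, defects = list()) {
  stageDomain <- as.integer(stageDomain)
  if (is.null(rangeMeanLength))
    rangeMeanLength <- max(1, (stageDomain[2] - stageDomain[1] + 1) / 4)
  new("FixtureSpec", seed = as.integer(seed), nTerms = as.integer(nTerms),
      maxDepth = as.integer(maxDepth),
      multiParentFraction = multiParentFraction, isaFraction = isaFraction,
      duplicateLabelFraction = duplicateLabelFraction,
      stageDomain = stageDomain, rangeMeanLength = rangeMeanLength,
      defects = defects)
}
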