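#' @include staging.R
NULL

## Disambiguating-ancestor candidates for one term: breadth-first over
## part_of edges, nearest first. Depth-1 parents keep relation order;
## deeper levels are ordered by (current) ancestor name, lexicographic.
## Every candidate is a single ancestor, never a multi-segment path.
.ancestorCandidates <- function(relations, nameOf, obsoleteOf, accession) {
  partOf <- relations[relations$type == "part_of", , drop = FALSE]
  seen <- accession
  frontier <- partOf$to[partOf$from == accession]
  frontier <- frontier[!obsoleteOf[frontier]]
  out <- character()
  first <- TRUE
  while (length(frontier)) {
    frontier <- setdiff(frontier, seen)
    if (!first)
      frontier <- frontier[order(nameOf[frontier], method = "radix")]
    out <- c(out, frontier)
    seen <- c(seen, frontier)
    nxt <- unique(partOf$to[partOf$from %in% frontier])
    frontier <- nxt[!obsoleteOf[nxt]]
    first <- FALSE
  }
  out
}

#' Short unambiguous display label for a term at a stage
#'
#' Print names pair the zero-padded stage token with the term's (post-
#' disambiguation) unique name, separated by a semicolon with no spaces:
#' `"TS14;midgut epithelium"`. They replace both the ambiguous bare label
#' and the unwieldy full path name in user interfaces.
#'
#' @param x an [AbstractOntology-class].
#' @param accession term accession.
#' @param stage integer stage; must lie within the term's stage range.
#' @return A single string.
#' @export
setMethod("printName", "AbstractOntology", function(x, accession, stage) {
  r <- stageRange(x, accession)
  stage <- as.integer(stage)
  if (stage < r[1] || stage > r[2])
    stop(accession, " is not present at stage ", stage,
         " (range ", r[1], "..", r[2], ")", call. = FALSE)
  sprintf("TS%02d;%s", stage, x@terms$name[x@terms$accession == accession])
})

#' Make term names unique by compound-name construction
#'
#' Evaluates every non-obsolete term name for uniqueness. Each term whose
#' label collides with another's is renamed
#' `"<disambiguating ancestor name> <original name>"` — e.g. an
#' "epithelium" that is part of "midgut" becomes "midgut epithelium" —
#' using the nearest `part_of` ancestor (breadth-first; depth-1 parents in
#' relation order, deeper ties broken by lexicographically smallest
#' ancestor name) whose prefix yields a name not already in use. The
#' original short label is retained as a RELATED synonym. The process
#' iterates until no further rename is possible; names still duplicated
#' then (e.g. same label under an identically named parent) are reported
#' as residual collisions rather than forced apart with multi-segment
#' path prefixes.
#'
#' Renaming never alters accessions, stage ranges or graph topology, and
#' the operation is idempotent.
#'
#' @param x an [AbstractOntology-class].
#' @param ... unused.
#' @return A list with elements `ontology` (the renamed
#'   [AbstractOntology-class]) and `report` (a [NamingReport-class]).
#' @export
setMethod("uniquifyNames", "AbstractOntology", function(x, ...) {
  terms <- x@terms
  syn <- x@synonyms
  renames <- data.frame(accession = character(), old = character(),
                        new = character(), ancestor = character(),
                        stringsAsFactors = FALSE)
  renamedOnce <- character()
  obsoleteOf <- stats::setNames(terms$obsolete, terms$accession)
  for (iter in seq_len(25L)) {
    live <- !terms$obsolete
    liveNames <- terms$name[live]
    dup <- unique(liveNames[duplicated(liveNames)])
    if (!length(dup)) break
    progress <- FALSE
    reserved <- character()
    for (d in .csort(dup)) {
      holders <- terms$accession[live & terms$name == d]
      holders <- holders[order(.localPart(holders))]
      ## holders whose full part_of-ancestor name multisets coincide are
      ## structurally indistinguishable: no single-ancestor prefix can
      ## separate them, so they stay for the residual report
      nameOf <- stats::setNames(terms$name, terms$accession)
      sig <- vapply(holders, function(h) paste(
        .csort(nameOf[.ancestorCandidates(x@relations, nameOf,
                                          obsoleteOf, h)]),
        collapse = "\r"), character(1))
      ambiguous <- holders[sig %in% sig[duplicated(sig)]]
      for (h in setdiff(holders, ambiguous)) {
        if (h %in% renamedOnce) next
        nameOf <- stats::setNames(terms$name, terms$accession)
        anc <- .ancestorCandidates(x@relations, nameOf, obsoleteOf, h)
        for (a in anc) {
          candidate <- paste(nameOf[[a]], d)
          if (candidate %in% terms$name[live] || candidate %in% reserved)
            next
          terms$name[terms$accession == h] <- candidate
          syn <- rbind(syn, data.frame(accession = h, synonym = d,
                                       scope = "RELATED",
                                       stringsAsFactors = FALSE))
          renames <- rbind(renames, data.frame(
            accession = h, old = d, new = candidate, ancestor = a,
            stringsAsFactors = FALSE))
          renamedOnce <- c(renamedOnce, h)
          reserved <- c(reserved, candidate)
          progress <- TRUE
          break
        }
        ## refresh live-name view so later holders see this rename
        live <- !terms$obsolete
      }
    }
    if (!progress) break
  }
  live <- !terms$obsolete
  liveNames <- terms$name[live]
  dup <- unique(liveNames[duplicated(liveNames)])
  residual <- data.frame(name = character(), accessions = character(),
                         stringsAsFactors = FALSE)
  for (d in .csort(dup)) {
    holders <- terms$accession[live & terms$name == d]
    residual <- rbind(residual, data.frame(
      name = d, accessions = paste(holders[order(.localPart(holders))],
                                   collapse = ","),
      stringsAsFactors = FALSE))
  }
  out <- x
  out@terms <- terms
  out@synonyms <- syn
  validObject(out)
  list(ontology = out,
       report = new("NamingReport", renames = renames,
                    residualCollisions = residual))
})
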