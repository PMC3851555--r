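#' @include naming.R
NULL

.cycleFindings <- function(edges, checkName, severity) {
  find <- .emptyFindings()
  if (!nrow(edges)) return(find)
  selfLoop <- edges$from == edges$to
  for (a in unique(edges$from[selfLoop]))
    find <- rbind(find, .finding(severity, checkName, a,
                                 paste0("cycle: ", a, " -> ", a)))
  edges <- edges[!selfLoop, , drop = FALSE]
  if (!nrow(edges)) return(find)
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = TRUE)
  comp <- igraph::components(g, mode = "strong")
  for (ci in which(comp$csize > 1)) {
    vs <- names(comp$membership)[comp$membership == ci]
    sg <- igraph::induced_subgraph(g, vs)
    v <- igraph::V(sg)[1]
    succ <- igraph::neighbors(sg, v, mode = "out")[1]
    path <- igraph::shortest_paths(sg, from = succ, to = v,
                                   mode = "out")$vpath[[1]]
    witness <- c(igraph::V(sg)$name[v], names(path))
    find <- rbind(find, .finding(
      severity, checkName, .csort(vs),
      paste0("cycle: ", paste(witness, collapse = " -> "), " -> ",
             igraph::V(sg)$name[v])))
  }
  find
}

#' Check that the ontology graph is acyclic
#'
#' The hierarchy over `part_of`/`is_a` edges must be a DAG — multiple
#' parents are allowed (brain part-of head and part-of central nervous
#' system is fine), cycles are not. One ERROR finding is emitted per
#' strongly connected component, with one witness cycle each (not all
#' cycles, which can be combinatorially many). `develops_from` edges are
#' checked separately and cycles there are WARNINGs, since that relation
#' is modeled but not traversed.
#'
#' @param x an [AbstractOntology-class].
#' @return A [ValidationReport-class].
#' @export
setMethod("checkAcyclic", "AbstractOntology", function(x) {
  live <- x@terms$accession[!x@terms$obsolete]
  rel <- x@relations[x@relations$from %in% live & x@relations$to %in% live,
                     , drop = FALSE]
  hier <- rel[rel$type %in% .HIERARCHY_TYPES, , drop = FALSE]
  dev <- rel[rel$type == "develops_from", , drop = FALSE]
  validationReport(.combineFindings(
    .cycleFindings(hier, "acyclic", "ERROR"),
    .cycleFindings(dev, "acyclic_develops_from", "WARNING")))
})

#' Check stage-range sanity and per-stage parent coverage
#'
#' Emits an ERROR for every term whose range is inverted (`start > end`)
#' or exceeds the stage domain, and an `orphan_at_stage` WARNING for
#' every (term, stage) at which a non-root term is present but none of
#' its `part_of`/`is_a` parents is — e.g. a child spanning stages 10–16
#' under a sole parent spanning 12–14 is orphaned at 10, 11, 15 and 16.
#' Both relation types count equally as coverage. Orphans are warnings,
#' not errors, so that legacy files predating the constraint still load.
#'
#' @param x an [AbstractOntology-class].
#' @return A [ValidationReport-class].
#' @export
setMethod("checkStageConsistency", "AbstractOntology", function(x) {
  find <- .emptyFindings()
  tm <- x@terms[!x@terms$obsolete, , drop = FALSE]
  dom <- x@stageDomain
  for (i in seq_len(nrow(tm))) {
    if (tm$start[i] > tm$end[i])
      find <- rbind(find, .finding(
        "ERROR", "inverted_range", tm$accession[i],
        paste0("stage range [", tm$start[i], ", ", tm$end[i],
               "] has start > end")))
    else if (tm$start[i] < dom[1] || tm$end[i] > dom[2])
      find <- rbind(find, .finding(
        "ERROR", "range_outside_domain", tm$accession[i],
        paste0("stage range [", tm$start[i], ", ", tm$end[i],
               "] exceeds stage domain [", dom[1], ", ", dom[2], "]")))
  }
  rel <- .hierarchyEdges(x)
  roots <- setdiff(tm$accession, rel$from)
  idxOf <- match(rel$to, tm$accession)
  for (i in seq_len(nrow(tm))) {
    acc <- tm$accession[i]
    if (acc %in% roots || tm$start[i] > tm$end[i]) next
    stages <- seq.int(max(tm$start[i], dom[1]), min(tm$end[i], dom[2]))
    pidx <- idxOf[rel$from == acc]
    covered <- rep(FALSE, length(stages))
    for (p in pidx)
      covered <- covered | (stages >= tm$start[p] & stages <= tm$end[p])
    for (s in stages[!covered])
      find <- rbind(find, .finding(
        "WARNING", "orphan_at_stage", acc,
        paste0(acc, " present at stage ", s, " with no parent present")))
  }
  validationReport(find)
})

#' Check term-name uniqueness
#'
#' One WARNING per duplicated non-obsolete name, listing every holder.
#' Duplicates are what compound-name construction ([uniquifyNames()])
#' exists to resolve.
#'
#' @param x an [AbstractOntology-class].
#' @return A [ValidationReport-class].
#' @export
setMethod("checkNamesUnique", "AbstractOntology", function(x) {
  find <- .emptyFindings()
  tm <- x@terms[!x@terms$obsolete, , drop = FALSE]
  dup <- unique(tm$name[duplicated(tm$name)])
  for (d in .csort(dup)) {
    holders <- tm$accession[tm$name == d]
    find <- rbind(find, .finding(
      "WARNING", "names_unique", holders[order(.localPart(holders))],
      paste0("name '", d, "' is shared by ", length(holders), " terms")))
  }
  validationReport(find)
})

#' Check a mapping table against the current ontology
#'
#' Persistent identifiers must stay consistent with the ontology they
#' index: an ERROR is emitted for every mapping row whose abstract
#' accession is unknown, for every row whose stage falls outside the
#' mapped term's current stage range, and for every instantiable
#' (term, stage) pair that has no row.
#'
#' @param x an [AbstractOntology-class].
#' @param mapping a [MappingTable-class].
#' @return A [ValidationReport-class].
#' @export
setMethod("checkMapping", "AbstractOntology", function(x, mapping) {
  find <- .emptyFindings()
  r <- mapping@rows
  tm <- x@terms
  idx <- match(r$abstract, tm$accession)
  for (i in seq_len(nrow(r))) {
    if (is.na(idx[i])) {
      find <- rbind(find, .finding(
        "ERROR", "mapping_unknown_abstract", r$timed[i],
        paste0(r$timed[i], " maps to unknown abstract accession ",
               r$abstract[i])))
    } else if (r$stage[i] < tm$start[idx[i]] || r$stage[i] > tm$end[idx[i]] ||
               tm$obsolete[idx[i]]) {
      find <- rbind(find, .finding(
        "ERROR", "mapping_stale_stage", r$timed[i],
        paste0(r$timed[i], " maps ", r$abstract[i], " at stage ", r$stage[i],
               " which is outside its current range")))
    }
  }
  pairs <- .instantiationPairs(x)
  have <- paste(r$abstract, r$stage)
  missing <- !(paste(pairs$abstract, pairs$stage) %in% have)
  for (i in which(missing))
    find <- rbind(find, .finding(
      "ERROR", "mapping_missing_row", pairs$abstract[i],
      paste0("no mapping row for ", pairs$abstract[i], " at stage ",
             pairs$stage[i])))
  validationReport(find)
})

#' Run the full validation suite
#'
#' Combines the acyclicity, single-root, stage-consistency and
#' name-uniqueness checks (plus the mapping check when a mapping is
#' given) into one report. Under `strict`, `orphan_at_stage` warnings are
#' promoted to errors.
#'
#' @param x an [AbstractOntology-class].
#' @param mapping optional [MappingTable-class].
#' @param strict promote orphan-at-stage warnings to errors.
#' @param ... unused.
#' @return A [ValidationReport-class].
#' @export
setMethod("validateOntology", "AbstractOntology",
          function(x, mapping = NULL, strict = FALSE, ...) {
  roots <- .rootsOf(x)
  rootFind <- if (length(roots) != 1 && nrow(x@terms))
    .finding("ERROR", "single_root", .csort(roots),
             paste0("expected exactly one root, found ", length(roots)))
  else .emptyFindings()
  find <- .combineFindings(
    checkAcyclic(x)@findings,
    rootFind,
    checkStageConsistency(x)@findings,
    checkNamesUnique(x)@findings,
    if (!is.null(mapping)) checkMapping(x, mapping)@findings
    else .emptyFindings())
  if (strict && nrow(find))
    find$severity[find$check == "orphan_at_stage"] <- "ERROR"
  validationReport(find)
})

## ---- version diffing ----------------------------------------------------

#' Categorized difference between two ontology versions
#'
#' Classifies every change between `old` and `new`: added and retired
#' accessions, renames, stage-range changes, and edges added or removed.
#' An ERROR-level finding flags suspected identifier reuse: an accession
#' present in both versions whose name changed while none of its old
#' labels (name or synonyms) survives — a heuristic, since there is no
#' formal identity criterion across versions, and documented as such in
#' the finding message.
#'
#' @param old,new [AbstractOntology-class] versions sharing one accession
#'   namespace.
#' @return A [DiffReport-class].
#' @export
setMethod("diffVersions", signature("AbstractOntology", "AbstractOntology"),
          function(old, new) {
  ot <- old@terms; nt <- new@terms
  byLocal <- function(a) a[order(.localPart(a))]
  added <- byLocal(setdiff(nt$accession, ot$accession))
  retired <- byLocal(setdiff(ot$accession, nt$accession))
  common <- byLocal(intersect(ot$accession, nt$accession))
  oi <- match(common, ot$accession); ni <- match(common, nt$accession)
  ren <- ot$name[oi] != nt$name[ni]
  renamed <- data.frame(accession = common[ren], old = ot$name[oi][ren],
                        new = nt$name[ni][ren], stringsAsFactors = FALSE)
  rch <- ot$start[oi] != nt$start[ni] | ot$end[oi] != nt$end[ni]
  rangeChanged <- data.frame(
    accession = common[rch],
    oldStart = ot$start[oi][rch], oldEnd = ot$end[oi][rch],
    newStart = nt$start[ni][rch], newEnd = nt$end[ni][rch],
    stringsAsFactors = FALSE)
  ekey <- function(r) paste(r$from, r$type, r$to)
  eo <- old@relations; en <- new@relations
  edgesAdded <- en[!(ekey(en) %in% ekey(eo)), , drop = FALSE]
  edgesRemoved <- eo[!(ekey(eo) %in% ekey(en)), , drop = FALSE]
  rownames(edgesAdded) <- NULL; rownames(edgesRemoved) <- NULL
  find <- .emptyFindings()
  labelsOf <- function(x, acc) {
    c(x@terms$name[x@terms$accession == acc],
      x@synonyms$synonym[x@synonyms$accession == acc])
  }
  for (acc in renamed$accession) {
    if (!length(intersect(labelsOf(old, acc), labelsOf(new, acc))))
      find <- rbind(find, .finding(
        "ERROR", "id_reuse_suspected", acc,
        paste0(acc, " changed name and retains none of its old labels; ",
               "possible identifier reuse (heuristic check)")))
  }
  new("DiffReport", added = added, retired = retired, renamed = renamed,
      rangeChanged = rangeChanged, edgesAdded = edgesAdded,
      edgesRemoved = edgesRemoved, findings = find)
})

#' Write a validation or diff report as TSV
#'
#' Columns: severity, check, accessions (comma-joined), message.
#'
#' @param report a [ValidationReport-class].
#' @param path output path.
#' @export
writeReport <- function(report, path) {
  f <- report@findings
  lines <- c("severity\tcheck\taccessions\tmessage",
             if (nrow(f)) paste(f$severity, f$check, f$accessions, f$message,
                                sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
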