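# Hand-built fixtures and independent brute-force oracles shared by the
# unit and acceptance tests. The oracles deliberately use naive
# enumeration, not the package's own graph code.

# Quick ontology builder: `edges` as "child->parent" or "child=>parent"
# (is_a) strings over term names; accessions assigned in `names` order.
mkOnto <- function(names, start, end, edges = character(),
                   stageDomain = c(1L, 28L), prefix = "EMAPA") {
  acc <- paste0(prefix, ":", seq_along(names))
  idx <- function(nm) acc[match(nm, names)]
  rel <- do.call(rbind, lapply(edges, function(e) {
    isa <- grepl("=>", e, fixed = TRUE)
    parts <- strsplit(e, "=>|->")[[1]]
    data.frame(from = idx(trimws(parts[1])),
               type = if (isa) "is_a" else "part_of",
               to = idx(trimws(parts[2])), stringsAsFactors = FALSE)
  }))
  abstractOntology(
    terms = data.frame(accession = acc, name = names,
                       start = rep_len(start, length(names)),
                       end = rep_len(end, length(names)),
                       stringsAsFactors = FALSE),
    relations = if (is.null(rel)) data.frame() else rel,
    stageDomain = stageDomain, prefix = prefix)
}

# The 7-term partonomy chain behind the EMAP:969 worked example.
midgutChain <- function() {
  nm <- c("mouse", "organ system", "visceral organ", "alimentary system",
          "gut", "midgut", "epithelium")
  mkOnto(nm, start = c(1L, rep(10L, 6)), end = 28L,
         edges = paste(nm[-1], "->", nm[-7]))
}

# Chain plus a colliding "epithelium" under the skin, forcing compound
# naming of both (built directly: mkOnto cannot address duplicate names).
midgutChainWithCollision <- function() {
  nm <- c("mouse", "organ system", "visceral organ", "alimentary system",
          "gut", "midgut", "epithelium", "skin", "epithelium")
  acc <- paste0("EMAPA:", seq_along(nm))
  abstractOntology(
    terms = data.frame(accession = acc, name = nm,
                       start = c(1L, rep(10L, 8)), end = 28L,
                       stringsAsFactors = FALSE),
    relations = data.frame(
      from = acc[2:9], type = "part_of",
      to = acc[c(1, 2, 3, 4, 5, 6, 1, 8)], stringsAsFactors = FALSE))
}

# ---- brute-force oracles -------------------------------------------------

# Nodes lying on a directed cycle, found by naive per-node reachability;
# returns the number of mutual-reachability classes among them (one
# expected finding per class).
oracleCycleClassCount <- function(edges) {
  nodes <- unique(c(edges$from, edges$to))
  if (!length(nodes)) return(0L)
  reach <- function(a) {
    seen <- character()
    frontier <- edges$to[edges$from == a]
    while (length(frontier)) {
      frontier <- setdiff(frontier, seen)
      seen <- c(seen, frontier)
      frontier <- unique(edges$to[edges$from %in% frontier])
    }
    seen
  }
  reachSets <- lapply(nodes, reach)
  names(reachSets) <- nodes
  onCycle <- nodes[vapply(nodes, function(a) a %in% reachSets[[a]],
                          logical(1))]
  if (!length(onCycle)) return(0L)
  classes <- list()
  for (a in onCycle) {
    placed <- FALSE
    for (i in seq_along(classes)) {
      b <- classes[[i]][1]
      if (b %in% reachSets[[a]] && a %in% reachSets[[b]]) {
        classes[[i]] <- c(classes[[i]], a)
        placed <- TRUE
        break
      }
    }
    if (!placed) classes[[length(classes) + 1L]] <- a
  }
  length(classes)
}

# (term, stage) orphan pairs by per-stage scanning.
oracleOrphans <- function(onto) {
  tm <- terms(onto)
  tm <- tm[!tm$obsolete, ]
  rel <- relations(onto)
  rel <- rel[rel$type %in% c("part_of", "is_a") &
               rel$from %in% tm$accession & rel$to %in% tm$accession, ]
  roots <- setdiff(tm$accession, rel$from)
  out <- character()
  for (i in seq_len(nrow(tm))) {
    a <- tm$accession[i]
    if (a %in% roots || tm$start[i] > tm$end[i]) next
    for (s in tm$start[i]:tm$end[i]) {
      if (s < stageDomain(onto)[1] || s > stageDomain(onto)[2]) next
      parents <- rel$to[rel$from == a]
      pi <- match(parents, tm$accession)
      if (!any(tm$start[pi] <= s & tm$end[pi] >= s))
        out <- c(out, paste(a, s))
    }
  }
  out
}

# Number of root-to-term paths, by dynamic programming over the DAG
# (independent of the recursive enumeration in fullPathNames).
oraclePathCount <- function(timed, accession) {
  ed <- edges(timed)
  ed <- ed[ed$type %in% c("part_of", "is_a"), ]
  memo <- new.env()
  npaths <- function(a) {
    if (!is.null(memo[[a]])) return(memo[[a]])
    parents <- ed$to[ed$from == a]
    n <- if (!length(parents)) 1L else sum(vapply(parents, npaths, numeric(1)))
    memo[[a]] <- n
    n
  }
  npaths(accession)
}

# Duplicate-name multiset by naive counting.
oracleDupNames <- function(onto) {
  tm <- terms(onto)
  nm <- tm$name[!tm$obsolete]
  tab <- table(nm)
  sort(names(tab[tab > 1]))
}

# Per-stage node count by interval membership.
oracleNodeCount <- function(onto, s) {
  tm <- terms(onto)
  sum(!tm$obsolete & tm$start <= s & tm$end >= s)
}
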