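#' @include core-model.R
NULL

## Stage tokens are "TS" + zero-padded stage number ("TS05", "TS14"); the
## parser also accepts unpadded and bare-integer forms.
.stageToken <- function(s) sprintf("TS%02d", as.integer(s))

.parseStageToken <- function(token) {
  token <- trimws(token)
  m <- regmatches(token, regexec("^(?:TS)?0*([0-9]+)$", token))[[1]]
  if (length(m) < 2) return(NA_integer_)
  as.integer(m[2])
}

.asLines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
    return(readLines(x, warn = FALSE))
  if (length(x) == 1 && grepl("\n", x))
    return(strsplit(x, "\n", fixed = TRUE)[[1]])
  as.character(x)
}

.splitTag <- function(line) {
  i <- regexpr(":", line, fixed = TRUE)
  if (i < 0) return(NULL)
  c(tag = substr(line, 1, i - 1),
    value = sub("^ ", "", substr(line, i + 1, nchar(line))))
}

#' Parse an OBO flat file
#'
#' Reads the line-oriented OBO dialect (header tag/value lines followed by
#' `[Term]` and other stanzas) into a lossless [OboDocument-class]:
#' stanza order, tag order and unrecognized tags are all preserved, so
#' `formatObo(parseObo(text))` is byte-identical for canonically formatted
#' input.
#'
#' @param x a file path, a single string containing newlines, or a
#'   character vector of lines.
#' @return An [OboDocument-class].
#' @seealso [formatObo()], [documentToOntology()]
#' @export
parseObo <- function(x) {
  lines <- .asLines(x)
  starts <- grep("^\\[", lines)
  headerEnd <- if (length(starts)) starts[1] - 1L else length(lines)
  headerLines <- lines[seq_len(headerEnd)]
  headerLines <- headerLines[nzchar(trimws(headerLines))]
  header <- data.frame(tag = character(), value = character(),
                       stringsAsFactors = FALSE)
  for (ln in headerLines) {
    kv <- .splitTag(ln)
    if (is.null(kv))
      stop("malformed header line: '", ln, "'", call. = FALSE)
    header <- rbind(header, data.frame(tag = kv[["tag"]], value = kv[["value"]],
                                       stringsAsFactors = FALSE))
  }
  stanzas <- list()
  seenIds <- character()
  for (i in seq_along(starts)) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1] - 1L else length(lines)
    type <- sub("^\\[(.*)\\]\\s*$", "\\1", lines[from])
    body <- lines[seq.int(from + 1L, length.out = max(0L, to - from))]
    keep <- nzchar(trimws(body))
    tagLines <- body[keep]
    lineNos <- (from + seq_along(body))[keep]
    tags <- data.frame(tag = character(), value = character(),
                       stringsAsFactors = FALSE)
    for (j in seq_along(tagLines)) {
      kv <- .splitTag(tagLines[j])
      if (is.null(kv))
        stop("malformed tag line ", lineNos[j], ": '", tagLines[j], "'",
             call. = FALSE)
      tags <- rbind(tags, data.frame(tag = kv[["tag"]], value = kv[["value"]],
                                     stringsAsFactors = FALSE))
    }
    if (type == "Term") {
      id <- tags$value[tags$tag == "id"]
      if (!length(id))
        stop("[Term] stanza starting at line ", from, " has no id tag",
             call. = FALSE)
      if (id[1] %in% seenIds)
        stop("duplicate id '", id[1], "' in stanza starting at line ", from,
             call. = FALSE)
      seenIds <- c(seenIds, id[1])
    }
    stanzas[[length(stanzas) + 1L]] <- list(type = type, tags = tags)
  }
  new("OboDocument", header = header, stanzas = stanzas)
}

#' Serialize an OboDocument to canonical OBO text
#'
#' Output is UTF-8, LF-terminated lines with no trailing whitespace: a
#' bit-exact contract so that serializations can be diffed and version
#' controlled. The same document always yields identical bytes.
#'
#' @param doc an [OboDocument-class].
#' @return Character vector of lines (without newline characters).
#' @export
formatObo <- function(doc) {
  blocks <- list()
  if (nrow(doc@header))
    blocks[[length(blocks) + 1L]] <-
      paste0(doc@header$tag, ": ", doc@header$value)
  for (st in doc@stanzas) {
    blocks[[length(blocks) + 1L]] <-
      c(paste0("[", st$type, "]"),
        if (nrow(st$tags)) paste0(st$tags$tag, ": ", st$tags$value))
  }
  if (!length(blocks)) return(character())
  out <- blocks[[1]]
  for (b in blocks[-1]) out <- c(out, "", b)
  out
}

#' @rdname formatObo
#' @param path output file path.
#' @export
writeObo <- function(doc, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(formatObo(doc), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

## ---- document -> abstract ontology -------------------------------------

.parseSynonymValue <- function(value) {
  m <- regmatches(value, regexec('^"(.*)"\\s*([A-Za-z_]*)', value))[[1]]
  if (length(m) < 2) return(c(synonym = value, scope = "RELATED"))
  scope <- if (nzchar(m[3])) m[3] else "RELATED"
  c(synonym = m[2], scope = scope)
}

.stripTrailingComment <- function(value) {
  trimws(sub("\\s*!.*$", "", value))
}

#' Interpret a parsed OBO document as an abstract ontology
#'
#' Extracts terms, typed relations, synonyms and stage ranges from the
#' `[Term]` stanzas of `doc`. Stage ranges are read from either supported
#' dialect regardless of configuration: relationship-style
#' (`relationship: starts_at TS12` / `ends_at TS14`) or property-value
#' style (`property_value: starts_at "12"`). A term with an unparsable
#' stage annotation is an error; a term with a missing annotation gets the
#' corresponding stage-domain bound and a WARNING finding in the returned
#' ontology's load report (an error under `strict`).
#'
#' @param doc an [OboDocument-class].
#' @param config an [OntologyConfig-class]; supplies the stage domain,
#'   accession prefix and strictness.
#' @return An [AbstractOntology-class]; defaulted-range findings are in
#'   `loadReport(x)`.
#' @export
documentToOntology <- function(doc, config = ontologyConfig()) {
  dom <- config@stageDomain
  acc <- character(); nm <- character(); st <- integer(); en <- integer()
  obs <- logical()
  rel <- .emptyRelations(); syn <- .emptySynonyms()
  find <- .emptyFindings()
  for (stanza in doc@stanzas) {
    if (stanza$type != "Term") next
    tags <- stanza$tags
    id <- tags$value[tags$tag == "id"][1]
    nameVal <- tags$value[tags$tag == "name"]
    start <- NA_integer_; end <- NA_integer_
    for (k in seq_len(nrow(tags))) {
      tg <- tags$tag[k]; val <- tags$value[k]
      if (tg == "synonym") {
        sv <- .parseSynonymValue(val)
        syn <- rbind(syn, data.frame(accession = id, synonym = sv[["synonym"]],
                                     scope = sv[["scope"]],
                                     stringsAsFactors = FALSE))
      } else if (tg == "is_a") {
        rel <- rbind(rel, data.frame(from = id, type = "is_a",
                                     to = .stripTrailingComment(val),
                                     stringsAsFactors = FALSE))
      } else if (tg %in% c("relationship", "property_value")) {
        val <- .stripTrailingComment(val)
        m <- regmatches(val, regexec("^(\\S+)\\s+(.+)$", val))[[1]]
        if (length(m) < 3) next
        rtype <- m[2]
        target <- gsub('"', "", strsplit(trimws(m[3]), "\\s+")[[1]][1])
        if (rtype %in% c("starts_at", "ends_at")) {
          s <- .parseStageToken(target)
          if (is.na(s))
            stop("term ", id, ": unparsable stage annotation '", val, "'",
                 call. = FALSE)
          if (rtype == "starts_at") start <- s else end <- s
        } else if (rtype %in% c("part_of", "develops_from")) {
          rel <- rbind(rel, data.frame(from = id, type = rtype, to = target,
                                       stringsAsFactors = FALSE))
        }
        ## other relationship types are preserved at document level only
      }
    }
    obsolete <- any(tags$tag == "is_obsolete" &
                      trimws(tags$value) == "true")
    if (is.na(start) || is.na(end)) {
      msg <- paste0("term ", id, ": missing stage annotation; defaulted to ",
                    "stage domain bound")
      if (config@strict)
        stop(msg, call. = FALSE)
      find <- rbind(find, .finding("WARNING", "missing_stage_annotation",
                                   id, msg))
      if (is.na(start)) start <- dom[1]
      if (is.na(end)) end <- dom[2]
    }
    acc <- c(acc, id)
    nm <- c(nm, if (length(nameVal)) nameVal[1] else id)
    st <- c(st, start); en <- c(en, end); obs <- c(obs, obsolete)
  }
  headerMeta <- stats::setNames(doc@header$value, doc@header$tag)
  onto <- abstractOntology(
    terms = data.frame(accession = acc, name = nm, start = st, end = en,
                       obsolete = obs, stringsAsFactors = FALSE),
    relations = rel, synonyms = syn, stageDomain = dom,
    prefix = config@abstractPrefix, metadata = headerMeta)
  onto@loadReport <- validationReport(find)
  onto
}

## ---- abstract ontology -> document -------------------------------------

.defaultHeader <- function(config) {
  data.frame(tag = c("format-version", "default-namespace"),
             value = c("1.2",
                       paste0(tolower(config@abstractPrefix), "_anatomy")),
             stringsAsFactors = FALSE)
}

.stageTags <- function(start, end, dialect) {
  if (dialect == "relationship")
    data.frame(tag = c("relationship", "relationship"),
               value = c(paste("starts_at", .stageToken(start)),
                         paste("ends_at", .stageToken(end))),
               stringsAsFactors = FALSE)
  else
    data.frame(tag = c("property_value", "property_value"),
               value = c(sprintf('starts_at "%d"', start),
                         sprintf('ends_at "%d"', end)),
               stringsAsFactors = FALSE)
}

#' Serialize an abstract ontology to an OboDocument
#'
#' Deterministic canonical form: stanzas sorted by accession local part;
#' within a stanza tags appear in the order id, name, synonyms (sorted),
#' stage annotations (in the configured dialect), `is_a` targets (sorted),
#' `part_of` then `develops_from` relationships (sorted), `is_obsolete`.
#' Two serializations of the same ontology are byte-identical.
#'
#' @param x an [AbstractOntology-class].
#' @param config an [OntologyConfig-class] (dialect selection).
#' @return An [OboDocument-class].
#' @export
ontologyToDocument <- function(x, config = ontologyConfig()) {
  header <- if (length(x@metadata))
    data.frame(tag = names(x@metadata), value = unname(x@metadata),
               stringsAsFactors = FALSE)
  else .defaultHeader(config)
  ord <- order(.localPart(x@terms$accession))
  stanzas <- vector("list", nrow(x@terms))
  for (i in seq_along(ord)) {
    row <- x@terms[ord[i], ]
    tags <- data.frame(tag = c("id", "name"),
                       value = c(row$accession, row$name),
                       stringsAsFactors = FALSE)
    syn <- x@synonyms[x@synonyms$accession == row$accession, , drop = FALSE]
    if (nrow(syn)) {
      syn <- syn[order(syn$synonym, syn$scope), , drop = FALSE]
      tags <- rbind(tags, data.frame(
        tag = "synonym",
        value = sprintf('"%s" %s []', syn$synonym, syn$scope),
        stringsAsFactors = FALSE))
    }
    tags <- rbind(tags, .stageTags(row$start, row$end, config@dialect))
    rel <- x@relations[x@relations$from == row$accession, , drop = FALSE]
    for (ty in c("is_a", "part_of", "develops_from")) {
      sub <- rel[rel$type == ty, , drop = FALSE]
      if (!nrow(sub)) next
      sub <- sub[order(.localPart(sub$to)), , drop = FALSE]
      tags <- rbind(tags, if (ty == "is_a")
        data.frame(tag = "is_a", value = sub$to, stringsAsFactors = FALSE)
        else data.frame(tag = "relationship",
                        value = paste(ty, sub$to), stringsAsFactors = FALSE))
    }
    if (row$obsolete)
      tags <- rbind(tags, data.frame(tag = "is_obsolete", value = "true",
                                     stringsAsFactors = FALSE))
    stanzas[[i]] <- list(type = "Term", tags = tags)
  }
  new("OboDocument", header = header, stanzas = stanzas)
}

#' Read / write abstract ontologies as OBO files
#'
#' Thin conveniences composing [parseObo()] with [documentToOntology()]
#' and [ontologyToDocument()] with [writeObo()].
#'
#' @param path file path.
#' @param config an [OntologyConfig-class].
#' @export
readOboOntology <- function(path, config = ontologyConfig()) {
  documentToOntology(parseObo(path), config)
}

#' @rdname readOboOntology
#' @param x an [AbstractOntology-class].
#' @export
writeOboOntology <- function(x, path, config = ontologyConfig()) {
  writeObo(ontologyToDocument(x, config), path)
}

## ---- timed ontology documents -------------------------------------------

#' Serialize a timed (per-stage) ontology to an OboDocument
#'
#' One document per stage. Timed accessions are the stanza ids; each
#' stanza carries the abstract accession as an `xref` cross-reference and
#' the stage is recorded in a header remark. When a [MappingTable-class]
#' is supplied, every timed term must have a mapping row and the mapped
#' timed accessions are used (an unmapped term is an error).
#'
#' @param timed a [TimedOntology-class].
#' @param mapping optional [MappingTable-class].
#' @param config an [OntologyConfig-class].
#' @return An [OboDocument-class].
#' @export
timedToDocument <- function(timed, mapping = NULL, config = ontologyConfig()) {
  tm <- timed@terms
  ed <- timed@edges
  if (!is.null(mapping)) {
    key <- paste(mapping@rows$abstract, mapping@rows$stage)
    idx <- match(paste(tm$abstract, timed@stage), key)
    if (anyNA(idx))
      stop("timed term not in mapping: ", tm$abstract[which(is.na(idx))[1]],
           " at stage ", timed@stage, call. = FALSE)
    newAcc <- mapping@rows$timed[idx]
    remap <- stats::setNames(newAcc, tm$accession)
    if (nrow(ed)) {
      ed$from <- unname(remap[ed$from])
      ed$to <- unname(remap[ed$to])
    }
    tm$accession <- newAcc
  }
  header <- data.frame(
    tag = c("format-version", "remark"),
    value = c("1.2", paste("stage", .stageToken(timed@stage))),
    stringsAsFactors = FALSE)
  ord <- order(.localPart(tm$accession))
  stanzas <- vector("list", nrow(tm))
  for (i in seq_along(ord)) {
    row <- tm[ord[i], ]
    tags <- data.frame(tag = c("id", "name", "xref"),
                       value = c(row$accession, row$name, row$abstract),
                       stringsAsFactors = FALSE)
    rel <- ed[ed$from == row$accession, , drop = FALSE]
    for (ty in c("is_a", "part_of", "develops_from")) {
      sub <- rel[rel$type == ty, , drop = FALSE]
      if (!nrow(sub)) next
      sub <- sub[order(.localPart(sub$to)), , drop = FALSE]
      tags <- rbind(tags, if (ty == "is_a")
        data.frame(tag = "is_a", value = sub$to, stringsAsFactors = FALSE)
        else data.frame(tag = "relationship", value = paste(ty, sub$to),
                        stringsAsFactors = FALSE))
    }
    stanzas[[i]] <- list(type = "Term", tags = tags)
  }
  new("OboDocument", header = header, stanzas = stanzas)
}

#' Interpret a parsed per-stage OBO document as a TimedOntology
#'
#' The stage is taken from the header remark written by
#' [timedToDocument()]; the abstract accession of each term from its first
#' `xref` tag (may be absent for legacy files — [deriveAbstract()] then
#' falls back to name-path matching).
#'
#' @param doc an [OboDocument-class].
#' @param config an [OntologyConfig-class].
#' @return A [TimedOntology-class].
#' @export
documentToTimed <- function(doc, config = ontologyConfig()) {
  remarks <- doc@header$value[doc@header$tag == "remark"]
  stage <- NA_integer_
  for (r in remarks) {
    m <- regmatches(r, regexec("stage\\s+(TS?[0-9]+|[0-9]+)", r))[[1]]
    if (length(m) >= 2) { stage <- .parseStageToken(m[2]); break }
  }
  if (is.na(stage))
    stop("per-stage document has no parsable stage remark in header",
         call. = FALSE)
  acc <- character(); abs <- character(); nm <- character()
  ed <- .emptyRelations()
  for (stanza in doc@stanzas) {
    if (stanza$type != "Term") next
    tags <- stanza$tags
    id <- tags$value[tags$tag == "id"][1]
    nameVal <- tags$value[tags$tag == "name"]
    xref <- tags$value[tags$tag == "xref"]
    acc <- c(acc, id)
    abs <- c(abs, if (length(xref)) .stripTrailingComment(xref[1]) else NA_character_)
    nm <- c(nm, if (length(nameVal)) nameVal[1] else id)
    for (k in seq_len(nrow(tags))) {
      tg <- tags$tag[k]; val <- .stripTrailingComment(tags$value[k])
      if (tg == "is_a") {
        ed <- rbind(ed, data.frame(from = id, type = "is_a", to = val,
                                   stringsAsFactors = FALSE))
      } else if (tg == "relationship") {
        m <- regmatches(val, regexec("^(\\S+)\\s+(\\S+)", val))[[1]]
        if (length(m) >= 3 && m[2] %in% c("part_of", "develops_from"))
          ed <- rbind(ed, data.frame(from = id, type = m[2], to = m[3],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  new("TimedOntology", stage = stage,
      terms = data.frame(accession = acc, abstract = abs, name = nm,
                         stringsAsFactors = FALSE),
      edges = ed, prefix = config@timedPrefix)
}

## ---- mapping file -------------------------------------------------------

#' Read a timed-to-abstract mapping file
#'
#' Tab-separated, three data columns with header line
#' `timed_id<TAB>abstract_id<TAB>stage`. The allocation counter and the
#' retired-accession set are carried on `# next_local_id` and `# retired`
#' comment lines so that identifier persistence survives a round trip.
#'
#' @param x file path, single string or character vector of lines.
#' @return A [MappingTable-class].
#' @export
readMapping <- function(x) {
  lines <- .asLines(x)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(mappingTable())
  if (lines[1] != "timed_id\tabstract_id\tstage")
    stop("mapping file line 1: expected header 'timed_id\\tabstract_id\\tstage'",
         call. = FALSE)
  timed <- character(); abs <- character(); stg <- integer()
  retired <- character(); nextId <- NULL
  for (i in seq_along(lines)[-1]) {
    ln <- lines[i]
    if (startsWith(ln, "#")) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (f[1] == "# next_local_id" && length(f) == 2)
        nextId <- as.integer(f[2])
      else if (f[1] == "# retired" && length(f) == 2)
        retired <- c(retired, f[2])
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 3)
      stop("mapping file line ", i, ": expected 3 tab-separated fields",
           call. = FALSE)
    s <- .parseStageToken(f[3])
    if (is.na(s))
      stop("mapping file line ", i, ": unparsable stage token '", f[3], "'",
           call. = FALSE)
    if (f[1] %in% timed)
      stop("mapping file line ", i, ": duplicate timed accession '", f[1], "'",
           call. = FALSE)
    timed <- c(timed, f[1]); abs <- c(abs, f[2]); stg <- c(stg, s)
  }
  mappingTable(data.frame(timed = timed, abstract = abs, stage = stg,
                          stringsAsFactors = FALSE),
               nextLocalId = nextId, retired = retired)
}

#' @rdname readMapping
#' @param table a [MappingTable-class].
#' @return `formatMapping()` the character lines; `writeMapping()` the path,
#'   invisibly.
#' @export
formatMapping <- function(table) {
  r <- table@rows
  ord <- order(r$stage, .localPart(r$timed))
  r <- r[ord, , drop = FALSE]
  c("timed_id\tabstract_id\tstage",
    paste0("# next_local_id\t", table@nextLocalId),
    if (length(table@retired))
      paste0("# retired\t", sort(table@retired)),
    if (nrow(r))
      paste(r$timed, r$abstract, .stageToken(r$stage), sep = "\t"))
}

#' @rdname readMapping
#' @param path output file path.
#' @export
writeMapping <- function(table, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(formatMapping(table), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
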