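#' @include AllClasses.R
NULL

#' @export
setGeneric("accessions", function(x, ...) standardGeneric("accessions"))

#' @export
setGeneric("terms", function(x, ...) standardGeneric("terms"))

#' @export
setGeneric("relations", function(x, ...) standardGeneric("relations"))

#' @export
setGeneric("synonyms", function(x, ...) standardGeneric("synonyms"))

#' @export
setGeneric("stageDomain", function(x) standardGeneric("stageDomain"))

#' @export
setGeneric("ontologyRoot", function(x) standardGeneric("ontologyRoot"))

#' @export
setGeneric("term", function(x, accession) standardGeneric("term"))

#' @export
setGeneric("stageRange", function(x, accession) standardGeneric("stageRange"))

#' @export
setGeneric("parentsAt", function(x, accession, stage) standardGeneric("parentsAt"))

#' @export
setGeneric("termStages", function(x, accession) standardGeneric("termStages"))

#' @export
setGeneric("stage", function(x) standardGeneric("stage"))

#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @export
setGeneric("findings", function(x) standardGeneric("findings"))

#' @export
setGeneric("hasErrors", function(x) standardGeneric("hasErrors"))

#' @export
setGeneric("mappingRows", function(x) standardGeneric("mappingRows"))

#' @export
setGeneric("retiredAccessions", function(x) standardGeneric("retiredAccessions"))

#' @export
setGeneric("nextLocalId", function(x) standardGeneric("nextLocalId"))

#' @export
setGeneric("instantiateStage", function(x, stage, ...)
  standardGeneric("instantiateStage"))

#' @export
setGeneric("instantiateAll", function(x, previous = mappingTable(), ...)
  standardGeneric("instantiateAll"))

#' @export
setGeneric("fullPathNames", function(x, accession)
  standardGeneric("fullPathNames"))

#' @export
setGeneric("printName", function(x, accession, stage)
  standardGeneric("printName"))

#' @export
setGeneric("uniquifyNames", function(x, ...) standardGeneric("uniquifyNames"))

#' @export
setGeneric("checkAcyclic", function(x) standardGeneric("checkAcyclic"))

#' @export
setGeneric("checkStageConsistency", function(x)
  standardGeneric("checkStageConsistency"))

#' @export
setGeneric("checkNamesUnique", function(x) standardGeneric("checkNamesUnique"))

#' @export
setGeneric("checkMapping", function(x, mapping) standardGeneric("checkMapping"))

#' @export
setGeneric("validateOntology", function(x, mapping = NULL, ...)
  standardGeneric("validateOntology"))

#' @export
setGeneric("diffVersions", function(old, new) standardGeneric("diffVersions"))
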