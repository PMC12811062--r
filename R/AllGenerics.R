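#' @include AllClasses.R
NULL

#' @export
setGeneric("geneIds", function(x, ...) standardGeneric("geneIds"))

#' @export
setGeneric("trueFitness", function(x, ...) standardGeneric("trueFitness"))

#' @export
setGeneric("t1Proportions", function(x, ...) standardGeneric("t1Proportions"))

#' @export
setGeneric("backgroundExpansion",
           function(x, ...) standardGeneric("backgroundExpansion"))

#' @export
setGeneric("fitnessRecords", function(x, ...) standardGeneric("fitnessRecords"))

#' @export
setGeneric("meanW", function(x, ...) standardGeneric("meanW"))

#' @export
setGeneric("replicateDistance",
           function(x, ...) standardGeneric("replicateDistance"))

#' @export
setGeneric("conditions", function(x, ...) standardGeneric("conditions"))

#' @export
setGeneric("stageCounts", function(x, ...) standardGeneric("stageCounts"))

#' @export
setGeneric("parallelCounts", function(x, ...) standardGeneric("parallelCounts"))

#' @export
setGeneric("differentialSets",
           function(x, ...) standardGeneric("differentialSets"))

#' @export
setGeneric("specificSets", function(x, ...) standardGeneric("specificSets"))

#' @export
setGeneric("fitnessTable", function(t1, t2, meta, ...)
    standardGeneric("fitnessTable"))

#' @export
setGeneric("runCascade", function(x, config = filterConfig(), ...)
    standardGeneric("runCascade"))
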