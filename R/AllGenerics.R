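#' @rdname DEResult-class
#' @param object,x an object.
#' @export
setGeneric("deCalls", function(x) standardGeneric("deCalls"))

#' @rdname DEResult-class
#' @export
setGeneric("deModel", function(x) standardGeneric("deModel"))

#' @rdname DEResult-class
#' @export
setGeneric("deParams", function(x) standardGeneric("deParams"))

#' @rdname deGenes
#' @export
setGeneric("deGenes", function(x, direction = c("both", "up", "down"))
  standardGeneric("deGenes"))

#' @rdname TermAnnotation-class
#' @export
setGeneric("termAccs", function(x) standardGeneric("termAccs"))

#' @rdname TermAnnotation-class
#' @export
setGeneric("termNames", function(x) standardGeneric("termNames"))

#' @rdname TermAnnotation-class
#' @export
setGeneric("termNamespace", function(x) standardGeneric("termNamespace"))

#' @rdname TermAnnotation-class
#' @export
setGeneric("termGenes", function(x, acc) standardGeneric("termGenes"))

#' @rdname TermAnnotation-class
#' @export
setGeneric("slimMap", function(x) standardGeneric("slimMap"))

#' @rdname TermAnnotation-class
#' @param value replacement value.
#' @export
setGeneric("slimMap<-", function(x, value) standardGeneric("slimMap<-"))

#' @rdname ModelComparison-class
#' @export
setGeneric("comparisonClasses", function(x) standardGeneric("comparisonClasses"))

#' @rdname ModelComparison-class
#' @export
setGeneric("comparisonSummary", function(x) standardGeneric("comparisonSummary"))

#' @rdname ConcordanceResult-class
#' @export
setGeneric("concordanceR", function(x) standardGeneric("concordanceR"))

#' @rdname ConcordanceResult-class
#' @export
setGeneric("concordancePairs", function(x) standardGeneric("concordancePairs"))
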