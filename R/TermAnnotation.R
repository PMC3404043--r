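#' Construct a TermAnnotation
#'
#' @param genes named list of character vectors: term accession ->
#'   non-empty gene set.
#' @param termName named character: accession -> display name. Defaults
#'   to the accessions themselves.
#' @param namespace named character or single string: GO namespace per
#'   term.
#' @param slim optional named character mapping each accession to a slim
#'   parent accession (total and idempotent).
#' @return a \linkS4class{TermAnnotation}.
#' @examples
#' ann <- TermAnnotation(
#'   genes = list("GO:0007049" = c("Ccnb1", "Cdk1", "Fzr1"),
#'                "GO:0005739" = c("Pdk1", "Mos")),
#'   termName = c("GO:0007049" = "cell cycle", "GO:0005739" = "mitochondrion"),
#'   namespace = c("GO:0007049" = "biological_process",
#'                 "GO:0005739" = "cellular_component"))
#' termAccs(ann)
#' @export
TermAnnotation <- function(genes, termName = NULL, namespace = "biological_process",
                           slim = character()) {
  genes <- lapply(genes, function(g) unique(as.character(g)))
  acc <- names(genes)
  if (is.null(termName)) termName <- stats::setNames(acc, acc)
  if (length(namespace) == 1L && is.null(names(namespace)) && length(acc))
    namespace <- stats::setNames(rep(namespace, length(acc)), acc)
  methods::new("TermAnnotation", genes = genes,
               termName = stats::setNames(as.character(termName[acc]), acc),
               namespace = stats::setNames(as.character(namespace[acc]), acc),
               slim = slim)
}

#' @rdname TermAnnotation-class
#' @param x a \linkS4class{TermAnnotation}.
#' @param acc a term accession.
#' @export
setMethod("termAccs", "TermAnnotation", function(x) names(x@genes))

#' @rdname TermAnnotation-class
#' @export
setMethod("termNames", "TermAnnotation", function(x) x@termName)

#' @rdname TermAnnotation-class
#' @export
setMethod("termNamespace", "TermAnnotation", function(x) x@namespace)

#' @rdname TermAnnotation-class
#' @export
setMethod("termGenes", "TermAnnotation", function(x, acc) {
  if (missing(acc)) return(x@genes)
  if (!acc %in% names(x@genes)) stop("unknown term accession: ", acc)
  x@genes[[acc]]
})

#' @rdname TermAnnotation-class
#' @export
setMethod("slimMap", "TermAnnotation", function(x) x@slim)

#' @rdname TermAnnotation-class
#' @export
setReplaceMethod("slimMap", "TermAnnotation", function(x, value) {
  x@slim <- value
  methods::validObject(x)
  x
})

#' @rdname TermAnnotation-class
#' @export
setMethod("length", "TermAnnotation", function(x) length(x@genes))

setMethod("show", "TermAnnotation", function(object) {
  cat("TermAnnotation:", length(object@genes), "terms")
  if (length(object@genes)) {
    ns <- table(object@namespace)
    cat(" (", paste(sprintf("%s: %d", names(ns), ns), collapse = ", "), ")", sep = "")
    cat("\n  gene-set sizes: ", paste(range(lengths(object@genes)), collapse = "-"),
        sep = "")
  }
  cat("\n  slim mapping:", if (length(object@slim)) "present" else "absent", "\n")
  invisible(NULL)
})
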