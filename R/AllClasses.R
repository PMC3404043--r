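#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

.MODELS <- c("A", "B")
.CONDITIONS <- c("control", "diabetic")
.NAMESPACES <- c("biological_process", "cellular_component", "molecular_function")
.CALLS <- c("up", "down", "unchanged")
.STRATA <- c("high", "low")

#' CountSet: a gene-by-library read-count container
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one
#' \code{counts} assay of non-negative integer read counts, with each
#' library (column) labelled by a disease model (\code{"A"} or \code{"B"})
#' and a condition (\code{"control"} or \code{"diabetic"}) in
#' \code{colData}. Gene identifiers are opaque, case-sensitive, unique
#' row names.
#'
#' @slot ... see \linkS4class{SummarizedExperiment}.
#' @seealso \code{\link{CountSet}} (constructor),
#'   \code{\link{readCountTable}}, \code{\link{filterDetected}}
#' @exportClass CountSet
setClass("CountSet", contains = "SummarizedExperiment")

setValidity("CountSet", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(is.na(cnt)))
      msg <- c(msg, "counts contain NA")
    else {
      if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(cnt != round(cnt))) msg <- c(msg, "counts must be integers")
    }
  }
  if (is.null(rownames(object)))
    msg <- c(msg, "gene identifiers (rownames) are required")
  else if (anyDuplicated(rownames(object)))
    msg <- c(msg, sprintf("duplicate gene ids: %s",
                          paste(unique(rownames(object)[duplicated(rownames(object))]),
                                collapse = ", ")))
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("model", "condition") %in% colnames(cd)))
    msg <- c(msg, "colData must have 'model' and 'condition'")
  else {
    if (!all(cd$model %in% .MODELS))
      msg <- c(msg, "model must be 'A' or 'B'")
    if (!all(cd$condition %in% .CONDITIONS))
      msg <- c(msg, "condition must be 'control' or 'diabetic'")
  }
  if (length(msg)) msg else TRUE
})

#' TermAnnotation: ontology-term to gene-set mapping
#'
#' Maps ontology term accessions (e.g. \code{GO:0007049}) to gene sets,
#' with a human-readable name and a GO namespace per term, and an
#' optional slim mapping (term accession to broad slim-term accession)
#' used by \code{\link{collapseToSlim}}.
#'
#' @slot genes named list of character vectors; names are unique term
#'   accessions, values are non-empty gene-id sets.
#' @slot termName named character, term accession to display name.
#' @slot namespace named character, term accession to one of
#'   \code{biological_process}, \code{cellular_component},
#'   \code{molecular_function}.
#' @slot slim named character mapping every term accession to its slim
#'   parent accession; empty when no slim mapping is attached. The
#'   mapping must be total over annotated terms and idempotent (a slim
#'   target that is itself annotated maps to itself).
#' @seealso \code{\link{readAnnotation}}, \code{\link{fisherEnrichment}}
#' @exportClass TermAnnotation
setClass("TermAnnotation",
         representation(genes = "list", termName = "character",
                        namespace = "character", slim = "character"))

setValidity("TermAnnotation", function(object) {
  msg <- character()
  acc <- names(object@genes)
  if (length(object@genes)) {
    if (is.null(acc) || any(!nzchar(acc)))
      msg <- c(msg, "every term needs an accession")
    if (anyDuplicated(acc))
      msg <- c(msg, sprintf("duplicate term accession: %s",
                            paste(unique(acc[duplicated(acc)]), collapse = ", ")))
    if (any(lengths(object@genes) == 0))
      msg <- c(msg, sprintf("empty gene set for term(s): %s",
                            paste(acc[lengths(object@genes) == 0], collapse = ", ")))
    if (!identical(sort(names(object@termName)), sort(acc)) ||
        !identical(sort(names(object@namespace)), sort(acc)))
      msg <- c(msg, "termName and namespace must cover exactly the annotated terms")
    if (!all(object@namespace %in% .NAMESPACES))
      msg <- c(msg, sprintf("namespace must be one of: %s",
                            paste(.NAMESPACES, collapse = ", ")))
  }
  if (length(object@slim)) {
    if (!all(acc %in% names(object@slim)))
      msg <- c(msg, "slim mapping must be total over annotated terms")
    tgt <- unique(object@slim)
    inmap <- tgt[tgt %in% names(object@slim)]
    if (length(inmap) && !all(object@slim[inmap] == inmap))
      msg <- c(msg, "slim mapping must be idempotent (a slim term maps to itself)")
  }
  if (length(msg)) msg else TRUE
})

#' DEResult: per-model stratified fold-change calls
#'
#' One record per filtered gene of one disease model: the normalized
#' control and diabetic expression values, the expression stratum
#' (\code{high}/\code{low}), the log2 fold change (diabetic over
#' control), and the call in \code{up}/\code{down}/\code{unchanged}.
#' The parameters the calls were made with (filter, stratum fraction,
#' cutoffs, normalization, pseudocount, stratum threshold) are kept in
#' \code{params}.
#'
#' @slot calls a \linkS4class{DataFrame} with columns \code{gene_id},
#'   \code{ctrl}, \code{diab}, \code{stratum}, \code{log2fc},
#'   \code{call}.
#' @slot model character, \code{"A"} or \code{"B"}.
#' @slot params named list of calling parameters.
#' @seealso \code{\link{callDE}}, \code{\link{deGenes}},
#'   \code{\link{compareModels}}
#' @exportClass DEResult
setClass("DEResult",
         representation(calls = "DataFrame", model = "character",
                        params = "list"))

setValidity("DEResult", function(object) {
  msg <- character()
  need <- c("gene_id", "ctrl", "diab", "stratum", "log2fc", "call")
  if (!all(need %in% colnames(object@calls)))
    msg <- c(msg, sprintf("calls must have columns: %s", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@calls$gene_id))
      msg <- c(msg, "duplicate gene ids in calls")
    if (!all(object@calls$call %in% .CALLS))
      msg <- c(msg, "call must be up/down/unchanged")
    if (!all(object@calls$stratum %in% .STRATA))
      msg <- c(msg, "stratum must be high/low")
  }
  if (length(object@model) != 1L || !object@model %in% .MODELS)
    msg <- c(msg, "model must be 'A' or 'B'")
  if (length(msg)) msg else TRUE
})

.COMPARISON_CLASSES <- c("up-both", "down-both", "up-A-only", "down-A-only",
                         "up-B-only", "down-B-only", "discordant", "unchanged")

#' ModelComparison: cross-model DE overlap classes
#'
#' Partition of the union of two models' filtered gene sets into the
#' eight disjoint classes \code{up-both}, \code{down-both},
#' \code{up-A-only}, \code{down-A-only}, \code{up-B-only},
#' \code{down-B-only}, \code{discordant} (up in one model and down in
#' the other) and \code{unchanged}.
#'
#' @slot classes named character vector, gene id to class.
#' @slot summary named integer vector of class sizes (all eight classes,
#'   zeros included).
#' @seealso \code{\link{compareModels}}, \code{\link{assignColorClasses}}
#' @exportClass ModelComparison
setClass("ModelComparison",
         representation(classes = "character", summary = "integer"))

setValidity("ModelComparison", function(object) {
  msg <- character()
  if (length(object@classes)) {
    if (is.null(names(object@classes)) || anyDuplicated(names(object@classes)))
      msg <- c(msg, "classes must be named by unique gene ids")
    if (!all(object@classes %in% .COMPARISON_CLASSES))
      msg <- c(msg, "invalid comparison class")
  }
  if (!identical(sort(names(object@summary)), sort(.COMPARISON_CLASSES)))
    msg <- c(msg, "summary must cover all eight classes")
  else if (sum(object@summary) != length(object@classes))
    msg <- c(msg, "summary counts must sum to the number of genes")
  if (length(msg)) msg else TRUE
})

#' SyntheticSpec: parameters of the synthetic count generator
#'
#' Describes a two-model, four-library synthetic experiment: gene count,
#' expected library size, negative-binomial dispersion (variance =
#' mu + dispersion * mu^2), planted differential-expression fractions and
#' effect sizes, the fraction of each model's DE genes shared between
#' models, the log-normal shape of baseline per-gene expression, and the
#' RNG seed.
#'
#' @slot nGenes integer, number of genes.
#' @slot librarySize numeric, expected total reads per library.
#' @slot dispersion numeric >= 0; 0 degenerates to Poisson noise.
#' @slot fracDeUp,fracDeDown fractions of genes planted up/down per model.
#' @slot lfcHigh,lfcLow planted |log2 fold change| for high- and
#'   low-expression DE genes.
#' @slot fracShared fraction of each model's planted DE genes shared (same
#'   gene, same direction) between the two models.
#' @slot baselineMeanlog,baselineSdlog log-normal parameters of baseline
#'   per-gene relative expression.
#' @slot seed integer RNG seed.
#' @seealso \code{\link{syntheticSpec}}, \code{\link{simulateCounts}}
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
         representation(nGenes = "integer", librarySize = "numeric",
                        dispersion = "numeric", fracDeUp = "numeric",
                        fracDeDown = "numeric", lfcHigh = "numeric",
                        lfcLow = "numeric", fracShared = "numeric",
                        baselineMeanlog = "numeric", baselineSdlog = "numeric",
                        seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  chkFrac <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
      sprintf("%s must be a single value in [0, 1]", nm)
    else character()
  }
  msg <- c(msg, chkFrac(object@fracDeUp, "fracDeUp"),
           chkFrac(object@fracDeDown, "fracDeDown"),
           chkFrac(object@fracShared, "fracShared"))
  if (!length(msg) && object@fracDeUp + object@fracDeDown > 1)
    msg <- c(msg, "fracDeUp + fracDeDown must be <= 1")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (object@nGenes < 1) msg <- c(msg, "nGenes must be >= 1")
  if (object@librarySize <= 0) msg <- c(msg, "librarySize must be > 0")
  if (object@baselineSdlog < 0) msg <- c(msg, "baselineSdlog must be >= 0")
  if (object@lfcHigh < 0 || object@lfcLow < 0)
    msg <- c(msg, "lfcHigh and lfcLow must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ConcordanceResult: sequencing vs qPCR fold-change agreement
#'
#' Paired log2 fold changes for a validation gene panel and their
#' Pearson correlation coefficient.
#'
#' @slot pairs a \linkS4class{DataFrame} with columns \code{gene_id},
#'   \code{seq_lfc}, \code{qpcr_lfc}.
#' @slot r numeric, Pearson correlation over the shared genes.
#' @seealso \code{\link{qpcrConcordance}}
#' @exportClass ConcordanceResult
setClass("ConcordanceResult",
         representation(pairs = "DataFrame", r = "numeric"))

setValidity("ConcordanceResult", function(object) {
  msg <- character()
  if (!all(c("gene_id", "seq_lfc", "qpcr_lfc") %in% colnames(object@pairs)))
    msg <- c(msg, "pairs must have gene_id, seq_lfc, qpcr_lfc")
  if (nrow(object@pairs) < 3)
    msg <- c(msg, "at least 3 gene pairs are required")
  if (length(object@r) != 1L || is.na(object@r) || object@r < -1 || object@r > 1)
    msg <- c(msg, "r must be a single value in [-1, 1]")
  if (length(msg)) msg else TRUE
})
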