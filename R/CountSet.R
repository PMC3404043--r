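#' Construct a CountSet
#'
#' Bundles a gene-by-library matrix of raw read counts with the
#' model/condition design of each library.
#'
#' @param counts integer matrix, genes in rows (unique rownames
#'   required), libraries in columns.
#' @param model character vector, one of \code{"A"}, \code{"B"} per
#'   library. Model A plays the chemically induced (STZ-like) role,
#'   model B the spontaneous genetic (NOD-like) role.
#' @param condition character vector, \code{"control"} or
#'   \code{"diabetic"} per library.
#' @return a \linkS4class{CountSet}.
#' @examples
#' cnt <- matrix(rpois(12, 50), nrow = 3,
#'               dimnames = list(paste0("g", 1:3),
#'                               c("ctrl_A", "diab_A", "ctrl_B", "diab_B")))
#' cs <- CountSet(cnt, model = c("A", "A", "B", "B"),
#'                condition = c("control", "diabetic", "control", "diabetic"))
#' cs
#' @export
CountSet <- function(counts, model, condition) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (length(model) != ncol(counts) || length(condition) != ncol(counts))
    stop("model and condition must have one entry per library (column)")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(model = as.character(model),
                                   condition = as.character(condition),
                                   row.names = colnames(counts)))
  methods::new("CountSet", se)
}

#' Raw counts of a CountSet
#'
#' @param object a \linkS4class{CountSet}.
#' @param ... ignored.
#' @return the integer count matrix.
#' @importFrom BiocGenerics counts
#' @export counts
#' @aliases counts,CountSet-method
#' @name counts
setMethod("counts", "CountSet", function(object, ...) {
  SummarizedExperiment::assay(object, "counts")
})

#' Library columns belonging to one disease model
#'
#' @param x a \linkS4class{CountSet}.
#' @param model \code{"A"} or \code{"B"}.
#' @param condition optional, restrict to \code{"control"} or
#'   \code{"diabetic"} libraries.
#' @return integer column indices.
#' @export
modelLibraries <- function(x, model, condition = NULL) {
  stopifnot(methods::is(x, "CountSet"))
  model <- match.arg(model, .MODELS)
  cd <- SummarizedExperiment::colData(x)
  idx <- which(cd$model == model)
  if (!is.null(condition)) {
    condition <- match.arg(condition, .CONDITIONS)
    idx <- idx[cd$condition[idx] == condition]
  }
  idx
}

setMethod("show", "CountSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("CountSet:", nrow(object), "genes x", ncol(object), "libraries\n")
  for (m in intersect(.MODELS, unique(cd$model)))
    cat(sprintf("  model %s: %s\n", m,
                paste(sprintf("%s (%s)", colnames(object)[cd$model == m],
                              cd$condition[cd$model == m]), collapse = ", ")))
  invisible(NULL)
})
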