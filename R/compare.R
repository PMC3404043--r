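#' Compare the DE calls of the two disease models
#'
#' Assigns every gene in the union of the two models' filtered gene
#' sets to exactly one of eight disjoint classes: up or down in both
#' models (\code{up-both}, \code{down-both}), up or down in exactly one
#' model (\code{up-A-only}, \code{down-A-only}, \code{up-B-only},
#' \code{down-B-only}), \code{discordant} (up in one model, down in the
#' other — reported separately, never counted as shared), or
#' \code{unchanged}. A gene absent from one model's filtered set counts
#' as un-called in that model.
#'
#' @param callsA,callsB \linkS4class{DEResult} objects for models A
#'   and B.
#' @return a \linkS4class{ModelComparison}.
#' @examples
#' sim <- simulateCounts(syntheticSpec(nGenes = 500, seed = 5))
#' cmp <- compareModels(callDE(sim$counts, "A"), callDE(sim$counts, "B"))
#' comparisonSummary(cmp)
#' @export
compareModels <- function(callsA, callsB) {
  stopifnot(methods::is(callsA, "DEResult"), methods::is(callsB, "DEResult"))
  if (callsA@model == callsB@model)
    warning("both call sets come from model ", callsA@model)
  genes <- union(deUniverse(callsA), deUniverse(callsB))
  if (!length(genes))
    warning("empty comparison: both call sets are empty")
  lookup <- function(res) {
    cl <- stats::setNames(as.character(res@calls$call), res@calls$gene_id)
    out <- cl[genes]
    out[is.na(out)] <- "unchanged"
    out
  }
  a <- lookup(callsA)
  b <- lookup(callsB)
  cls <- rep("unchanged", length(genes))
  cls[a == "up" & b == "up"] <- "up-both"
  cls[a == "down" & b == "down"] <- "down-both"
  cls[(a == "up" & b == "down") | (a == "down" & b == "up")] <- "discordant"
  cls[a == "up" & b == "unchanged"] <- "up-A-only"
  cls[a == "down" & b == "unchanged"] <- "down-A-only"
  cls[a == "unchanged" & b == "up"] <- "up-B-only"
  cls[a == "unchanged" & b == "down"] <- "down-B-only"
  names(cls) <- genes
  summ <- vapply(.COMPARISON_CLASSES, function(cc) sum(cls == cc), integer(1))
  methods::new("ModelComparison", classes = cls, summary = summ)
}

#' @rdname ModelComparison-class
#' @param x a \linkS4class{ModelComparison}.
#' @export
setMethod("comparisonClasses", "ModelComparison", function(x) x@classes)

#' @rdname ModelComparison-class
#' @export
setMethod("comparisonSummary", "ModelComparison", function(x) x@summary)

setMethod("show", "ModelComparison", function(object) {
  cat("ModelComparison:", length(object@classes), "genes\n")
  for (cc in .COMPARISON_CLASSES)
    cat(sprintf("  %-12s %d\n", cc, object@summary[[cc]]))
  invisible(NULL)
})

.COLOR_MAP <- c("up-both" = "red", "down-both" = "blue",
                "up-B-only" = "yellow", "down-B-only" = "green",
                "up-A-only" = "orange", "down-A-only" = "purple")

#' KEGG-style color classes for a model comparison
#'
#' Maps the six DE sharing classes onto the six-color legend used for
#' KEGG pathway color maps: red = up in both models, blue = down in
#' both, yellow/green = up/down uniquely in model B (the NOD-like
#' model), orange/purple = up/down uniquely in model A (the STZ-like
#' model). Unchanged and discordant genes are omitted. The result can be
#' written as a two-column KEGG color-map upload table.
#'
#' @param comparison a \linkS4class{ModelComparison}.
#' @return data.frame with columns \code{gene_id} and \code{color}.
#' @export
assignColorClasses <- function(comparison) {
  stopifnot(methods::is(comparison, "ModelComparison"))
  cls <- comparison@classes
  keep <- cls %in% names(.COLOR_MAP)
  data.frame(gene_id = names(cls)[keep],
             color = unname(.COLOR_MAP[cls[keep]]),
             stringsAsFactors = FALSE)
}

#' Sequencing versus qPCR fold-change concordance
#'
#' Pearson correlation between sequencing and qPCR log2 fold changes
#' over the validation genes common to both tables. qPCR input is
#' expected as pre-computed log2 relative expression (delta-delta-Ct
#' already applied).
#'
#' @param seqLfc data.frame with columns \code{gene_id} and
#'   \code{log2fc}, or a \linkS4class{DEResult}.
#' @param qpcrLfc data.frame with columns \code{gene_id} and
#'   \code{qpcr_lfc} (as produced by \code{\link{simulateQpcr}}), or
#'   \code{log2fc}.
#' @return a \linkS4class{ConcordanceResult}.
#' @examples
#' sim <- simulateCounts(syntheticSpec(nGenes = 500, seed = 5))
#' res <- callDE(sim$counts, "A")
#' panel <- head(deGenes(res, "up"), 8)
#' qp <- simulateQpcr(sim$truth, panel, noiseSd = 0.2, seed = 9)
#' qpcrConcordance(res, qp)
#' @export
qpcrConcordance <- function(seqLfc, qpcrLfc) {
  if (methods::is(seqLfc, "DEResult"))
    seqLfc <- data.frame(gene_id = seqLfc@calls$gene_id,
                         log2fc = seqLfc@calls$log2fc,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "log2fc") %in% colnames(seqLfc)))
  qcol <- if ("qpcr_lfc" %in% colnames(qpcrLfc)) "qpcr_lfc" else "log2fc"
  stopifnot("gene_id" %in% colnames(qpcrLfc), qcol %in% colnames(qpcrLfc))
  shared <- intersect(seqLfc$gene_id, qpcrLfc$gene_id)
  if (length(shared) < 3)
    stop("insufficient data: only ", length(shared),
         " shared gene(s); at least 3 required")
  s <- seqLfc$log2fc[match(shared, seqLfc$gene_id)]
  q <- qpcrLfc[[qcol]][match(shared, qpcrLfc$gene_id)]
  if (any(!is.finite(s)) || any(!is.finite(q)))
    stop("non-finite fold change among shared genes")
  if (stats::sd(s) == 0 || stats::sd(q) == 0)
    stop("undefined correlation: zero variance in one of the vectors")
  methods::new("ConcordanceResult",
               pairs = S4Vectors::DataFrame(gene_id = shared, seq_lfc = s,
                                            qpcr_lfc = q),
               r = stats::cor(s, q))
}

#' @rdname ConcordanceResult-class
#' @param x a \linkS4class{ConcordanceResult}.
#' @export
setMethod("concordanceR", "ConcordanceResult", function(x) x@r)

#' @rdname ConcordanceResult-class
#' @export
setMethod("concordancePairs", "ConcordanceResult", function(x) x@pairs)

setMethod("show", "ConcordanceResult", function(object) {
  cat(sprintf("ConcordanceResult: %d gene pairs, Pearson r = %.3f\n",
              nrow(object@pairs), object@r))
  invisible(NULL)
})
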