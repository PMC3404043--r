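#' @rdname DEResult-class
#' @export
setMethod("deCalls", "DEResult", function(x) x@calls)

#' @rdname DEResult-class
#' @export
setMethod("deModel", "DEResult", function(x) x@model)

#' @rdname DEResult-class
#' @export
setMethod("deParams", "DEResult", function(x) x@params)

#' Extract called gene sets from a DEResult
#'
#' @param x a \linkS4class{DEResult}.
#' @param direction \code{"up"}, \code{"down"}, or \code{"both"} (the
#'   union of up and down calls).
#' @return character vector of gene ids.
#' @export
setMethod("deGenes", "DEResult", function(x, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  keep <- if (direction == "both") x@calls$call != "unchanged"
          else x@calls$call == direction
  as.character(x@calls$gene_id[keep])
})

#' Genes in the tested universe of a DEResult
#'
#' The universe is the model's filter-passing gene set: every gene that
#' received a call, whatever the call was.
#'
#' @param x a \linkS4class{DEResult}.
#' @return character vector of gene ids.
#' @export
deUniverse <- function(x) {
  stopifnot(methods::is(x, "DEResult"))
  as.character(x@calls$gene_id)
}

setMethod("show", "DEResult", function(object) {
  cc <- object@calls
  cat(sprintf("DEResult (model %s): %d genes\n", object@model, nrow(cc)))
  if (nrow(cc)) {
    for (s in .STRATA) {
      sel <- cc$stratum == s
      cat(sprintf("  %s stratum (n=%d): %d up, %d down, %d unchanged\n",
                  s, sum(sel),
                  sum(cc$call[sel] == "up"), sum(cc$call[sel] == "down"),
                  sum(cc$call[sel] == "unchanged")))
    }
  }
  p <- object@params
  if (length(p))
    cat("  cutoffs: high >", p$highCutoff, ", low >", p$lowCutoff,
        "; normalization:", p$normalization, "\n")
  invisible(NULL)
})
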