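#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X hypergeometric with \code{K} annotated genes in a
#' universe of \code{N}, drawing \code{n} genes — the one-sided Fisher
#' exact p-value of over-representation for a 2x2 table with these
#' margins. Vectorized over all arguments.
#'
#' @param k observed annotated genes in the drawn set.
#' @param K annotated genes in the universe.
#' @param n size of the drawn (DE) set.
#' @param N universe size.
#' @return numeric vector of upper-tail probabilities.
#' @examples
#' hyperTailP(4, 5, 4, 10)  # 5/210
#' @export
hyperTailP <- function(k, K, n, N) {
  stopifnot(all(k >= 0), all(K <= N), all(n <= N), all(k <= pmin(K, n)))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' One-sided Fisher exact over-representation analysis
#'
#' For each annotated term, builds the 2x2 table of DE membership versus
#' term membership over the gene universe and computes the upper-tail
#' hypergeometric probability P(X >= k) — the one-sided Fisher exact
#' test of over-representation. Term gene sets are intersected with the
#' universe before counting; terms with no universe gene are omitted.
#' Results are sorted by ascending p, ties broken by accession.
#'
#' The recommended universe is the model's filter-passing gene set
#' (\code{\link{deUniverse}}), so the test conditions on detectability.
#'
#' @param deGenes character vector of DE gene ids; must be a subset of
#'   \code{universe}.
#' @param universe character vector of gene ids defining the universe.
#' @param annotation a \linkS4class{TermAnnotation}.
#' @param alternative \code{"greater"} (over-representation, default) or
#'   \code{"two.sided"} (full Fisher exact test).
#' @param adjust multiple-testing adjustment for the \code{q} column:
#'   \code{"none"} (default; \code{q = p}) or \code{"bh"}
#'   (Benjamini-Hochberg).
#' @return data.frame with columns \code{acc}, \code{name},
#'   \code{namespace}, \code{k} (DE genes in term), \code{n} (DE genes),
#'   \code{K} (universe genes in term), \code{N} (universe size),
#'   \code{p}, \code{q}.
#' @examples
#' ann <- TermAnnotation(genes = list("T:1" = c("g1", "g2", "g3", "g4"),
#'                                    "T:2" = c("g7", "g8")))
#' fisherEnrichment(c("g1", "g2", "g3", "g7"), paste0("g", 1:10), ann)
#' @export
fisherEnrichment <- function(deGenes, universe, annotation,
                             alternative = c("greater", "two.sided"),
                             adjust = c("none", "bh")) {
  alternative <- match.arg(alternative)
  adjust <- match.arg(adjust)
  stopifnot(methods::is(annotation, "TermAnnotation"))
  universe <- unique(as.character(universe))
  deGenes <- unique(as.character(deGenes))
  if (!length(universe)) stop("empty universe")
  stray <- setdiff(deGenes, universe)
  if (length(stray))
    stop("DE gene(s) not in universe: ", paste(stray, collapse = ", "))
  N <- length(universe)
  n <- length(deGenes)
  empty <- data.frame(acc = character(), name = character(),
                      namespace = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE)
  if (!length(annotation@genes)) return(empty)
  inTerm <- lapply(annotation@genes, intersect, universe)
  K <- lengths(inTerm)
  keep <- K > 0
  if (!any(keep)) return(empty)
  inTerm <- inTerm[keep]
  K <- K[keep]
  k <- vapply(inTerm, function(g) length(intersect(g, deGenes)), integer(1))
  acc <- names(inTerm)
  p <- if (alternative == "greater") {
    hyperTailP(k, K, n, N)
  } else {
    vapply(seq_along(k), function(i) {
      tab <- matrix(c(k[i], n - k[i], K[i] - k[i], N - K[i] - n + k[i]), 2)
      stats::fisher.test(tab, alternative = "two.sided")$p.value
    }, numeric(1))
  }
  out <- data.frame(acc = acc,
                    name = unname(annotation@termName[acc]),
                    namespace = unname(annotation@namespace[acc]),
                    k = unname(k), n = n, K = unname(K), N = N,
                    p = unname(p), stringsAsFactors = FALSE)
  out$q <- adjustPvalues(out$p, method = adjust)
  out <- out[order(out$p, out$acc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Adjust enrichment p-values
#'
#' \code{none} copies the p-values; \code{bh} applies the
#' Benjamini-Hochberg step-up procedure (via \code{\link[stats]{p.adjust}}).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param method \code{"none"} or \code{"bh"}.
#' @return numeric vector of adjusted values.
#' @export
adjustPvalues <- function(p, method = c("none", "bh")) {
  method <- match.arg(method)
  stopifnot(all(p > 0 & p <= 1))
  if (method == "none") p else stats::p.adjust(p, method = "BH")
}

#' Collapse an annotation onto its GO-slim terms
#'
#' Replaces the annotation's terms by their slim parents: each slim
#' term's gene set is the union of the gene sets of all terms mapping to
#' it. The slim term inherits the name and namespace of the identically
#' named annotated term when one exists, otherwise of the first mapped
#' term. The result carries the identity slim mapping.
#'
#' @param annotation a \linkS4class{TermAnnotation} with a slim mapping
#'   attached (see \code{\link{slimMap}}).
#' @return a \linkS4class{TermAnnotation} with one term per distinct
#'   slim target.
#' @export
collapseToSlim <- function(annotation) {
  stopifnot(methods::is(annotation, "TermAnnotation"))
  if (!length(annotation@slim))
    stop("no slim mapping attached; supply one via slimMap()<- or skip collapsing")
  acc <- names(annotation@genes)
  target <- annotation@slim[acc]
  slimAcc <- unique(unname(target))
  sets <- lapply(slimAcc, function(s)
    unique(unlist(annotation@genes[acc[target == s]], use.names = FALSE)))
  names(sets) <- slimAcc
  nm <- vapply(slimAcc, function(s) {
    if (s %in% acc) unname(annotation@termName[s])
    else unname(annotation@termName[acc[target == s][1]])
  }, character(1))
  ns <- vapply(slimAcc, function(s) {
    if (s %in% acc) unname(annotation@namespace[s])
    else unname(annotation@namespace[acc[target == s][1]])
  }, character(1))
  TermAnnotation(genes = sets,
                 termName = stats::setNames(nm, slimAcc),
                 namespace = stats::setNames(ns, slimAcc),
                 slim = stats::setNames(slimAcc, slimAcc))
}
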