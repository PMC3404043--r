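#' Detection filter: genes with strictly more than a minimum read count
#'
#' Retains genes whose raw read counts, summed over all libraries of the
#' chosen model (control plus diabetic), are strictly greater than
#' \code{minReads}. The default of 10 reproduces the "more than 10
#' reads" detection rule used for pooled-oocyte libraries. The returned
#' object keeps only the model's libraries.
#'
#' @param x a \linkS4class{CountSet}.
#' @param model \code{"A"} or \code{"B"}.
#' @param minReads minimum summed read count; strict inequality.
#' @return a \linkS4class{CountSet} restricted to the passing genes and
#'   the model's libraries. Warns (and returns an empty set) when no
#'   gene passes.
#' @examples
#' sim <- simulateCounts(syntheticSpec(nGenes = 300, seed = 2))
#' filterDetected(sim$counts, model = "A")
#' @export
filterDetected <- function(x, model, minReads = 10) {
  stopifnot(methods::is(x, "CountSet"), minReads >= 0)
  libs <- modelLibraries(x, model)
  if (!length(modelLibraries(x, model, "control")) ||
      !length(modelLibraries(x, model, "diabetic")))
    stop("model ", model, " needs at least one control and one diabetic library")
  keep <- rowSums(counts(x)[, libs, drop = FALSE]) > minReads
  message(sprintf("detection filter (model %s, > %g reads): %d retained, %d discarded",
                  model, minReads, sum(keep), sum(!keep)))
  if (!any(keep))
    warning("no gene passes the detection filter for model ", model)
  x[keep, libs]
}

#' Library-size normalization
#'
#' \code{cpm} rescales each library to a total of one million
#' (counts-per-million); \code{none} returns the raw counts, matching a
#' direct raw-read-count comparison between libraries of similar depth.
#'
#' @param x a \linkS4class{CountSet}.
#' @param method \code{"cpm"} or \code{"none"}.
#' @return a numeric matrix with the dimensions and dimnames of
#'   \code{counts(x)}.
#' @export
normalizeCounts <- function(x, method = c("cpm", "none")) {
  stopifnot(methods::is(x, "CountSet"))
  method <- match.arg(method)
  cnt <- counts(x)
  mode(cnt) <- "double"
  if (method == "none") return(cnt)
  tot <- colSums(cnt)
  if (any(tot == 0))
    stop("zero total count in library: ",
         paste(colnames(cnt)[tot == 0], collapse = ", "))
  sweep(cnt, 2, tot / 1e6, "/")
}

#' Split genes into high- and low-expression strata
#'
#' Computes the grand mean m of the per-gene mean normalized count
#' across the supplied libraries; a gene is \code{high} when its
#' per-gene mean is strictly greater than \code{m * stratumFraction}
#' (default 1/10 of the mean over all detected genes), else \code{low}.
#'
#' @param norm numeric matrix of normalized counts (genes x the model's
#'   libraries), e.g. from \code{\link{normalizeCounts}}.
#' @param stratumFraction fraction of the grand mean that separates the
#'   strata.
#' @return named character vector (\code{"high"}/\code{"low"}) per gene.
#' @export
stratifyGenes <- function(norm, stratumFraction = 0.1) {
  stopifnot(is.matrix(norm), stratumFraction > 0)
  if (!nrow(norm)) {
    warning("empty input: no genes to stratify")
    return(stats::setNames(character(), character()))
  }
  gm <- rowMeans(norm)
  thr <- mean(gm) * stratumFraction
  message(sprintf("stratum threshold: mean count %.6g x %g = %.6g",
                  mean(gm), stratumFraction, thr))
  stats::setNames(ifelse(gm > thr, "high", "low"), rownames(norm))
}

#' Log2 fold change with a symmetric pseudocount
#'
#' \code{log2((diab + pseudocount) / (ctrl + pseudocount))}: positive
#' values mean higher expression in the diabetic library. The symmetric
#' pseudocount keeps the value finite when one side is zero and
#' preserves antisymmetry under swapping the two conditions.
#'
#' @param ctrl,diab non-negative normalized expression values
#'   (vectorized).
#' @param pseudocount count-scale offset added to both sides; must be
#'   positive if any input can be zero.
#' @return numeric vector of log2 fold changes.
#' @examples
#' log2FoldChange(100, 200, pseudocount = 0)  # exactly 1
#' @export
log2FoldChange <- function(ctrl, diab, pseudocount = 0.5) {
  stopifnot(all(ctrl >= 0), all(diab >= 0), pseudocount >= 0)
  if (pseudocount == 0 && any(ctrl == 0 & diab == 0))
    stop("log2 fold change undefined: both conditions zero with pseudocount 0")
  log2((diab + pseudocount) / (ctrl + pseudocount))
}

#' Classify a log2 fold change by stratum-specific cutoffs
#'
#' High-stratum genes are \code{up} when log2fc is strictly greater than
#' \code{highCutoff} (default 0.8) and \code{down} below its negation;
#' low-stratum genes use the stricter \code{lowCutoff} (default 2),
#' chosen to reduce the false-positive rate among weakly expressed
#' genes. Values exactly at a cutoff are \code{unchanged} (strict
#' inequalities).
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @param stratum character vector, \code{"high"}/\code{"low"} per gene.
#' @param highCutoff,lowCutoff positive cutoffs for the two strata.
#' @return character vector in \code{up}/\code{down}/\code{unchanged}.
#' @examples
#' classifyDE(c(1, 1), c("high", "low"))     # "up", "unchanged"
#' classifyDE(0.8, "high")                   # "unchanged" (strict >)
#' @export
classifyDE <- function(log2fc, stratum, highCutoff = 0.8, lowCutoff = 2) {
  stopifnot(length(log2fc) == length(stratum),
            all(stratum %in% .STRATA), highCutoff > 0, lowCutoff > 0)
  cut <- ifelse(stratum == "high", highCutoff, lowCutoff)
  ifelse(log2fc > cut, "up", ifelse(log2fc < -cut, "down", "unchanged"))
}

#' Stratified fold-change differential-expression calling
#'
#' Runs the full per-model procedure on a raw count table: detection
#' filter (summed reads strictly > \code{minReads}), library
#' normalization, stratification of the filtered genes at
#' \code{stratumFraction} of the mean per-gene count, log2 fold change
#' of diabetic over control, and stratum-specific cutoff classification
#' (\code{> highCutoff} for the high stratum, \code{> lowCutoff} for the
#' low stratum, strict, symmetric for down-regulation). With replicated
#' libraries the per-condition value is the mean of the condition's
#' normalized libraries.
#'
#' @param x a \linkS4class{CountSet} containing at least one control and
#'   one diabetic library for \code{model}.
#' @param model \code{"A"} or \code{"B"}.
#' @param minReads detection-filter minimum (strict).
#' @param stratumFraction high/low split point as a fraction of the mean
#'   per-gene count of the filtered set.
#' @param highCutoff,lowCutoff log2 fold-change cutoffs for the high and
#'   low stratum.
#' @param normalization \code{"cpm"} or \code{"none"}.
#' @param pseudocount symmetric offset for the fold change.
#' @return a \linkS4class{DEResult}.
#' @examples
#' sim <- simulateCounts(syntheticSpec(nGenes = 500, seed = 11))
#' res <- callDE(sim$counts, model = "A")
#' res
#' head(deGenes(res, "up"))
#' @export
callDE <- function(x, model, minReads = 10, stratumFraction = 0.1,
                   highCutoff = 0.8, lowCutoff = 2,
                   normalization = c("cpm", "none"), pseudocount = 0.5) {
  normalization <- match.arg(normalization)
  filt <- filterDetected(x, model, minReads = minReads)
  params <- list(model = model, minReads = minReads,
                 stratumFraction = stratumFraction, highCutoff = highCutoff,
                 lowCutoff = lowCutoff, normalization = normalization,
                 pseudocount = pseudocount,
                 seed = S4Vectors::metadata(x)$seed)
  if (!nrow(filt)) {
    return(methods::new("DEResult",
                        calls = S4Vectors::DataFrame(gene_id = character(),
                                                     ctrl = numeric(),
                                                     diab = numeric(),
                                                     stratum = character(),
                                                     log2fc = numeric(),
                                                     call = character()),
                        model = model, params = params))
  }
  norm <- normalizeCounts(filt, method = normalization)
  ctrlIdx <- modelLibraries(filt, model, "control")
  diabIdx <- modelLibraries(filt, model, "diabetic")
  ctrl <- rowMeans(norm[, ctrlIdx, drop = FALSE])
  diab <- rowMeans(norm[, diabIdx, drop = FALSE])
  stratum <- stratifyGenes(norm, stratumFraction = stratumFraction)
  lfc <- log2FoldChange(ctrl, diab, pseudocount = pseudocount)
  call <- classifyDE(lfc, stratum, highCutoff = highCutoff,
                     lowCutoff = lowCutoff)
  for (s in .STRATA)
    message(sprintf("model %s, %s stratum: %d up, %d down, %d unchanged",
                    model, s, sum(call == "up" & stratum == s),
                    sum(call == "down" & stratum == s),
                    sum(call == "unchanged" & stratum == s)))
  methods::new("DEResult",
               calls = S4Vectors::DataFrame(gene_id = rownames(norm),
                                            ctrl = unname(ctrl),
                                            diab = unname(diab),
                                            stratum = unname(stratum),
                                            log2fc = unname(lfc),
                                            call = unname(call)),
               model = model, params = params)
}
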