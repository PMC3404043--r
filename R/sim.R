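#' Parameters for the synthetic two-model count generator
#'
#' The defaults emulate the scale of a pooled-oocyte whole-transcriptome
#' experiment: 16,457 genes, one library of ~1e6 mapped reads per
#' condition, and a long-tailed (log-normal) baseline expression profile
#' calibrated so that roughly 8,792 genes carry strictly more than 10
#' summed reads per model. Planted differential expression echoes the
#' scale of a two-model type 1 diabetes comparison: ~7% of genes up and
#' ~4% down per model, with half of each model's DE genes shared between
#' the models.
#'
#' @param nGenes number of genes.
#' @param librarySize expected total reads per library.
#' @param dispersion negative-binomial dispersion phi (variance =
#'   mu + phi * mu^2); 0 gives Poisson noise.
#' @param fracDeUp,fracDeDown fractions of genes planted up-/down-regulated
#'   in each model.
#' @param lfcHigh,lfcLow planted |log2 fold change| for DE genes in the
#'   high and low expression stratum respectively.
#' @param fracShared fraction of each model's planted DE genes that is
#'   common to both models (same gene, same direction).
#' @param baselineMeanlog,baselineSdlog log-normal parameters of the
#'   baseline per-gene relative expression.
#' @param seed RNG seed.
#' @return a \linkS4class{SyntheticSpec}.
#' @examples
#' spec <- syntheticSpec(nGenes = 500, seed = 7)
#' @export
syntheticSpec <- function(nGenes = 16457L, librarySize = 1e6,
                          dispersion = 0.05, fracDeUp = 0.07,
                          fracDeDown = 0.04, lfcHigh = 1.5, lfcLow = 2.5,
                          fracShared = 0.5, baselineMeanlog = 0,
                          baselineSdlog = 2.12, seed = 1L) {
  for (nm in c("fracDeUp", "fracDeDown", "fracShared")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("parameter '", nm, "' must be a single value in [0, 1]")
  }
  if (fracDeUp + fracDeDown > 1)
    stop("parameters 'fracDeUp' + 'fracDeDown' must not exceed 1")
  if (dispersion < 0) stop("parameter 'dispersion' must be >= 0")
  methods::new("SyntheticSpec", nGenes = as.integer(nGenes),
               librarySize = librarySize, dispersion = dispersion,
               fracDeUp = fracDeUp, fracDeDown = fracDeDown,
               lfcHigh = lfcHigh, lfcLow = lfcLow, fracShared = fracShared,
               baselineMeanlog = baselineMeanlog, baselineSdlog = baselineSdlog,
               seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0(
    "SyntheticSpec: %d genes, library size %.3g, dispersion %.3g\n",
    "  planted DE per model: %.3g up / %.3g down (|lfc| %g high / %g low),",
    " %.0f%% shared\n  baseline lognormal(%g, %g), seed %d\n"),
    object@nGenes, object@librarySize, object@dispersion,
    object@fracDeUp, object@fracDeDown, object@lfcHigh, object@lfcLow,
    100 * object@fracShared, object@baselineMeanlog, object@baselineSdlog,
    object@seed))
  invisible(NULL)
})

.rcounts <- function(n, mu, phi) {
  if (phi == 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Simulate a two-model count table with known ground truth
#'
#' Draws baseline per-gene relative expression from a log-normal
#' distribution, plants up-/down-regulated genes per model
#' (multiplicative on the diabetic library's mean; effect size
#' \code{lfcHigh} or \code{lfcLow} by the gene's baseline stratum), and
#' samples negative-binomial counts for the four libraries control-A,
#' diabetic-A, control-B, diabetic-B. A fraction \code{fracShared} of
#' each model's DE genes is common to both models with the same
#' direction.
#'
#' The truth table records, per gene, the planted class per model
#' (\code{up}/\code{down}/\code{null}), the planted log2 fold change per
#' model, and the generation-time stratum (\code{high}/\code{low}),
#' computed from the expected baseline counts with the same rule the
#' caller applies: among genes whose expected summed count exceeds 10,
#' a gene is \code{high} when its expected count exceeds 1/10 of the
#' mean expected count.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param replicates libraries per condition (default 1, matching a
#'   pooled-sample design with one library per condition).
#' @return a list with elements \code{counts} (a
#'   \linkS4class{CountSet}) and \code{truth} (a data.frame with columns
#'   \code{gene_id}, \code{class_A}, \code{class_B}, \code{true_lfc_A},
#'   \code{true_lfc_B}, \code{stratum}).
#' @note Sets the session RNG seed from \code{spec}; identical specs
#'   give bit-identical output.
#' @examples
#' sim <- simulateCounts(syntheticSpec(nGenes = 200, seed = 3))
#' sim$counts
#' table(sim$truth$class_A)
#' @export
simulateCounts <- function(spec, replicates = 1L) {
  stopifnot(methods::is(spec, "SyntheticSpec"))
  methods::validObject(spec)
  n <- spec@nGenes
  set.seed(spec@seed)
  gid <- sprintf("g%05d", seq_len(n))

  x <- stats::rlnorm(n, spec@baselineMeanlog, spec@baselineSdlog)
  mu0 <- x / sum(x) * spec@librarySize

  # generation-time stratum from expected baseline counts
  det <- 2 * mu0 > 10
  m <- if (any(det)) mean(mu0[det]) else mean(mu0)
  stratum <- ifelse(mu0 > m / 10, "high", "low")

  nUp <- round(spec@fracDeUp * n)
  nDown <- round(spec@fracDeDown * n)
  nShUp <- round(spec@fracShared * nUp)
  nShDown <- round(spec@fracShared * nDown)
  need <- nShUp + nShDown + 2 * (nUp - nShUp) + 2 * (nDown - nShDown)
  if (need > n)
    stop("planted DE design needs ", need, " distinct genes but only ",
         n, " exist; lower fracDeUp/fracDeDown or raise fracShared")
  pool <- sample.int(n, need)
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  idx <- list(up_sh = take(nShUp), down_sh = take(nShDown),
              up_A = take(nUp - nShUp), down_A = take(nDown - nShDown),
              up_B = take(nUp - nShUp), down_B = take(nDown - nShDown))

  classOf <- function(up, down) {
    cl <- rep("null", n)
    cl[up] <- "up"
    cl[down] <- "down"
    cl
  }
  classA <- classOf(c(idx$up_sh, idx$up_A), c(idx$down_sh, idx$down_A))
  classB <- classOf(c(idx$up_sh, idx$up_B), c(idx$down_sh, idx$down_B))

  mag <- ifelse(stratum == "high", spec@lfcHigh, spec@lfcLow)
  lfcA <- ifelse(classA == "up", mag, ifelse(classA == "down", -mag, 0))
  lfcB <- ifelse(classB == "up", mag, ifelse(classB == "down", -mag, 0))

  nr <- as.integer(replicates)
  if (nr < 1L) stop("replicates must be >= 1")
  libMu <- list(ctrl_A = mu0, diab_A = mu0 * 2^lfcA,
                ctrl_B = mu0, diab_B = mu0 * 2^lfcB)
  cols <- list()
  for (lib in names(libMu)) {
    for (r in seq_len(nr)) {
      nm <- if (nr == 1L) lib else sprintf("%s_%d", lib, r)
      cols[[nm]] <- .rcounts(n, libMu[[lib]], spec@dispersion)
    }
  }
  cnt <- do.call(cbind, cols)
  rownames(cnt) <- gid
  design <- do.call(rbind, strsplit(rep(names(libMu), each = nr), "_"))
  cs <- CountSet(cnt,
                 model = design[, 2],
                 condition = ifelse(design[, 1] == "ctrl", "control", "diabetic"))
  S4Vectors::metadata(cs)$seed <- spec@seed
  truth <- data.frame(gene_id = gid, class_A = classA, class_B = classB,
                      true_lfc_A = lfcA, true_lfc_B = lfcB,
                      stratum = stratum, stringsAsFactors = FALSE)
  list(counts = cs, truth = truth)
}

#' Simulate a term annotation with planted enrichment
#'
#' Generates \code{nTerms} gene sets over the genes of a truth table.
#' The first \code{enrichedTerms} terms (accessions \code{SIM:0001},
#' \code{SIM:0002}, ...) sample true-DE genes of the chosen model with
#' \code{enrichmentOdds}-fold higher weight than null genes; the
#' remaining terms sample uniformly. \code{enrichmentOdds = Inf} draws
#' enriched-term members exclusively from true-DE genes.
#'
#' @param truth truth table from \code{\link{simulateCounts}}.
#' @param nTerms total number of terms (0 gives an empty annotation).
#' @param enrichedTerms number of terms with planted enrichment.
#' @param enrichmentOdds sampling-odds ratio (>= 1) of true-DE over null
#'   genes within enriched terms.
#' @param seed RNG seed.
#' @param model which model's DE truth drives the enrichment.
#' @param sizeRange inclusive range term sizes are drawn from.
#' @param namespace GO namespace assigned to every generated term.
#' @return a \linkS4class{TermAnnotation}.
#' @export
simulateAnnotation <- function(truth, nTerms = 50L, enrichedTerms = 0L,
                               enrichmentOdds = 10, seed = 1L,
                               model = c("A", "B"), sizeRange = c(10L, 200L),
                               namespace = "biological_process") {
  model <- match.arg(model)
  nTerms <- as.integer(nTerms)
  enrichedTerms <- as.integer(enrichedTerms)
  if (enrichmentOdds < 1) stop("parameter 'enrichmentOdds' must be >= 1")
  if (enrichedTerms < 0 || nTerms < enrichedTerms)
    stop("need nTerms >= enrichedTerms >= 0")
  if (nTerms == 0L)
    return(TermAnnotation(genes = stats::setNames(list(), character())))
  set.seed(as.integer(seed))
  genes <- truth$gene_id
  isDE <- truth[[paste0("class_", model)]] != "null"
  lo <- max(1L, sizeRange[1])
  hi <- min(length(genes), sizeRange[2])
  sizes <- sample(lo:hi, nTerms, replace = TRUE)
  sets <- vector("list", nTerms)
  for (i in seq_len(nTerms)) {
    if (i <= enrichedTerms) {
      if (is.infinite(enrichmentOdds)) {
        k <- min(sizes[i], sum(isDE))
        sets[[i]] <- sample(genes[isDE], k)
        sizes[i] <- k
      } else {
        w <- ifelse(isDE, enrichmentOdds, 1)
        sets[[i]] <- sample(genes, sizes[i], prob = w)
      }
    } else {
      sets[[i]] <- sample(genes, sizes[i])
    }
  }
  acc <- sprintf("SIM:%04d", seq_len(nTerms))
  names(sets) <- acc
  message(sprintf("simulated %d terms (%d enriched); sizes %d-%d",
                  nTerms, enrichedTerms, min(sizes), max(sizes)))
  TermAnnotation(genes = sets,
                 termName = stats::setNames(sprintf("synthetic term %d%s",
                                                    seq_len(nTerms),
                                                    ifelse(seq_len(nTerms) <= enrichedTerms,
                                                           " (planted)", "")), acc),
                 namespace = namespace)
}

#' Simulate qPCR validation measurements
#'
#' Produces, for a panel of genes, a qPCR-style log2 fold change equal
#' to the planted (true) log2 fold change plus Gaussian measurement
#' noise — emulating a relative-quantification read-out after the
#' delta-delta-Ct transform.
#'
#' @param truth truth table from \code{\link{simulateCounts}}.
#' @param genes gene ids of the validation panel.
#' @param noiseSd standard deviation of the measurement noise, log2
#'   units.
#' @param seed RNG seed.
#' @param model which model's planted fold changes to measure.
#' @return data.frame with columns \code{gene_id}, \code{true_lfc},
#'   \code{qpcr_lfc}.
#' @export
simulateQpcr <- function(truth, genes, noiseSd = 0.25, seed = 1L,
                         model = c("A", "B")) {
  model <- match.arg(model)
  missing <- setdiff(genes, truth$gene_id)
  if (length(missing))
    stop("gene id(s) not in truth table: ", paste(missing, collapse = ", "))
  set.seed(as.integer(seed))
  lfc <- truth[[paste0("true_lfc_", model)]][match(genes, truth$gene_id)]
  data.frame(gene_id = as.character(genes), true_lfc = lfc,
             qpcr_lfc = lfc + stats::rnorm(length(genes), 0, noiseSd),
             stringsAsFactors = FALSE)
}
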