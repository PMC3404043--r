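.PKG_VERSION <- function()
  as.character(utils::packageVersion("stratDE"))

.fmtNum <- function(x) formatC(x, digits = 6, format = "g")
.fmtP <- function(x) formatC(x, digits = 6, format = "e")

.bodyMd5 <- function(lines) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  unname(tools::md5sum(tmp))
}

# header comments record provenance: version, seed, thresholds, body checksum
.writeTable <- function(body, path, meta = list()) {
  hdr <- c(sprintf("#stratDE=%s", .PKG_VERSION()),
           vapply(names(meta), function(k)
             sprintf("#%s=%s", k, as.character(meta[[k]])), character(1)),
           sprintf("#body_md5=%s", .bodyMd5(body)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

.readTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  # comment header is the leading block of '#' lines only
  isHdr <- grepl("^#", lines)
  firstBody <- which(!isHdr)[1]
  isHdr <- if (is.na(firstBody)) rep(TRUE, length(lines))
           else seq_along(lines) < firstBody
  meta <- list()
  for (h in sub("^#", "", lines[isHdr])) {
    kv <- strsplit(h, "=", fixed = TRUE)[[1]]
    if (length(kv) >= 2)
      meta[[kv[1]]] <- paste(kv[-1], collapse = "=")
  }
  list(meta = meta, body = lines[!isHdr], offset = sum(isHdr))
}

.tsvSplit <- function(lines) strsplit(lines, "\t", fixed = TRUE)

# ---- count tables -----------------------------------------------------------

.DEFAULT_LIBRARY_SPEC <- data.frame(
  label = c("ctrl_A", "diab_A", "ctrl_B", "diab_B"),
  model = c("A", "A", "B", "B"),
  condition = c("control", "diabetic", "control", "diabetic"),
  stringsAsFactors = FALSE)

#' Default four-library design
#'
#' The library specification matching the standard two-model layout
#' \code{ctrl_A, diab_A, ctrl_B, diab_B}.
#'
#' @return data.frame with columns \code{label}, \code{model},
#'   \code{condition}.
#' @export
defaultLibrarySpec <- function() .DEFAULT_LIBRARY_SPEC

#' Read a count table from TSV
#'
#' Expects a tab-separated file whose first column is \code{gene_id}
#' and whose remaining columns are non-negative integer read counts,
#' one column per library. Leading \code{#} comment lines are ignored.
#' Malformed content is rejected with the offending file coordinates:
#' duplicated gene ids are reported with all their line numbers,
#' non-integer cells with row and column.
#'
#' @param path file path.
#' @param librarySpec data.frame with columns \code{label},
#'   \code{model}, \code{condition} assigning a design role to every
#'   count column; defaults to \code{\link{defaultLibrarySpec}}.
#' @return a \linkS4class{CountSet}.
#' @export
readCountTable <- function(path, librarySpec = defaultLibrarySpec()) {
  stopifnot(all(c("label", "model", "condition") %in% colnames(librarySpec)))
  tab <- .readTable(path)
  if (!length(tab$body)) stop("format error: empty file: ", path)
  cells <- .tsvSplit(tab$body)
  header <- cells[[1]]
  if (header[1] != "gene_id")
    stop("format error: first column must be 'gene_id', found '", header[1], "'")
  labels <- header[-1]
  if (!setequal(labels, librarySpec$label) || anyDuplicated(labels))
    stop("configuration error: file columns (",
         paste(labels, collapse = ", "),
         ") do not match the library spec labels (",
         paste(librarySpec$label, collapse = ", "), ")")
  rows <- cells[-1]
  lineNo <- tab$offset + 1 + seq_along(rows)
  bad <- which(lengths(rows) != length(header))
  if (length(bad))
    stop("format error: line ", lineNo[bad[1]], " has ",
         lengths(rows)[bad[1]], " fields, expected ", length(header))
  ids <- vapply(rows, `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("format error: duplicate gene id '", dup, "' on lines ",
         paste(lineNo[ids == dup], collapse = " and "))
  }
  cnt <- matrix(NA_integer_, nrow = length(rows), ncol = length(labels),
                dimnames = list(ids, labels))
  for (j in seq_along(labels)) {
    raw <- vapply(rows, `[`, character(1), j + 1L)
    ok <- grepl("^[0-9]+$", raw)
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop("format error: non-integer count '", raw[i], "' at line ",
           lineNo[i], ", column '", labels[j], "'")
    }
    cnt[, j] <- as.integer(raw)
  }
  spec <- librarySpec[match(labels, librarySpec$label), ]
  cs <- CountSet(cnt, model = spec$model, condition = spec$condition)
  if (!is.null(tab$meta$seed))
    S4Vectors::metadata(cs)$seed <- as.integer(tab$meta$seed)
  message(sprintf("read %d genes x %d libraries from %s",
                  nrow(cs), ncol(cs), path))
  cs
}

#' Write a count table to TSV
#'
#' @param x a \linkS4class{CountSet}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeCountTable <- function(x, path) {
  stopifnot(methods::is(x, "CountSet"))
  cnt <- counts(x)
  body <- c(paste(c("gene_id", colnames(cnt)), collapse = "\t"),
            paste(rownames(cnt),
                  apply(cnt, 1, paste, collapse = "\t"), sep = "\t"))
  meta <- list()
  if (!is.null(S4Vectors::metadata(x)$seed))
    meta$seed <- S4Vectors::metadata(x)$seed
  .writeTable(body, path, meta)
}

# ---- truth tables -----------------------------------------------------------

#' Write / read a simulation truth table
#'
#' TSV with columns \code{gene_id}, \code{class_A}, \code{class_B},
#' \code{true_lfc_A}, \code{true_lfc_B}, \code{stratum}.
#'
#' @param truth truth data.frame from \code{\link{simulateCounts}}.
#' @param path file path.
#' @return \code{writeTruthTable}: the path, invisibly;
#'   \code{readTruthTable}: the truth data.frame.
#' @export
writeTruthTable <- function(truth, path) {
  cols <- c("gene_id", "class_A", "class_B", "true_lfc_A", "true_lfc_B",
            "stratum")
  stopifnot(all(cols %in% colnames(truth)))
  body <- c(paste(cols, collapse = "\t"),
            paste(truth$gene_id, truth$class_A, truth$class_B,
                  .fmtNum(truth$true_lfc_A), .fmtNum(truth$true_lfc_B),
                  truth$stratum, sep = "\t"))
  .writeTable(body, path)
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(path) {
  tab <- .readTable(path)
  df <- utils::read.delim(text = tab$body, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "character",
                                         "numeric", "numeric", "character"))
  df
}

# ---- annotations (GMT dialect) ---------------------------------------------

#' Read a term annotation in GMT dialect
#'
#' Each line is \code{acc<TAB>name|namespace<TAB>gene1<TAB>gene2...}.
#' Duplicate accessions, empty gene lists and namespace tokens outside
#' the three GO namespaces are format errors.
#'
#' @param path GMT file path.
#' @return a \linkS4class{TermAnnotation} (without slim mapping; attach
#'   one via \code{\link{slimMap}<-} or \code{\link{readSlimMap}}).
#' @export
readAnnotation <- function(path) {
  tab <- .readTable(path)
  if (!length(tab$body))
    return(TermAnnotation(genes = stats::setNames(list(), character())))
  cells <- .tsvSplit(tab$body)
  lineNo <- tab$offset + seq_along(cells)
  genes <- list(); nm <- character(); ns <- character()
  for (i in seq_along(cells)) {
    f <- cells[[i]]
    if (length(f) < 3)
      stop("format error: empty gene list for term '", f[1],
           "' at line ", lineNo[i])
    acc <- f[1]
    if (acc %in% names(genes))
      stop("format error: term '", acc, "' listed twice (line ", lineNo[i], ")")
    desc <- strsplit(f[2], "|", fixed = TRUE)[[1]]
    if (length(desc) != 2 || !desc[2] %in% .NAMESPACES)
      stop("format error: line ", lineNo[i],
           ": description must be 'name|namespace' with namespace one of ",
           paste(.NAMESPACES, collapse = ", "))
    genes[[acc]] <- f[-(1:2)]
    nm[acc] <- desc[1]
    ns[acc] <- desc[2]
  }
  message(sprintf("read %d terms from %s", length(genes), path))
  TermAnnotation(genes = genes, termName = nm, namespace = ns)
}

#' Write a term annotation in GMT dialect
#'
#' @param annotation a \linkS4class{TermAnnotation}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeAnnotation <- function(annotation, path) {
  stopifnot(methods::is(annotation, "TermAnnotation"))
  acc <- names(annotation@genes)
  body <- vapply(acc, function(a)
    paste(c(a, paste0(annotation@termName[a], "|", annotation@namespace[a]),
            annotation@genes[[a]]), collapse = "\t"), character(1))
  .writeTable(unname(body), path)
}

#' Read / write a slim mapping table
#'
#' Two-column TSV \code{term<TAB>slim} mapping each term accession to
#' its slim parent accession.
#'
#' @param path file path.
#' @param slim named character vector (term -> slim accession).
#' @return \code{readSlimMap}: a named character vector suitable for
#'   \code{\link{slimMap}<-}.
#' @export
readSlimMap <- function(path) {
  tab <- .readTable(path)
  cells <- .tsvSplit(tab$body)
  if (length(cells) && identical(cells[[1]], c("term", "slim")))
    cells <- cells[-1]
  if (any(lengths(cells) != 2))
    stop("format error: slim map lines must have exactly 2 fields")
  stats::setNames(vapply(cells, `[`, character(1), 2),
                  vapply(cells, `[`, character(1), 1))
}

#' @rdname readSlimMap
#' @export
writeSlimMap <- function(slim, path) {
  body <- c("term\tslim", paste(names(slim), slim, sep = "\t"))
  .writeTable(body, path)
}

# ---- DE calls ---------------------------------------------------------------

#' Write / read stratified DE calls
#'
#' TSV with a commented header recording the package version, seed,
#' all calling thresholds and a checksum of the table body; columns
#' \code{gene_id}, \code{ctrl}, \code{diab}, \code{stratum},
#' \code{log2fc}, \code{call}. Floats are written with 6 significant
#' digits; discrete fields round-trip exactly and a written file
#' re-read and re-written is byte-identical.
#'
#' @param res a \linkS4class{DEResult}.
#' @param path file path.
#' @return \code{writeDECalls}: the path, invisibly;
#'   \code{readDECalls}: a \linkS4class{DEResult}.
#' @export
writeDECalls <- function(res, path) {
  stopifnot(methods::is(res, "DEResult"))
  cc <- res@calls
  body <- c("gene_id\tctrl\tdiab\tstratum\tlog2fc\tcall",
            if (nrow(cc))
              paste(cc$gene_id, .fmtNum(cc$ctrl), .fmtNum(cc$diab),
                    cc$stratum, .fmtNum(cc$log2fc), cc$call, sep = "\t"))
  meta <- res@params
  meta$model <- res@model
  meta <- meta[!vapply(meta, is.null, logical(1))]
  .writeTable(body, path, meta)
}

#' @rdname writeDECalls
#' @export
readDECalls <- function(path) {
  tab <- .readTable(path)
  df <- utils::read.delim(text = tab$body, stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "numeric", "character"))
  meta <- tab$meta
  num <- function(k) if (!is.null(meta[[k]])) as.numeric(meta[[k]]) else NULL
  params <- list(model = meta$model, minReads = num("minReads"),
                 stratumFraction = num("stratumFraction"),
                 highCutoff = num("highCutoff"), lowCutoff = num("lowCutoff"),
                 normalization = meta$normalization,
                 pseudocount = num("pseudocount"), seed = num("seed"))
  params <- params[!vapply(params, is.null, logical(1))]
  methods::new("DEResult",
               calls = S4Vectors::DataFrame(gene_id = df$gene_id,
                                            ctrl = df$ctrl, diab = df$diab,
                                            stratum = df$stratum,
                                            log2fc = df$log2fc,
                                            call = df$call),
               model = if (!is.null(meta$model)) meta$model else "A",
               params = params)
}

# ---- enrichment tables ------------------------------------------------------

#' Write / read an enrichment result table
#'
#' TSV with columns \code{acc}, \code{name}, \code{namespace}, \code{k},
#' \code{n}, \code{K}, \code{N}, \code{p}, \code{q}; p-values in
#' scientific notation with 6 significant digits. An empty result is a
#' valid header-only file.
#'
#' @param enrichment data.frame from \code{\link{fisherEnrichment}}.
#' @param path file path.
#' @return \code{writeEnrichment}: the path, invisibly;
#'   \code{readEnrichment}: the enrichment data.frame.
#' @export
writeEnrichment <- function(enrichment, path) {
  cols <- c("acc", "name", "namespace", "k", "n", "K", "N", "p", "q")
  stopifnot(all(cols %in% colnames(enrichment)))
  body <- c(paste(cols, collapse = "\t"),
            if (nrow(enrichment))
              paste(enrichment$acc, enrichment$name, enrichment$namespace,
                    enrichment$k, enrichment$n, enrichment$K, enrichment$N,
                    .fmtP(enrichment$p), .fmtP(enrichment$q), sep = "\t"))
  .writeTable(body, path)
}

#' @rdname writeEnrichment
#' @export
readEnrichment <- function(path) {
  tab <- .readTable(path)
  df <- utils::read.delim(text = tab$body, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "character",
                                         "integer", "integer", "integer",
                                         "integer", "numeric", "numeric"))
  df
}

# ---- model comparisons ------------------------------------------------------

#' Write / read a model comparison
#'
#' One row per gene with its overlap class; the per-class summary is
#' recomputed on read.
#'
#' @param comparison a \linkS4class{ModelComparison}.
#' @param path file path.
#' @return \code{writeComparison}: the path, invisibly;
#'   \code{readComparison}: a \linkS4class{ModelComparison}.
#' @export
writeComparison <- function(comparison, path) {
  stopifnot(methods::is(comparison, "ModelComparison"))
  cls <- comparison@classes
  body <- c("gene_id\tclass",
            if (length(cls)) paste(names(cls), cls, sep = "\t"))
  .writeTable(body, path)
}

#' @rdname writeComparison
#' @export
readComparison <- function(path) {
  tab <- .readTable(path)
  df <- utils::read.delim(text = tab$body, stringsAsFactors = FALSE,
                          colClasses = c("character", "character"))
  cls <- stats::setNames(df$class, df$gene_id)
  summ <- vapply(.COMPARISON_CLASSES, function(cc) sum(cls == cc), integer(1))
  methods::new("ModelComparison", classes = cls, summary = summ)
}

#' Write a KEGG color-map upload table
#'
#' Two-column, header-less \code{gene_id<TAB>color} table as accepted by
#' KEGG pathway color-mapping uploads.
#'
#' @param colorMap data.frame from \code{\link{assignColorClasses}}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeColorMap <- function(colorMap, path) {
  stopifnot(all(c("gene_id", "color") %in% colnames(colorMap)))
  writeLines(paste(colorMap$gene_id, colorMap$color, sep = "\t"), path)
  invisible(path)
}
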