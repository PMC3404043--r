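test_that("overlap classes follow set intersection on a worked example", {
  a <- makeDEResult(c("g1", "g2", "g3", "g4"),
                    c("up", "up", "unchanged", "unchanged"), "A")
  b <- makeDEResult(c("g2", "g3", "g4", "g5"),
                    c("up", "up", "unchanged", "unchanged"), "B")
  cmp <- compareModels(a, b)
  s <- comparisonSummary(cmp)
  expect_identical(s[["up-both"]], 1L)     # g2
  expect_identical(s[["up-A-only"]], 1L)   # g1
  expect_identical(s[["up-B-only"]], 1L)   # g3
  expect_identical(s[["unchanged"]], 2L)   # g4, g5
  expect_identical(comparisonClasses(cmp)[["g2"]], "up-both")
})

test_that("disjoint DE sets produce only '-only' classes", {
  a <- makeDEResult(c("g1", "g2"), c("up", "down"), "A")
  b <- makeDEResult(c("g3", "g4"), c("up", "down"), "B")
  s <- comparisonSummary(compareModels(a, b))
  expect_identical(s[["up-both"]], 0L)
  expect_identical(s[["down-both"]], 0L)
  expect_identical(s[["up-A-only"]], 1L)
  expect_identical(s[["down-B-only"]], 1L)
})

test_that("direction-discordant genes are reported apart, never as shared", {
  a <- makeDEResult("g1", "up", "A")
  b <- makeDEResult("g1", "down", "B")
  cmp <- compareModels(a, b)
  expect_identical(comparisonClasses(cmp)[["g1"]], "discordant")
  expect_identical(comparisonSummary(cmp)[["up-both"]], 0L)
  expect_identical(comparisonSummary(cmp)[["down-both"]], 0L)
})

test_that("classes partition the union and match a set-algebra reference", {
  set.seed(12)
  for (i in 1:20) {
    genesA <- sprintf("g%03d", sample(1:120, 60))
    genesB <- sprintf("g%03d", sample(1:120, 60))
    callsA <- sample(c("up", "down", "unchanged"), 60, replace = TRUE)
    callsB <- sample(c("up", "down", "unchanged"), 60, replace = TRUE)
    cmp <- compareModels(makeDEResult(genesA, callsA, "A"),
                         makeDEResult(genesB, callsB, "B"))
    cls <- comparisonClasses(cmp)
    expect_setequal(names(cls), union(genesA, genesB))
    expect_identical(sum(comparisonSummary(cmp)), length(cls))
    # reference classes from plain set algebra
    upA <- genesA[callsA == "up"]; dnA <- genesA[callsA == "down"]
    upB <- genesB[callsB == "up"]; dnB <- genesB[callsB == "down"]
    ref <- vapply(names(cls), function(g) {
      a <- if (g %in% upA) "u" else if (g %in% dnA) "d" else "n"
      b <- if (g %in% upB) "u" else if (g %in% dnB) "d" else "n"
      switch(paste0(a, b),
             uu = "up-both", dd = "down-both",
             ud = "discordant", du = "discordant",
             un = "up-A-only", dn = "down-A-only",
             nu = "up-B-only", nd = "down-B-only", nn = "unchanged")
    }, character(1))
    expect_identical(cls, ref)
    expect_lte(comparisonSummary(cmp)[["up-both"]],
               min(length(upA), length(upB)))
  }
})

test_that("color classes are the six-color KEGG legend, a bijection", {
  a <- makeDEResult(paste0("g", 1:6),
                    c("up", "down", "up", "down", "unchanged", "unchanged"), "A")
  b <- makeDEResult(paste0("g", 1:6),
                    c("up", "down", "unchanged", "unchanged", "up", "down"), "B")
  cmap <- assignColorClasses(compareModels(a, b))
  got <- setNames(cmap$color, cmap$gene_id)
  expect_identical(got[["g1"]], "red")      # up in both
  expect_identical(got[["g2"]], "blue")     # down in both
  expect_identical(got[["g3"]], "orange")   # up uniquely in A (STZ-like)
  expect_identical(got[["g4"]], "purple")   # down uniquely in A
  expect_identical(got[["g5"]], "yellow")   # up uniquely in B (NOD-like)
  expect_identical(got[["g6"]], "green")    # down uniquely in B
  expect_identical(anyDuplicated(cmap$color), 0L)
  # unchanged and discordant genes carry no color
  a2 <- makeDEResult(c("gu", "gd"), c("unchanged", "up"), "A")
  b2 <- makeDEResult(c("gu", "gd"), c("unchanged", "down"), "B")
  cmap2 <- assignColorClasses(compareModels(a2, b2))
  expect_identical(nrow(cmap2), 0L)
})

test_that("concordance handles exact, negated and degenerate inputs", {
  seq <- data.frame(gene_id = paste0("g", 1:6), log2fc = c(-2, -1, 0, 1, 2, 3))
  qp <- data.frame(gene_id = paste0("g", 1:6), qpcr_lfc = c(-2, -1, 0, 1, 2, 3))
  expect_equal(concordanceR(qpcrConcordance(seq, qp)), 1.0)
  qp$qpcr_lfc <- -qp$qpcr_lfc
  expect_equal(concordanceR(qpcrConcordance(seq, qp)), -1.0)
  expect_error(qpcrConcordance(seq[1:2, ], qp), "insufficient|shared")
  qp$qpcr_lfc <- 5
  expect_error(qpcrConcordance(seq, qp), "zero variance")
})

test_that("Pearson r is invariant under positive affine transforms", {
  set.seed(3)
  seq <- data.frame(gene_id = paste0("g", 1:10), log2fc = rnorm(10))
  qp <- data.frame(gene_id = paste0("g", 1:10),
                   qpcr_lfc = seq$log2fc + rnorm(10, 0, 0.3))
  r0 <- concordanceR(qpcrConcordance(seq, qp))
  qp$qpcr_lfc <- 2.5 * qp$qpcr_lfc + 7
  expect_equal(concordanceR(qpcrConcordance(seq, qp)), r0)
  seq$log2fc <- 0.1 * seq$log2fc - 3
  expect_equal(concordanceR(qpcrConcordance(seq, qp)), r0)
})

test_that("simulated validation panels reach high concordance", {
  sim <- simulateCounts(syntheticSpec(nGenes = 2000, lfcHigh = 3, lfcLow = 3,
                                      dispersion = 0.05, seed = 29))
  res <- suppressMessages(callDE(sim$counts, "A"))
  panel <- c(head(deGenes(res, "up"), 5), head(deGenes(res, "down"), 5))
  qp <- simulateQpcr(sim$truth, panel, noiseSd = 0.25, seed = 31)
  conc <- qpcrConcordance(res, qp)
  expect_gte(concordanceR(conc), 0.95)
  expect_identical(nrow(concordancePairs(conc)), 10L)
})
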