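test_that("detection filter uses a strict 'more than' inequality on summed reads", {
  cnt <- matrix(c(2L, 3L, 0L, 0L,   # sum A = 5
                  5L, 5L, 0L, 0L,   # sum A = 10
                  6L, 5L, 0L, 1L),  # sum A = 11
                nrow = 3, byrow = TRUE,
                dimnames = list(c("gLo", "gAt", "gHi"),
                                c("ctrl_A", "diab_A", "ctrl_B", "diab_B")))
  cs <- CountSet(cnt, model = c("A", "A", "B", "B"),
                 condition = c("control", "diabetic", "control", "diabetic"))
  kept <- suppressMessages(filterDetected(cs, "A", minReads = 10))
  expect_identical(rownames(kept), "gHi")
  expect_identical(ncol(kept), 2L)  # only model A libraries retained
})

test_that("filter at minReads = 0 keeps every expressed gene", {
  cnt <- counts(randomCountSet(nGenes = 100, seed = 2, mu = 30)) + 1L
  cs <- CountSet(cnt, model = c("A", "A", "B", "B"),
                 condition = c("control", "diabetic", "control", "diabetic"))
  kept <- suppressMessages(filterDetected(cs, "A", minReads = 0))
  expect_identical(rownames(kept), rownames(cs))
})

test_that("raising the filter threshold can only shrink the retained set", {
  for (s in 1:10) {
    cs <- randomCountSet(nGenes = 200, seed = s, mu = 8)
    k10 <- rownames(suppressMessages(filterDetected(cs, "A", minReads = 10)))
    k20 <- rownames(suppressMessages(suppressWarnings(
      filterDetected(cs, "A", minReads = 20))))
    # brute-force reference sets from the raw matrix
    sums <- rowSums(counts(cs)[, 1:2])
    expect_setequal(k10, names(sums)[sums > 10])
    expect_setequal(k20, names(sums)[sums > 20])
    expect_true(all(k20 %in% k10))
  }
})

test_that("cpm normalization matches its definition and edgeR's computation", {
  cs <- tinyCountSet()
  norm <- normalizeCounts(cs, "cpm")
  expect_equal(colSums(norm), setNames(rep(1e6, 4), colnames(cs)))
  skip_if_not_installed("edgeR")
  ref <- edgeR::cpm(counts(cs), lib.size = colSums(counts(cs)))
  expect_equal(norm, ref, ignore_attr = TRUE)
})

test_that("normalization 'none' is the identity and cpm equalizes depth", {
  cs <- tinyCountSet()
  expect_equal(normalizeCounts(cs, "none"), counts(cs), ignore_attr = TRUE)
  # depths 1e6 and 2e6, gene counts (10, 20) -> cpm (10, 10), lfc 0
  cnt <- matrix(c(10L, 20L, 999990L, 1999980L), nrow = 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), c("ctrl_A", "diab_A")))
  cs2 <- CountSet(cnt, model = c("A", "A"),
                  condition = c("control", "diabetic"))
  norm <- normalizeCounts(cs2, "cpm")
  expect_equal(unname(norm["g1", ]), c(10, 10))
  expect_equal(log2FoldChange(norm["g1", 1], norm["g1", 2], 0), 0)
})

test_that("cpm refuses a zero-total library and names it", {
  cnt <- matrix(c(0L, 5L), nrow = 1,
                dimnames = list("g1", c("ctrl_A", "diab_A")))
  cs <- CountSet(cnt, model = c("A", "A"),
                 condition = c("control", "diabetic"))
  expect_error(normalizeCounts(cs, "cpm"), "ctrl_A")
})

test_that("stratification follows the 1/10-of-mean rule", {
  # identical counts: every gene sits at the mean, far above mean/10
  eq <- matrix(50, nrow = 5, ncol = 2,
               dimnames = list(paste0("g", 1:5), c("c", "d")))
  expect_true(all(suppressMessages(stratifyGenes(eq)) == "high"))
  # a single gene always exceeds 1/10 of its own mean
  one <- matrix(c(3, 5), nrow = 1, dimnames = list("g1", c("c", "d")))
  expect_identical(unname(suppressMessages(stratifyGenes(one))), "high")
})

test_that("stratification equals an independent recomputation on random tables", {
  for (s in 1:5) {
    set.seed(s)
    norm <- matrix(rlnorm(2000, 2, 1.8), ncol = 2,
                   dimnames = list(sprintf("g%04d", 1:1000), c("c", "d")))
    got <- suppressMessages(stratifyGenes(norm, 0.1))
    # reference coded directly from the rule's wording
    perGene <- (norm[, 1] + norm[, 2]) / 2
    ref <- ifelse(perGene > mean(perGene) * (1 / 10), "high", "low")
    expect_identical(unname(got), unname(ref))
  }
})

test_that("log2 fold change is exact and antisymmetric", {
  expect_identical(log2FoldChange(100, 100, 0.5), 0)
  expect_identical(log2FoldChange(100, 200, 0), 1)
  set.seed(1)
  x <- runif(100, 0, 500)
  y <- runif(100, 0, 500)
  expect_equal(log2FoldChange(x, y, 0.5), -log2FoldChange(y, x, 0.5))
  expect_error(log2FoldChange(0, 0, pseudocount = 0), "undefined")
})

test_that("cutoff classification is strict and stratum-specific", {
  expect_identical(classifyDE(1.0, "high"), "up")
  expect_identical(classifyDE(1.0, "low"), "unchanged")
  expect_identical(classifyDE(0.8, "high"), "unchanged")
  expect_identical(classifyDE(2.0, "low"), "unchanged")
  expect_identical(classifyDE(-0.8, "high"), "unchanged")
  expect_identical(classifyDE(-0.81, "high"), "down")
  expect_identical(classifyDE(2.01, "low"), "up")
})

test_that("calls partition the filtered genes and respect swap symmetry", {
  cs <- randomCountSet(nGenes = 500, seed = 31)
  res <- suppressMessages(callDE(cs, "A"))
  cc <- deCalls(res)
  expect_identical(nrow(cc),
                   nrow(suppressMessages(filterDetected(cs, "A"))))
  expect_identical(sum(cc$call == "up") + sum(cc$call == "down") +
                     sum(cc$call == "unchanged"), nrow(cc))
  # swap control and diabetic labels: up and down must exchange exactly
  swapped <- cs
  cd <- SummarizedExperiment::colData(swapped)
  cd$condition <- ifelse(cd$condition == "control", "diabetic", "control")
  SummarizedExperiment::colData(swapped) <- cd
  res2 <- suppressMessages(callDE(swapped, "A"))
  cc2 <- deCalls(res2)
  expect_identical(cc$gene_id, cc2$gene_id)
  expect_identical(cc$stratum, cc2$stratum)
  expect_equal(cc$log2fc, -cc2$log2fc)
  expect_identical(cc$call == "up", cc2$call == "down")
})

test_that("the stricter low-stratum cutoff lowers the null false-positive rate", {
  spec <- syntheticSpec(nGenes = 3000, fracDeUp = 0, fracDeDown = 0,
                        dispersion = 0.05, seed = 17)
  sim <- simulateCounts(spec)
  loose <- suppressMessages(callDE(sim$counts, "A", lowCutoff = 0.8))
  strict <- suppressMessages(callDE(sim$counts, "A", lowCutoff = 2))
  low <- deCalls(strict)$stratum == "low"
  fprStrict <- mean(deCalls(strict)$call[low] != "unchanged")
  fprLoose <- mean(deCalls(loose)$call[low] != "unchanged")
  expect_lte(fprStrict, fprLoose)
})
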