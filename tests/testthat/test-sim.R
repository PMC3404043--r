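test_that("identical specs give bit-identical output", {
  spec <- syntheticSpec(nGenes = 400, seed = 42)
  a <- simulateCounts(spec)
  b <- simulateCounts(spec)
  expect_identical(counts(a$counts), counts(b$counts))
  expect_identical(a$truth, b$truth)
})

test_that("null spec plants nothing and every gene has one truth record", {
  spec <- syntheticSpec(nGenes = 300, fracDeUp = 0, fracDeDown = 0,
                        dispersion = 0, seed = 7)
  sim <- simulateCounts(spec)
  expect_identical(nrow(sim$truth), nrow(sim$counts))
  expect_setequal(sim$truth$gene_id, rownames(sim$counts))
  expect_true(all(sim$truth$class_A == "null"))
  expect_true(all(sim$truth$class_B == "null"))
  expect_true(all(sim$truth$true_lfc_A == 0))
})

test_that("invalid spec fractions raise errors naming the field", {
  expect_error(syntheticSpec(fracDeUp = 1.2), "fracDeUp")
  expect_error(syntheticSpec(fracShared = -0.1), "fracShared")
  expect_error(syntheticSpec(fracDeUp = 0.6, fracDeDown = 0.6),
               "fracDeUp.*fracDeDown")
  expect_error(syntheticSpec(dispersion = -1), "dispersion")
})

test_that("planted fold changes are realized in expectation", {
  # strong planted effects, replicated libraries, low dispersion
  spec <- syntheticSpec(nGenes = 600, librarySize = 3e5, dispersion = 0.01,
                        fracDeUp = 0.1, fracDeDown = 0.1, lfcHigh = 2,
                        lfcLow = 2, fracShared = 1, seed = 13)
  sim <- simulateCounts(spec, replicates = 20)
  cnt <- counts(sim$counts)
  ctrlA <- rowMeans(cnt[, modelLibraries(sim$counts, "A", "control")])
  diabA <- rowMeans(cnt[, modelLibraries(sim$counts, "A", "diabetic")])
  up <- sim$truth$class_A == "up" & ctrlA > 50
  expect_gt(sum(up), 5)
  obs <- log2(diabA[up] / ctrlA[up])
  expect_true(all(abs(obs - 2) < 0.5))
})

test_that("per-gene mean counts converge to the documented baseline mean", {
  # the generator's recipe is documented: lognormal baseline scaled to the
  # library size; replay it independently and check the law of large numbers
  spec <- syntheticSpec(nGenes = 300, librarySize = 2e5, dispersion = 0,
                        fracDeUp = 0, fracDeDown = 0, seed = 5)
  sim <- simulateCounts(spec, replicates = 25)
  set.seed(5)
  x <- rlnorm(300, 0, 2.12)
  mu0 <- x / sum(x) * 2e5
  obs <- rowMeans(counts(sim$counts))
  big <- mu0 > 20
  expect_gt(sum(big), 30)
  expect_lt(median(abs(obs[big] - mu0[big]) / mu0[big]), 0.05)
})

test_that("shared planted DE genes agree in direction across models", {
  spec <- syntheticSpec(nGenes = 1000, fracDeUp = 0.1, fracDeDown = 0.1,
                        fracShared = 0.6, seed = 3)
  sim <- simulateCounts(spec)
  tr <- sim$truth
  shared <- tr$class_A != "null" & tr$class_B != "null"
  expect_true(all(tr$class_A[shared] == tr$class_B[shared]))
  nUpA <- sum(tr$class_A == "up")
  expect_equal(sum(shared & tr$class_A == "up") / nUpA, 0.6, tolerance = 0.02)
})

test_that("annotation generator honours its parameter contract", {
  sim <- simulateCounts(syntheticSpec(nGenes = 400, seed = 9))
  expect_error(simulateAnnotation(sim$truth, enrichmentOdds = 0.5),
               "enrichmentOdds")
  expect_error(simulateAnnotation(sim$truth, nTerms = 2, enrichedTerms = 3))
  empty <- simulateAnnotation(sim$truth, nTerms = 0)
  expect_s4_class(empty, "TermAnnotation")
  expect_length(termAccs(empty), 0)
  # empty annotation flows through enrichment as an empty result
  res <- suppressMessages(callDE(sim$counts, "A"))
  enr <- fisherEnrichment(deGenes(res), deUniverse(res), empty)
  expect_identical(nrow(enr), 0L)
})

test_that("infinite enrichment odds draw members exclusively from true-DE genes", {
  sim <- simulateCounts(syntheticSpec(nGenes = 800, fracDeUp = 0.1,
                                      fracDeDown = 0.05, seed = 21))
  ann <- suppressMessages(
    simulateAnnotation(sim$truth, nTerms = 3, enrichedTerms = 1,
                       enrichmentOdds = Inf, seed = 2))
  de <- sim$truth$gene_id[sim$truth$class_A != "null"]
  planted <- termGenes(ann, "SIM:0001")
  expect_true(all(planted %in% de))
  # its p-value is the minimal achievable for its margins: k = K
  universe <- sim$truth$gene_id
  enr <- fisherEnrichment(de, universe, ann)
  row <- enr[enr$acc == "SIM:0001", ]
  expect_identical(row$k, row$K)
  expect_equal(row$p,
               oracleHyperTail(row$K, row$n, row$N)[row$K + 1],
               tolerance = 1e-12)
})

test_that("qPCR simulator is exact at zero noise and flags unknown genes", {
  sim <- simulateCounts(syntheticSpec(nGenes = 300, fracDeUp = 0.2, seed = 4))
  panel <- head(sim$truth$gene_id[sim$truth$class_A == "up"], 8)
  qp <- simulateQpcr(sim$truth, panel, noiseSd = 0, seed = 1)
  expect_identical(qp$qpcr_lfc, qp$true_lfc)
  expect_error(simulateQpcr(sim$truth, c(panel, "nope1", "nope2")),
               "nope1.*nope2")
})

test_that("a 10-gene panel at noise 0.25 almost always reaches r >= 0.95", {
  # Monte-Carlo: truth fold changes spanning +/-3 log2 units
  truth <- data.frame(gene_id = sprintf("g%02d", 1:10),
                      class_A = "up", class_B = "null",
                      true_lfc_A = seq(-3, 3, length.out = 10),
                      true_lfc_B = 0, stratum = "high",
                      stringsAsFactors = FALSE)
  hits <- 0L
  for (s in 1:1000) {
    qp <- simulateQpcr(truth, truth$gene_id, noiseSd = 0.25, seed = s)
    if (cor(qp$true_lfc, qp$qpcr_lfc) >= 0.95) hits <- hits + 1L
  }
  expect_gte(hits, 950L)
})
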