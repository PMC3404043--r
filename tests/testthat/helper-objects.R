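# small in-code fixtures shared across test files

tinyCountSet <- function() {
  cnt <- matrix(c(12L, 30L, 5L, 8L,
                  40L, 10L, 7L, 9L,
                  100L, 210L, 55L, 60L),
                nrow = 3, byrow = TRUE,
                dimnames = list(c("Dnmt1", "Mbd3", "Zar1"),
                                c("ctrl_A", "diab_A", "ctrl_B", "diab_B")))
  CountSet(cnt, model = c("A", "A", "B", "B"),
           condition = c("control", "diabetic", "control", "diabetic"))
}

randomCountSet <- function(nGenes = 1000, seed = 1, mu = 60, phi = 0.2) {
  set.seed(seed)
  base <- rlnorm(nGenes, log(mu), 1.5)
  cnt <- sapply(1:4, function(i) rnbinom(nGenes, mu = base, size = 1 / phi))
  dimnames(cnt) <- list(sprintf("g%04d", seq_len(nGenes)),
                        c("ctrl_A", "diab_A", "ctrl_B", "diab_B"))
  CountSet(cnt, model = c("A", "A", "B", "B"),
           condition = c("control", "diabetic", "control", "diabetic"))
}

# build a DEResult directly from call assignments (for comparison tests)
makeDEResult <- function(genes, calls, model) {
  methods::new("DEResult",
               calls = S4Vectors::DataFrame(
                 gene_id = genes,
                 ctrl = rep(100, length(genes)),
                 diab = rep(100, length(genes)),
                 stratum = rep("high", length(genes)),
                 log2fc = ifelse(calls == "up", 1.5,
                                 ifelse(calls == "down", -1.5, 0)),
                 call = calls),
               model = model, params = list())
}

tinyAnnotation <- function() {
  TermAnnotation(
    genes = list("GO:0000001" = c("g1", "g2", "g3"),
                 "GO:0000002" = c("g3", "g4"),
                 "GO:0000003" = c("g5", "g6", "g7", "g8")),
    termName = c("GO:0000001" = "alpha", "GO:0000002" = "beta",
                 "GO:0000003" = "gamma"),
    namespace = c("GO:0000001" = "biological_process",
                  "GO:0000002" = "biological_process",
                  "GO:0000003" = "cellular_component"))
}

# independent upper-tail hypergeometric probability by direct summation
oracleHyperTail <- function(K, n, N) {
  m <- min(K, n)
  j <- 0:m
  terms <- choose(K, j) * choose(N - K, n - j) / choose(N, n)
  rev(cumsum(rev(terms)))  # element i+1 is P(X >= i)
}
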