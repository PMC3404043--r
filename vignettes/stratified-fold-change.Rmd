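---
title: "Stratified fold-change DE calling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified fold-change DE calling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratDE)
```

## The analysis problem

Pooled-oocyte whole-transcriptome experiments commonly sequence a
single library per condition: tens of MII oocytes are lysed together,
their mRNA amplified and sequenced, and the mapped-read count per
transcript taken as its expression level. With one library per
condition and per disease model (a chemically induced STZ-like model
"A" and a spontaneous genetic NOD-like model "B"), there is no
within-condition variance to estimate, so dispersion-based tests
(edgeR/DESeq2-style) are not applicable. The procedure implemented here
is a deterministic decision rule on the two counts each gene has per
model, designed around one empirical fact: the sampling noise of a
fold change grows as counts shrink, so lowly expressed genes need a
stricter cutoff to keep the false-positive rate acceptable.

## The calling procedure

For one model with control library $c$ and diabetic library $d$:

1. **Detection filter.** Keep gene $g$ iff $c_g + d_g > 10$ (strict,
   on raw counts). Summing the model's two libraries is the least
   arbitrary reading of a per-gene read-count minimum when the
   source protocol does not name a library; a per-library minimum can
   be emulated by raising `minReads`.
2. **Normalization.** Default `cpm` rescales each library to $10^6$
   total counts over the filtered genes. With one library per
   condition at similar depth this shifts every log2 fold change by
   the same constant, so it changes nothing qualitatively;
   `normalization = "none"` reproduces the literal raw-count
   procedure. `cpm` is the default because it stays correct under
   unequal sequencing depth.
3. **Stratification.** With $m$ the mean over filtered genes of the
   per-gene mean normalized count across the model's libraries, gene
   $g$ is *high* iff its per-gene mean exceeds $m/10$
   (`stratumFraction = 0.1`), else *low*. The mean is computed
   **after** filtering: "all detected genes" is read as the
   filter-passing set, since genes at or below 10 reads are explicitly
   not "detected". Each model is stratified independently.
4. **Fold change.** $\mathrm{lfc}_g = \log_2\!\frac{d_g +
   \varepsilon}{c_g + \varepsilon}$ with symmetric pseudocount
   $\varepsilon = 0.5$. The pseudocount keeps post-filter genes that
   are zero in one library finite while preserving antisymmetry under
   swapping conditions; $\varepsilon = 0$ recovers exact textbook
   ratios for strictly positive counts.
5. **Calling.** High stratum: up iff $\mathrm{lfc} > 0.8$, down iff
   $\mathrm{lfc} < -0.8$. Low stratum: the same with cutoff $2$. All
   inequalities are strict ("more than", "bigger than"), so a fold
   change exactly at a cutoff is *unchanged*. Up/down/unchanged
   partition the filtered set by construction.

The rationale for the stratum-specific cutoff is directly testable: on
a null simulation (no planted effects, NB dispersion 0.05) the
fraction of low-stratum genes exceeding cutoff 2 is an order of
magnitude below the fraction exceeding 0.8 (~0.02–0.04 versus ~0.33 at
the default conditions; recomputed at run time by
`scripts/acceptance.R`, never assumed).

## Enrichment

`fisherEnrichment` performs one-sided over-representation: for each
term, $p = P(X \ge k)$ for hypergeometric $X$ with $K$ annotated genes
in a universe of $N$ and a DE list of $n$. Choices made where the
procedure was open:

* **Universe.** The model's filter-passing gene set (`deUniverse`),
  not the whole genome: the test must condition on which genes were
  detectable in the experiment. Published per-term p-values from any
  specific study cannot be recomputed without its exact universe and
  gene lists, which is why the package's checks are property-based
  (closed-form oracle agreement, planted-term recovery) rather than
  table look-ups.
* **Sidedness.** One-sided upper tail by default — the question asked
  is "enrichment"; `alternative = "two.sided"` delegates to
  `fisher.test` for completeness.
* **Multiple testing.** Raw p-values by default (the convention in the
  tables this mirrors, where many reported values exceed 0.01);
  Benjamini–Hochberg via `adjust = "bh"`.
* The implementation uses `stats::phyper`; the test suite verifies it
  against independent direct summation of
  $\binom{K}{j}\binom{N-K}{n-j}/\binom{N}{n}$ for **all** margins with
  $N \le 50$ to $10^{-12}$, and against `fisher.test` on random
  tables.

GO-slim collapsing (`collapseToSlim`) takes the union of member genes
over all terms mapping to each slim target. The slim mapping is
supplied as an explicit term-to-slim table; the package deliberately
does not parse ontology graphs or propagate ancestors — a mitochondria
-style cellular-component analysis is just `fisherEnrichment` of the
shared-DE set against a (possibly slim-collapsed)
cellular-component annotation.

## Cross-model comparison and validation

`compareModels` partitions the union of both models' filtered sets
into eight disjoint classes. A gene up in one model and down in the
other is reported as `discordant` — surfaced explicitly rather than
silently folded into the "-only" classes, since overlap figures
usually leave this case unstated. The six shared/unique classes map
bijectively onto the KEGG color legend (red/blue both-up/both-down,
yellow/green unique to model B, orange/purple unique to model A).

`qpcrConcordance` takes qPCR input as pre-computed log2 relative
expression (ΔΔCt already applied) because normalizer genes and Ct
processing are assay-specific; it requires ≥3 shared genes and
refuses zero-variance vectors rather than returning NaN.

## The synthetic-data generator

`simulateCounts` emulates the *structure* of the motivating data, with
every default chosen once, up front, as the study condition:

* **16,457 genes**, one library per condition (`replicates = 1`), the
  pooled design's defining feature.
* **Baseline expression** is log-normal(0, 2.12) relative abundance
  scaled to an expected **1e6 reads per library**. The sdlog was
  calibrated once by simulation so that the strict >10 summed-read
  filter passes ≈8,792 genes — the detection scale of the motivating
  experiment — and then frozen; a long right tail spanning both strata
  is the realistic regime for amplified single-tube cDNA libraries.
* **Noise** is negative binomial with mean–dispersion
  parameterization, $\mathrm{Var} = \mu + \phi\mu^2$, default $\phi =
  0.05$ (modest overdispersion for technical-replicate-like libraries;
  $\phi = 0$ degenerates to Poisson).
* **Planted DE** is multiplicative on the diabetic mean:
  `fracDeUp = 0.07` and `fracDeDown = 0.04` of genes per model, half
  shared between models (`fracShared = 0.5`) — echoing the ~1,000-up /
  several-hundred-down per model and ~500/~100 shared scale of the
  two-model diabetes comparison. Planted |lfc| is 1.5 for high-stratum
  and 2.5 for low-stratum genes, comfortably above the respective
  cutoffs.
* The generation-time stratum recorded in the truth table applies the
  caller's rule to the *expected* counts, so it is the planted
  analogue, not a copy, of the caller's decision.

What the generator does **not** emulate: amplification-cycle bias,
positional/GC effects, mapping ambiguity, and any biological
correlation structure between genes (counts are independent across
genes given their means). Passing recovery tests therefore shows the
decision rule is implemented correctly and behaves as designed under
its own noise model — not that the thresholds are optimal for any
real library.

`simulateAnnotation` draws term gene sets uniformly, except the first
`enrichedTerms` accessions (`SIM:0001`, ...) which oversample true-DE
genes at `enrichmentOdds`; `enrichmentOdds = Inf` makes the planted
term all-DE, attaining the minimal achievable p for its margins.
`simulateQpcr` returns truth lfc plus Gaussian noise in log2 units —
a ΔΔCt-style read-out.

## Numerical and I/O choices

* Strict inequalities at every threshold (filter, stratum, cutoffs);
  ties go to the conservative side (not detected / low / unchanged).
* All sim functions take explicit seeds and set the session RNG;
  identical spec ⇒ bit-identical output.
* Result files carry a commented header (`#key=value`) with package
  version, seed, all thresholds and a body checksum. Floats are
  written with 6 significant digits, p-values in scientific notation.
  Discrete fields round-trip exactly; float fields round-trip to the
  written precision; a written file re-read and re-written is
  byte-identical.
* Gene identifiers are opaque case-sensitive strings — no alias or
  symbol resolution, which is annotation-version-dependent.

## Problem sizes in the test suite

The suite exercises the full 16,457-gene scale where the property
demands it (scale emulation, null calibration, planted-effect
recovery) and 100-repetition batteries at 1,000 genes for the
partition/symmetry and comparison-oracle properties; the hypergeometric
oracle sweep covers every margin with $N \le 50$. The complete suite
runs in well under a minute of CPU.

## Known limitations

* No replicate-aware inference: with replicated libraries the caller
  averages normalized counts per condition instead of modelling
  within-condition variance. For replicated designs a dispersion-based
  test is the right tool; this package implements the replicate-free
  procedure.
* The fold-change rule has no per-gene error control; the low-stratum
  cutoff bounds the aggregate false-positive rate empirically, not
  formally.
* Enrichment treats terms independently (no ontology-graph
  propagation, no term–term redundancy pruning).
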