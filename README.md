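# nfkbtargets

Identify transcription-factor target genes among differentially
expressed genes by combining expression analysis with ChIP-Seq binding.

The package grew out of a concrete question in developmental immunology:
which NF-κB subunits (canonical p65/p50 versus noncanonical RelB/p52)
drive the transcriptional differences between fetal and adult
neutrophils? The computational chain it implements is general, though:

1. **Differential expression** — quantile normalization, per-gene
   pooled-variance Student *t* tests on log2 intensities, and
   Benjamini–Hochberg FDR control with DE called at strict *q* < 0.05;
   optional probe→gene collapsing by a min-*q* representative rule.
2. **Over-representation analysis** — hypergeometric upper-tail tests of
   the DE list against GMT gene-set collections over an explicit
   background universe, with fold enrichment `(k/n)/(K/N)`.
3. **Binding assignment** — a gene counts as *bound* by a subunit if a
   ChIP-Seq peak overlaps the gene or lies within 1 kb of it (inclusive,
   gene-body anchored; TSS anchoring available).
4. **Target enrichment** — per subunit and per direction (up/down), a
   2×2 Fisher exact test of DE × bound over the background, reporting
   the sample odds ratio `(a·d)/(b·c)`, the exact two-sided p-value, the
   target genes (DE ∩ bound), and the target fraction `100·a/(a+b)` as
   an integer percent.
5. **Synthetic data** — a coupled generator for expression, gene models
   and per-subunit peaks with known ground truth (which genes are DE,
   which promoters are bound, the true binding odds ratio), used by the
   test suite to prove calibration and parameter recovery.

Data containers follow Bioconductor conventions: expression lives in a
`SummarizedExperiment`-backed `ExpressionTable`, intervals are `GRanges`
(BED I/O converts the coordinate conventions exactly), and results are
`DataFrame` subclasses with bookkeeping in `metadata()`.

## Worked example

Simulate a study-shaped experiment (12,000 genes, 3 vs 3 arrays, ~60
up-DE genes, true RelB binding-odds factor 4), assign binding by the
1 kb rule, and test RelB enrichment among the up-DE genes:

```r
library(nfkbtargets)

cfg <- simConfig(seed = 7)
sim <- simulateExperiment(cfg)
bound <- assignBinding(sim$genes, sim$peaks$RelB)   # 1 kb window
rec <- subunitEnrichment(sim$truth$de_up, bound,
                         background = names(sim$genes), "RelB", "up")
rec[, c("a", "b", "c", "d", "odds_ratio", "p_value", "fraction_pct")]
#>           a         b         c         d odds_ratio   p_value fraction_pct
#> 1        20        40      1782     10158    2.85017 0.0003595           33
```

Of the 60 truly upregulated genes, 20 carry a RelB peak within 1 kb
(33%), against a background binding rate of ~15%; the sample odds ratio
2.85 is a draw around the generating value 4 (the 25-seed median sits
near 4), and the exact test rejects at p ≈ 3.6 × 10⁻⁴.

The published worked example runs through the same code path: with 40
bound genes among 56 upregulated and 24 among 68 downregulated,

```r
targetFraction(40, 56)   # 71
targetFraction(24, 68)   # 35
```

i.e. 71% of upregulated and 35% of downregulated genes are subunit
targets. The exact-test primitives are available directly:

```r
fisherExact2x2(3, 1, 1, 3)
#> $odds_ratio  9
#> $p_value     0.4857143   (= 34/70 by enumeration)
```

A full pipeline run (normalization → DE → optional ORA → targets →
deterministic TSV/JSON outputs) is one call:

```r
res <- runPipeline(sim$expr, sim$genes, sim$peaks, outDir = "out")
```

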