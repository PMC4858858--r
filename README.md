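# risctools

Integrated post-transcriptional analysis of the naïve → primed transition in
embryonic stem cells: Argonaute-RIP enrichment calling, translating-ribosome
occupancy, ground-state miRNA selection, and miRNA:3′UTR binding-site
statistics — plus a synthetic-data generator with recorded ground truth so
that every stage of the pipeline is testable end to end.

## The scientific problem

When mouse ES cells leave ground-state pluripotency and become primed
epiblast-like cells, part of the regulation is post-transcriptional: mRNAs
held by the RNA-induced silencing complex (RISC) can be *released* from
Argonaute (Ago) and loaded onto ribosomes without large changes in total mRNA.
Detecting this requires combining three measurements on a common gene
universe:

1. **Ago-RIP arrays** — Ago-IP and total-RNA channels per stage. Ago
   enrichment for gene *g* at stage *n* is
   `E_n = log2(Ago IP) − log2(total)`. The Ago-channel log2-intensity
   distribution is bimodal (unbound background + bound subpopulation); a
   two-component Gaussian mixture is fitted by EM and the bound call uses
   `T1 = μ₁ + 3σ₁`, which admits a background gene with probability
   ≈ 0.00135 (0.001 to one significant figure). A gene is **released** at
   transition n → n+1 when it is bound at *n*, `E_n ≥ T2` (default 2),
   `E_{n+1} ≤ T3` (default 0.5), and `|ΔE| ≥ 1.5`; **loaded** is the mirror
   rule.
2. **Ribosome-IP/input RNA-seq** — counts are scaled by median-of-ratios size
   factors (`s_j = median_g count_gj / geomean_g`), filtered for expression
   (mean ≥ 50 counts in at least one condition) and variability
   (sd/mean ≤ 20 % per replicate group), and summarized per gene as
   `log2RiboΔE = log2(R_ELA) − log2(R_ES)` with `R = mean IP / mean input`.
   Genes with `log2RiboΔE > 1` are called translationally up-regulated.
3. **Small-RNA-seq + 3′UTRs** — RPM-normalized miRNA counts over four
   conditions; "set D" (the down-regulated ground-state signature) is
   `mean log2 RPM ≥ 5 ∧ log2FC ≤ −1`. Set-D miRNAs are scanned against 3′UTRs
   with a seed-weighted affine-gap local aligner (miRanda-style scoring; hits
   pass at score ≥ 140 and duplex energy ≤ −10 kcal/mol); per-gene scores are
   summed and gene families are compared against a random-gene or
   scrambled-UTR null with Wilcoxon rank-sum tests.

Cross-cutting statistics (sign-test concordance with two randomization
controls, a |log2FC| ≥ 1 / adjusted p < 0.05 / mean ≥ 7.5 DE filter,
Euclidean complete-linkage clustering) and an integration table relating Ago
ΔE classes to `log2RiboΔE` complete the pipeline.

## Worked example

```r
library(risctools)
res <- runPipeline(seed = 7, nGenes = 5000,
                   mirnaArgs = list(genesPerFamily = 20, nBackgroundGenes = 40))
print(res)
```

```
Integrated post-transcriptional analysis (seed 7 )
  genes: 5000; bound per stage: 1004, 1004
  Ago transitions: 50 released, 50 loaded
  polysome: 3262 genes pass filters; 31 up / 0 down (log2RiboDeltaE)
  miRNAs in set D: 9
  family binding test:
    CYP450   n= 20 median=   455.5 null= 292.0 p=0.0233
    DNMT     n= 20 median=   846.0 null= 292.0 p=6.27e-07
    KDM      n= 20 median=   923.5 null= 292.0 p=1.97e-07
    SWISNF   n= 20 median=  1056.0 null= 292.0 p=1.34e-07
  integration (log2RiboDeltaE by Ago deltaE class):
    released  n=  32 mean=+1.507 p=8.96e-27
    loaded    n=  34 mean=+0.049 p=0.282
    unchanged n=3196 mean=+0.005 p=0.292
```

Reading this: the mixture fit on the simulated Ago channel recovered the
background component (μ₁ ≈ 6.00, σ₁ ≈ 0.51, so T1 ≈ 7.53) and called ~1000
bound genes per stage; the 50 planted released and 50 planted loaded genes
were all recovered. Of the released genes passing the polysome filters, the
mean ribosome-occupancy change is ≈ +1.5 log2 units (one-sample t-test
p ≈ 9e-27), reproducing the anti-correlation between Ago release and
translation, while the loaded/unchanged classes stay centred at zero. The
three target families (DNMT, KDM, SWI/SNF) carry planted set-D binding sites
and are strongly enriched in cumulative binding score over the random-gene
null; the unrelated control family (CYP450) is not.

Individual stages are exposed as ordinary functions —
`quantileNormalize()`, `fitBackgroundMixture()`, `boundCallThreshold()`,
`agoEnrichment()`, `classifyTransitions()`; `sizeFactorsMedianRatio()`,
`filterGenes()`, `ribosomeEnrichment()`, `selectTranslationallyRegulated()`;
`rpmNormalize()`, `selectSetD()`, `alignDuplex()`/`scanDuplexes()`,
`cumulativeBindingScore()`, `scrambleUtrs()`, `familyBindingTest()`,
`mirnaZScores()`; `signTestConcordance()`, `randomizedSignControls()`,
`deGeneFilter()`, `hierarchicalCluster()`, `familyEnrichmentCompare()` — and
the three generators `simulateArrayExperiment()`,
`simulateCountExperiment()`, `simulateMirnaAndUtrs()` return both the data
and a `SimTruth` object for scoring recovery.

## Vignette

`vignettes/risc-priming-pipeline.Rmd` documents the statistical model behind
each stage, every tunable threshold with its default and rationale, what the
synthetic generators do and do not emulate, and the package's numerical
choices and limitations.
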