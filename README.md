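# ancestryMosaic

Tools for asking how much a set of hybridizing populations' evolutionary
history varies **among chromosomes** — the "genomic mosaic of ancestry"
question. The motivating pattern comes from butterfly species complexes,
where the Z sex chromosome often shows a clean, tree-like history while the
autosomes carry substantial admixture, but the machinery is general: it
needs only pooled population allele counts (or a frequency matrix) with
chromosome/position metadata, a chromosome-size table, and — for the
trait-variance module — a 0/1/2 genotype matrix and a phenotype.

## What it computes

**Admixture graphs and PCVE.** The population allele-frequency covariance
matrix is estimated with per-SNP across-population centering and
block-resampling standard errors (blocks of 100 SNPs). A population tree
plus 0–8 migration edges is fitted to it by least squares under the linear
drift model `W = U diag(c) Uᵀ`, where `U` holds each population's ancestry
weights over branch segments, `c` the per-branch drift, and migration edges
contribute `w` / `1 − w` mixture paths. The tree-likeness of a chromosome
is its PCVE,

```
PCVE = 1 − Σ(Ŵij − Wij)² / Σ(Ŵij − mean(Ŵ))² ,
```

the proportion of the covariance explained by the fitted graph: a
chromosome whose history is a clean bifurcating tree has high PCVE with
zero migration edges.

**Four-taxon window scores.** SNPs are coded within populations by the
common allele when its frequency reaches 0.95 (else ambiguous), polarized
by an outgroup, and each SNP with exactly two derived focal taxa votes for
the topology grouping them. Votes are tallied in 10-kb windows, averaged
over 50-kb sliding windows, and normalized to sum to one — a windowed
topology-weighting scan.

**Among-chromosome tree heterogeneity.** A tree is estimated per
chromosome (coded-allele Hamming distances + neighbor joining, rooted on
the outgroup) and pairwise tree differences are scored with the
generalized Robinson–Foulds distance on mutual clustering information
(optimal split matching, in bits). Significance comes from re-estimating
all trees under 50 random SNP-to-chromosome permutations;
`P = (1 + #{null ≥ observed}) / 51` is never zero, so a maximal result is
reported as `P = 1/51 < 0.02`.

**Va partitioning.** From per-SNP effect estimates (a built-in ridge/GCV
estimator, or any externally produced effects) and allele frequencies,
additive genetic variance is split among chromosomes as
`Va_c = Σ_{j∈c} 2 p_j (1 − p_j) β_j²`, e.g. autosomes vs Z.

A ground-truth-known simulator (chromosome-specific admixture graphs →
frequencies → two-stage pool-seq read counts; sparse polygenic traits)
backs every stage. See the methods vignette
(`vignettes/ancestry-mosaic-methods.Rmd`) for models, conventions and
limitations.

## Worked example

Simulate a small genome in which four autosomes carry a migration edge
(weight 0.4) while the Z chromosome follows the same tree without
admixture, then ask which chromosomes look tree-like:

```r
library(ancestryMosaic)

branches <- data.frame(
  parent = c("R","R","I","I","J","J","R"),
  child  = c("I","J","A","B","C","D","O"),
  drift  = c(0.4, 0.4, 0.02, 0.01, 0.4, 0.02, 0.01))
zGraph    <- populationGraph(branches, outgroup = "O")
autoGraph <- populationGraph(branches, outgroup = "O",
               migrations = data.frame(from = "C", to = "B", weight = 0.4))
autoGraph
#> PopulationGraph: 5 leaves, 7 branches, 1 migration edge(s)
#>   outgroup: O
#>   ((A:0.02,B:0.01):0.4,(C:0.4,D:0.02):0.4,O:0.01);
#>   migration mid(C) -> B, w = 0.400

sizes  <- c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6, chr4 = 2e6, Z = 1e6)
graphs <- list(chr1 = autoGraph, chr2 = autoGraph, chr3 = autoGraph,
               chr4 = autoGraph, Z = zGraph)
cfg <- simulationConfig(sizes, 2000L, graphs,
         rootFreqDist = rootDist("uniform", min = 0.2, max = 0.8),
         poolDepth = 100, poolSize = 48L)
sim   <- simulateGenomeDataset(cfg, seed = 1)
freqs <- estimateFrequencies(sim$counts, minDepth = 1)

pcve0 <- sapply(names(sizes), function(ch) {
  cv  <- blockCovariance(freqs[snpChromosomes(freqs) == ch, ], blockSize = 100)
  fit <- fitAdmixtureGraphs(cv, outgroup = "O", maxEdges = 1,
                            restarts = 3, seed = 2)
  c(m0 = pcveValue(fit[[1]]), m1 = pcveValue(fit[[2]]),
    w  = fittedGraph(fit[[2]])@migrations$weight)
})
round(t(pcve0), 3)
#>         m0 m1     w
#> chr1 0.958  1 0.413
#> chr2 0.956  1 0.397
#> chr3 0.957  1 0.414
#> chr4 0.960  1 0.388
#> Z    1.000  1 0.024
```

Read: a bifurcating tree (`m0`) explains ~96% of the covariance on the
admixed autosomes but essentially all of it on the Z — the Z is the
tree-like chromosome. Adding one migration edge (`m1`) brings the
autosomes to PCVE ≈ 1 and recovers the planted admixture proportion
(ŵ ≈ 0.39–0.41 vs the true 0.4); on the Z the extra edge is fitted with a
weight near zero because there is nothing for it to explain.

The same dataset feeds the heterogeneity test
(`permutationTest(codeAlleles(freqs), outgroup = "O")`), the window scan
(`quartetScan()`), and — with `simulateTraitData()` — the Va partition
(`estimateEffects()` + `partitionVa()`).

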