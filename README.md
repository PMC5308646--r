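# embryoLnc

Tools for analysing long non-coding RNAs (lncRNAs) in stage-structured
single-cell transcriptomes of pre-implantation embryos. The package is
aimed at researchers who have assembled transcripts and FPKM expression
matrices across ordered developmental stages (oocyte through blastocyst)
and want to (i) identify novel lncRNAs, (ii) quantify how stage-restricted
each gene's expression is, (iii) test whether lncRNAs *cis*-correlate with
their genomic neighbors, (iv) organise stage-specific genes into
co-expression modules with hub genes, and (v) ask whether modules are
preserved across species.

## What it computes

**ROC coverage threshold.** Assembled transcripts are labeled *good* when
they recover at least 75% of a reference transcript's exonic bases. Over
candidate thresholds *T* (the observed coverages plus a below-minimum
sentinel), the optimum is the corner-closest point of the empirical ROC,

    i* = argmin_i { (1 - sensitivity[i])^2 + (1 - specificity[i])^2 },
    t* = T[i*],

computed separately for coding and noncoding references and averaged.

**Novel-lncRNA pipeline.** Four ordered filters: intersection of two
assembler outputs (identical intron chain, same strand), removal of
transcripts with any exonic overlap to provided annotation sets
(strand-agnostic, 1 bp suffices), a size/exon filter (exonic length
strictly > 200 bp, at least 2 exons), and a coding-potential consensus
over four predictor calls (default: all four must say noncoding).

**Temporal specificity.** A gene's pooled stage profile V is normalized to
a density e with e_i = log10(v_i + 1) / sum_j log10(v_j + 1). With base-2
entropy H, the Jensen-Shannon distance to the point-mass profile e^s of
exclusive expression in stage s is

    JSdist(e, e^s) = sqrt( H((e + e^s)/2) - (H(e) + H(e^s))/2 ),

and the specificity score is JSsp(e) = max_s { 1 - JSdist(e, e^s) },
in [0, 1], with genes above 0.5 called temporally specific. Class
comparisons (lncRNA vs coding) use KS, Fisher exact, and Mann-Whitney
tests.

**cis neighbors.** Gene pairs with body gap < 10 kb, classified divergent
(head-to-head, opposite strands), convergent, or unidirectional; Pearson
correlation of density-normalized profiles against a null of 10,000
random coding-coding pairs (Welch t, KS, Cohen's d), plus the per-module
neighbor-fraction t-test.

**Co-expression network.** Signed adjacency a_ij = ((1 + cor_ij)/2)^beta
(default beta = 5), topological overlap matrix
TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij), average-linkage
clustering on 1 - TOM with a hybrid tree cut, eigengenes (first PC, unit
variance, sign-fixed), eigengene merging above correlation 0.85,
module-trait correlation, module membership kME_q(i) = cor(x_i, ME_q),
hubs at kME >= 0.9, and TOM-weighted hub edge lists.

**Preservation and enrichment.** One-to-one ortholog mapping, then
upper-tail hypergeometric tests on module overlaps within the shared
universe, and GMT-based gene-set enrichment (overlap >= 5, p <= 0.05).

A synthetic-data generator (`simConfig`, `simulateAnnotation`,
`simulateExpression`, `simulateAssemblyFixture`) plants all of this
structure — stage-specific genes, stage-tied modules, correlated neighbor
pairs, assembly fixtures with known classes — so that every analysis can
be validated against known truth.

## Worked example

```r
library(embryoLnc)
library(SummarizedExperiment)

cfg <- simConfig(seed = 1)          # 400 genes, 7 stages, 90 cells
ann <- simulateAnnotation(cfg)
se  <- simulateExpression(ann, ann$truth, cfg)

## temporal specificity
sc <- specificityScore(normalizeDensity(poolStages(se)))
spec <- ann$truth@specificStage
sub <- sc[match(names(spec), sc$gene_id), ]
mean(sub$max_score > 0.5 & sub$argmax_stage == unname(spec))
#> [1] 1

## cis neighbors vs random null
pr <- normalizeDensity(poolStages(se))
nb <- pairCorrelation(findNeighbors(ann$genes), pr)
nullPairs <- pairCorrelation(
  randomCodingPairs(ann$genes, n = 10000, seed = 2,
                    excludeNeighbors = nb), pr)
cmp <- comparePairClasses(nb, nullPairs)
round(c(neighbor = cmp$mean_lnc, random = cmp$mean_null), 3)
#> neighbor   random
#>    0.779    0.016

## the per-module neighbor percentage summary
neighborFractionSummary(c(56.23, 59.46, 54.13, 55.20, 52.81, 63.21,
                          57.43, 47.37, 56.57))[c("mean", "sd",
                                                  "t_statistic", "p_value")]
#> $mean [1] 55.82333   $sd [1] 4.400105
#> $t_statistic [1] 3.97036   $p_value [1] 0.004116858
```

The specificity call says every planted stage-specific gene scored above
the 0.5 cutoff at its planted stage; the neighbor comparison shows the
planted shared-factor pairs (rho = 0.8) far above the random coding-pair
baseline; and the nine-module percentage summary reproduces mean 55.82
+/- 4.40 with t = 3.970, p = 0.004 — the paired and one-sample forms
coincide because each row sums to 100.

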