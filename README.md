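# DioxinScore

Rat strains differ enormously in their sensitivity to
2,3,7,8-tetrachlorodibenzo-p-dioxin (TCDD): strains carrying a
transactivation-domain variant of the aryl hydrocarbon receptor (AHR)
survive doses that are lethal to wildtype-AHR strains. Comparing hepatic
transcriptional responses between two dioxin-**resistant** strains (H/W,
Line-A) and two dioxin-**sensitive** strains (L-E, Line-C) separates genes
whose response merely accompanies AHR activation from genes whose response
tracks the toxic phenotype. `DioxinScore` implements that cross-strain
analysis as a tested, reusable R package, together with a synthetic-data
generator so every stage can be exercised without the original microarray
data.

## The scoring scheme

For each strain *s*, each gene *g* gets an exposed-vs-control contrast from
a condition-means linear model with empirical-Bayes variance moderation:

    t̃_gs = β̂_gs / sqrt(s̃_g² · v),   s̃_g² = (d₀·s₀² + d·s_g²) / (d₀ + d)

where `s_g²` is the pooled residual variance on `d` degrees of freedom and
(d₀, s₀²) are the moments of a scaled inverse-chi-square variance prior
estimated from all genes (digamma/trigamma moment matching). Two-sided
p-values on `d₀ + d` df are Benjamini–Hochberg adjusted within each
strain, and each gene is scored per strain:

    score = +1  (induced,  p_adj < 0.01, log2FC > 0)
            −1  (repressed, p_adj < 0.01, log2FC < 0)
             0  (unaltered)

Scores are summed within each collective — R for the two resistant
strains, S for the two sensitive strains, each in −2..+2 — and the pair
(R, S) classifies the gene:

| (R, S)                    | label               | meaning                              |
|---------------------------|---------------------|--------------------------------------|
| R + S = ±4                | Type-I (up/down)    | concordant in all four strains       |
| \|R\| = 2, S = 0          | Type-II resistant   | both resistant strains, no sensitive |
| R = 0, \|S\| = 2          | Type-II sensitive   | both sensitive strains, no resistant |
| R = S = 0                 | unresponsive        |                                      |
| otherwise                 | partial / discordant|                                      |

Type-II genes — responsive in exactly one collective — are the candidates
for involvement in strain-specific toxicity (hepatotoxicity, wasting,
lethality). Around the core scheme the package provides the 5×5 two-way
table and overlap summaries, a two-proportion test with continuity
correction, permutation-FDR category enrichment (ratio
`E = (k/n)/(K/N)` against random gene lists), complete-linkage clustering
of samples under `1 − Pearson r` distance, and ΔΔCt qPCR quantification
(`expression = 2^−ΔΔCt`) with Welch/ANOVA group tests.

## Worked example

```r
library(DioxinScore)

cfg <- simConfig(seed = 17)        # 8605 genes, 4 strains x 2 x 4 animals
re  <- generateDataset(cfg)        # ResponseExperiment with known truth
sc  <- runStrainContrasts(re, alpha = 0.01)
sc
#> StrainContrasts over 4 strains, 8605 genes
#> prior: d0 = 4.066, s0_sq = 0.05049; residual df = 24
#> genes at p_adj < 0.01: HW=101, LnA=99, LE=138, LnC=138

gs <- scoreGenes(sc)
buildTwoWayTable(gs)
#> CrossTable (rows: resistant score, columns: sensitive score), 8605 genes
#>    -2 -1    0  1  2
#> -2  5  0    1  0  0
#> -1  0  0   72  0  0
#> 0  23 73 8244 79 14
#> 1   0  0   72  0  0
#> 2   0  0    2  0 20

ov <- summarizeOverlap(gs)
c(ov$responsive_any, ov$type_I, ov$type_II)
#> [1] 361  25  40
```

The prior estimates (d0 ≈ 4.07, s0² ≈ 0.050) recover the generating
variance prior (4, 0.05); all 25 planted Type-I genes and 37 of the 43
planted sensitive-collective Type-II genes receive their true labels at
this seed — Type-II effects are small (|log2FC| = 1.4), so a minority
drop to "partial" when one strain narrowly misses the threshold, exactly
the behaviour the scheme is designed to expose. The published two-way
grid ships with the package:

```r
ov <- summarizeOverlap(publishedTwoWayCounts())
c(ov$responsive_any, ov$type_I, ov$type_II, ov$multi_strain)
#> [1] 452  25  46 144
proportionTest(31, 138, 108, 412)$p_value
#> [1] 0.4447798
```

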