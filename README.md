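# limbatlas

Cross-species single-cell analysis of the developing and regenerating
vertebrate limb, built around one biological question: does a species (such
as the axolotl) carry cells with the transcriptional program of the apical
ectodermal ridge (AER), is that program re-used by the wound epithelium
(apical epithelial cap, AEC) during regeneration, and does part of it leak
into mesodermal connective-tissue (CT) cells?

The package is aimed at computational biologists who want to run — and
stress-test on data with known ground truth — the full comparative
pipeline: building a shared one-to-one gene space across species (including
an allotetraploid with L/S homeolog gene pairs), per-dataset preprocessing
with cell-cycle-correlated principal-component removal, cross-dataset
integration, cluster replicability scoring, per-cell gene-set enrichment,
transcriptional-program discovery, and spatial (Visium-style) spot
clustering. Every stage is exercised end-to-end on a synthetic
multi-species generator whose planted truth (cell types, a species-private
goblet-cell analogue, a cycling confound, an AER program, and a partial
program planted in CT cells) makes the whole pipeline testable offline.

## Methods at the core

* **Shared gene space** — duplicate sources for a symbol (homeologs
  `SYM.L`/`SYM.S`, duplicate transcripts) are collapsed by keeping the
  source row with the greatest total raw count; datasets are then
  restricted to the symbols present in every species.
* **Cycle-correlated PC correction** — for each principal component the
  absolute loadings of the cell-cycle genes are summed; components with
  sum above a threshold are flagged, the top 10% of genes by absolute
  loading of each flagged PC are removed, and the PCA is refitted.
* **Neighbour-voting AUROC** (MetaNeighbor-style) — a cell–cell Spearman
  network is rank-standardized per cell; cells of a test dataset are voted
  for by their mean connectivity to a training cluster, and the score for a
  cluster pair is the mid-rank Mann–Whitney AUROC averaged over both
  directions. 0.5 means "cannot decide"; above 0.9 is strong replication.
* **Per-cell AUC enrichment** (AUCell-style) — genes are ranked per cell by
  raw count; with `T = ceiling(0.05 * nGenes)` the score is the area under
  the set-member recovery curve over the top `T` ranks, divided by its
  maximum possible area, giving a value in [0, 1].
* **Consensus NMF** — repeated seeded NMF restarts are pooled, outlier
  spectra dropped, the rest clustered; per-cluster median spectra are the
  consensus modules, usages are refitted by non-negative least squares, and
  the module count `k` is chosen as the error minimum among values with at
  least 80% of the maximal stability (mean silhouette).
* **Cross-lineage aggregation** — in a program-gene-restricted PC space,
  the fraction of mesodermal cells whose k-nearest neighbours are
  majority-epithelial; the statistic that turns "CT cells gather with the
  AEC" into a number.

## Worked example

```r
library(limbatlas)
library(SummarizedExperiment)

cfg <- synthConfig(nSpecies = 2, cellsPerDataset = 300, nGenes = 600,
                   sharedTypes = c(AER = 0.2, BasalEctoderm = 0.3, CT = 0.5),
                   privateTypes = list(species1 = "Goblet"), nPrivateGenes = 20,
                   seed = 7)
panel <- generateDevelopmentPanel(cfg)
collapsed <- lapply(panel$datasets, collapseDuplicates, orth = panel$orthology)
shared <- buildSharedSpace(collapsed)
nrow(shared[[1]])
#> [1] 560          # 600 symbols minus 2 x 20 species-private genes

shared <- lapply(shared, normalizeSelectHVG, nHVG = 400)
pca <- fitPCA(shared$species1, nComponents = 20)
pca
#> PCAModel: 300 cells x 20 components over 400 genes
#>   var explained (first 5 ):  34.7% 21.1% 11.7% 2.9% 2.3%

cl <- clusterCells(pca, nPCs = 15, k = 20, seed = 1)
table(cluster = cl, truth = colData(shared$species1)$true_type)
#>        truth
#> cluster AER BasalEctoderm  CT Goblet
#>       0   0             0 135      0
#>       1   0            81   0      0
#>       2  54             0   0      0
#>       3   0             0   0     30
```

Clustering recovers the four planted types exactly. Cross-species cluster
replicability then identifies the AER population across species:

```r
labs <- unlist(lapply(shared, function(m) as.character(colData(m)$true_type)),
               use.names = FALSE)
feats <- selectSimilarityFeatures(shared, mode = "binned_variance")
sim <- neighborVotingAUROC(feats, clusters = labs)
round(aurocMatrix(sim)["species1|AER", "species2|AER"], 3)
#> [1] 1            # same-type pair replicates perfectly ...
round(aurocMatrix(sim)["species1|AER", "species2|CT"], 3)
#> [1] 0.268        # ... unrelated types do not
```

and per-cell enrichment for the planted AER program separates AER cells
from every other type:

```r
prog <- panel$genes$symbols[panel$genes$program]
enr <- aucellScore(shared$species1, prog, setName = "AER program")
round(tapply(enrichmentScores(enr),
             colData(shared$species1)$true_type, mean), 3)
#>   AER BasalEctoderm    CT Goblet
#> 0.946         0.073 0.106  0.119
```

The regeneration-mode generator (`generateRegenerationSeries()`), the
gene-set projection (`projectOnGenesets()` + `crossLineageAggregation()`)
and the spatial section (`generateSpatialSection()`, `clusterSpots()`,
`overlayTable()`) follow the same pattern; see the methods vignette for the
modelling details and parameter rationale.

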