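# btudiv

Clade-wise analysis of gut-microbiota host specificity and host–microbiota
co-divergence from 16S rRNA amplicon data.

## The problem

Whole-community comparisons of gut microbiota (GM) across host species hide an
important heterogeneity: different bacterial clades can be bound to their hosts
with very different tightness. `btudiv` decomposes an ASV (amplicon sequence
variant) table into **Binned Taxonomic Units (BTUs)** — putatively monophyletic
ASV groups defined either by shared genus assignment or by complete-linkage
clustering of marker-sequence similarity at 95%/97% — and quantifies two
distinct signals independently for every BTU:

* **Host-species specificity** — one-factor PERMANOVA of the BTU's
  sample-by-sample dissimilarities (Bray–Curtis and binary Jaccard, on
  whole-library proportions) against host species identity, summarized by the
  adjusted coefficient of determination
  *R²adj = 1 − (1 − R²)(n − 1)/(n − k)*, comparable across BTUs hosted by
  different numbers of samples (*n*) and species (*k*).
* **Co-divergence** — Procrustean cophylogeny of principal-coordinate
  embeddings: compositional (*P_COMP*, community dissimilarities vs. host
  cophenetic distances) and phylogenetic (*P_PHYLO*, genetic distances among
  the BTU's ASVs vs. host cophenetic distances, linked through ASV-in-sample
  occurrences). The statistic is the symmetric Procrustes correlation
  *r = √(1 − m²)*; significance comes from a species-block permutation null
  that reshuffles species identities across intact blocks of same-species
  samples (10,000 rounds by default), rebuilding the host-side embedding each
  round.

Benjamini–Hochberg FDR is applied per binning-method × distance × statistic
family, effect sizes are compared across statistics and distances with
Kendall's τ, and the union of ASVs in high-specificity BTUs
(R²adj ≥ 0.2, FDR < 0.05) is tested against random equal-size ASV subsets.
A Dirichlet-multinomial community simulator plants null, host-specific and
co-diverging BTUs with known truth, so every stage is testable without any
external data. The methods vignette (`vignettes/btu-methods.Rmd`) documents
the models, parameter defaults, numerical choices and limitations.

## Worked example

Simulate a small community — 10 host species × 4 samples, three planted BTUs
(one null, one host-specific, one co-diverging) of 12 ASVs each — and run the
reference-based pipeline:

```r
library(btudiv)

cfg <- simulationConfig(nSpecies = 10, samplesPerSpecies = 4,
                        nNullBtus = 1, nSpecificBtus = 1, nCodivergingBtus = 1,
                        asvsPerBtu = 12, seqLength = 80,
                        meanLibrarySize = 1200, libraryDispersion = 5,
                        seed = 52)
sim <- simulateDataset(cfg)
sim$experiment
#> AsvExperiment: 40 samples from 10 host species, 36 ASVs, 45,778 reads
#>   host tree: 10 tips

acfg <- analysisConfig(binning = "genus", nPermPermanova = 999,
                       nPermPaco = 999, nPermSubset = 999,
                       minSampleReads = 100, minBtuReads = 100,
                       minBtuAsvs = 3, seed = 6)
report <- runPipeline(sim$experiment, acfg)
subset(report$btuResults, distance == "bray",
       select = c(btu, R2adj, qSpecificity, pcomp, qPcomp, pphylo, qPphylo))
```

```
btu         |  R2adj | qSpec  | P_COMP | q     | P_PHYLO | q
Genus_btu01 | -0.009 | 0.5950 |  0.37  | 0.917 |  0.00   | 1.00
Genus_btu02 |  0.995 | 0.0015 |  0.75  | 0.917 |  0.12   | 1.00
Genus_btu03 |  0.989 | 0.0015 |  0.96  | 0.003 |  0.04   | 0.22
```

Reading the table against the planted truth (`sim$truth$regime`): the null
BTU (`btu01`) shows no species signal (R²adj ≈ 0, nothing significant); the
host-specific BTU (`btu02`) is strongly species-specific (R²adj = 0.995,
FDR = 0.0015) but **not** co-diverging — its species affinities carry no
phylogenetic structure, and the block-permutation null absorbs pure
specificity; the co-diverging BTU (`btu03`) is both species-specific and
compositionally congruent with the host phylogeny (P_COMP = 0.96,
FDR = 0.003). Separating those last two cases is precisely what the per-BTU
decomposition is for. (At this small scale the phylogenetic mode is
underpowered — P_PHYLO q = 0.22; it gains power at the default study
conditions, 20 species × 5 samples with 25 ASVs per BTU.)

`writeReport(report, "out/")` emits the per-BTU tables
(`btu_results_<method>_<distance>.tsv`), the whole-community analysis, the
effect-size concordance table, the subset test, the read/ASV accounting and a
machine-readable run log; outputs are byte-identical for a fixed seed.

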