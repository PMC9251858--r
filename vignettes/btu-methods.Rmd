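---
title: "BTU-level host specificity and co-divergence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BTU-level host specificity and co-divergence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Gut microbiota (GM) surveyed by 16S rRNA amplicon sequencing often differ
between host species, and sometimes track the hosts' phylogeny. Whole-community
analyses blur an important distinction: different bacterial clades may be bound
to their hosts with very different tightness. `btudiv` implements a clade-wise
decomposition of this question. An ASV table is split into **Binned Taxonomic
Units** (BTUs) — putatively monophyletic groups of ASVs defined either by a
shared genus assignment (reference-based) or by complete-linkage clustering of
marker-sequence similarity at 95% or 97% (reference-free) — and two signals are
quantified independently for every BTU:

* **Host-species specificity**: how strongly the ASV composition within the
  BTU differs among host species, measured by one-factor PERMANOVA with an
  adjusted coefficient of determination,
  $R^2_{adj} = 1 - (1 - R^2)\,(n-1)/(n-k)$,
  which makes effect sizes comparable across BTUs hosted by different numbers
  of samples ($n$) and species ($k$).
* **Co-divergence**: whether microbial divergence tracks host phylogenetic
  divergence, measured by a Procrustean cophylogeny statistic in two modes —
  compositional (`P_COMP`: community dissimilarities between samples against
  host cophenetic distances) and phylogenetic (`P_PHYLO`: genetic distances
  among the BTU's ASVs against host cophenetic distances, linked through
  ASV-in-sample occurrences).

These two signals are logically distinct: a clade can be perfectly
host-specific while carrying no phylogenetic signal (host switching,
ecological filtering), and separating them per clade is the point of the
decomposition.

# The pipeline, stage by stage

## Input filtering

ASVs unassigned at phylum level, or flagged as chloroplast, mitochondrial or
archaeal at any rank (case-insensitive prefix match, since database spellings
vary), are removed first; samples are then filtered on library size (default:
strictly below 1000 reads). The order matters for borderline libraries, and it
is fixed as taxa-then-samples so that library sizes reflect retained ASVs.

## BTU definition

Reference-based binning groups ASVs by genus string; genus-unassigned ASVs are
excluded (and reported). Reference-free binning aligns the marker sequences,
computes pairwise Jukes–Cantor-corrected distances
$d = -\tfrac34 \log(1 - \tfrac43 p)$ (with an infinite sentinel at saturation,
$p \ge 3/4$, treated as "never merge"), and cuts a complete-linkage dendrogram
at height $h = 1 - \text{similarity}$. Complete linkage guarantees that the
maximum pairwise distance inside every BTU is at most $h$; the package asserts
this on every partition it produces. Because the corrected distance exceeds
$1 - \text{identity}$, a `rawDistance` switch applies the cut on uncorrected
$p$ instead; the default is the corrected scale, matching the distance matrix
the clustering criterion is defined on. Cutting one dendrogram at two heights
makes the 95% partition automatically a coarsening of the 97% partition.

The aligner is a center-star construction: the sequence minimizing the summed
k-mer distance to all others is the center, all others are aligned to it by
global alignment (match +1, mismatch −1, gap −2), and the pairwise gaps are
merged. Inputs whose sequences all share one length — denoised same-primer
amplicons — are treated as already position-homologous and returned unchanged;
forcing pairwise alignment between unrelated, mutually saturated sequences
would only inject spurious gaps into the merged columns. This is also what
makes the alignment an exact identity on the simulator's indel-free output.

After binning, only BTUs with at least 5000 reads and 10 ASVs (inclusive
thresholds) enter testing; rarer or less diverse BTUs give erratic effect
sizes.

## Community dissimilarities

Counts are transformed to proportions of the **whole** library before any BTU
subsetting, so a BTU's rows sum to its share of each library rather than to 1;
a `renormalizeWithinBtu` flag exists for sensitivity analysis. Per BTU, only
hosting samples (at least one read across the BTU's ASVs) are compared, with
Bray–Curtis and the classic set-form binary Jaccard dissimilarities. BTUs
hosted by fewer than 3 samples, fewer than 2 species, or no more samples than
species are untestable and are skipped with a log entry (they remain in the
read/ASV accounting as untested).

## PERMANOVA

The one-factor pseudo-F is computed in the Gower-trace form,
$SS_{total} = \mathrm{tr}(G)$ with $G = -\tfrac12 C D^2 C$, using the
algebraic identity
$SS_{within} = \sum_g \sum_{i<j \in g} d^2_{ij} / n_g$,
which is valid for non-Euclidean (negative-eigenvalue) dissimilarities without
correction. Significance comes from unrestricted random relabelling of
samples, $p = (1 + \#\{F_\pi \ge F\})/(1 + n_{perm})$. The permutation stream
is seeded per BTU and shared between the Bray–Curtis and Jaccard runs so that
cross-distance effect-size comparisons are not inflated by permutation noise.

## PACo-style co-divergence

Both distance matrices are embedded by principal coordinates (eigenvectors of
$G$ scaled by the square root of their eigenvalues; axes with eigenvalues
below $10^{-8}$ of the largest, including all negative ones, are dropped and
counted — no Cailliez correction). The host side is lifted to sample level by
assigning each sample its species' coordinates (cophenetic distance zero
within species), the natural sample-level lift of a species-level distance.
The superimposition is symmetric Procrustes: both configurations are
column-centered and scaled to unit total sum of squares, the optimal rotation
comes from the SVD of $X^\top Y$, and
$m^2 = 1 - (\sum_i \sigma_i)^2$, $r = \sqrt{1 - m^2}$.
Zero-padding reconciles differing axis counts; it provably does not change the
nonzero singular values, which the test suite asserts against an explicit
padding oracle. Only the symmetric scaling is shipped: with both
configurations centered and the residual normalized so that $r$ is defined on
$[0, 1]$, an "asymmetric" variant collapses to the same statistic.

The null model is a **species-block permutation**: species identities are
reshuffled across intact blocks of same-species samples, preserving all
within-species structure, and the host-side configuration is rebuilt every
round; $p = (1 + \#\{m^2_\pi \le m^2\})/(1 + n_{perm})$. With one sample per
species this reduces to an ordinary label permutation (asserted
distributionally in the tests).

Rebuilding an $n \times n$ PCoA per permutation would dominate the runtime, so
the package exploits the block structure: the host-side sample-level matrix is
$Z W Z^\top$ in the squared distances ($Z$ the sample-to-species indicator,
$W$ the squared cophenetic matrix of the assigned species), hence
$G = M(-\tfrac12 W)M^\top$ with $M = CZ$. Only $W$ changes under a
permutation, so each round costs one $k \times k$ eigendecomposition
($k$ = species) instead of an $n \times n$ one. The lifted solver is exact —
the test suite pins it to the direct PCoA-plus-Procrustes computation at
$10^{-10}$ — and the same machinery serves `P_PHYLO`, where host coordinates
are stacked per (ASV, sample) occurrence.

For `P_PHYLO` the association can be built at two granularities: one row per
(ASV, sample) occurrence (the default, so consistently resampled associations
weigh more) or collapsed to unique (ASV, species) pairs (so repeated sampling
of a species carries no extra weight); with one sample per species the two
coincide exactly. The response is the PCoA of genetic distances among the
BTU's ASVs. The distance model is chosen per BTU between the closed-form JC69 and
K80 corrections by AICc of a pairwise multinomial likelihood over the site
categories match/transition/transversion (one free parameter per pair for
JC69, two for K80). This is a deliberate reduction of a full substitution-model
scan to the two closed-form, distance-compatible corrections; saturated pairs
get an infinite sentinel, and a matrix containing any sentinel falls back to
raw p-distances with a log flag.

## Multiple testing, concordance, and accounting

Benjamini–Hochberg FDR is applied per family; the default family structure is
one family per binning method × distance × statistic (`P_PHYLO`, being
distance-independent, forms one family per method and is joined to both
distance report sections). A `pooled` option collapses all statistics of a
method into one family; the two choices genuinely differ, which a test
asserts. Effect sizes are compared across statistics and distances by
Kendall's τ-b. The union of ASVs from high-specificity BTUs
($R^2_{adj} \ge 0.2$, FDR < 0.05) is tested against random equal-size ASV
draws from the full table, re-running the identical distance-plus-PERMANOVA
pipeline per draw. Finally every retained ASV and read is accounted into
untested / non-significant / significant / high-effect categories so that
totals are conserved.

A Mantel test (per-species mean profiles against cophenetic distances) is
provided as a companion statistic; its effect sizes track the Procrustes
correlation in rank across BTUs, which the suite verifies, but the Procrustes
framework is the primary co-divergence instrument.

# The synthetic community generator

Real surveys of this design (hundreds of samples, tens of host species,
~10,000 ASVs, mean libraries near 6000 reads) cannot be shipped or recomputed
at desk scale, so the generator emulates the processed data's shape with
planted, recoverable truth. Defaults are the package's study conditions:
20 host species × 5 samples, 12 BTUs (4 per regime) × 25 ASVs, 250 nt
markers, mean library 6000 reads.

* **Host tree**: pure-birth (Yule), rescaled to unit height, so cophenetic
  distances live on a fixed scale.
* **Sequences**: site-independent JC69 evolution along per-BTU guide trees
  (indel-free, so alignment is exactly the identity and distance oracles are
  closed-form). The default root-to-tip rate of 0.02 substitutions/site puts
  within-BTU divergence at up to ~4%, the scale of congeneric 16S variants;
  between-BTU comparisons are saturated, so reference-free binning separates
  planted BTUs cleanly.
* **Regimes.** Every BTU receives the same expected share of every library
  (within-BTU species-wise normalization), which keeps the per-BTU analyses
  statistically independent and the null BTUs exactly null. *Null*: every
  ASV's expected relative abundance is identical across species. *Specific*:
  per-ASV species-affinity vectors are symmetric Dirichlet draws
  (concentration α, default 0.1; small α = strong specificity) over randomly
  ordered species — species signal with no phylogenetic signal.
  *Co-diverging*: the guide tree mirrors the host tree (extra ASVs grafted as
  shallow clades at their species' tip) and the affinity of an ASV homed at
  species $h$ decays with host phylogenetic distance,
  $A(s) \propto e^{-d(h,s)/\lambda}$, default $\lambda = 0.5$ tree heights.
  A uniform "leakage" of affinity to the other species would, by symmetry,
  make all between-species community distances equal and therefore carry no
  compositional gradient at all; the proximity-decay form is what makes
  compositional co-divergence a real, continuously tunable signal while
  $\lambda \to 0$ recovers a strictly diagonal incidence. λ was fixed at half
  the tree height — comparable to typical between-species cophenetic
  distances — before any downstream calibration, and not revisited.
* **Counts**: per-sample library sizes are negative binomial (mean 6000, size
  1.5 — the size back-computed from the reported spread of real libraries of
  this design), and counts are multinomial given the species' expected
  profile. Every planted BTU gets a unique synthetic genus, so
  reference-based binning recovers the planted partition exactly.
* **Reproducibility**: one sequential seeded stream per dataset with a fixed
  draw order (host tree; per-BTU guide tree, sequences, base abundances,
  affinities; library sizes; per-sample counts). The same seed gives
  bit-identical output within this implementation.

What the generator does **not** emulate: read-level error, chimeras, PCR and
primer bias, indels, taxonomic misassignment, compositional correlations
between clades, and within-species ecological structure. Passing tests
therefore demonstrate the statistical machinery — calibration, power,
recovery, invariances — under a faithful abstraction of the data's shape, not
robustness to upstream artefacts of real sequencing.

# Validation design and problem sizes

The test suite validates each stage against independent oracles: hand-computed
PERMANOVA traces and an exhaustive-permutation p on a symmetric toy;
coordinate-space MANOVA traces on random Euclidean instances; closed-form JC
expectations against Monte-Carlo sequence simulation; explicit set-arithmetic
for dissimilarities; an exhaustive complete-linkage guarantee; zero-padding
and direct-PCoA oracles for the Procrustes machinery; and `vegan`/`ape`
cross-checks where those packages implement the same primitive.

Statistical properties are tested at sizes chosen to give stable Monte-Carlo
estimates in minutes on one CPU: type-I error with 500 null replicates
(199 permutations each; rejection within the binomial 95% band of α = 0.05),
power and signal separation on 100 datasets at the default study conditions,
strength monotonicity across five Dirichlet concentrations (10 → 0.1, eight
matched seeds per level), and a full-pipeline smoke run at a study-shaped
scale (20 species, 100 samples, 1000 ASVs, three binning methods, two
distances, 999 permutations). `scripts/acceptance.R` re-runs the pipeline
from scratch at the default conditions and writes the principal quantities as
JSON.

# Numerical choices and degenerate inputs

* Eigenvalue retention threshold $10^{-8}$ of the largest (relative), both in
  PCoA and the lifted solver; negative eigenvalues are counted and logged.
* Saturated (infinite-sentinel) distances: "never merge" in clustering; raw
  fallback with a flag in genetic distances.
* All-zero dissimilarity matrices (e.g. a BTU whose ASVs occur in every
  sample, under binary Jaccard) are untestable, as are configurations with
  coincident points; both raise a typed condition the pipeline logs.
* Permutation p-values use the add-one convention and can never drop below
  $1/(n_{perm}+1)$.
* Tie-breaking in agglomeration follows `stats::hclust`; partitions are
  deterministic for a fixed input ordering, and BTU labels are assigned in
  dendrogram order of first appearance.

# Known limitations

* The center-star aligner is intended for same-locus amplicons; it is not a
  general-purpose MSA and does not model secondary structure. Equal-length
  inputs bypass alignment entirely (see above), so a dataset containing
  balanced insertion/deletion pairs of identical net length would be treated
  as ungapped.
* Genetic-distance model choice is restricted to JC69/K80; TN93/F81 and
  rate-heterogeneity corrections are out of scope.
* Monophyly of BTUs is assumed from the construction (genus identity or
  complete-linkage similarity), not verified against a phylogeny.
* PERMANOVA is single-factor by design; host ecological covariates are not
  modelled.
* The block-permutation null conditions on the observed hosting pattern;
  BTUs whose hosting is itself strongly informative are only partially
  captured by the compositional statistic.
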