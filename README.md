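# soilnetfun

Tools for asking how forest management — specifically stand density — shapes
the belowground ecosystem: soil chemistry, microbial community structure, the
architecture and robustness of microbial co-occurrence networks, and
integrated soil multifunctionality. The package implements the full analysis
chain used in density-gradient plantation studies (four density levels, two
soil depths, replicated composite samples) and ships a synthetic-data
generator that emulates that design, so every stage is testable end to end
without sequencing data.

It is aimed at soil microbial ecologists who work with ASV count tables and
soil property panels and want the whole chain — diversity, networks,
robustness, multifunctionality, and the statistics linking them — in one
place, with every estimator implemented from its definition and
cross-checked against independent references.

## What it computes

**Diversity.** Rarefaction (single draw without replacement, default 20,000
reads), Good's coverage `1 − F1/N`, and the standard alpha estimators:
observed richness, bias-corrected Chao1 `S + F1(F1−1)/(2(F2+1))`, ACE (rare
cutoff 10), Shannon `−Σ pᵢ ln pᵢ`, Gini–Simpson `1 − Σ pᵢ²`, and Pielou
`H/ln S`. Beta diversity: Bray–Curtis `1 − 2Σmin(aᵢ,bᵢ)/(Σa+Σb)`, principal
coordinates (eigendecomposition of the double-centred Gower matrix, negative
eigenvalues reported, optional Cailliez correction), one-way PERMANOVA
(pseudo-F, free label permutation), and the Mantel test (Spearman, 999
permutations by default).

**Co-occurrence networks.** Prevalence filter (taxa present in ≥ 80% of
samples), tie-aware pairwise Spearman correlations with two-sided
t-approximation p-values (exact permutation p for tiny n), edges where
`|r| > 0.6` and `p < 0.05` (both strict), and the full topology summary:
node/edge counts, positive/negative edge counts, average degree `2E/N`,
density `2E/(N(N−1))`, within-component average path length and diameter,
average local clustering, and Louvain modularity.

**Robustness.** Natural connectivity `ln((1/N) Σ e^{λᵢ})` over the adjacency
eigenvalues, a random node-removal simulation (1–99% of nodes, 1,000
repetitions per fraction, C++ core), and the OLS stability slope of the mean
decline — smaller `|slope|`, more stable network.

**Multifunctionality.** Min-max normalization of seven soil functions
(SOC, TN, AN, NN, URE, PHO, NR), the averaging M-index (row mean) and the
threshold T-index (share of functions strictly above 70% of each function's
maximum).

**Linkage.** Random-forest permutation importance (%IncMSE computed per
tree on out-of-bag samples), the stability–multifunctionality regression and
median split, and a from-scratch PLS path model (mode A, centroid scheme,
seeded percentile bootstrap) with exact direct/indirect/total effect
decomposition by path enumeration.

## Worked example

```r
library(soilnetfun)

design <- study_design()                     # 4 densities x 2 depths x 6 reps
soil   <- generate_soil_table(design, seed = 1)
fungi  <- generate_abundance_table(design, fungal_composition_model(), seed = 2)
fungi  <- rarefy_counts(fungi, depth = 20000, seed = 3)

alpha <- alpha_diversity(fungi)
head(alpha[, c("sample_id", "chao1", "shannon", "pielou")], 3)
#>     sample_id    chao1  shannon    pielou
#> 1 VHD_0-20_r1 114.0000 2.836421 0.6022725
#> 2 VHD_0-20_r2 113.1429 2.819411 0.5963994
#> 3 VHD_0-20_r3 122.2000 2.868631 0.6013038

dm <- bray_curtis(fungi)
permanova(dm, fungi$metadata$density, n_permutations = 999, seed = 4)
#> PERMANOVA (pseudo-F) : statistic = 33.265 , p = 0.001  ( 999 permutations )

filt <- prevalence_filter(fungi, 0.8)
cm   <- correlation_matrix(filt)
net  <- build_network(cm$r, cm$p, edge_rule(), group = "fungi")
topology(net)
#>   group nodes_num edges_num positive_cor_num negative_cor_num average_degree
#> 1 fungi        38       398              212              186       20.94737
#>   average_path_length network_diameter network_density clustering_coefficient
#> 1            1.093394                2       0.5661451              0.7311553
#>   modularity
#> 1 0.04518825

curve <- removal_simulation(net, n_simulations = 1000, seed = 5)
stability_slope(curve)
#> stability slope: -24.488 (fit over fractions 0.01 - 0.99 )

scores <- multifun_scores(soil[, FUNCTION_VARIABLES], sample_ids = soil$sample_id)
resp   <- multifun_response(scores, soil[, c("sample_id", "density", "depth")])
subset(resp, index == "M_index" & depth == "0-20")
#>    density depth   index      mean         sd n
#> 1      VHD  0-20 M_index 0.5406548 0.02160893 6
#> 5       HD  0-20 M_index 0.8988876 0.03845688 6
#> 9      MD  0-20 M_index 0.4669659 0.05847562 6
#> 13      LD  0-20 M_index 0.2486663 0.05866842 6
```

The PERMANOVA confirms the density-sensitive composition planted by
`fungal_composition_model()`; the dense synthetic network declines steeply
under node removal (slope −24.5 natural-connectivity units per unit removal
fraction); and the surface-layer M-index peaks under high density (0.90),
the unimodal pattern the soil generator's default parameters encode.

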