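# trinetomics

Integrative trans-omics correlation-network analysis for cohorts profiled on
three layers at once: **gut microbiome** (metagenomic species, MGS, and
functional module abundances), **urine metabolome** (untargeted feature
intensities), and **blood clinical parameters**. The package is aimed at
analysts of multi-omics cohort studies who want a reproducible, seeded
pipeline from raw abundance tables to cross-domain communities and
predictive benchmarks — plus a synthetic cohort generator with planted
ground truth for validating every stage.

## What it computes

1. **Metabolite co-abundance modules.** After `log2` transformation,
   pairwise biweight midcorrelations `bicor(x, y)` are raised into a signed
   adjacency `a_ij = ((1 + c_ij)/2)^β` (default β = 13, selectable by the
   scale-free topology criterion), converted to topological-overlap
   dissimilarity, clustered by average linkage with a deterministic deep-cut
   (deep split 4, minimum module size 3), and summarized per module by the
   eigenprofile (first principal component, unit variance, sign-oriented).
2. **Cross-domain correlation screens.** All-pairs Spearman ρ with
   two-sided t-approximation p-values; Benjamini–Hochberg q within each
   domain-pair screen; *triangular retention* of
   (microbe, metabolite module, phenotype) triples whose three legs are all
   significant at p < 0.05; a network edge filter at q < 0.1 ∧ |ρ| ≥ 0.3
   keeping only inter-omic edges.
3. **Community modeling.** Girvan–Newman decomposition of the filtered
   graph — iterative removal of the maximum-edge-betweenness edge (weighted
   Brandes in C++, lengths 1 − |ρ|), with the cut chosen by maximal
   modularity `Q = Σ_c (e_c/m − (d_c/2m)²)` — and per-community summaries of
   node/edge composition by domain pair.
4. **Covariate statistics.** Single-variable PERMANOVA (Gower-centered
   Bray–Curtis, permutation p with the add-one rule) ranked by effect size
   r²; Mann–Whitney differential abundance (exact for small samples);
   reporter Z-scores `Z = Σ z_i / √k` with sampled background correction
   and |Z| ≥ 1.96 significance.
5. **Predictive evaluation.** 5-repeat, 10-fold, stratified,
   down-sampled cross-validation with a pluggable learner (default:
   500-tree random forest); AUC as the exact rank statistic `U/(n₁n₀)` and
   Spearman prediction accuracy for continuous targets.
6. **Synthetic cohorts.** A latent-factor generator
   (`generate_cohort()`) producing compositional zero-inflated microbiome,
   log-normal metabolome with planted co-abundant modules, clinical
   biomarkers and a logistic disease label, together with the planted
   edges/modules so recovery can be scored (`score_recovery()`).

## Worked example

```r
library(trinetomics)

co <- generate_cohort(cohort_config(seed = 1))   # 138 subjects, 3 domains
co$mgs
#> <omics_matrix> domain=microbiome_mgs, 138 samples x 100 features

lmet <- log2_transform(co$metabolites)
dis  <- tom_dissimilarity(signed_adjacency(bicor_matrix(unclass(lmet)), 13))
part <- cluster_modules(dis, data = unclass(lmet))
table(part)[1:6]
#>  ME1 ME10 ME11 ME12  ME2  ME3
#>   19   10    4    4   17   17

edges <- feature_level_edges(co)     # q < 0.1, |rho| >= 0.3, inter-omic only
graph <- graph_from_edges(edges)
graph
#> <trans_omics_graph> 214 nodes, 943 edges

comm <- girvan_newman(graph)
comm
#> <community_partition> 11 communities, Q = 0.8924

score_recovery(co$truth, inferred_edges = edges, inferred_modules = part)
#> $edge_sensitivity 0.986   $edge_precision 0.994   $module_ari 0.951
```

98.6% of the planted cross-domain feature pairs survive the q/|ρ| edge
filter, 99.4% of retained edges are planted ones, the metabolite modules
match the planted partition at ARI 0.95, and the community decomposition
groups each latent factor's features together (11 communities at Q = 0.89
for the 10 planted factors plus stragglers).

`run_all(analysis_config(seed = 1), outdir)` executes every stage on a
simulated cohort and writes TSV/JSON results (edge tables, module maps,
eigenprofiles, PERMANOVA screen, differential abundance, reporter scores,
communities, CV metrics) plus a manifest with config, seeds and checksums.
A command-line dispatcher with per-stage subcommands is installed at
`inst/cli/trinetomics.R`.

## Documentation

The methods vignette (`vignettes/trans-omics-pipeline.Rmd`) describes the
model behind each stage, the tunable parameters and their defaults, the
numerical conventions (tie-breaking, degenerate inputs, fallbacks), what
the synthetic generator does and does not emulate, and known limitations.
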