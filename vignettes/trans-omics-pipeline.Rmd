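---
title: "Trans-omics correlation networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trans-omics correlation networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analytical problem

Cohort studies increasingly profile several molecular layers on the same
subjects: shotgun metagenomics of the gut microbiome (summarized as
metagenomic species, MGS, and functional gene modules), untargeted
metabolomics of urine, and a panel of blood clinical parameters.
`trinetomics` implements an integrative workflow for such three-domain data:
it reduces the metabolome to co-abundant modules, screens all cross-domain
feature pairs for rank correlation, keeps the triples of features that are
coherently associated across all three domains, models the filtered
inter-omic graph as communities, and quantifies how well each domain
predicts clinical state. Every stage is driven by one configuration object
(`analysis_config()`) and one master seed.

Because real cohorts of this kind are not freely redistributable, the
package ships a first-class synthetic cohort generator with a recoverable
ground truth; all calibration and recovery claims made below are claims
about that generator, exercised by the test suite.

## Metabolite co-abundance modules

Untargeted metabolomics yields tens of thousands of redundant features
(adducts, fragments, isotopes, co-regulated compounds). The package follows
the weighted signed co-abundance approach: after a `log2` transform
(`log2_transform()`, pseudocount defaulting to half the smallest non-zero
intensity, which keeps the transform scale-aware and finite at zero), the
pairwise **biweight midcorrelation** (`bicor()`) is computed. Bicor weights
observations by Tukey biweights around the median,
`u_i = (x_i - med)/(9 mad)`, `w_i = (1 - u_i^2)^2` inside `|u_i| < 1`, which
makes the correlation robust to the spike-like outliers common in intensity
data. When a feature's MAD is zero the biweights are undefined and that
side degrades to ordinary centered deviations (logged); this is the only
fallback in the stage.

The signed adjacency `a_ij = ((1 + c_ij)/2)^beta` maps strong negative
correlations near 0 and strong positive ones near 1. The power `beta`
(default 13) can be chosen by the scale-free topology criterion
(`pick_soft_threshold()`): for each candidate power the whole-network
connectivity distribution is binned and `log10(frequency)` is regressed on
`log10(connectivity)`; the smallest power whose fit R² reaches the target
(default 0.85) wins, with the argmax as fallback and the largest grid power
(plus a warning) when connectivity is degenerate. Features are then
clustered on the **topological overlap dissimilarity** rather than
`1 - a_ij`: sharing of neighborhoods is a much more stable signal than a
single adjacency entry at high powers.

The published dynamic hybrid tree-cut algorithm is heavily parameterized;
`cluster_modules()` implements a deliberately simplified, deterministic
variant: average-linkage clustering cut at a fixed fraction of the maximal
merge height, `h_cut = (1 - 0.01 (deep_split + 1)) h_max`, so deep split 4
(the default) cuts at 95% of the tree height and deep split 0 at 99%.
The fraction is anchored at the *top* of the tree because TOM trees built
from sparse high-power networks concentrate all unrelated-feature merges in
a narrow plateau just below `h_max`; cutting slightly below that plateau
separates genuine co-abundance branches without chasing within-branch
structure. Branches below `min_size` (default 3) are labeled
`"unassigned"`; when the expression data are available, each unassigned
feature is rescued into the module whose eigenprofile it correlates with at
0.3 or better. If all dissimilarities are identical the tree is a single
plateau and everything is unassigned — the documented degenerate rule.
This variant is not claimed to match the original hybrid cut
feature-for-feature; what is claimed (and tested) is recovery of planted
modules: on cohorts with loading 0.8, ten modules of 5–20 metabolites and
300 samples, the adjusted Rand index against truth exceeds 0.8 (it is
typically ≈ 1).

Each module is summarized by its **eigenprofile** (`eigenprofiles()`): the
first principal component of the standardized member submatrix, scaled to
unit variance and oriented so its correlation with the member-mean profile
is nonnegative (when that mean is constant — e.g. two perfectly
anti-correlated members — orientation falls back to the first member).
The variance-explained fraction is reported alongside.

## Correlation screens and triangular retention

All cross-domain screens use Spearman correlation (`spearman_cor()`):
Pearson on mid-ranks with a two-sided p from the t approximation
`t = rho sqrt((n-2)/(1-rho^2))`. The t approximation is appropriate for the
cohort sizes this pipeline targets (n ≈ 100–300); it is exact enough that
`cor.test`'s estimate agrees to machine precision on tied data. Missing
phenotype values are handled by pairwise deletion with re-ranking, and the
number of complete pairs is recorded per edge (`n_used`); pairs with fewer
than 4 complete observations or a constant vector are skipped and counted.

Multiple testing is controlled per screen: each domain pair
(MGS × metabolite module, MGS × biomarker, metabolite module × biomarker)
forms one Benjamini–Hochberg family (`bh_adjust()`), mirroring an analysis
that adjusts within each round of correlations rather than globally.
Two retention rules coexist deliberately, as both appear in this style of
analysis: **triangular retention** (`triangular_retention()`) keeps feature
triples whose three legs are all significant at p < 0.05 — used for
heatmap-style reporting of coherent cross-domain triples — while the
**network filter** (`filter_for_network()`) keeps single edges at q < 0.1
and |rho| ≥ 0.3 (boundary kept), discarding within-domain edges entirely,
as only inter-omic structure is wanted in the community graph.

## Community modeling

The filtered edges form a node-typed undirected graph
(`graph_from_edges()`). Girvan–Newman decomposition (`girvan_newman()`)
iteratively removes the edge with the highest **edge betweenness** — the
number of weighted shortest paths between all unordered node pairs crossing
the edge, with fractional credit for ties — recomputing betweenness after
every removal until no edges remain. Betweenness is computed by Brandes'
algorithm in C++ (the per-removal recomputation makes pure R infeasible at
realistic graph sizes); it is verified exactly against exhaustive
shortest-path enumeration on random graphs.

Three details are open in most descriptions of this procedure and are fixed
here as documented choices:

* **Edge length.** "Weighted shortest paths" needs a length; the package
  uses `1 - |rho|` (stronger correlation = shorter path), floored at 1e-6
  so perfect correlations cannot create zero-length paths; a unit-length
  option exists.
* **Tie breaking.** Equal betweenness is resolved by lexicographic edge id
  (edges are canonicalized `from < to` and sorted at construction), making
  the removal order fully deterministic.
* **Cut selection.** The removal sequence is scanned and the recorded
  component partition (initial components included) maximizing
  Newman–Girvan modularity `Q = sum_c (e_c/m - (d_c/2m)^2)` on the original
  graph is returned — the canonical companion criterion when a stopping
  rule is not stated. Earliest cut wins ties.

`community_summary()` prunes communities below `min_community_size`
(default 5, a choice standing in for an unspecified "pruning of loose
connections") and tabulates node counts per domain and edge counts,
percentages and correlation signs per domain pair. Percentages are of the
community's own edge total; they are displayed to one decimal when the
community has at least 1000 edges and to the nearest integer otherwise,
which reproduces the usual display convention for such summaries. The raw
(unrounded) percentages always sum to 100.

## Covariate screening, differential abundance, enrichment

**PERMANOVA** (`permanova()`) is implemented directly for the
single-variable case: the squared distance matrix is Gower-centered,
`G = -1/2 J D^2 J`, the model sum of squares is the quadratic form of `G`
on the standardized centered covariate, `r^2 = SS_model/SS_total`, and the
pseudo-F is referenced to its permutation distribution with the add-one
rule (p is never 0; 999 permutations by default, seeded). The direct
implementation makes the per-variable screen (`permanova_screen()`) and
null-calibration simulations fast; `vegan::adonis2` serves as the
independent cross-check in the tests, and the distance defaults to
Bray–Curtis on relative abundances (`bray_curtis()`, via `vegan::vegdist`)
— a conventional choice for compositional microbiome data, configurable in
principle by passing any distance matrix.

**Differential abundance** uses the Mann–Whitney U test
(`mann_whitney()`): exact enumeration of the permutation distribution for
combined sizes up to 12 (ties handled through mid-ranks), the
tie-corrected normal approximation without continuity correction above
that. `U` counts pairs where the first group exceeds the second (ties ½),
so `U = 0` means complete separation downward.

**Reporter scores** (`reporter_score()`) aggregate member-feature
significance into module-level Z-scores: `z_i = qnorm(1 - p_i)` signed by
the feature's direction (here, the sign of the group-median difference),
`Z = sum z_i / sqrt(k)`, background-corrected by the mean and standard
deviation of the same aggregate over random size-k feature draws
(sampling, 1000 draws by default, seeded; a closed-form Normal null would
also be defensible but the sampling null is agnostic to the realized
p-value distribution). Modules with `|Z_corrected| >= 1.96` are flagged.
Calibration is tested: randomly drawn modules give corrected scores with
mean ≈ 0 and sd ≈ 1.

## Predictive evaluation

`repeated_cv()` implements repeated, stratified, down-sampled k-fold
cross-validation (defaults 10 folds × 5 repeats). For classification the
folds are stratified to the cohort's class proportions and, within each
*training* fold only, the majority class is randomly subsampled to the
minority size before fitting — the standard remedy for the unbalanced
case/control ratios of screening cohorts. Test folds are never modified,
so reported performance refers to the real class balance. Down-sampling is
not applied to regression targets: no class structure exists there, and the
package takes no position on what down-sampling should mean for continuous
responses. The learner is a pluggable `fit`/`predict` contract; the default
is a 500-tree random forest with the library's standard features-per-split
(`sqrt(p)` classification, `p/3` regression). Classification is scored by
AUC (`roc_auc()`, the exact rank statistic `U/(n1 n0)`, identical to the
Mann–Whitney U up to scaling — an identity the tests assert), regression by
Spearman correlation between out-of-fold predictions and observations.
Out-of-fold predictions are pooled within each repeat, scored per repeat,
and averaged across repeats.

One caveat the tests document: a degenerate "predict the training mean"
baseline is not exactly null under cross-validation — fold-wise training
means are mildly *anti*-correlated with held-out values (the usual
leave-out artifact, ≈ −0.27 at 10 folds and n = 100), so null checks on
baselines are one-sided (no positive signal).

## The synthetic cohort and what it does not show

`generate_cohort()` draws, per subject, independent standard normal latent
factors; a feature assigned to factor j has latent value
`lambda f_j + sqrt(1 - lambda^2) sd_noise eps`, so two features sharing a
factor have latent correlation `lambda^2` at the default noise scale, and
one factor per feature keeps the planted-edge truth unambiguous.
Microbiome latents are exponentiated, zero-inflated by per-entry Bernoulli
presence at the configured prevalence (default 0.9), and renormalized per
sample (compositional closure; a sample losing all features keeps its
dominant one so closure stays defined). Metabolite latents are
exponentiated into log-normal intensities; each factor owns one metabolite
module with size drawn from the configured range. Biomarkers are affine
transforms of their latents on clinical-looking scales. The binary disease
label follows a logistic model on standardized driver biomarkers that are
chosen among the *factor-independent* biomarkers, with a baseline case
fraction of 0.74 — emulating a screening cohort enriched for cases — so
the microbiome carries no label signal by construction and the expected
qualitative result (biomarkers outclassify the microbiome) is a designed
property, not an accident. Defaults (138 subjects, 100 MGS, 150
metabolites, 30 biomarkers, 10 factors, loading 0.8) emulate the scale of
a single-center screening cohort while remaining fast enough for repeated
simulation.

What the generator does **not** emulate: batch and injection-order
effects, sequencing depth variation, compositional negative correlation
induced by closure of strong signals, heavy-tailed clinical outliers,
missing phenotype patterns, or any causal structure between domains.
Passing recovery and calibration tests therefore demonstrates correctness
of the algorithms under a clean latent-factor model — not performance on
real cohort data.

## Validation problem sizes

The test suite validates at sizes chosen to make the statistical checks
meaningful while keeping repeated simulation practical: FDR calibration on
200 null cohorts (50 MGS × 50 metabolites × 20 biomarkers, n = 150, with
the realized false-discovery proportion computed within each BH family);
PERMANOVA null calibration on 1000 replicates (n = 40, 100 features, 999
permutations, rejection rate required in [0.03, 0.07]); reporter
calibration on 500 random modules; planted-structure recovery on the
standard cohort at loading 0.8 and n = 300; and exact oracle equivalence
of edge betweenness against path enumeration on 100 random graphs of up to
10 nodes. `scripts/acceptance.R` re-runs the full pipeline on the default
cohort from a command-line seed and reports the main computed quantities.

## Known limitations

* The tree cut is a static simplification of the published dynamic hybrid
  algorithm; module boundaries on real, noisy dendrograms will differ from
  the original implementation even where planted structure is recovered.
* Spearman screens are not compositionality-aware; on strongly
  closed data, proportionality-based association measures would be more
  appropriate than plain rank correlation.
* PERMANOVA is single-variable by design; confounding between covariates
  is not adjusted for.
* Girvan–Newman recomputes betweenness after every removal (O(E²V) with
  the C++ kernel); graphs beyond a few thousand edges call for a different
  community algorithm.
* The generator's one-factor-per-feature rule precludes overlapping module
  structure; recovery scores on it say nothing about overlapping or nested
  co-abundance patterns.
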