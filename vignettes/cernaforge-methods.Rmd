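---
title: "Models and methods behind cernaforge"
author: "cernaforge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cernaforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernaforge)
```

`cernaforge` implements a complete case/control transcriptomic inference
pipeline — cohort merging and batch removal, moderated differential
expression, weighted co-expression modules, a LASSO + random-forest
diagnostic signature, lncRNA–miRNA–mRNA (ceRNA) network construction with
hub extraction and direction-consistency pruning, and ssGSEA immune
scoring — driven by a synthetic-cohort generator that plants every
structure the analysis assumes. This vignette records the models, the
parameters that matter, the numerical choices, and what the synthetic
validation does and does not demonstrate.

## The synthetic-cohort generator

`generate_cohort()` emulates a merged two-group, multi-batch log2
microarray study. Its defaults are the study conditions the pipeline was
designed for: 16 controls vs 44 cases (the merged-cohort design of the
motivating OSA study), 1000 genes, four planted modules of 60 genes, 86
planted DE mRNAs at |log2FC| = 1.5, observation noise 0.5 log2 units, two
batches with per-feature offset SD 0.8, 120 miRNAs with planted miRNA
effects of 2.5 log2 units (comfortably above the miRNA threshold of 2),
and 10 planted ceRNA triplets carried by 5 miRNAs and a 4-lncRNA pool.

Design choices worth knowing:

* **Modules are latent-factor blocks**: gene = loading × module eigenvector
  + Gaussian noise. This matches the eigengene abstraction the module
  detector relies on. Loadings are drawn from U(0.9, 1.3); the floor keeps
  every planted module gene's variance above that of background DE genes,
  so the top-25% variance filter retains whole modules — the working
  premise of variance filtering before co-expression analysis.
* **Factors are centred within group**, so group-mean differences equal the
  planted effects exactly; planted truth is never contaminated by
  finite-sample factor imbalance. The first half of the modules
  additionally receives a case shift of the eigenvector
  (`module_trait_effect`, default 1.2), producing eigengene–trait
  correlations around 0.5 — the strength of module–trait association the
  pipeline is meant to pick up. Setting it to 0 yields a trait-null cohort.
* **Triplets are closed under the per-miRNA product.** Each triplet miRNA
  has exactly one mRNA partner and one or more lncRNA partners, so the set
  of (mRNA, miRNA, lncRNA) paths implied by the planted edges equals the
  recorded triplet list; triplet enumeration can then be scored exactly.
* **lncRNAs have no expression matrix.** As in the motivating study they
  exist only as predicted interaction partners plus a validated direction
  label, which is what the pruning stage consumes.
* **Decoy interactions** are sampled uniformly outside the true edge set;
  the two lncRNA databases share a configurable fraction of their decoys,
  so the database intersection contains the true edges for any overlap.
* **Immune gene sets** are drawn from non-DE background genes (disjoint
  sets), and shifted sets have their members raised by `shift` in case
  samples only.
* All randomness flows through one seed per generator call; identical
  parameters and seed give byte-identical bundles.

What the generator does **not** emulate: probe-level microarray artefacts,
missing values, heavy-tailed noise, correlated miRNA–mRNA sample-level
expression (the matched-design Pearson mode of the ceRNA step is provided
but the default generator validates the direction-based mode), and the
overlapping, hierarchically organized gene sets of real immune signatures.
Passing recovery tests on these cohorts therefore demonstrates the
correctness and calibration of the pipeline's logic, not its performance
on any particular real platform.

## Batch removal

`remove_batch_effect()` fits, per feature, a linear model with group and
batch covariates and subtracts only the fitted batch component
(via limma's removeBatchEffect with a group design). Batch perfectly
confounded with group is refused, since the decomposition is then not
identifiable. On data that truly follow the additive model
(baseline + group effect + batch offset, no other structure) removal is
exact to numerical precision; with latent module factors the batch estimate
carries finite-sample factor noise, which is expected and harmless
downstream. Whether differential expression runs on batch-corrected or raw
merged values is configurable (`de_on_batch_corrected`, default `TRUE`).

## Moderated differential expression

For feature *g* with group sizes n₁, n₂ and pooled variance s²_g on
d = n₁+n₂−2 df, the prior (d₀, s₀²) is estimated by moment matching on
log s²_g (the scaled-F model: e_g = log s²_g − ψ(d/2) + log(d/2), with
trigamma inversion for d₀), and

s̃²_g = (d₀ s₀² + d s²_g)/(d₀ + d), t_g = log2FC_g /(s̃_g √(1/n₁+1/n₂))

on d₀+d df; d₀ = ∞ is handled as the normal limit, and `d0 = 0` reduces to
the ordinary pooled t exactly (a tested identity). Zero-variance features
are reported with t = ±∞, p = 0 and a `degenerate` flag rather than being
silently moderated away. Thresholds are strict inequalities, exactly as the
rules are usually printed (|log2FC| > 0.58, adjusted p < 0.05 for mRNA;
|log2FC| > 2 for miRNA), with log2FC oriented case minus control so "up"
means higher in cases.

## Co-expression modules

The network is unsigned (|Pearson cor|^β). The soft threshold is the
smallest power whose scale-free fit reaches the target R² (default 0.85).
The fit summarizes connectivity over 10 equal-count bins and regresses the
log empirical *density* (bin count divided by bin width) on the log mean
bin connectivity; with equal-count bins the raw counts are constant by
construction, and the density correction is what makes the regression
informative. The signed fit index is −sign(slope)·R². When no candidate
reaches the target — common on small, module-saturated matrices such as
the demo's filtered 250 genes — the best-fitting power is used and a
warning is raised.

Module detection is the deterministic "tree" variant of the dynamic cut
(the full hybrid algorithm, with its PAM-like reassignment stage, is out
of scope): average-linkage clustering of 1−TOM, a static cut at 0.99 of
the maximum merge height, then a recursive refinement in which each
cluster's subtree is re-cut and a split is accepted only if it produces at
least two submodules of `min_module_size` (default 50, reading the quoted
"minBlockSize = 50" as the minimum module size a tree cut actually takes)
whose eigengene dissimilarity is at least `merge_cut_height` (default
0.15). The split guard is the merge criterion applied symmetrically, so
the procedure never creates modules the merge step would immediately undo;
it is what separates correlated disease modules that a single static cut
tends to leave fused. Genes outside any accepted module are grey.
Eigengenes are unit-norm first principal components of the standardized
module expression, sign-oriented towards the module mean profile. The gene
tree uses 1−TOM; Euclidean distance is used only for sample outlier
detection, resolving the ambiguity in the usual description of the
workflow. Module–trait p-values are reported raw (uncorrected across
modules), matching how such matrices are usually printed.

## Diagnostic signature

LASSO feature selection is L1-penalized logistic regression over a λ path
(glmnet) with features standardized internally; λ is the 10-fold
cross-validated deviance minimizer by default (`lambda_rule = "1se"` is
available — the published workflow shows a CV curve without stating the
rule). The forest is fit in regression mode on the 0/1 response
deliberately: %IncMSE and IncNodePurity, the two importance measures
reported in this literature, are regression-forest quantities. AUC is
computed by the rank (Mann–Whitney) identity with ties counted one half.
Outer cross-validation (default 5-fold, the split of roles being 10-fold
for λ inside the selection and 5-fold for performance) refits the entire
LASSO + forest pipeline per fold; folds that lose a class in the held-out
set (leave-one-out) contribute scores but no per-fold AUC, and a pooled
AUC over all held-out scores is reported alongside. Published AUCs for the
real cohorts (around 0.91 training / 0.79 validation) depend on the
original data and split seed and are context, not test targets.

## ceRNA construction and pruning

"Negative correlation" between miRNA and mRNA is operationalized as
opposite DE direction, because the mRNA and miRNA profiles come from
non-overlapping cohorts where sample-level correlation is undefined; a
matched-design Pearson mode would be the natural extension. Only the
up-mRNA/down-miRNA/up-lncRNA polarity is constructed by default (the
polarity observed in the motivating study); `polarity = "both"` admits the
mirror. miRNA ids are canonicalized (whitespace, "miR" infix case,
-3p/-5p suffixes preserved) before any intersection, since prediction
databases disagree on casing. Hub ties at rank k break lexicographically.
Degree is computed on the full assembled network and the hub subnetwork is
induced afterwards. Pruning removes lncRNAs whose validated direction is
not "up" together with their edges, then re-applies the
continuous-targeting rule, so miRNAs left without a lncRNA partner (and
nodes thereby orphaned) drop out: a miRNA that cannot bridge an mRNA and a
lncRNA supports no triplet. On the bundled reconstruction of the published
hub network this yields exactly three lncRNAs, five miRNAs, three mRNAs
and twelve pathways. (The literature around the original analysis states
the pathway count inconsistently — twelve, nineteen and ten in different
places; the Results/Abstract figure of twelve is the one reproduced here.)

## Immune scoring

The ssGSEA score of set S in sample j ranks genes by expression (average
ranks for ties), walks the list in descending order accumulating the
rank^α-weighted in-set ECDF minus the uniform out-of-set ECDF, and sums
the running difference (α = 0.25; matrix-wide min–max normalization to
[0, 1], both configurable). Because only ranks enter, scores are invariant
to monotone per-sample transforms. One property deserves emphasis: the
score is compositional. Raising one gene group in cases depresses the
ranks — and therefore the scores — of every other set by a small,
systematic amount, and with enough samples a Mann–Whitney test will detect
it. The planted-shift recovery analyses therefore score against a
transcriptome-scale universe (6000 genes), where two shifted 30-gene sets
perturb unrelated sets by well under the sampling noise; on the demo's
compact 1000-gene cohort the same effect makes unshifted sets nominally
significant, which is a faithful property of ssGSEA rather than a defect
of the test. Spearman p-values use the t approximation on n−2 df (the
cohort sizes in this setting are ≥ 34), with exact permutation enumeration
available for n ≤ 10. Group comparisons use the two-sided Mann–Whitney
test, exact by enumeration for group sizes ≤ 8 without ties, otherwise the
tie-corrected, continuity-corrected normal approximation, reporting
U = min(U₁, U₂). No curated human immune signature list is bundled — the
provenance and licensing of the usual "from the literature" collections is
unclear — so gene sets enter as standard GMT files or from the generator.

## Orchestration, determinism and problem sizes

`pipeline_config()` validates every parameter (unknown keys rejected)
before any stage runs; `run_pipeline()` executes the stages in order,
writes each stage's tables plus a manifest (parameters, seed, input
hashes, package version) into the run directory, and logs feature counts
at every filter so the funnel (DE → module-specific → network → hubs →
pruned) is visible in every run. `run_demo()` generates a default bundle
(20/20 samples to keep the demo fast), runs everything, and writes a
recovery summary. All stochastic steps (generation, fold assignment,
forests, splits) are driven by explicit seeds through a local RNG scope,
so reruns are byte-identical.

The shipped validation uses deliberately desk-scale problem sizes: TOM and
module recovery at 1000 genes × 44 samples, DE null calibration over 50
cohorts of 200 features, LASSO recovery over 25 cohorts of 30 candidates,
immune recovery over 10 cohorts of 6000 genes. These sizes were chosen so
that each property is measured with reasonable statistical resolution
while the whole suite stays interactive; all of them are parameters, not
limits of the implementation (the module stage is O(p²) memory in the TOM
and is comfortable to a few thousand filtered genes — blockwise processing
for >20k genes is a non-goal).

## Known limitations

* The tree-variant cut, even with the recursive refinement, is less able
  than the full hybrid dynamic cut to recover modules embedded in strong
  background correlation, and offers no PAM-style reassignment of
  borderline genes.
* Direction-based ceRNA filtering cannot use expression magnitude; a
  matched-cohort correlation filter is stubbed but not the default.
* ssGSEA's compositional sensitivity (above) means group comparisons on
  small gene universes should be read with care.
* The signature stage assumes a binary phenotype; multi-class and paired
  designs are out of scope, as are GO/KEGG enrichment and any live
  database queries.
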