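---
title: "Methods: temperature, host tolerance, and the gut microbiome"
author: "thermogut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temperature, host tolerance, and the gut microbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermogut)
```

## The question and the design

`thermogut` analyses a split-family thermal-challenge design: two host
groups selected for cold tolerance (resistant, sensitive), three full-sib
families per group, seven fish per family per temperature arm (warm
control vs cold challenge, different siblings in each arm), and two gut
compartments per fish. The scientific questions are (i) how temperature
and host tolerance structure gut-community diversity and composition,
(ii) whether the resistant host background *buffers* the community's
response to cold, and (iii) whether the host's own transcriptomic response
is coupled to the microbiome's.

Because fish in the two arms are different individuals, nothing is paired:
all warm-vs-cold comparisons are between group-level quantities, and
family enters as a random effect rather than a blocking pair.

## Stage-by-stage model

### Filtering, rarefaction, α-diversity

Features seen in fewer than two samples are removed
(`filter_doubletons()`), and samples are subsampled without replacement to
a common depth (`rarefy()`, default 6000 reads per sample) so that
richness and dissimilarity are not library-size artifacts. Richness is the
count of features with positive count; Shannon diversity is
H′ = −Σ pᵢ log pᵢ over present features. The logarithm base defaults to 2,
the historical convention of the amplicon toolchain this pipeline mirrors;
base *e* is one argument away. Rarefaction conserves each sample's total
exactly and never inflates a count; both properties are tested.

Diversity responses are modeled with a REML random-intercept linear mixed
model (`fit_diversity_lmm()`, via `nlme`): fixed effects for temperature
and tolerance, a random intercept for family. Marginal F-tests are
reported with `nlme`'s innermost-level denominator degrees of freedom, and
the convention is recorded in the result because denominator-df choices
differ between mixed-model implementations. The model can be fitted per
sample or per fish (`unit = "fish"` averages the two gut parts first);
both options exist because a 168-sample/84-fish design supports either
reading and they give different residual df.

### β-diversity and distance contrasts

Bray–Curtis dissimilarity on (rarefied) counts is the working metric;
Jaccard distance on presence/absence serves the expression matrix, where
"present" means above a detection threshold (default 0 — any positive
normalized abundance counts; the cutoff is exposed because normalized
expression has no canonical zero). Two empty presence sets get distance 0.

`distance_contrast()` compares two declared multisets of pairwise
distances (e.g., resistant warm↔cold pairs vs sensitive warm↔cold pairs)
with a pooled-variance t statistic and a Monte-Carlo p-value from
relabeling the pooled distances (default 1000 permutations), Bonferroni
correction across declared comparisons. Distances that share a sample are
not independent; the classical procedure this reproduces treats pairs as
exchangeable units anyway, and we keep that behavior deliberately rather
than "fixing" it — the permutation machinery itself is validated on
synthetic matrices whose entries are exchangeable by construction.

### PERMANOVA

`adonis_dm()` is a from-scratch sequential (Type I) permutational
multivariate ANOVA. With Gower-centered G = C(−½D∘D)C and cumulative
treatment-coded designs X₀ ⊂ … ⊂ X_m with hat matrices Hₖ:

* SSₖ = tr((Hₖ − Hₖ₋₁)G), SS_res = tr((I − H_m)G), total SS = tr(G);
* pseudo-Fₖ = (SSₖ/dfₖ)/(SS_res/df_res), R²ₖ = SSₖ/tr(G);
* p-values from free joint row/column permutation of G (default 999),
  ties counted as exceeding (conservative).

Degrees of freedom are ranks of successive design increments, so nested
or confounded factors get their *effective* df: with families nested in
tolerance groups, `family` after `tolerance` contributes 4 df, not 5. A
`family_numeric` switch recodes family as a single numeric covariate
(1 df) for users who need to mirror legacy tables built that way; the
factor coding is the default because collapsing six families to one slope
is an artifact of numeric coding, not a model choice we endorse. Sequential
SS depends on term order (tested); the partition identity
ΣSS + SS_res = tr(G) holds for every order.

On Euclidean distances the whole decomposition collapses to ordinary
multivariate ANOVA on coordinates; the test suite checks this identity
exactly on hand-computable instances and against brute-force
coordinate-space ANOVA on random small instances, and checks agreement
with `vegan::adonis2` as an independent reference.

### Indicator values

`indval()` implements the Dufrêne–Legendre statistic: for feature *i* and
group *j*, specificity Aᵢⱼ = x̄ᵢⱼ / Σₖ x̄ᵢₖ (share of mean abundance),
fidelity Bᵢⱼ = within-group prevalence, IndValᵢⱼ = Aᵢⱼ·Bᵢⱼ·100. The
per-feature statistic is maxⱼ IndValᵢⱼ with a group-label permutation p
(default 1000). Raw p is primary; a Holm adjustment across features is
attached by `filter_indicators()` for reference, since the significance
threshold for calling a feature "host-associated" is a user decision and
is exposed as one. The Monte-Carlo p is checked against exhaustive
enumeration of label assignments on ≤8-sample instances.

### Core microbiome and resilience

The core is every feature whose prevalence among *individuals* strictly
exceeds 0.5 in the warm arm or the cold arm. Individuals are fish, not
samples: a fish is positive if either gut part carries the feature. The
"either arm" default follows the protocol's methods wording; a
`mode = "both"` option implements the stricter reading because the two
are genuinely ambiguous in the source material. Core counts are
renormalized to percentages within the core; per group, each feature's
fold change is mean(cold)/mean(warm) on those percentages, and the two
groups' |log₂ FC| distributions are compared with a two-sided Wilcoxon
rank-sum test. A zero warm-arm mean is replaced by half the smallest
nonzero renormalized value and flagged — a pseudo-abundance, reported, so
fold changes stay finite without silently dropping features.

### Host–microbiome linkage

`component_scores()` reduces each data set to k sample scores (default
k = 4; the source protocol names four components in its methods and five
in its results text, so k is a logged knob, defaulting to the methods
value). The microbiome side uses PCoA on Bray–Curtis; the expression side
uses PCA on log-transformed values (`pca_log`, offset = half the smallest
positive value), because the raw scale of non-negative normalized
expression is dominated by a handful of high-abundance transcripts and
hides multivariate structure that is plainly visible on the log scale.

`cca_redundancy()` computes canonical correlations ρₜ via an
orthonormalized cross-product SVD and summarizes the linkage as the
Stewart–Love redundancy of A given B: Σₜ ρₜ² · (fraction of A's total
variance captured by A's t-th canonical variate). The source material
reports "total variance explained through all canonical variates" without
a formula; the redundancy index is the standard statistic matching that
description, and the choice is recorded in the output. Two exact
identities pin the implementation down: redundancy(A | A) = 1, and with
one column per side it equals the squared Pearson correlation.
`cca_permutation_test()` shuffles the row order of B only (destroying the
sample correspondence, preserving each side's internal covariance),
default 1000 permutations.

## The synthetic generator

`generate_microbiome()` draws from an explicit compositional model so
that every downstream claim has a known truth:

* a log-normal baseline abundance spectrum (log-sd 1.5) over `n_taxa`
  (default 150), perturbed per tolerance group (log-sd 0.3) so the groups
  differ already at warm — the host-background effect;
* `n_core_taxa` (default 11) taxa given a floor-plus-boost on the log
  baseline so they are abundant, and a damped fold-change response
  (×0.3), making them the prevalent, resilient fraction the core-microbiome
  stage is meant to find;
* a shared taxon log-fold-change direction L ~ N(0,1); each group's cold
  composition is warm × exp(δ_group·L), with δ_resistant = 0.3 ≤
  δ_sensitive = 1.0 — the headline buffering structure;
* cold-induced richness loss: the rarest 30% of non-core taxa are zeroed
  at cold (detection-limit dropout, which is how richness is lost in real
  cold-stressed communities — abundant members rarely vanish outright);
* per-family random log intercepts (sd 0.15), giving the mixed model a
  variance component to recover;
* per-sample Dirichlet-multinomial counts: concentration 60 at warm, 30
  at cold (more dispersion under stress), library sizes
  Poisson(20 000).

`generate_expression()` builds expression as
λ·(scores × loadings) + N(0, σ²) on the log scale, exponentiated; the
latent scores are the standardized leading principal directions (default
4) of the realized clr compositions, using a half-read pseudo-proportion
at nominal depth. Tying the scores to the *leading* compositional axes is
what makes the linkage recoverable by an ordination-based CCA: signal
planted in trailing axes would be invisible to any method that looks at
top components, which would test the generator, not the statistic. With
λ = 0 the two data sets are independent — the null configuration used for
calibration.

What the generator does **not** emulate: sequence-level artifacts
(chimeras, primer bias), taxonomic correlation structure (taxa are
exchangeable), a gut-part effect (the two compartments are replicate
draws from the same fish-level composition, so the PERMANOVA `part` term
is null by construction), and compositional zeros beyond the dropout
mechanism. Passing tests therefore demonstrate that the statistics
recover the planted design under realistic overdispersion and sparsity —
not that they are robust to every failure mode of real amplicon data.

## Numerical and testing choices

* Permutation p-values are (1 + #{stat* ≥ stat})/(1 + n_perm) everywhere;
  ties count toward the null.
* One master seed drives a named stream per artifact (counts, expression,
  rarefaction, each permutation stage), so changing one stage's draw count
  cannot shift another's.
* Sample order is canonicalized lexicographically on ingest
  (`align_tables()`), making permutation streams reproducible regardless
  of input file order.
* Eigenvalues below 10⁻⁹ of the spectral radius are treated as null in
  PCoA; negative eigenvalues (non-Euclidean Bray–Curtis) are dropped and
  reported, and the reconstruction error they imply is bounded in tests.
* The test suite runs the study-scale checks at reduced permutation
  counts (99–199) and moderate seed sweeps (20–200 seeds, 50 for the
  end-to-end recovery, 100 for the CCA power check), sizes chosen so the
  binomial/KS margins are meaningful while the whole suite stays fast;
  protocol-default permutation counts (999/1000) are asserted separately
  as configuration defaults and used by `run_pipeline()`.
* In the mixed-model recovery test, planted family effects are
  standardized to realized variance 1 so the check isolates estimator
  error from the sampling noise of drawing six effects.

## Limitations

* The PERMANOVA uses free permutation; exchangeability restrictions
  (strata by family or tank) are not applied by default, matching the
  classical Adonis default rather than the strictest possible null.
* The distance-contrast test inherits the pair-nonindependence of the
  procedure it reproduces; treat its p-values as the field does, not as
  exact.
* Redundancy-based CCA linkage is correlational; with n of order 100 and
  k = 4 it detects shared structure but does not identify direction or
  mechanism.
* Rarefaction discards data; it is kept because the downstream metrics
  (richness, Bray–Curtis) are depth-sensitive and the protocol being
  mirrored rarefies. No variance-stabilizing alternative is provided.
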