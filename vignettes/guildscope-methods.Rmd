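---
title: "Methods: guild discovery and anemia risk prediction from gut microbiome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guild discovery and anemia risk prediction from gut microbiome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

guildscope implements the statistical pipeline of a prospective
gut-microbiome cohort study of gestational anemia (GA): pregnant women
sampled in the second (T2) and third (T3) trimester, with GA defined as
hemoglobin strictly below 100 g/L at T3 — deliberately stricter than the
WHO 110 g/L cutoff, to allow for the physiological plasma-volume
increase of pregnancy. The package covers the whole arc from
participant-flow accounting to prospective risk prediction, and ships a
seeded synthetic-cohort generator so that every stage can be tested
against known ground truth. This vignette explains the models, the
tunable parameters, the numerical choices, and what the simulation
evidence does and does not establish.

```{r setup, message = FALSE}
library(guildscope)
```

## The synthetic cohort generator

No per-sample sequencing data are distributed with the study design the
package targets, so the generator (`generateCommunity()`) is a
first-class component, not a test fixture. It draws from a latent
log-normal factor model:

* each sample draws one standard-normal factor per taxon *block*
  (the planted co-abundance guilds);
* the log-abundance of taxon $t$ in block $b$ is
  $\mu_t + \sqrt{\rho}\, f_b + \sqrt{1-\rho}\,\varepsilon_t$, so the
  within-block latent correlation is exactly $\rho$
  (`withinBlockCorr`);
* log-abundances are exponentiated and column-normalized into
  compositions, and reads are drawn multinomially at a per-sample
  log-normal depth.

This produces compositional, overdispersed, block-correlated count
tables — the three features the downstream analyses assume. The
defaults are the cohort's reference conditions: 156 cases vs 402
controls, 99 genera in 8 blocks, $\rho = 0.7$, mean depth 40{,}000
reads (log-SD 0.3) so that rarefaction to the study depth of 31{,}291
has work to do, and five planted 2-fold differential genera. The
reported genus-level effect sizes in this literature are thresholded
LDA scores rather than fold changes, so the planted fold change is a
free parameter; 2-fold on a moderately abundant genus is the smallest
effect the screening pipeline should plausibly catch at $n = 558$, and
it is fixed once here rather than tuned per experiment.

Group labels come in two modes. With fixed labels, the configured
case/control counts are assigned at random and the planted
`differentialTaxa` shift case abundances. With `outcomeCoefficients`,
labels are instead drawn from a logistic model on the standardized true
block abundances, with the intercept solved numerically so the expected
prevalence matches 156/558; in this mode planted fold changes are
ignored (with a warning), because a shift conditional on a label cannot
precede a label drawn from the realized abundances.

Covariate and clinical-index distributions
(`defaultCovariateSpec()`, `defaultClinicalSpec()`) are calibrated to
the descriptive cohort table: 13 enrollment covariates with the
reported category frequencies, and eight clinical indices in
conventional units whose case-minus-control shifts reproduce the
reported directions (ALB, DB, FT4, Hb, RBC, TB decreased in GA; serum
iron unshifted). Hemoglobin honors the cohort design by truncated-
normal draws: everyone is non-anemic at T2, cases are below 100 g/L at
T3. One master seed expands into per-stage child seeds by a fixed
affine rule (`childSeed()`), so adding a timepoint or the clinical
table never perturbs earlier draws.

What the generator does *not* emulate: taxonomic misassignment, raw
read errors, within-subject longitudinal dynamics (T2 and T3 are
independent draws for the same subjects), and covariate-microbiome
confounding (covariates are drawn independently of the community
unless the user wires them together). Passing tests therefore show
that the pipeline recovers structure *of the kind it assumes*, not
that real cohorts satisfy those assumptions.

## Cohort flow and descriptive statistics

`applyExclusions()` applies an ordered exclusion cascade in which a
subject flagged for several criteria is counted once, under the first
criterion — the arithmetic that makes a participant-flow diagram's
counts subtract cleanly (781 providers − 19 − 8 − 142 − 54 = 558).
`summarizeTable1()` produces mean ± SD with Welch's *t* for continuous
characteristics and n (%) with *uncorrected* Pearson χ² for
categorical ones. The continuity-corrected χ² was rejected because only
the uncorrected statistic reproduces the printed two-decimal p-values
of the reference cohort table for fetal gender (0.98) and parity
(0.48); gravidity computes to 0.7447, one rounding step from the
printed 0.75. Welch rather than pooled *t* is the robust default when
the source says only "t-test". Percentages are always recomputed from
counts; the formatted strings are presentation-only.

## Diversity and PERMANOVA

Alpha diversity uses Shannon entropy in log base 2 (the common
amplicon-pipeline convention; the base is a parameter) and observed
features. `rarefyCounts()` subsamples each column without replacement
to a common depth, dropping (never rescaling) samples below depth —
standard rarefaction semantics. Beta diversity offers Bray–Curtis (via
vegan) and both UniFrac variants computed over an `ape` tree:
unweighted UniFrac is unique-branch length over covered-branch length,
and weighted UniFrac is normalized by the branch-length-weighted sum of
the two profiles so values lie in [0, 1] (the classical normalized
variant, recorded in the result's `variant` attribute; verified against
phyloseq in the test suite).

`permanova()` implements the one-factor pseudo-F from total and
within-group sums of squared distances with a seeded label-permutation
p-value using the +1 convention, $p = (1 + \#\{F^* \ge F\})/(B + 1)$,
so p is never zero; 9999 permutations is the study convention. The
implementation is cross-checked against exhaustive enumeration at
$n = 6$ and against vegan's `adonis2` statistic, and its type-I error
is verified to sit in [0.03, 0.07] under a 500-replicate null. The
PERMANOVA is unadjusted one-factor; whether covariate-stratified
permutations were used in the source analysis is unstated, and the
simple design is the reproducible default.

## Differential abundance

`lefseLite()` is a deterministic LEfSe-style pipeline:
Kruskal–Wallis screening per taxon, Benjamini–Hochberg FDR across taxa
*at the screening stage* (the source applies its 5% FDR there, which
is nonstandard for classic LEfSe but followed here), then an LDA
effect size with the conventional retention rule `q < 0.05` and
`|LDA| > 2`. The effect size is a reproducible single-feature variant:
abundances are rescaled to the per-million scale, and because the
one-dimensional discriminant direction has unit norm, the projected
between-class difference equals the raw difference of group means;
the score is its log10, floored at magnitude 1 so scores land on the
familiar 0–6 scale. No bootstrap subsampling is performed —
reproducibility was chosen over fidelity to LEfSe's stochastic
averaging, and the threshold semantics are unchanged. A consequence
worth knowing: the score scales with absolute abundance, so a rare
taxon with a large fold change can sit below `|LDA| = 2`, exactly as
in LEfSe.

`adjustedLinearModels()` is the covariate-adjusted confirmation step:
per taxon, ordinary least squares of the arcsine-square-root
transformed relative abundance on group plus the 13 enrollment
covariates (dummy-encoded against the first level), group-coefficient
t-test, BH across taxa. The arcsine-square-root transform is the
classic choice for proportions; log10 with a half-minimum pseudocount
is available by flag. Since the source's exact model version is
uncited, coefficients are not numerically comparable to published
ones — only the screening logic is.

## Co-abundance guilds

`clusterCags()` follows the guild-discovery recipe: taxa (the top 99
by mean relative abundance, ties broken lexicographically) are
clustered hierarchically on the distance $1 - \rho_\text{Spearman}$
between abundance profiles, with Ward linkage — the source names only
the distance; Ward gives compact, balanced guilds and is the common
choice in the co-abundance literature (linkage is a parameter). The
number of clusters is selected by significance testing: for every
candidate $k$, each pair of clusters is tested by PERMANOVA on the
Kendall-correlation distance $1 - \tau_b$ restricted to the pair, with
cluster membership as labels; the chosen $k$ is the largest candidate
with all pairwise $p < 0.05$. Kendall τ-b (tie-corrected) is essential
because zero-inflated genus vectors are massively tied. When no $k$
passes, the $k$ with maximal mean between-cluster R² is used and
flagged prominently.

One property of this (source-prescribed) rule deserves honesty: the
clusters are cut from nearly the same correlations they are then
tested on, so the pairwise tests are circular and anti-conservative —
with genuinely unstructured data the rule still tends to find
"significant" small $k$ rather than falling back. The fallback
therefore engages on degenerate inputs or stricter `alpha`, not on
generic noise; the per-$k$ diagnostics are always returned so users
can override $k$. Whether taxa should be clustered on abundance
profiles or on rows of the Kendall matrix is not recoverable from the
source; both are implemented (`profile = "abundance"` default).

Guild abundance is the sum of member relative abundances per sample,
with an explicit `unassigned` remainder row so columns still sum to 1.

## Sparse partial-correlation networks

`sparsePartialNetwork()` estimates a Gaussian graphical model by the
graphical lasso (Friedman-style block coordinate descent, written for
this package) along a log-spaced path of 100 penalties from
$\lambda_{\max}$ (smallest penalty giving the empty graph) down to
$0.01\,\lambda_{\max}$. Model selection uses the extended BIC with
$\gamma = 0.5$, evaluated at the *support-constrained maximum
likelihood* for each candidate edge set — the original EBIC
formulation for graphical models. The more common shortcut of scoring
the penalized estimate itself was tried first and systematically kept
a spurious chain-closing edge in the X→Y→Z benchmark at $p = 3$,
$n = 2000$: the sparse support only appears under heavy shrinkage,
whose likelihood cost swamps the per-edge penalty. Refitting each
support removes that artifact; with it, chains stay open, null graphs
are empty, and larger $\gamma$ never yields more edges. Edge weights
are partial correlations
$-\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}$ from the selected
support's constrained MLE (so the two-variable network reports the
exact pairwise correlation). Non-positive-definite input correlations
are diagonally regularized and logged; the unpenalized limit is
special-cased to direct inversion and verified against `solve()`.

## Clinical associations

`adjustedIndexDifference()` fits each clinical index on group plus
covariates over complete cases (missing-data counts logged), BH across
indices. `partialSpearman()` computes partial Spearman correlations by
rank-transforming *all* variables — including numeric covariates —
then residualizing and correlating; ranking the covariates matters, as
residualizing ranks on raw covariate values leaves a visible
nonlinearity bias under strong confounding (≈0.11 at $n = 1000$ in our
benchmark, vs ≈0.02 with ranked covariates). P-values use the
t-approximation with $n - 2 - (\text{covariate columns})$ degrees of
freedom, and BH is applied jointly across the whole taxa × indices
grid — more conservative than per-index adjustment, matching a blanket
"FDR < 0.05" rule. `pointBiserial()` is Pearson on 0/1 coding, which
the tests confirm is p-equivalent to the pooled t-test.
`sankeyEdges()` exports the two-layer taxon→index→outcome edge list,
keeping only q-significant edges per layer.

## Prospective prediction

`splitCohort()` draws a class-stratified discovery/validation split;
both a single fraction (default 0.6) and exact per-class counts (the
reference design used 91/244 vs 65/158) are supported. The classifier
behind `evaluateFeatureSets()` is ridge-penalized logistic regression
(IRLS, penalty $\lambda\|\beta\|^2/2$ off the intercept, default
$\lambda = 1$ on standardized features). The source never names its
classifier; logistic regression is the minimal standard for ROC
biomarker panels and the ridge stabilizes strongly correlated guild
abundances and guarantees convergence under separation. Feature
selection, guild clustering and standardization parameters are derived
from discovery samples only — stricter leakage control than the
source's ambiguous wording, and deliberately so.

AUC uses the Mann–Whitney pairwise definition (verified against
exhaustive pair counting up to $n = 30$), and confidence intervals use
DeLong placement values,
$\widehat{V} = \mathrm{var}(V_{10})/n_1 + \mathrm{var}(V_{01})/n_0$,
normal approximation truncated to [0, 1] (verified against pROC, a
bootstrap, and a 500-replicate coverage study landing in [0.92,
0.98]). Five feature panels mirror the study: clinical indices,
covariate-adjusted significant genera, screening-retained genera,
guild abundances, and guilds plus clinical indices. Published AUCs
(e.g. 0.7738/0.8223 for the guild panel) depend on the unreleased
cohort and are not reproduction targets; what the package verifies
instead is the *ordering*: with an outcome driven by one guild's
abundance at log-odds 1, the guild panel beats noise-level clinical
indices in validation AUC in ≥9/10 seeds and clears 0.70 in the
median at $n = 558$.

## Numerical and engineering choices

* Permutation p-values always use the +1 convention; permutation
  streams are seeded and isolated from the caller's RNG state.
* Case class is always explicit (`caseLevel`) in scoring functions:
  factor-level order is locale-dependent and silently flips signs
  otherwise.
* Rank-sum tests enumerate exactly for tie-free groups of ≤20,
  otherwise use the tie-corrected normal approximation.
* Welch t with both groups constant: statistic 0 and p 1 on equal
  means, an error otherwise. Constant taxa get Kendall τ of 0 (with a
  warning) and Kruskal–Wallis p of 1.
* Degenerate DeLong variance (AUC of 0 or 1) collapses the interval
  with a warning rather than fabricating width.
* Readers reject malformed tables (ragged rows, duplicates, negative
  or fractional counts) naming the offending row; writers round-trip
  integers bit-identically.

## Reference problem sizes

The test suite and the acceptance script run the simulations at fixed
reference sizes chosen to make the statistical claims testable while
keeping a full run comfortably interactive: 500 replicates for the
PERMANOVA size and DeLong coverage studies (300 in the script), 100
null communities for the screening false-positive study (60 in the
script), 10 seeds at $n = 500$, 60 taxa, 4 blocks for guild recovery
(5 in the script), and 10 seeds at the full cohort geometry
($n = 558$, 99 genera, 8 blocks) for the end-to-end feature-set
comparison (5 in the script). These sizes are the package's reference
conditions and are stated here so results are interpreted at the scale
that produced them.

## Known limitations

The guild-number selection rule is anti-conservative by construction
(see above). The deterministic LDA score omits LEfSe's bootstrap
averaging. The generator's covariates are independent of the
community, so covariate adjustment is exercised for type-I control and
direction stability, not for real confounding repair. T2/T3 are
independent draws, so within-subject trajectory methods are out of
scope. And all headline numbers from the reference cohort that depend
on its raw data (published AUCs, specific genus lists) are outside
what synthetic data can or should reproduce.
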