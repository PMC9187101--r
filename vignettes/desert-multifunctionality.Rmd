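---
title: "Methods: diversity, multifunctionality and their drivers in a desert plant community"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, multifunctionality and their drivers in a desert plant community}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desertMF)
```

# The scientific problem

Arid desert ecosystems deliver several functions at once — they cycle
nutrients, store carbon, regulate water, and produce woody biomass — and the
question this pipeline addresses is how plant diversity (species diversity
and phylogenetic diversity) and soil conditions (pH, salinity, C:N) jointly
maintain that *multifunctionality* across plots arranged along a natural
water/salt gradient. The pipeline takes four inputs: a rooted, branch-length
phylogeny of the species pool (Newick), a plot × species abundance table, a
species height table, and a plot soil table; it returns per-plot diversity
and phylogenetic-structure indices, a multifunctionality index, and three
complementary views of its drivers (regression screens, path models,
importance ranking).

# Diversity and phylogenetic structure

Species diversity per plot uses the classical trio: richness `D = S`,
Shannon–Wiener `H' = -Σ P_i ln P_i` (natural log), and the Simpson
dominance index `F = 1 - Σ P_i²`, with `P_i` the relative abundance of
species *i*. Because `F` is also the conventional symbol for the number of
functions in the multifunctionality index, the code names them `simpson`
and `n_functions` respectively and never reuses one symbol for both.

Faith's PD is the sum of branch lengths of the minimal subtree connecting a
plot's species. **Convention:** PD is root-inclusive (the stem path from
the community's most recent common ancestor up to the root of the supplied
tree is counted), matching the convention of the Phylocom family of tools;
a single-species plot therefore has PD equal to that species' root-to-tip
path. This matters when comparing against software that excludes the root
path, and it is the reason `faith_pd(tree, "C")` on `((A:1,B:1):1,C:2);`
returns 2, not 0.

MPD (mean pairwise distance) and MNTD (mean nearest-taxon distance) are
computed from the patristic distance matrix, in presence/absence form by
default and abundance-weighted behind a flag (surveys differ on which they
report; both are provided because the choice is rarely printed). Their
standardized effect sizes carry the community-phylogenetics sign
convention:

$$NRI = -1 \times \frac{MPD_{obs} - \overline{MPD}_{null}}{SD(MPD_{null})}$$

so *positive* values mean phylogenetic clustering. The null is the
**taxa shuffle**: tip labels are permuted uniformly over the full
distance-matrix pool, holding community size fixed; 999 randomizations by
default (tests use 199 for speed). The null SD uses the sample (n−1)
denominator. Two p-values accompany each SES: the one-sided add-one rank
p, `(r+1)/(n_rand+1)`, which is uniform under the null and is what the
calibration tests check, and a derived two-sided p, which is conservative
at finite `n_rand` because of the cap at 1 and rank discreteness.

Degenerate cases are markers, not crashes: a singleton community has
undefined MPD/MNTD (`NA` + flag), and a community spanning the entire pool
has a zero-variance null (the shuffle cannot change the metric), flagged as
such. Null draws use a canonical (sorted) species order so results do not
depend on how the distance matrix happens to be ordered, and every plot
gets its own deterministically derived seed so serial and per-plot-parallel
runs agree.

# Single functions and the multifunctionality index

Four single functions are built per plot: nutrient cycling from total
phosphorus, total nitrogen, available phosphorus and ammonium nitrogen;
carbon stocks from soil organic carbon; water regulation from soil water
content; wood production from the community-weighted mean plant height.
Because the nutrient constituents mix units (g/kg and mg/kg), they are
z-scored *before* averaging into the composite (a raw-mean mode exists for
sensitivity analysis); every function column is then (re-)standardized so
the function matrix has mean 0 and sample SD 1 per column. The averaging
multifunctionality index is the per-plot mean of the four standardized
functions, so MF has mean 0 across plots and SD at most 1. The index is
invariant to affine rescaling of any raw indicator — changing units cannot
change MF — and the tests assert this to 1e-9.

Two data-handling conventions: soil sampled in depth layers is averaged
per plot (unweighted across layers; a top-layer-only mode exists), and the
C:N ratio is computed as SOC/TN when not supplied. Plots with zero total
abundance are excluded with a logged warning rather than aborting a run.

# Associations: screens and path models

Bivariate screens regress MF on each predictor in linear and quadratic
form; the quadratic form captures unimodal ("single peak") responses such
as those reported for NRI/NTI in desert surveys, and its R² can never fall
below the linear R² on the same data.

The path models are recursive (acyclic) models over observed variables.
Estimation is equation-wise least squares on standardized variables, which
is the exact maximum-likelihood estimate for recursive models with
independent errors — no iterative SEM optimizer is needed, and coefficient
p-values come from the per-equation t statistics. The implied correlation
matrix is assembled from `Σ = (I−B)⁻¹ Ψ (I−B)⁻ᵀ` with the exogenous block
of `Ψ` fixed at the sample correlations and residual variances chosen so
implied variances reproduce the sample (unit) variances. Fit uses
`χ² = (n−1)·F_ML`, `NC = χ²/df`, and CFI against the independence
baseline, clipped to [0, 1] with `max(χ²−df, 0)` in the numerator.

**Degrees of freedom.** Free parameters are counted as one per edge, one
residual variance per endogenous variable, one variance per exogenous
variable; correlations among exogenous variables are *fixed* at their
sample values, not free. This yields df = 0 (and χ² = 0, CFI = 1 by
convention) for a saturated model and df = 1 for the three-variable chain.
Commercial SEM defaults sometimes free the exogenous covariances, so NC
and CFI from other software should be compared only approximately. A
consequence worth knowing: a model whose only omitted pairs are exogenous
pairs fits perfectly (their sample correlations enter the implied matrix
unchanged) while retaining df > 0, so NC = 0 there is not evidence of an
over-constrained fit. Standardized coefficients outside [−1, 1] or
negative residual variances trigger a Heywood-case warning rather than an
error: with collinear predictors they are legitimate output that the
analyst must see.

Indirect effects are sums over all directed paths of length ≥ 2 of the
product of standardized edge coefficients; total effects add the direct
edge. On fully recursive models the total effect of the source on any
variable equals the marginal standardized slope (Wright's path tracing),
which the tests verify to 1e-6. Which variables to drop from a model
("pruning" weak paths) is deliberately left to the analyst: automated
pruning rules vary across studies and silently change df.

# Importance ranking

The forest is a bootstrap CART ensemble (defaults: 500 trees,
`mtry = ⌈p/3⌉`, minimum node size 5) with in-bag bookkeeping retained.
Importance of a feature is the mean rise in out-of-bag MSE after permuting
that feature's column (10 shuffles by default), floored at zero, with
descending-score ranks and ties broken by feature name. Permutation
importance was chosen over impurity importance because the four function
columns are mutually correlated, and impurity importance is biased there.

One caveat is printed by the pipeline itself: when the response is MF —
the *mean* of the features — the ranking measures each function's
variance/covariance contribution to MF, not a causal weight. Concretely,
`cov(f_i, MF) = (1 + Σ_{j≠i} r_ij)/4` for standardized columns, so a
function dominates exactly when it correlates with the other functions
more strongly than they correlate among themselves. If all four functions
were mutually independent, every one would contribute exactly 25% and the
ranking would be meaningless noise — a useful null to keep in mind when
reading importance plots.

# The synthetic landscape

The generator emulates the survey design the pipeline targets: `n_plots =
80` plots along a single latent water/salt gradient `g` (evenly spaced on
[0, 1]; a 1-D gradient suffices for all the statistical structure
exercised), a pool of 30 desert species on an ultrametric Yule tree
(birth rate 1), and log-Brownian plant heights (σ² = 0.25 per unit branch
length, root height 1.5 m) exponentiated to guarantee positivity.

Species respond to the gradient through Gaussian niches (width 0.15 on the
unit gradient) whose optima blend a Brownian, tree-correlated component
with an independent draw (`clustering` = 0.5 by default; 1 makes
co-occurring species phylogenetically clustered). Abundances are Poisson
draws around the niche response (12 expected individuals at the optimum);
empty plots are redrawn up to 50 times and flagged if still empty. Niche
width 0.15 gives plot richness of roughly 6–29 species out of 30 with
turnover along the gradient; much wider niches make every plot contain the
whole pool, which is both unrealistic and degenerate (the taxa-shuffle
null has zero variance there).

Soil variables are linear in `g` plus Gaussian noise, with couplings chosen
once to mirror the qualitative structure reported for arid desert basins:
water content falls away from the river and salinity rises; organic carbon
tracks the gradient most tightly, so carbon stocks is usually the dominant
contributor to MF variance; the nutrient pool is noisier; pH declines along
the gradient (alkaline riparian soils) so that pH associates positively
with MF — soil-science arguments run both ways on that sign, and the
direction reported for such basins was adopted. Log plant height is tilted
by niche position (`height_niche_slope` = 0.6): riparian phreatophytes are
tall, distal dwarf shrubs short, which gives wood production a
sign-consistent, subordinate link to the gradient. A second preset,
`soc_dominant_coefs()`, weakens the non-carbon couplings to make carbon
stocks *clearly* dominant (≥ 5% covariance margin in most draws); it is
the premise of the importance-recovery checks, because near-ties between
variance contributions are not resolvable by any ranking method.

What the generator does **not** emulate: 2-D spatial structure and
autocorrelation beyond the single gradient, species-level abundance
distributions calibrated to real surveys, within-species trait variation,
measurement error in CWM, and soil-variable cross-correlations beyond
their common dependence on `g`. Passing tests on synthetic data therefore
demonstrate correctness of the computations and recoverability of known
structure — not that real desert data will show any particular result.

# Numerical choices and problem sizes

Tolerances: exact (1e-12) for closed-form identities and oracle
equivalence; 1e-9 for affine invariance and round-trip identities; ±0.05
for parameter recovery at n = 5000; Monte-Carlo bands elsewhere are ±3
binomial/normal standard errors at the stated replicate counts. Tests run
the permutation nulls at 199 randomizations (the pipeline default is 999),
calibrate the null on 500 plots, check χ² calibration on 400 simulated
chains of n = 400, and run importance recovery on 50 replicates of n = 200
with 150-tree forests — sizes chosen so the full suite completes in about
half a minute while keeping every Monte-Carlo band comfortably away from
its threshold. Missing branch lengths in Newick input are an error by
default (silently defaulting corrupts PD sums; an opt-in defaults them to
1). Plots and species are matched by exact string identity — no fuzzy
joins.

# Known limitations

* NC/CFI replication against other SEM software is approximate by
  construction (df-counting conventions; see above).
* The taxa-shuffle null is the only null model provided; independent-swap
  and trial-swap nulls, β-diversity analogues, threshold-based
  multifunctionality, Hill numbers and rarefaction are out of scope.
* Importance scores split between correlated features (the duplicated-
  feature test documents this); rankings, not magnitudes, are the
  supported reading.
* The pipeline consumes measured soil values; assay methods, phylogeny
  inference and tree visualization live upstream of it.
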