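# desertMF

Biodiversity–ecosystem-multifunctionality analysis for arid desert plant
communities sampled along a water/salt gradient.

Field studies of drylands ask how plant diversity and soil conditions jointly
maintain the many things an ecosystem does at once. This package implements
that analysis pipeline end to end for an 80-plot desert design: it computes
species diversity, phylogenetic α-diversity with permutation nulls, a
z-score multifunctionality index over four single ecosystem functions, and
then asks which drivers matter — by regression screens, by recursive path
analysis, and by random-forest importance ranking. A synthetic-landscape
generator reproduces the statistical structure of such a survey so every
stage is testable without field data; user-supplied data in plain-text
formats (Newick tree, plot × species abundances, species heights, plot soil
tables) run through the identical code path.

## The statistics at the core

* **Species diversity** per plot: richness `D = S`, Shannon–Wiener
  `H' = −Σ Pᵢ ln Pᵢ`, Simpson `F = 1 − Σ Pᵢ²`, with `Pᵢ` the relative
  abundance of species *i*.
* **Phylogenetic diversity**: Faith's PD (sum of branch lengths of the
  minimal subtree spanning a plot's species, root-inclusive), and the
  standardized structure indices

  `NRI = −1 × (MPD_obs − mean MPD_null) / SD(MPD_null)`,
  `NTI = −1 × (MNTD_obs − mean MNTD_null) / SD(MNTD_null)`,

  where the null shuffles tip labels across the whole species pool
  (taxa-shuffle, 999 randomizations by default). Positive values indicate
  phylogenetic clustering.
* **Community-weighted mean (CWM)** plant height: `CWM = Σ Pᵢ × traitᵢ`.
* **Single functions and multifunctionality**: nutrient cycling (composite
  of TP, TN, AP, AN), carbon stocks (SOC), water regulation (SWC) and wood
  production (CWM height) are z-scored across plots;
  `MF = (1/4) Σ z(fᵢ)` per plot.
* **Association**: bivariate linear/quadratic screens, and recursive
  observed-variable path models fitted by equation-wise least squares on
  standardized data (exact ML for recursive models), with χ² = (n−1)·F_ML,
  normed chi-square NC = χ²/df and CFI against the independence baseline;
  indirect effects are products of standardized coefficients summed over
  directed paths.
* **Importance**: out-of-bag permutation importance from a bootstrap
  CART ensemble of MF on the four functions.

## Worked example

The analysis is organised as numbered stage scripts over the package
functions:

```sh
Rscript analysis/01_simulate.R     # synthetic 80-plot landscape -> results/data/
Rscript analysis/02_diversity.R    # diversity, CWM, PD, NRI/NTI
Rscript analysis/03_functions.R    # single functions + MF
Rscript analysis/04_regressions.R  # bivariate screens
Rscript analysis/05_path_models.R  # path models (NC, CFI, indirect effects)
Rscript analysis/06_importance.R   # random-forest ranking
```

Stage 2 prints, for the default seed:

```
richness: 6-29 | H' mean: 2.67 | Simpson mean: 0.91
PD range: 7.7-22.5 | mean NRI: 0.08 | mean NTI: -0.34
```

— plot richness falls with distance from the river, and the near-zero mean
NRI says the default landscape is not strongly phylogenetically structured
(raise `clustering` in `sim_config()` to change that). Stage 6 prints:

```
          feature importance rank
    carbon_stocks 0.23603061    1
  wood_production 0.19552516    2
 water_regulation 0.09855565    3
 nutrient_cycling 0.05544514    4
```

— the importance score is the rise in out-of-bag mean-squared error when
that function's column is permuted; carbon stocks contributes most of MF's
variance under the default gradient couplings. Because MF is the mean of
the four standardized functions, the ranking reads as a
variance-contribution ordering, not a causal one (the note printed by the
script says the same).

The same pipeline runs from files in one call:

```r
library(desertMF)
cfg <- run_config(tree = "tree.nwk", community = "community.tsv",
                  traits = "traits.tsv", soil = "soil.tsv",
                  n_rand = 999, seed = 1, out_dir = "out")
res <- run_pipeline(cfg)
res$path_fits$multifunctionality   # chi-square, NC, CFI, coefficients
```

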