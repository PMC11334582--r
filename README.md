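# crossdiv

Cross-domain biodiversity effects in algal–bacterial communities.

`crossdiv` is an R package for factorial phytoplankton diversity
experiments that manipulate **species richness** and **intraspecific
(strain) richness** simultaneously — e.g. 3 diatom species × 3 origins
combined into 16 treatments (9 monocultures, 3 intraspecific
polycultures, 3 species polycultures, 1 full polyculture) in triplicate —
and ask how diversity affects community productivity and the taxonomic
and functional diversity of the associated bacteria in the attached
(>3 µm) and free-living (0.2–3 µm) size fractions.

It is aimed at microbial ecologists who want the complete analysis chain
of such an experiment as tested, seedable, scriptable functions, plus a
synthetic-data generator with known ground truth for power analysis and
method validation.

## What it computes

- **Alpha diversity**: ASV counts rarefied to a fixed depth (default
  3000 reads, 100 iterations, exact hypergeometric subsampling), Shannon
  index H′ (natural log) and the effective number of species
  ENS = e^H′; the analogous effective number of substrates utilized from
  blank-corrected CLPP plates (31 carbon substrates).
- **Beta diversity**: Bray–Curtis dissimilarities
  d(x,y) = Σ|xᵢ−yᵢ|/Σ(xᵢ+yᵢ); single-factor PERMANOVA
  (pseudo-F = (SS_A/(a−1))/(SS_W/(N−a)), 999 label permutations,
  p = (b+1)/(m+1)) with Bonferroni-adjusted pairwise tests; NMDS
  minimizing Kruskal stress-1 with isotonic regression.
- **Net biodiversity effects**:
  NBE = Y_polyculture − mean(Y_component monocultures), per sample, with
  Student-t (or BCa bootstrap) 95 % CIs per treatment and diversity
  level, and the Loreau–Hector additive partition
  ΔY = CE + SE, CE = N·mean(ΔRY)·mean(M), SE = N·cov_pop(ΔRY, M).
- **Rank-based contrasts and screens**: tie-corrected Kruskal–Wallis,
  Dunn post-hoc tests with Holm adjustment, Spearman taxon–biomass
  screens with Benjamini–Hochberg control within taxonomic levels.
- **Piecewise path models**: per-equation OLS with standardized
  coefficients, d-separation basis set, global fit by Fisher's
  C = −2Σln pᵢ ~ χ²₂ₖ, and model comparison by
  AICc = C + 2Kn/(n−K−1).
- **Synthetic experiments**: `simulation_config()` /
  `simulate_experiment()` generate complete bundles (biomass, growth
  series, per-fraction ASV tables with taxonomy, CLPP plates,
  abundances) with tunable complementarity (δ_CE), selection tilt
  (δ_SE) and microbiome host-specificity (w), and record the analytic
  expected ΔY/CE/SE as ground truth.

## A worked example

```r
library(crossdiv)

res <- run_pipeline(list(
  seed = 42,
  out_dir = "crossdiv_results",
  simulation = list(),                 # default synthetic study conditions
  rarefaction_depth = 3000, rarefaction_iterations = 100,
  n_perm = 999
))

res$permanova[, 1:5]
#>     fraction  factor pseudo_F      R2 p_value
#>     attached species  25.7594 0.68220   0.001
#>     attached  origin   1.0440 0.08003   0.404
#>  free_living species  32.2972 0.72910   0.001
#>  free_living  origin   0.8588 0.06679   0.543
#>         clpp species   0.9454 0.07303   0.584
#>         clpp  origin   0.8732 0.06783   0.706
```

Monoculture microbiomes separate strongly by host species in both size
fractions (p at the 0.001 permutation floor) but not by origin, and CLPP
substrate-use profiles are functionally redundant — the compositional
signature the generator is built to emulate.

```r
s <- res$nbe_summary
s[s$grouping == "diversity_level" & s$variable %in% c("biomass", "ens_free_living"),
  c("variable", "diversity_level", "nbe_mean", "ci_low", "ci_high", "n", "significant")]
#>         variable    diversity_level nbe_mean  ci_low ci_high n significant
#>          biomass          full_poly    49.28 -83.682  182.24 3       FALSE
#>          biomass intraspecific_poly    52.06  29.654   74.47 9        TRUE
#>          biomass       species_poly    53.82  31.422   76.21 9        TRUE
#>  ens_free_living          full_poly    15.31  12.275   18.34 3        TRUE
#>  ens_free_living intraspecific_poly     3.55   2.049    5.05 9        TRUE
#>  ens_free_living       species_poly    10.31   9.373   11.25 9        TRUE
```

Net biodiversity effects on biomass are positive (≈ +50 carbon units,
i.e. the injected 20 % complementarity boost on a ~250-unit mean) and
significant where nine samples support the interval; the full-polyculture
level has only three replicates, so its t interval is wide. Free-living
bacterial diversity gains from host diversity, increasingly so at higher
diversity levels.

```r
head(res$partition, 4)[, 4:6]
#>  delta_y     ce      se
#>   28.830 28.590  0.2401
#>    4.667  4.455  0.2126
#>   36.678 36.429  0.2490
#>   58.953 59.195 -0.2419

res$sem_comparison[, c("model", "K", "C", "global_p", "AICc", "best")]
#>        model  K     C  global_p  AICc  best
#>     additive 14 36.44 0.0008966 77.17  TRUE
#>  interaction 15 36.44 0.0008966 81.44 FALSE
```

Complementarity effects are positive and selection effects hover around
zero (CE + SE = ΔY holds to machine precision), and AICc prefers the
additive path model over one with a species × strain interaction.

A command-line wrapper is installed at `exec/crossdiv`
(`crossdiv simulate`, `diversity`, `permanova`, `nmds`, `nbe`,
`partition`, `sem`, `correlate`, `run-all`); see
`inst/extdata/demo_config.yaml` for a small end-to-end configuration.

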