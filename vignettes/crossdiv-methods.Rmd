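---
title: "Methods: cross-domain biodiversity effects in algal-bacterial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-domain biodiversity effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossdiv)
```

## The experimental system and what the package computes

`crossdiv` analyses factorial phytoplankton diversity experiments in which
both **species richness** and **intraspecific (strain) richness** are
manipulated and the response of community productivity and of the
host-associated bacterial communities is measured. The canonical design
crosses 3 diatom species with 3 geographic origins (9 strains) into 16
treatment combinations — 9 monocultures, 3 intraspecific polycultures (one
species, all 3 origins), 3 species polycultures (all species, one origin)
and the full 9-strain polyculture — each in triplicate (48 cultures).
Bacterial communities are characterized per culture in two size fractions
(host surface-attached, collected on a 3 µm filter, and free-living,
0.2–3 µm), by 16S amplicon (ASV) counts, and functionally by
substrate-utilization plates with 31 carbon sources (CLPP).

The analysis chain is:

1. **Alpha diversity.** ASV counts are rarefied to a fixed depth (default
   3000 reads) by repeated subsampling without replacement (default 100
   iterations); the Shannon index $H' = -\sum_i p_i \ln p_i$ is computed on
   each subsample and averaged, and reported as the effective number of
   species $\mathrm{ENS} = e^{H'}$. Natural logarithms are forced by the
   ENS definition. CLPP diversity is the ENS of the blank-corrected
   substrate-use profile ("effective number of substrates utilized").
2. **Beta diversity.** Bray–Curtis dissimilarity
   $d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$ on relative
   abundances; single-factor PERMANOVA with 999 label permutations and
   Bonferroni-adjusted pairwise tests; NMDS ordination minimizing Kruskal
   stress-1.
3. **Net biodiversity effects.** For every polyculture sample and response
   variable $Y$,
   $\mathrm{NBE} = Y_\mathrm{polyculture} - \operatorname{mean}(Y_\mathrm{component\ monocultures})$,
   summarized per treatment and per diversity level with 95 % confidence
   intervals; where per-component yields in mixture are known, the NBE for
   biomass is split additively into complementarity and selection effects
   (Loreau–Hector): with $\Delta RY_i = Y_{O,i}/M_i - RY_{E,i}$,
   $\mathrm{CE} = N \overline{\Delta RY}\, \overline{M}$ and
   $\mathrm{SE} = N \operatorname{cov_{pop}}(\Delta RY, M)$, so
   $\mathrm{CE} + \mathrm{SE} = \Delta Y$ exactly.
4. **Univariate contrasts.** Kruskal–Wallis (tie-corrected) with Dunn
   post-hoc tests under Holm adjustment; Spearman screens of taxon relative
   abundances against biomass with Benjamini–Hochberg control applied
   separately within each taxonomic level (genus to class).
5. **Piecewise path models.** Each endogenous variable is an OLS equation
   on its parents; standardized coefficients are $b\,\mathrm{sd}(x)/\mathrm{sd}(y)$;
   global fit is tested by the d-separation basis set combined with
   Fisher's $C = -2\sum\ln p_i \sim \chi^2_{2k}$, and candidate models are
   compared by $\mathrm{AICc} = C + 2Kn/(n-K-1)$.

## The synthetic-data generator

Real sequencing data for such experiments lives in public archives and the
accompanying lab tables are not distributable, so the package ships a
generator (`simulation_config()`, `simulate_experiment()`) that reproduces
the *statistical structure* the analysis assumes, with analytic ground
truth for every injected effect. All randomness flows from a single master
seed; stage-level sub-seeds are derived by fixed labels (`derive_seed`),
so any stage can be re-run in isolation and identical configs give
byte-identical bundles.

**Biomass.** Monoculture biomass of strain $i$ is
$\mathrm{LogNormal}(\ln \mu_i, \sigma_b)$. A polyculture with initial
strain proportions $p_i$ has expected biomass
$(\sum_i p_i \mu_i)(1 + \delta_{CE})$: the complementarity parameter
$\delta_{CE}$ boosts every component proportionally, while the selection
parameter $\delta_{SE}$ tilts $p_i$ towards high-$\mu$ strains. The
recorded truth includes the lognormal mean factor $e^{\sigma_b^2/2}$, so
expected $\Delta Y$, CE and SE are exact, and CE + SE = $\Delta Y$ by
construction. Defaults: $\mu$ spread over 162–330 carbon units with both a
species and an origin gradient, $\sigma_b = 0.1$, $\delta_{CE} = 0.2$,
$\delta_{SE} = 0$.

**Microbiomes.** Each strain carries a host-specific composition $\pi_i$
(mass concentrated on a species-level block plus a smaller strain-level
block of taxa); a culture's community is the proportion-weighted mixture
$\sum_i p_i [(1-w)\pi_\mathrm{core} + w\,\pi_i]$ with host-specificity
weight $w$ (default 0.75 — no quantitative effect size is available for
host specificity, so the default is chosen, once, to give a clear signal
at triplicate sample sizes and is documented as arbitrary). The attached
and free-living fractions are separated by a deterministic per-taxon
multiplicative shift, compositional noise is Dirichlet (concentration
$\alpha = 200$) and counts are multinomial at a depth drawn uniformly from
[5000, 20000], so rarefaction to 3000 always succeeds by default. Because
polyculture communities are mixtures, mixing distinct host-specific
compositions *raises* expected diversity (concavity of Shannon entropy) —
the generator's analogue of a positive cross-domain diversity effect; no
emergent interaction taxa are simulated, and an attached-specific
microbiome convergence mechanism is deliberately out of scope.

**Growth and plates.** Growth series are sums of per-strain logistic
curves started from a total of 10 RFU split by $p_i$, observed daily with
multiplicative lognormal noise; the maximum specific growth rate is
estimated as the largest 3-point sliding-window slope of $\ln$ RFU (window
length exposed; 3 consecutive daily points balances bias against noise at
daily sampling). CLPP absorbance is
blank + use-probability × signal + Gaussian noise; by default all strains
share one substrate profile (`clpp_specificity = 0`), mirroring the
functional redundancy typically observed, so CLPP contrasts are null under
the default generator. Free-living bacterial abundance is lognormal with
no injected diversity effect.

**What passing tests do and do not show.** The generator reproduces the
design, the compositional structure, the noise families and the effect
injection the analysis assumes — it does not simulate reads, chimeras,
primer bias, temporal dynamics, or interaction-specific taxa. Green tests
therefore certify that the *estimators* recover what they claim under the
assumed model, not that the model captures every feature of real amplicon
data.

## Numerical and inferential choices

- **Rarefaction** averages the *metric* across iterations (not the
  counts), using sequential conditional hypergeometric draws (exact
  multivariate-hypergeometric subsampling, vectorized across iterations).
  Samples under depth are dropped with a logged warning, never scaled.
  Whether averaging the metric or the counts is intended is ambiguous in
  typical method descriptions; the metric-averaging reading is used and
  flagged here.
- **CLPP reduction**: blank subtraction with clamping at zero is the
  simplest defensible processing when plate-level replicate handling is
  unspecified; it is applied uniformly and exposed through
  `clpp_profile()`.
- **Permutation p-values** include the observed statistic,
  $p = (b + 1)/(m + 1)$, so 999 permutations give an attainable floor of
  0.001. Pairwise PERMANOVA re-permutes within each pair's subset, with
  per-pair seeds derived from the master seed.
- **NMDS** starts from the metric (classical) MDS solution plus random
  restarts (default 50), alternates isotonic regression (primary tie
  handling) with Guttman transform updates, and never accepts a stress
  increase, so the within-run stress sequence is non-increasing and the
  returned stress cannot exceed the metric start. Degenerate all-equal
  dissimilarity inputs are flagged non-converged.
- **NBE expectation** uses the mean of monoculture *replicate means* (not
  pooled replicates) so unequal replication cannot bias a component
  strain's weight. CIs are Student-t by default — the minimal assumption
  at $n = 3$ — with a seedable BCa bootstrap behind a flag. Because NBE
  replicates within a level share monoculture baselines, the t interval is
  mildly anticonservative (measured ≈ 92–93 % coverage at the default
  design under a zero-effect generator); this is inherent to treating
  per-sample NBEs as independent and is documented rather than corrected,
  matching standard practice.
- **Selection effect** uses the population (1/N) covariance so the
  additive identity CE + SE = ΔY holds to machine precision — the identity
  is the partition's defining property and is enforced by tests on random
  inputs.
- **d-separation claims** are tested as the p-value of the conditioned
  variable in an OLS regression of the topologically later variable on the
  earlier one plus the union of both variables' parents — the standard
  recipe for Gaussian linear path models. Correlated-error pairs are
  declared dependencies and excluded from the basis set. The basis set is
  computed on a deterministic topological order with alphabetical
  tie-breaks, so it is invariant to how a model is written down.
- **AICc** uses the Fisher's-C-based form $C + 2Kn/(n-K-1)$ with $K$
  counting slopes, intercepts, error variances and residual correlations;
  a likelihood-based AIC would differ and is not used. Equation fitting
  requires only per-equation residual degrees of freedom; candidates with
  $n \le K + 1$ are flagged infeasible rather than fitted-and-ranked.
- **Interactions** are products of mean-centered parents, so main-effect
  coefficients keep their marginal interpretation.
- Significance is $\alpha = 0.05$, two-sided, throughout; every stochastic
  routine accepts an explicit seed.

## Simulation sizes used by the test suite

The suite's Monte-Carlo studies use sizes chosen to give stable
assertions: 10 000 random partitions for the additive identity; 400
zero-effect experiments (199 permutations each) for permutation validity,
plus exhaustive-enumeration agreement on small instances; 300 experiments
for NBE recovery and 500 for CI calibration at
$\delta_{CE} = 0.2/0, \sigma_b = 0.05$; 200 path-model datasets at
$n = 100$ for AICc recovery and d-sep calibration; 100 full experiments
(rarefaction with 10 iterations) for the qualitative diversity-effect
pattern; 1000 random p-vectors for the multiple-testing oracles. All are
deterministic under fixed seeds.

## A worked run

```{r example, eval = FALSE}
library(crossdiv)

res <- run_pipeline(list(
  seed = 42,
  out_dir = "crossdiv_results",
  simulation = list(),          # default study conditions
  rarefaction_depth = 3000, rarefaction_iterations = 100,
  n_perm = 999
))

res$permanova          # species vs origin effects per fraction (+ CLPP)
res$nbe_summary        # NBE with 95% CIs per level and treatment
res$partition          # complementarity vs selection per polyculture
res$sem_comparison     # candidate path models ranked by AICc
```

## Known limitations

- Single-factor PERMANOVA only (the design's factors are analysed
  separately, as in the figure-level analyses it supports); no
  dispersion test (PERMDISP) or distance-based RDA.
- The partition requires per-component yields in mixture; the package
  never imputes them (with real data they are typically only available
  for a subset of treatments, e.g. from species-resolved counts).
- No phylogenetic or coverage-based diversity metrics.
- Path models are Gaussian-linear without latent variables or random
  effects; claim tests inherit OLS assumptions.
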