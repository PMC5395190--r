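---
title: "Decomposing trait variance and covariance across taxonomic and ecological levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing trait variance and covariance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitdecomp)
```

## The problem

Functional traits of co-occurring woody plants — leaf mass per area
(LMA, g/m²), green-leaf nitrogen concentration (N~green~, % dry mass),
leaf half-life (LHL, days) and wood density (WD, g/cm³) — vary at many
nested levels at once: between deciduous and evergreen functional types,
between growth forms, among families, among species within families,
among conspecific individuals, and between seasons within an individual.
The between-species levels are read as mostly genetic differentiation;
the within-species levels as mostly environmental response. traitdecomp
quantifies how much trait variance and, crucially, how much *pairwise
trait covariance* sits at each of these levels, and whether the
species-level pattern carries a phylogenetic signal.

The package bundles the species list of a subtropical forest community
at Dujiangyan (SW China) — 45 woody angiosperm species in 20 families,
294 sampled individuals — as `dujiangyan_species()`, and a synthetic
generator that produces complete datasets with that community's shape
and known ground truth, so the whole pipeline is testable end to end.

## The multilevel variance model

For one trait, log-transformed (all four traits are right-skewed and
approximately log-normal; the log also linearizes allometric power
relationships):

$$y_i \sim N(\mu_i, \sigma^2_y), \qquad
\mu_i = \alpha_0 + \alpha_{FT(i)} + \alpha_{GF(i)} + \alpha_{season(i)}
 + \beta_{fam(i)} + \beta_{spec(i)} + \beta_{ind(i)}$$

with random effects $\beta_{fam} \sim N(0, \sigma^2_{fam})$,
$\beta_{spec} \sim N(0, \sigma^2_{spec})$,
$\beta_{ind} \sim N(0, \sigma^2_{ind})$. The residual is the
season-within-individual variation, except for LHL, which has a single
value per individual: there the individual term is dropped and the
residual *is* the among-individual variation. Priors are vague:
$N(0, 1000)$ on the grand mean, $U(-3, 3)$ on each fixed coefficient
(on the log-trait scale; traits are not z-scored), and $U(0, 10)$ on
every standard deviation.

Fixed factors are two-level in this design and are coded sum-to-zero
($+\delta$ / $-\delta$), which makes the *finite-population SD* — the SD
of the level coefficients with denominator $J-1$, here
$|\delta|\sqrt{2}$ — well defined and directly comparable with the
random-effect SDs. Reporting every term as an SD on the log scale puts
fixed and random sources of variation on one ruler; that comparability
is the point of the analysis. Whether to use corner or sum-to-zero
constraints is a genuinely open choice; we use sum-to-zero because the
finite-population SD is then invariant to which level is "first", and
the SD-scale results do not depend on the constraint.

### Sampling

`fit_trait_variance()` runs a Gibbs sampler written in C++ (Rcpp):
conjugate normal updates for the grand mean, fixed coefficients
(truncated to the prior box by inverse-CDF sampling) and random-effect
blocks, and truncated inverse-gamma draws for the variance components
(a $U(0, 10)$ prior on $\sigma$ is an inverse-gamma posterior on
$\sigma^2$ truncated at 100, sampled exactly through the gamma CDF of
the precision). Additive models of this kind mix slowly along the
directions that trade the grand mean against random-effect block means,
and a species-level fixed coefficient against the species effects. The
sampler therefore adds exact *translation moves*: after each sweep it
draws the likelihood-invariant shift between $\alpha_0$ and each block
mean (and between $\delta_{FT}$, $\delta_{GF}$ and the species effects)
from its full conditional under the priors. Residuals are untouched by
these moves, so they are ordinary Gibbs updates on a redundant
parametrization; in testing they reduced the worst potential scale
reduction factors from roughly 1.3 to below 1.05 on short chains.

Defaults: 3 chains, 20,000 iterations, 5,000 burn-in, thinning 5, all
overridable; convergence is summarised by the classic Gelman–Rubin
`rhat()` per parameter and flagged at the conventional 1.2 cut-off.
Chains are seeded as `seed + chain - 1`, so a run is exactly
reproducible. A fixed coefficient whose posterior piles up at the
$\pm 3$ bound triggers a warning, since that usually means the data are
on the wrong scale.

Small variance components deserve a caveat: with 20 families, the
sampling spread of a group-level SD is about $1/\sqrt{2(J-1)} \approx
16\%$ of its value, and a component much smaller than the residual
(e.g. individual SD of 0.05 under a residual of 0.35 with two
observations per individual) is only weakly identified — its posterior
is honest about that, but no estimator can pin it within a few percent.
Recovery checks must therefore be read at the information level the
design supports.

## Partitioning trait covariances

The covariance analogue of the sequential ANOVA decomposes the total
corrected sum of cross-products of two log traits. We use the
polarization identity as the operational definition:

$$SCP_{term} = \tfrac{1}{2}\left[SS_{term}(x + y) - SS_{term}(x) - SS_{term}(y)\right]$$

computed from three sequential (Type-I) ANOVAs sharing one term order.
Components are signed — a term can contribute covariance *against* the
overall association — and sum exactly to the total corrected
cross-product, so the percentages sum to 100. Sequential SS are
order-dependent in unbalanced data; the default order, functional type
→ growth form → family → species → individual → season, follows the
ecological hierarchy (family fitted after the functional-type and
growth-form contrasts absorbs only the taxonomic variation left over,
since families contain both leaf habits), and is a recorded,
user-overridable setting. F tests use the error stratum at which each
term varies: functional type and growth form against the family mean
square, family against species, species against individual, individual
and season against the residual. `sequential_anova()` accepts numeric
covariates (e.g. log soil nitrogen) as leading 1-df terms.

Significance of the per-term components is not defined by classical
theory, so `component_significance()` uses a stratum-restricted
permutation test: the first trait's incremental fitted component for a
term is permuted among the term's units *within the enclosing stratum*
(species within family, individuals within species, seasons within
individual, families globally), and the species-level fixed factors are
permuted as label reassignments among species. The two-sided p-value
comes from the permutation distribution of the absolute component. This
is a documented design choice, not a claim about how any particular
historical software did it; its type-I behaviour is checked by
simulation in the test suite.

## Phylogenetic signal and independent contrasts

`blomberg_k()` implements the K statistic: the ratio of the tip mean
squared error (about the phylogenetically GLS-estimated mean) to the
GLS mean squared error under the tree's variance–covariance matrix,
standardised by its Brownian-motion expectation
$(\mathrm{tr}\,C - n/\mathbf{1}'C^{-1}\mathbf{1})/(n-1)$. K ≈ 1 is what
Brownian evolution on the given tree produces; K ≈ 0 means trait values
are decoupled from phylogeny. `k_randomization_test()` permutes trait
values among species (1000 randomizations by default), reports the
2.5–97.5 percentile band of the randomized K, calls the observed K
significant when it exceeds the upper bound, and reports a percentile
p-value alongside (the band rule and the percentile p can disagree near
the boundary; both are given).

`independent_contrasts()` is the standard pruning recursion: at each
internal node the contrast $(x_1 - x_2)/\sqrt{v_1 + v_2}$, the
ancestral value as the branch-length-weighted average, and the parent
branch lengthened by $v_1 v_2/(v_1+v_2)$. Polytomies (ubiquitous in
supertrees) are resolved to arbitrary bifurcations whose new internal
branches get an epsilon of $10^{-8}\times$ tree depth — small enough
not to move any contrast, large enough to keep the recursion defined.
Contrast correlations are computed through the origin (contrast signs
are arbitrary) with $n - 1$ degrees of freedom. Species missing a trait
are pruned per trait, and per pair for correlations, so every analysis
uses its maximal species set; `species_tree_overlap()` reports
table/tree mismatches before anything phylogenetic runs.

## Four correlation levels and bivariate slopes

`trait_correlations()` reports, per trait pair: the overall Pearson
correlation across individual observations; the correlation of species
means (means of log values); the PIC correlation; and the
within-species correlation, defined as the pooled Pearson correlation
of species-mean-centred deviations with $df = n - n_{species} - 1$ —
the standard pooled within-group estimator (the choice is ours; the
quantity is not otherwise pinned down). Pairs involving LHL use one
observation per individual, averaging the seasonal traits within
individuals first. The dissociation between a strong species-mean
correlation and a near-zero within-species correlation is exactly what
the covariance partition expresses term by term, and the generator can
produce it on demand for testing.

`bivariate_slope()` fits the standardized major axis,
$b = \mathrm{sign}(r)\, s_y/s_x$, the symmetric line appropriate for
allometric log–log relationships, with the standard confidence interval
$b(\sqrt{B+1} \pm \sqrt{B})$, $B = F_{1-\alpha;1,n-2}(1-r^2)/(n-2)$;
OLS is available by flag and the method is always recorded. Note that
for $y = \beta x + \varepsilon$ the population SMA slope is
$\mathrm{sign}(\beta)\sqrt{\sigma^2_y/\sigma^2_x}$, which is steeper
than $\beta$ unless the fit is perfect — comparisons must compare like
with like.

## Leaf demography

Under a constant abscission rate, a marked cohort with live counts
$N_1 \to N_2$ over $T_1 \to T_2$ gives
$LHL = (T_2 - T_1)\,\ln(1/2)/\ln(N_2/N_1)$. `estimate_lhl_interval()`
flags the degenerate cases rather than guessing: $N_2 = N_1$ (no
abscission observed; half-life unbounded), $N_2 = 0$ (rate unbounded
under the exponential model; excluded by default, a +0.5 continuity
correction is available but off), $N_2 > N_1$ (leaf gain contradicts
the design). `lhl_per_individual()` keeps, by default, only the first
cohort marked on each branch — the cohort with the most leaves and the
most stable estimates — averages its usable intervals, then averages
across branches (arithmetic means; the least-assumption summary, noted
as a configuration choice). Individuals with no usable interval are
excluded with a logged reason, never an error. Wood density is simply
core dry mass over fresh volume.

## The synthetic generator: what it emulates, and what not

`generate_trait_dataset()` draws log traits as grand mean + fixed
offsets + correlated multivariate-normal level effects (family,
species, individual, season-residual) and exponentiates, so the
multilevel model is exactly correctly specified and every component is
recoverable. Defaults were chosen once to resemble a subtropical woody
community and are not calibration targets:

* taxonomy: the packaged 45-species/20-family/294-individual community
  (a simulated Yule taxonomy of configurable shape is available, with
  functional type assigned at family level and flipped per species at
  rate 0.15, since real families mix leaf habits);
* grand means $\exp^{-1}$: LMA 80 g/m², N~green~ 2%, LHL 250 d, WD
  0.5 g/cm³;
* functional type is the dominant fixed contrast (e.g. ±0.25 on log
  LMA), growth form small, season intermediate with opposite signs for
  LMA and N~green~;
* level SDs put most variation at species level, least at individual
  level, mirroring the qualitative field pattern; LHL's
  individual-level SD doubles as its residual;
* level correlations encode the leaf-economics structure at family and
  species level (LMA–N~green~ negative, LMA–LHL and LMA–WD positive)
  and weak within-species structure.

The tree is a fresh pure-birth (Yule) simulation over the species —
tree shape is not part of the ground truth, only the species labels
are. Censuses are simulated for a configurable fraction of individuals
(default 0.3, ≈ 90 of 294) with 2 branches, cohorts of 5–20 leaves and
census days 0/122/334/487/640, each leaf's lifetime exponential with
the individual's true LHL as median.

What the generator does *not* emulate: measurement error distinct from
seasonal residuals, missing data patterns (real coverage differs per
trait; the analysis functions handle missingness by pairwise deletion,
but the default synthetic data are complete), phylogenetic signal in
the trait values themselves (level effects are exchangeable across the
tree — Brownian traits are generated separately by
`simulate_bm_traits()`), spatial soil structure (soil N is drawn
independently of traits, matching the absence of a soil effect as the
study condition), and non-exponential leaf survival. Passing tests on
synthetic data therefore demonstrate the estimators' correctness under
the stated model, not robustness to violations of it.

`truth.json` written by `make_demo_data()` stores the full generator
configuration and seed with 17 significant digits, so
`regenerate_from_truth()` reproduces the dataset bit for bit.

## Numerical choices

* Correlation matrices are accepted as positive semi-definite down to
  an eigenvalue of $-10^{-8}$ and factored by symmetric eigendecomposition
  (not Cholesky), so boundary cases like $r = \pm 1$ generate exactly.
* Truncated normal and truncated inverse-gamma draws use inverse-CDF
  sampling; when the conditional mass inside the bounds underflows, the
  draw falls back to the nearer bound.
* Variance-component draws guard the scale at $10^{-300}$ so a
  zero-variance degenerate dataset concentrates the posterior at the
  lower boundary instead of failing.
* Sequential SS come from `stats::lm`/`stats::anova` (QR with
  pivoting); rank-deficient terms contribute 0 df and are logged. The
  test suite re-derives every SS with an independent
  projection-difference oracle at $10^{-8}$.
* The SCP partition reports percentages as missing (with a warning)
  when the total cross-product is numerically zero.
* Permutation p-values use the add-one convention
  $(1 + \#\{|S^*| \ge |S|\})/(B + 1)$ and warn when the attainable
  resolution cannot reach 0.05.
* Ties in census dates are invalid input (strictly increasing), not
  silently merged.

## Problem sizes in the test suite

The suite exercises every estimator on simulated data sized to be
decisive yet quick: 200 Brownian replicates on 45-tip trees for the K
calibration; 3 × 20 replicate fits at n ≈ 480 observations for
multilevel recovery (6,000 iterations × 3 chains each); 100 random
unbalanced designs for cross-product conservation; 500 simulated
censuses of 10⁴ leaves for the half-life estimator; 100 replicate
25-tip simulations for the contrast diagnostics. These sizes are the
package's own choices for routine verification; larger runs only
sharpen the same comparisons.

## Known limitations

* Fixed factors are restricted to two levels (that is the design the
  model serves); a general sum-to-zero multi-level fixed factor would
  need a different update block.
* The permutation test permutes estimated components, an approximation
  whose calibration is demonstrated by simulation rather than by exact
  exchangeability arguments; with very few units per stratum its
  resolution is limited.
* The within-species correlation pools across species; species-specific
  within correlations are not separately estimated (replication per
  species is far too small in the motivating design).
* K and the contrasts assume the supplied branch lengths are
  meaningful; with unit branch lengths the statistics remain defined
  but their Brownian calibration changes.
* The season term is modelled as a fixed two-level contrast, not as a
  random year effect; multi-year censuses would need an extended model.
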