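# traitdecomp

Partitioning the variance and covariance of plant functional traits
across taxonomic and ecological levels.

Co-occurring woody plants differ in leaf mass per area (LMA), green-leaf
nitrogen (N<sub>green</sub>), leaf half-life (LHL) and wood density
(WD), and these traits covary along the leaf- (and stem-) economics
spectrum. The interesting question is *where* that variation and
covariation sits: between deciduous and evergreen functional types,
between growth forms, among families, among species within families
(mostly genetic causes), or among individuals and between seasons within
individuals (mostly environmental causes). traitdecomp is a toolkit for
exactly this decomposition, aimed at community ecologists with
individual-level trait tables, marked leaf-cohort censuses and a species
phylogeny.

## What it implements

* **Leaf half-life** from censored census intervals under exponential
  abscission: `LHL = (T₂−T₁)·ln(½)/ln(N₂/N₁)`, with principled handling
  of no-loss, total-loss and leaf-gain intervals
  (`estimate_lhl_interval()`, `lhl_per_individual()`), and wood density
  as core dry mass per fresh volume (`wood_density()`).
* **Bayesian multilevel ANOVA** per trait (`fit_trait_variance()`), on
  the log scale: fixed two-level effects (functional type, growth form,
  season) and nested random effects (family, species, individual), with
  vague priors (N(0, 1000) grand mean, U(−3, 3) fixed coefficients,
  U(0, 10) on every SD). Every term is summarised as an effect-size SD —
  finite-population SDs for fixed factors — with 50%/95% credible
  intervals and Gelman–Rubin Rhat (`finite_population_sd()`, `rhat()`).
  The Gibbs sampler is compiled (Rcpp) and includes translation moves
  that cure the slow mixing typical of additive hierarchies.
* **Covariance partitioning** (`partition_cross_products()`): the total
  sum of cross-products of each log-trait pair decomposed into signed
  sequential per-term components via the polarization identity
  `SCP = [SS(x+y) − SS(x) − SS(y)]/2`, with stratum-aware sequential
  ANOVA (`sequential_anova()`) and stratum-restricted permutation tests
  (`component_significance()`).
* **Phylogenetic signal**: Blomberg's K with a 1000-fold randomization
  test (`blomberg_k()`, `k_randomization_test()`) and Felsenstein's
  independent contrasts with through-origin correlations
  (`independent_contrasts()`, `pic_correlation()`).
* **Four-level correlation tables** (overall / species-mean / PIC /
  within-species; `trait_correlations()`) and standardized-major-axis
  log–log slopes (`bivariate_slope()`).
* **A synthetic-data generator with known ground truth**
  (`generator_config()`, `generate_trait_dataset()`,
  `simulate_bm_traits()`, `simulate_leaf_census()`), pre-shaped to the
  packaged Dujiangyan community table (`dujiangyan_species()`: 45
  species, 20 families, 294 individuals), plus a one-call pipeline
  (`run_full_analysis()`, `make_demo_data()`).

Results are tibbles; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods, so everything chains with the pipe.

## Worked example

```r
library(traitdecomp)

d <- generate_trait_dataset(generator_config(), seed = 42)
d
#> <synthetic_traits> 2058 trait records | 45 species | 20 families | 93 censused individuals (seed 42)

fit <- fit_trait_variance(d$traits, "LMA", seed = 1)
fit
#> <trait_varcomp> LMA: 588 observations, 3 chains x 3000 kept draws
#> Effect-size SDs (posterior mean [95% CrI], Rhat):
#>   functional_type   0.233 [0.116, 0.353]  Rhat 1.000
#>   growth_form       0.121 [0.009, 0.255]  Rhat 1.000
#>   season            0.065 [0.052, 0.077]  Rhat 1.000
#>   family            0.154 [0.068, 0.261]  Rhat 1.001
#>   species           0.201 [0.154, 0.264]  Rhat 1.002
#>   individual        0.055 [0.030, 0.073]  Rhat 1.010
#>   residual          0.112 [0.103, 0.122]  Rhat 1.006
```

Functional type and species dominate log-LMA variation while
individuals contribute least — and the posterior means sit close to the
generator's truth (±0.25·√2 ≈ 0.354 for the functional-type
finite-population SD; 0.12/0.20/0.05/0.12 for family/species/
individual/residual), with every Rhat ≈ 1.

```r
tabs <- trait_correlations(d$traits, tree = d$tree)
subset(tabs, trait_x == "LMA" & trait_y == "Ngreen")
#>   trait_x trait_y          level      r  p_value   n
#>       LMA  Ngreen        overall -0.456 1.64e-31 588
#>       LMA  Ngreen   species_mean -0.517 2.76e-04  45
#>       LMA  Ngreen            pic -0.827 2.66e-12  44
#>       LMA  Ngreen within_species -0.500 1.00e-35 588
```

The LMA–N<sub>green</sub> axis is negative at every level, strongest
among species — the classic economics-spectrum pattern the generator
encodes. The covariance partition says the same thing term by term:

```r
part <- d$traits |>
  (\(tr) {
    w <- traitdecomp:::wide_log_tables(tr)$obs
    meta <- dplyr::distinct(tr, individual_id, family,
                            functional_type, growth_form)
    dd <- dplyr::inner_join(w, meta, by = "individual_id")
    dd$species <- dd$species_id
    partition_cross_products(dd, "LMA", "Ngreen",
                             n_permutations = 999, seed = 1)
  })()
part
#> <trait_covpart> LMA x Ngreen | total corrected SCP -28.2862
#>   term               df     scp pct_scp sign  p_value
#> 1 functional_type     1 -13.4     47.5  -       0.001
#> 2 growth_form         1  -0.549    1.94 -       0.001
#> 3 family             19  -0.502    1.78 -       0.872
#> 4 species            23  -6.50    23.0  -       0.028
#> 5 individual_id     249  -2.12     7.48 -       0.001
#> 6 season              1  -3.17    11.2  -       0.001
#> 7 .residual         293  -2.00     7.08 -      NA
```

Half of the negative LMA–N<sub>green</sub> covariance is carried by the
deciduous/evergreen contrast and another quarter by species within
families; components sum exactly to the total corrected cross-product.
(`run_full_analysis()` produces these tables for all traits and pairs in
one call.) Because the generator draws level effects exchangeably across
the tree, species means carry *no* phylogenetic signal, and the K test
says so:

```r
sm <- species_summary(d$traits)
sm$species_id <- with(sm, gsub("[^A-Za-z0-9]+", "_", paste(genus, species)))
lma <- subset(sm, trait == "LMA")
k_randomization_test(d$tree, setNames(log(lma$mean), lma$species_id), seed = 1)
#> <phylo_signal> K = 0.019 | K_rand = 0.045 (95% CI 0.016-0.107, 1000 reps) | not significant (p = 0.939, n = 45)
```

Brownian-motion traits simulated with `simulate_bm_traits()` instead
give K ≈ 1 on average (see below).

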