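test_that("finite-population SD matches the direct formula", {
  expect_equal(finite_population_sd(c(-1.5, 1.5)), 1.5 * sqrt(2))
  expect_equal(finite_population_sd(c(0, 0, 0)), 0)
  expect_true(is.na(finite_population_sd(3)))
  coefs <- c(0.4, -1.2, 0.7, 0.1)
  expect_equal(finite_population_sd(coefs),
               sqrt(sum((coefs - mean(coefs))^2) / 3))
})

test_that("rhat matches the hand-computed between/within formula", {
  ch <- list(c(1, 2, 3, 4), c(2, 3, 4, 5))
  W <- (var(ch[[1]]) + var(ch[[2]])) / 2
  B_over_n <- var(c(mean(ch[[1]]), mean(ch[[2]])))
  expect_equal(rhat(ch), sqrt(3 / 4 + B_over_n / W))

  expect_equal(rhat(list(ch[[1]], ch[[1]])), sqrt(3 / 4))

  sep <- withr::with_seed(1, list(rnorm(1000), rnorm(1000, 10)))
  expect_gt(rhat(sep), 1.2)

  expect_error(rhat(list(1:4)), class = "traitdecomp_validation_error")
  expect_error(rhat(list(1:4, 1:5)), class = "traitdecomp_validation_error")
})

test_that("identical observations concentrate every SD posterior near zero", {
  tab <- tidyr::expand_grid(
    family = c("F1", "F2"), sp = c("a", "b"), ind = 1:2,
    season = c("spring", "fall")
  ) |>
    dplyr::mutate(individual_id = paste(family, sp, ind),
                  genus = family, species = paste(sp, family),
                  functional_type = ifelse(family == "F1", "deciduous", "evergreen"),
                  growth_form = ifelse(sp == "a", "tree", "shrub"),
                  trait = "LMA", value = 50)
  fit <- suppressWarnings(fit_trait_variance(tab, "LMA", chains = 2,
                                             iterations = 2000, burn_in = 500,
                                             thin = 1, seed = 1))
  sds <- fit$summary[fit$summary$term != "grand_mean", ]
  expect_true(all(sds$q50 < 0.1))
  expect_equal(fit$summary$estimate[fit$summary$term == "grand_mean"],
               log(50), tolerance = 0.01)
})

test_that("chains are reproducible from the seed", {
  d <- generate_trait_dataset(generator_config(), seed = 3)
  f1 <- fit_trait_variance(d$traits, "WD", iterations = 1500, burn_in = 500,
                           thin = 1, seed = 9)
  f2 <- fit_trait_variance(d$traits, "WD", iterations = 1500, burn_in = 500,
                           thin = 1, seed = 9)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_trait_variance(d$traits, "WD", iterations = 1500, burn_in = 500,
                           thin = 1, seed = 10)
  expect_false(identical(f1$draws$sd_family, f3$draws$sd_family))
})

test_that("SD posteriors respect the uniform prior support", {
  d <- generate_trait_dataset(generator_config(), seed = 3)
  fit <- suppressWarnings(fit_trait_variance(d$traits, "Ngreen",
                                             iterations = 2000,
                                             burn_in = 500, thin = 1,
                                             seed = 2))
  for (p in c("sd_family", "sd_species", "sd_individual", "sd_residual")) {
    expect_true(all(fit$draws[[p]] > 0 & fit$draws[[p]] <= 10))
  }
  expect_true(all(abs(fit$draws$delta_functional_type) <= 3))
})

test_that("posterior SDs recover the generating configuration", {
  cfg <- recovery_config(sd_fam = 0.20, sd_spec = 0.30, sd_ind = 0.10,
                         sd_res = 0.15)
  d <- generate_trait_dataset(cfg, seed = 31)
  fit <- fit_trait_variance(d$traits, "LMA", iterations = 6000,
                            burn_in = 1500, thin = 2, seed = 1)
  s <- fit$summary
  # single replicate: the identifiable "truth" for the group levels is
  # the SD realized in the drawn effects; the configured SD is the
  # superpopulation value (their gap is ~1/sqrt(2(J-1)) relative)
  realized <- c(
    family = sd(d$truth$family_effects[, "LMA"]),
    species = sd(d$truth$species_effects[, "LMA"]),
    individual = sd(d$truth$individual_effects[, "LMA"]),
    residual = 0.15
  )
  nominal <- c(family = 0.20, species = 0.30, individual = 0.10,
               residual = 0.15)
  for (term in names(realized)) {
    row <- s[s$term == term, ]
    expect_lt(abs(row$estimate - realized[[term]]) / realized[[term]], 0.25)
    expect_true(row$q2.5 <= nominal[[term]] && nominal[[term]] <= row$q97.5)
  }
  expect_true(all(s$rhat < 1.2))
  # credible intervals nest: 50% inside 95%
  expect_true(all(s$q25 >= s$q2.5 & s$q75 <= s$q97.5))
})

test_that("LHL drops season and individual terms by default", {
  d <- generate_trait_dataset(generator_config(), seed = 5)
  fit <- fit_trait_variance(d$traits, "LHL", iterations = 1500,
                            burn_in = 500, thin = 1, seed = 1)
  expect_false("season" %in% fit$summary$term)
  expect_false("individual" %in% fit$summary$term)
  expect_true(all(c("family", "species", "residual") %in% fit$summary$term))
})

test_that("a fixed coefficient pinned at the prior bound triggers a warning", {
  tab <- tidyr::expand_grid(family = sprintf("F%d", 1:4), sp = 1:2, ind = 1:3) |>
    dplyr::mutate(individual_id = paste(family, sp, ind),
                  genus = family, species = paste(family, sp),
                  functional_type = ifelse(sp == 1, "deciduous", "evergreen"),
                  growth_form = "tree", season = NA_character_,
                  trait = "WD",
                  value = exp(ifelse(functional_type == "evergreen", 5, -5)))
  ws <- testthat::capture_warnings(
    suppressMessages(fit_trait_variance(tab, "WD", include_season = FALSE,
                                        chains = 2, iterations = 1200,
                                        burn_in = 400, thin = 1, seed = 1)))
  expect_true(any(grepl("prior bound", ws)))
})

test_that("tidy and glance expose the posterior summaries", {
  d <- generate_trait_dataset(generator_config(), seed = 3)
  fit <- suppressWarnings(
    fit_trait_variance(d$traits, "WD", iterations = 1500, burn_in = 500,
                       thin = 1, seed = 2))
  td <- tidy(fit)
  expect_true(all(c("trait", "term", "estimate", "q2.5", "q97.5", "rhat")
                  %in% names(td)))
  g <- glance(fit)
  expect_equal(g$n_obs, fit$n_obs)
  expect_true(is.logical(g$converged))
  expect_s3_class(autoplot(fit), "ggplot")
})
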