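test_that("balanced two-group data decompose by hand", {
  d <- tibble::tibble(g = c("a", "a", "b", "b"), y = c(1, 1, 3, 3))
  a <- suppressWarnings(sequential_anova(d, "y", terms = "g"))
  expect_equal(a$ss[a$term == "g"], 4)
  expect_equal(a$ss[a$term == ".residual"], 0)
  expect_equal(a$pct_ss[a$term == "g"], 100)
})

test_that("single-level terms get zero df without failing", {
  d <- tibble::tibble(g = c("a", "a", "b", "b"), h = "only",
                      y = c(1, 2, 3, 5))
  expect_message(a <- sequential_anova(d, "y", terms = c("h", "g")),
                 "0 df.*h")
  expect_equal(a$df[a$term == "h"], 0)
  expect_equal(a$ss[a$term == "h"], 0)
  expect_equal(sum(a$ss), sum((d$y - mean(d$y))^2))
})

test_that("sequential SS equal the QR projection-difference oracle", {
  for (seed in 1:10) {
    d <- random_design(seed = seed)
    a <- sequential_anova(d, "y", terms = c("g1", "g2"))
    oracle <- seq_ss_oracle(d, d$y, c("g1", "g2"))
    expect_equal(setNames(a$ss, a$term), oracle, tolerance = 1e-8)
  }
})

test_that("stratum-aware F tests pick the documented error terms", {
  d <- generate_trait_dataset(generator_config(), seed = 7)
  tabs <- traitdecomp:::wide_log_tables(d$traits)
  meta <- dplyr::distinct(d$traits, .data$individual_id, .data$family,
                          .data$functional_type, .data$growth_form)
  dd <- dplyr::inner_join(tabs$obs, meta, by = "individual_id")
  dd$species <- dd$species_id
  a <- sequential_anova(dd, "LMA")
  et <- setNames(a$error_term, a$term)
  expect_equal(et[["functional_type"]], "family")
  expect_equal(et[["family"]], "species")
  expect_equal(et[["species"]], "individual_id")
  expect_equal(et[["individual_id"]], ".residual")
  expect_equal(et[["season"]], ".residual")
})

test_that("a numeric covariate enters as a 1-df leading term", {
  d <- random_design(seed = 3)
  d$cov <- withr::with_seed(4, rnorm(nrow(d)))
  a <- sequential_anova(d, "y", terms = c("cov", "g1"))
  expect_equal(a$df[a$term == "cov"], 1)
  expect_equal(setNames(a$ss, a$term),
               seq_ss_oracle(d, d$y, c("cov", "g1")), tolerance = 1e-8)
})

test_that("the polarization identity makes y = x reduce to the SS partition", {
  d <- random_design(seed = 11)
  d$yx <- d$x
  p <- partition_cross_products(d, "x", "yx", terms = c("g1", "g2"))
  a <- sequential_anova(d, "x", terms = c("g1", "g2"))
  expect_equal(p$scp, a$ss, tolerance = 1e-10)
  expect_equal(p$pct_scp, a$pct_ss, tolerance = 1e-10)

  d$neg <- -d$x
  pn <- partition_cross_products(d, "x", "neg", terms = c("g1", "g2"))
  expect_equal(pn$scp, -a$ss, tolerance = 1e-10)
})

test_that("components sum to the total corrected cross-product", {
  for (seed in 1:30) {
    d <- random_design(seed = seed)
    p <- partition_cross_products(d, "x", "y", terms = c("g1", "g2"))
    total <- sum((d$x - mean(d$x)) * (d$y - mean(d$y)))
    expect_equal(sum(p$scp), total, tolerance = 1e-8)
    expect_equal(attr(p, "total_scp"), total, tolerance = 1e-8)
    expect_equal(sum(p$pct_scp), 100, tolerance = 1e-6)
  }
})

test_that("SCP components equal the incremental-component cross-products", {
  d <- random_design(seed = 17)
  p <- partition_cross_products(d, "x", "y", terms = c("g1", "g2"))
  cx <- traitdecomp:::incremental_components(d, d$x, c("g1", "g2"))
  cy <- traitdecomp:::incremental_components(d, d$y, c("g1", "g2"))
  expect_equal(p$scp, unname(colSums(cx * cy)), tolerance = 1e-8)
})

test_that("scaling one trait scales components but not percentages", {
  d <- random_design(seed = 23)
  p1 <- partition_cross_products(d, "x", "y", terms = c("g1", "g2"))
  d$y3 <- 3 * d$y
  p3 <- partition_cross_products(d, "x", "y3", terms = c("g1", "g2"))
  expect_equal(p3$scp, 3 * p1$scp, tolerance = 1e-10)
  expect_equal(p3$pct_scp, p1$pct_scp, tolerance = 1e-10)
})

test_that("permutations can be skipped and are seed-reproducible", {
  d <- random_design(seed = 29)
  p0 <- partition_cross_products(d, "x", "y", terms = c("g1", "g2"))
  expect_false("p_value" %in% names(p0))

  d2 <- generate_trait_dataset(generator_config(), seed = 13)
  tabs <- traitdecomp:::wide_log_tables(d2$traits)
  meta <- dplyr::distinct(d2$traits, .data$individual_id, .data$family,
                          .data$functional_type, .data$growth_form)
  dd <- dplyr::inner_join(tabs$obs, meta, by = "individual_id")
  dd$species <- dd$species_id
  pa <- partition_cross_products(dd, "LMA", "Ngreen", n_permutations = 59,
                                 seed = 2)
  pb <- partition_cross_products(dd, "LMA", "Ngreen", n_permutations = 59,
                                 seed = 2)
  expect_identical(pa$p_value, pb$p_value)
  expect_s3_class(autoplot(pa), "ggplot")
})

test_that("a strong species-level correlation is detected by the permutation test", {
  cfg <- recovery_config(sd_fam = 0, sd_spec = 0.3, sd_ind = 0.05,
                         sd_res = 0.1, n_fam = 10, spec_per_fam = 4,
                         ind_per_spec = 4)
  R <- cfg$level_correlations$species
  R["LMA", "Ngreen"] <- R["Ngreen", "LMA"] <- 0.9
  cfg$level_correlations$species <- R
  d <- generate_trait_dataset(cfg, seed = 41)
  tabs <- traitdecomp:::wide_log_tables(d$traits)
  meta <- dplyr::distinct(d$traits, .data$individual_id, .data$family,
                          .data$functional_type, .data$growth_form)
  dd <- dplyr::inner_join(tabs$obs, meta, by = "individual_id")
  dd$species <- dd$species_id
  p <- suppressMessages(partition_cross_products(
    dd, "LMA", "Ngreen", n_permutations = 199, seed = 3))
  expect_lt(p$p_value[p$term == "species"], 0.05)
})

test_that("null species-level covariance yields calibrated p-values", {
  pvals <- vapply(1:12, function(rep) {
    cfg <- recovery_config(sd_fam = 0, sd_spec = 0.3, sd_ind = 0.05,
                           sd_res = 0.1, n_fam = 10, spec_per_fam = 4,
                           ind_per_spec = 3)
    d <- generate_trait_dataset(cfg, seed = 100 + rep)
    tabs <- traitdecomp:::wide_log_tables(d$traits)
    meta <- dplyr::distinct(d$traits, .data$individual_id, .data$family,
                            .data$functional_type, .data$growth_form)
    dd <- dplyr::inner_join(tabs$obs, meta, by = "individual_id")
    dd$species <- dd$species_id
    p <- suppressMessages(partition_cross_products(
      dd, "LMA", "WD", n_permutations = 99, seed = rep))
    p$p_value[p$term == "species"]
  }, numeric(1))
  # under the null the p-values should be roughly uniform on (0, 1]
  expect_gt(mean(pvals), 0.2)
  expect_gt(max(pvals), 0.5)
})
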