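test_that("within-species correlation ignores species means by construction", {
  mk <- function(sp, fam, vals_lma, vals_n) {
    tibble::tibble(
      individual_id = rep(paste0(sp, seq_along(vals_lma)), 2),
      family = fam, genus = fam, species = sp,
      functional_type = "evergreen", growth_form = "tree",
      season = "spring",
      trait = rep(c("LMA", "Ngreen"), each = length(vals_lma)),
      value = c(vals_lma, vals_n)
    )
  }
  # per species: identical deviations on both traits, so the pooled
  # species-centred cloud is exactly collinear whatever the means are
  tab <- dplyr::bind_rows(
    mk("a", "F1", exp(c(1 + 0.2, 1 - 0.2)), exp(c(2 + 0.2, 2 - 0.2))),
    mk("b", "F2", exp(c(5 + 0.3, 5 - 0.3)), exp(c(0.5 + 0.3, 0.5 - 0.3)))
  )
  out <- trait_correlations(tab)
  within <- out[out$level == "within_species", ]
  expect_equal(within$r, 1, tolerance = 1e-10)
})

test_that("independent traits show near-zero correlations at every level", {
  cfg <- recovery_config(sd_fam = 0.1, sd_spec = 0.25, sd_ind = 0.05,
                         sd_res = 0.1, zero_fixed = TRUE)
  d <- generate_trait_dataset(cfg, seed = 51)
  out <- trait_correlations(d$traits, tree = d$tree)
  pair <- out[out$trait_x == "LMA" & out$trait_y == "WD", ]
  expect_lt(abs(pair$r[pair$level == "overall"]), 0.15)
  expect_lt(abs(pair$r[pair$level == "species_mean"]), 0.35)
  expect_lt(abs(pair$r[pair$level == "within_species"]), 0.15)
})

test_that("the overall correlation obeys the between/within mixing identity", {
  d <- generate_trait_dataset(generator_config(), seed = 9)
  tabs <- traitdecomp:::wide_log_tables(d$traits)
  dd <- tabs$obs[stats::complete.cases(tabs$obs[c("LMA", "Ngreen")]), ]
  x <- dd$LMA
  y <- dd$Ngreen
  sp <- dd$species_id
  xb <- stats::ave(x, sp)
  yb <- stats::ave(y, sp)
  # exact decomposition of the corrected cross-product and SS
  mix_r <- (sum((xb - mean(x)) * (yb - mean(y))) + sum((x - xb) * (y - yb))) /
    sqrt((sum((xb - mean(x))^2) + sum((x - xb)^2)) *
           (sum((yb - mean(y))^2) + sum((y - yb)^2)))
  out <- trait_correlations(d$traits)
  overall <- out$r[out$trait_x == "LMA" & out$trait_y == "Ngreen" &
                     out$level == "overall"]
  expect_equal(overall, mix_r, tolerance = 1e-10)
})

test_that("pairs with LHL use one observation per individual", {
  d <- generate_trait_dataset(generator_config(), seed = 9)
  out <- trait_correlations(d$traits)
  n_ind <- length(unique(d$traits$individual_id))
  lhl_overall <- out[out$trait_y == "LHL" | out$trait_x == "LHL", ]
  expect_true(all(lhl_overall$n[lhl_overall$level == "overall"] == n_ind))
})

test_that("the PIC level matches a direct contrast correlation", {
  d <- generate_trait_dataset(generator_config(), seed = 15)
  out <- trait_correlations(d$traits, tree = d$tree)
  # species means of log values (individual means averaged per species)
  indiv <- traitdecomp:::wide_log_tables(d$traits)$indiv
  sm <- indiv |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(LMA = mean(.data$LMA), WD = mean(.data$WD))
  v1 <- setNames(sm$LMA, sm$species_id)
  v2 <- setNames(sm$WD, sm$species_id)
  shared <- intersect(names(v1), names(v2))
  c1 <- independent_contrasts(d$tree, v1[shared])
  c2 <- independent_contrasts(d$tree, v2[shared])
  direct <- pic_correlation(c1, c2)
  got <- out[out$trait_x == "LMA" & out$trait_y == "WD" & out$level == "pic", ]
  expect_equal(got$r, direct$r, tolerance = 1e-12)
  expect_equal(got$n, direct$n_contrasts)
})

test_that("without a tree the PIC level is reported missing", {
  d <- generate_trait_dataset(generator_config(), seed = 15)
  out <- trait_correlations(d$traits)
  expect_true(all(is.na(out$r[out$level == "pic"])))
  expect_false(anyNA(out$r[out$level == "overall"]))
})

test_that("SMA slopes follow the analytic formula", {
  x <- log(seq(2, 40, length.out = 25))
  s <- bivariate_slope(x, 2 * x)
  expect_equal(s$slope, 2)
  expect_equal(suppressWarnings(bivariate_slope(x, 2 * x, method = "ols"))$slope, 2)

  # SD_y = SD_x with r = -0.5 forces slope -1
  withr::with_seed(2, {
    z1 <- scale(rnorm(400))[, 1]
    z2 <- scale(stats::residuals(lm(rnorm(400) ~ z1)))[, 1]
    y <- -0.5 * z1 + sqrt(1 - 0.25) * z2
  })
  s2 <- bivariate_slope(z1, y)
  expect_equal(s2$slope, -1, tolerance = 1e-10)
  expect_lt(s2$conf_low, s2$slope)
  expect_gt(s2$conf_high, s2$slope)

  expect_error(bivariate_slope(rep(1, 10), rnorm(10)), "zero variance",
               class = "traitdecomp_validation_error")
  expect_error(bivariate_slope(1:2, 1:2), class = "traitdecomp_validation_error")
})

test_that("SMA is the geometric-mean relationship: reciprocal slopes", {
  withr::with_seed(3, {
    x <- rnorm(60)
    y <- -1.06 * x + rnorm(60, sd = 0.4)
  })
  sxy <- bivariate_slope(x, y)$slope
  syx <- bivariate_slope(y, x)$slope
  expect_equal(abs(sxy), 1 / abs(syx), tolerance = 1e-10)
})

test_that("the SMA confidence interval covers the population slope", {
  # population SMA slope = -sqrt(var_y / var_x) for y = b x + e
  slope_true <- -sqrt((1.06^2 * 0.4^2 + 0.25^2) / 0.4^2)
  covered <- withr::with_seed(8, {
    vapply(1:40, function(i) {
      x <- rnorm(300, sd = 0.4)
      y <- -1.06 * x + rnorm(300, sd = 0.25)
      s <- bivariate_slope(x, y)
      s$conf_low <= slope_true && slope_true <= s$conf_high
    }, logical(1))
  })
  expect_gte(mean(covered), 0.9)
})
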