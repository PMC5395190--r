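# Shared fixtures, built in code.

# A minimal valid long trait table.
tiny_trait_table <- function() {
  tibble::tibble(
    individual_id = c("i1", "i1", "i2"),
    family = "Fagaceae", genus = "Quercus", species = "serrata",
    functional_type = "deciduous", growth_form = "tree",
    season = c("spring", "fall", NA),
    trait = c("LMA", "LMA", "LHL"),
    value = c(80, 95, 250)
  )
}

# Generator config with a simulated balanced-ish taxonomy, identity
# correlations and chosen per-level SDs for one focal trait; used by
# variance-recovery tests.
recovery_config <- function(sd_fam, sd_spec, sd_ind, sd_res,
                            n_fam = 20, spec_per_fam = 3, ind_per_spec = 4,
                            zero_fixed = FALSE) {
  sds <- default_level_sds()
  sds["family", ] <- sd_fam
  sds["species", ] <- sd_spec
  sds["individual", ] <- sd_ind
  sds["residual", ] <- sd_res
  eye <- diag(4)
  dimnames(eye) <- list(trait_levels_vec(), trait_levels_vec())
  fe <- default_fixed_effects()
  if (zero_fixed) fe <- lapply(fe, function(v) v * 0)
  generator_config(
    taxonomy = NULL, n_families = n_fam, species_per_family = spec_per_fam,
    individuals_per_species = ind_per_spec,
    fixed_effects = fe,
    level_sds = sds,
    level_correlations = list(family = eye, species = eye,
                              individual = eye, residual = eye),
    fraction_censused = 0
  )
}

trait_levels_vec <- function() c("LMA", "Ngreen", "LHL", "WD")

# Random unbalanced nested design with two correlated responses, for
# cross-product conservation checks.
random_design <- function(n_groups = 6, seed = NULL) {
  withr::with_seed(seed, {
    g1 <- sample(letters[1:n_groups], 60, replace = TRUE)
    g2 <- paste0(g1, sample(1:3, 60, replace = TRUE))
    x <- rnorm(60) + as.integer(factor(g1))
    y <- 0.5 * x + rnorm(60) - as.integer(factor(g2)) / 2
    tibble::tibble(g1 = g1, g2 = g2, x = x, y = y)
  })
}

# Independent sequential-SS oracle: projection differences from
# successively larger QR fits.
seq_ss_oracle <- function(data, v, terms) {
  n <- length(v)
  M <- matrix(1, n, 1)
  fit_prev <- qr.fitted(qr(M), v)
  ss <- setNames(numeric(length(terms) + 1), c(terms, ".residual"))
  for (t in terms) {
    x <- data[[t]]
    Mt <- if (is.numeric(x)) matrix(x, n, 1) else
      stats::model.matrix(~ f - 1, data.frame(f = factor(x)))
    M <- cbind(M, Mt)
    fit <- qr.fitted(qr(M), v)
    ss[t] <- sum((fit - fit_prev)^2)
    fit_prev <- fit
  }
  ss[".residual"] <- sum((v - fit_prev)^2)
  ss
}
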