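# Bayesian multilevel analysis of variance for one trait.
#
# Log trait ~ grand mean + functional type + growth form + season (fixed,
# two-level, sum-to-zero) + family + species + individual (random, nested)
# + residual. Priors: N(0, 1000) on the grand mean, U(-3, 3) on each fixed
# coefficient, U(0, 10) on every standard deviation. The importance of
# every term is expressed as a standard deviation: the posterior of the
# variance-component SD for random terms, and the finite-population SD of
# the level coefficients for fixed terms, so fixed and random effects are
# on one comparable scale.

#' Finite-population standard deviation of factor-level coefficients
#'
#' The spread (denominator J - 1) of a fixed factor's J level
#' coefficients around their mean, which puts fixed effects on the same
#' SD scale as random-effect variance components. Undefined (missing) for
#' fewer than two levels.
#'
#' @param coefficients Numeric vector of level coefficients.
#' @return A single standard deviation, or `NA` when `J < 2`.
#' @export
#' @examples
#' finite_population_sd(c(-1.5, 1.5)) # 1.5 * sqrt(2)
finite_population_sd <- function(coefficients) {
  if (length(coefficients) < 2) return(NA_real_)
  sd(coefficients)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic Rhat: the square root of the weighted between/within-chain
#' variance ratio. Values near 1 indicate the chains have mixed; the
#' pipeline flags parameters with Rhat >= 1.2.
#'
#' @param chains A list of equal-length numeric vectors (one per chain)
#'   or a matrix with one column per chain.
#' @return The Rhat statistic.
#' @export
rhat <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (length(chains) < 2) {
    abort("rhat needs at least two chains", class = "traitdecomp_validation_error")
  }
  lens <- lengths(chains)
  if (length(unique(lens)) != 1) {
    abort("chains must have equal length", class = "traitdecomp_validation_error")
  }
  n <- lens[1]
  W <- mean(vapply(chains, var, numeric(1)))
  B_over_n <- var(vapply(chains, mean, numeric(1)))
  if (W == 0) return(if (B_over_n == 0) 1 else Inf)
  sqrt((n - 1) / n + B_over_n / W)
}

#' Fit the Bayesian multilevel variance model for one trait
#'
#' Log-transforms the trait internally and samples the posterior with a
#' Gibbs sampler (conjugate updates for the mean and effects, inverse-CDF
#' truncated draws for the bounded fixed coefficients and for the
#' variance components under the uniform prior on the SD).
#'
#' Terms default to the trait's design: season is included when two
#' seasons were observed (never for LHL, which has one value per
#' individual), and the individual random term is included when
#' individuals have repeated observations (for LHL the residual already
#' is the among-individual variation). Random terms with fewer than two
#' levels are dropped with a warning.
#'
#' @param records A trait table (long format).
#' @param trait Trait to model (`"LMA"`, `"Ngreen"`, `"LHL"`, `"WD"`).
#' @param include_season,include_individual Override the term defaults.
#' @param chains Number of MCMC chains (>= 2, for Rhat).
#' @param iterations,burn_in,thin Chain length controls.
#' @param seed Base RNG seed; chain `c` uses `seed + c - 1`.
#' @param priors List with `grand_mean_var`, `fixed_bound`, `sd_bound`.
#' @return A `trait_varcomp` object: posterior draws of every effect-size
#'   SD, a summary table with credible intervals and Rhat, and the model
#'   metadata. See [tidy()], [glance()], [autoplot()].
#' @export
fit_trait_variance <- function(records, trait,
                               include_season = NULL,
                               include_individual = NULL,
                               chains = 3, iterations = 20000,
                               burn_in = 5000, thin = 5, seed = 1,
                               priors = list(grand_mean_var = 1000,
                                             fixed_bound = 3, sd_bound = 10)) {
  if (chains < 2) {
    abort("at least 2 chains are required for the Rhat diagnostic",
          class = "traitdecomp_config_error")
  }
  d <- dplyr::filter(records, .data$trait == !!trait, !is.na(.data$value))
  if (nrow(d) < 3) {
    abort(sprintf("not enough observations for trait %s", trait),
          class = "traitdecomp_validation_error")
  }
  y <- log(d$value)
  n <- length(y)

  fam <- factor(d$family)
  spec <- factor(species_label(d$genus, d$species))
  ind <- factor(d$individual_id)

  include_season <- include_season %||%
    (trait != "LHL" && length(unique(d$season[!is.na(d$season)])) == 2)
  include_individual <- include_individual %||% anyDuplicated(d$individual_id) > 0

  has_fam <- nlevels(fam) >= 2
  if (!has_fam) warn("family term dropped: fewer than 2 families")
  has_spec <- nlevels(spec) >= 2
  if (!has_spec) warn("species term dropped: fewer than 2 species")
  has_ind <- include_individual && nlevels(ind) >= 2

  two_level_sign <- function(x, plus, minus, term) {
    lev <- unique(x[!is.na(x)])
    if (length(lev) > 2) {
      abort(sprintf("fixed term %s has more than 2 levels", term),
            class = "traitdecomp_config_error")
    }
    if (length(lev) < 2) {
      warn(sprintf("%s term dropped: fewer than 2 levels", term))
      return(NULL)
    }
    ifelse(x == plus, 1, -1)
  }
  s_ft <- two_level_sign(d$functional_type, "evergreen", "deciduous",
                         "functional_type")
  s_gf <- two_level_sign(d$growth_form, "tree", "shrub", "growth_form")
  s_season <- if (include_season) {
    two_level_sign(d$season, "spring", "fall", "season")
  } else NULL

  par_names <- c("grand_mean", "delta_functional_type", "delta_growth_form",
                 "delta_season", "sd_family", "sd_species", "sd_individual",
                 "sd_residual")
  draws <- purrr::map_dfr(seq_len(chains), function(ch) {
    m <- with_seed(if (is.null(seed)) NULL else seed + ch - 1,
      gibbs_varcomp(y,
                    as.integer(fam) - 1L, nlevels(fam),
                    as.integer(spec) - 1L, nlevels(spec),
                    as.integer(ind) - 1L, nlevels(ind),
                    s_ft %||% numeric(n), s_gf %||% numeric(n),
                    s_season %||% numeric(n),
                    !is.null(s_ft), !is.null(s_gf), !is.null(s_season),
                    has_fam, has_spec, has_ind,
                    as.integer(iterations), as.integer(burn_in),
                    as.integer(thin),
                    priors$grand_mean_var, priors$fixed_bound,
                    priors$sd_bound))
    colnames(m) <- par_names
    out <- tibble::as_tibble(m)
    out$chain <- ch
    out$draw <- seq_len(nrow(m))
    out
  })
  # finite-population SD of a two-level sum-to-zero factor {+d, -d}
  for (term in c("functional_type", "growth_form", "season")) {
    delta <- draws[[paste0("delta_", term)]]
    draws[[paste0("sd_", term)]] <- abs(delta) * sqrt(2)
  }

  fb <- priors$fixed_bound
  for (term in c("functional_type", "growth_form", "season")) {
    delta <- draws[[paste0("delta_", term)]]
    if (!all(is.na(delta)) && mean(abs(delta) > fb - 0.05, na.rm = TRUE) > 0.05) {
      warn(sprintf("prior bound active for %s coefficient (U(-%g, %g)); check the data scale",
                   term, fb, fb))
    }
  }

  sd_terms <- c("sd_functional_type", "sd_growth_form", "sd_season",
                "sd_family", "sd_species", "sd_individual", "sd_residual")
  summarise_par <- function(p) {
    x <- draws[[p]]
    if (all(is.na(x))) return(NULL)
    q <- quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
    rh <- rhat(lapply(split(x, draws$chain), identity))
    tibble::tibble(term = sub("^sd_", "", sub("^delta_", "", p)),
                   estimate = mean(x), std_error = sd(x),
                   q2.5 = q[1], q25 = q[2], q50 = q[3], q75 = q[4],
                   q97.5 = q[5], rhat = rh)
  }
  summary <- dplyr::bind_rows(lapply(c("grand_mean", sd_terms), summarise_par))
  if (any(summary$rhat >= 1.2, na.rm = TRUE)) {
    warn(sprintf("Rhat >= 1.2 for: %s (chains may not have converged)",
                 paste(summary$term[summary$rhat >= 1.2], collapse = ", ")))
  }

  structure(list(
    trait = trait, draws = draws, summary = summary, n_obs = n,
    terms = summary$term[summary$term != "grand_mean"],
    settings = list(chains = chains, iterations = iterations,
                    burn_in = burn_in, thin = thin, seed = seed,
                    priors = priors)
  ), class = "trait_varcomp")
}

#' @export
print.trait_varcomp <- function(x, ...) {
  cat(sprintf("<trait_varcomp> %s: %d observations, %d chains x %d kept draws\n",
              x$trait, x$n_obs, x$settings$chains,
              nrow(x$draws) / x$settings$chains))
  cat("Effect-size SDs (posterior mean [95% CrI], Rhat):\n")
  s <- x$summary[x$summary$term != "grand_mean", ]
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-16s %6.3f [%5.3f, %5.3f]  Rhat %.3f\n", s$term[i],
                s$estimate[i], s$q2.5[i], s$q97.5[i], s$rhat[i]))
  }
  invisible(x)
}

#' Tidy posterior summaries of a fitted variance decomposition
#'
#' One row per model term with the posterior mean, SD, 50% and 95%
#' credible-interval bounds and Rhat of the term's effect-size SD (the
#' grand mean row summarises the mean itself).
#'
#' @param x A `trait_varcomp` object from [fit_trait_variance()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.trait_varcomp <- function(x, ...) {
  dplyr::mutate(x$summary, trait = x$trait, .before = 1)
}

#' One-row model summary of a fitted variance decomposition
#'
#' @param x A `trait_varcomp` object.
#' @param ... Unused.
#' @return A tibble with the trait, sample size, number of kept draws,
#'   the largest Rhat and whether all terms pass the Rhat < 1.2 rule.
#' @export
glance.trait_varcomp <- function(x, ...) {
  tibble::tibble(trait = x$trait, n_obs = x$n_obs, n_draws = nrow(x$draws),
                 max_rhat = max(x$summary$rhat, na.rm = TRUE),
                 converged = max(x$summary$rhat, na.rm = TRUE) < 1.2)
}
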