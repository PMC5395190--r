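# Synthetic hierarchical trait data with known ground truth.
#
# Traits are generated on the log scale as
#   grand mean + functional-type + growth-form + season offsets
#   + correlated family / species / individual draws + residual
# and exponentiated, so downstream models (which log-transform) are
# exactly correctly specified and every variance component is known.

#' Default generator ground truth
#'
#' The log-scale grand means, fixed half-offsets, per-level SDs and
#' per-level trait correlation matrices used by [generator_config()]
#' when no overrides are given. Offsets are sum-to-zero halves:
#' evergreen/tree/spring carry `+delta`, deciduous/shrub/fall `-delta`.
#'
#' @return `default_grand_means()`: a named numeric vector;
#'   `default_fixed_effects()`: a list of named vectors per fixed term;
#'   `default_level_sds()`: a 4 x 4 matrix (levels x traits);
#'   `default_level_correlations()`: a list of 4 x 4 correlation
#'   matrices per level.
#' @name generator_defaults
NULL

#' @rdname generator_defaults
#' @export
default_grand_means <- function() {
  c(LMA = log(80), Ngreen = log(2), LHL = log(250), WD = log(0.5))
}

#' @rdname generator_defaults
#' @export
default_fixed_effects <- function() {
  list(
    functional_type = c(LMA = 0.25, Ngreen = -0.25, LHL = 0.45, WD = 0.10),
    growth_form     = c(LMA = 0.03, Ngreen = -0.03, LHL = 0.05, WD = 0.02),
    season          = c(LMA = -0.05, Ngreen = 0.12, LHL = 0.00, WD = -0.03)
  )
}

#' @rdname generator_defaults
#' @export
default_level_sds <- function() {
  rbind(
    family     = c(LMA = 0.12, Ngreen = 0.12, LHL = 0.15, WD = 0.06),
    species    = c(LMA = 0.20, Ngreen = 0.18, LHL = 0.30, WD = 0.12),
    individual = c(LMA = 0.05, Ngreen = 0.05, LHL = 0.40, WD = 0.03),
    residual   = c(LMA = 0.12, Ngreen = 0.15, LHL = 0.00, WD = 0.06)
  )
}

cor_from_pairs <- function(traits, pairs) {
  R <- diag(length(traits))
  dimnames(R) <- list(traits, traits)
  for (p in pairs) {
    R[p[[1]], p[[2]]] <- R[p[[2]], p[[1]]] <- p[[3]]
  }
  R
}

#' @rdname generator_defaults
#' @export
default_level_correlations <- function() {
  tr <- trait_levels()
  list(
    family = cor_from_pairs(tr, list(
      list("LMA", "Ngreen", -0.50), list("LMA", "LHL", 0.45),
      list("LMA", "WD", 0.30), list("Ngreen", "LHL", -0.35),
      list("Ngreen", "WD", -0.35), list("LHL", "WD", 0.25))),
    species = cor_from_pairs(tr, list(
      list("LMA", "Ngreen", -0.70), list("LMA", "LHL", 0.60),
      list("LMA", "WD", 0.40), list("Ngreen", "LHL", -0.50),
      list("Ngreen", "WD", -0.50), list("LHL", "WD", 0.35))),
    individual = cor_from_pairs(tr, list(list("LMA", "Ngreen", -0.30))),
    residual = cor_from_pairs(tr, list(list("LMA", "Ngreen", -0.40)))
  )
}

#' Configuration for the synthetic trait-data generator
#'
#' Defines the ground truth of a simulated community: taxonomy (by
#' default the packaged Dujiangyan species list, i.e. 45 species in 20
#' families with 294 individuals), per-trait fixed offsets on the log
#' scale, per-level standard deviations, and per-level trait correlation
#' matrices. Leaf half-life is generated once per individual (its
#' individual-level SD acts as the among-individual residual); the other
#' traits get two seasonal observations per individual.
#'
#' @param taxonomy A species table like [dujiangyan_species()], or `NULL`
#'   to simulate one from the count arguments.
#' @param n_families,species_per_family,individuals_per_species Shape of a
#'   simulated taxonomy when `taxonomy` is `NULL`; the latter two are a
#'   single count or a `c(min, max)` range sampled per unit.
#' @param exception_rate Probability that a species flips the functional
#'   type of its family (families can contain both leaf habits).
#' @param grand_means Named log-scale trait means.
#' @param fixed_effects List of named per-trait half-offsets for
#'   `functional_type`, `growth_form`, `season`.
#' @param level_sds Matrix of log-scale SDs, rows `family`, `species`,
#'   `individual`, `residual`, columns traits.
#' @param level_correlations List of trait correlation matrices per level.
#' @param fraction_censused Fraction of individuals carrying marked leaf
#'   cohorts for half-life estimation.
#' @param n_branches Marked branches per censused individual.
#' @param cohort_size_range Range of initial cohort sizes (leaves).
#' @param census_times Census days since cohort marking.
#' @param soil_log_mean,soil_log_sd Log-scale parameters of the (trait-
#'   independent) soil nitrogen distribution, g/kg.
#' @return A validated `trait_generator_config` list.
#' @export
generator_config <- function(taxonomy = dujiangyan_species(),
                             n_families = 20,
                             species_per_family = c(1, 7),
                             individuals_per_species = c(1, 16),
                             exception_rate = 0.15,
                             grand_means = default_grand_means(),
                             fixed_effects = default_fixed_effects(),
                             level_sds = default_level_sds(),
                             level_correlations = default_level_correlations(),
                             fraction_censused = 0.3,
                             n_branches = 2,
                             cohort_size_range = c(5, 20),
                             census_times = c(0, 122, 334, 487, 640),
                             soil_log_mean = log(3),
                             soil_log_sd = 0.6) {
  traits <- names(grand_means)
  if (any(level_sds < 0)) {
    abort("level SDs must be non-negative", class = "traitdecomp_config_error")
  }
  for (lev in names(level_correlations)) {
    R <- level_correlations[[lev]]
    if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-12)) {
      abort(sprintf("correlation matrix for level '%s' must be symmetric with unit diagonal", lev),
            class = "traitdecomp_config_error")
    }
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      abort(sprintf("correlation matrix for level '%s' is not positive semi-definite", lev),
            class = "traitdecomp_config_error")
    }
  }
  structure(list(
    taxonomy = taxonomy, n_families = n_families,
    species_per_family = species_per_family,
    individuals_per_species = individuals_per_species,
    exception_rate = exception_rate, traits = traits,
    grand_means = grand_means, fixed_effects = fixed_effects,
    level_sds = level_sds, level_correlations = level_correlations,
    fraction_censused = fraction_censused, n_branches = n_branches,
    cohort_size_range = cohort_size_range, census_times = census_times,
    soil_log_mean = soil_log_mean, soil_log_sd = soil_log_sd
  ), class = "trait_generator_config")
}

#' Simulate a taxonomy table
#'
#' Builds a species table (family, genus, species, functional type,
#' growth form, individuals sampled) for use as generator ground truth.
#' Functional type is assigned at the family level and flipped per
#' species with probability `exception_rate`.
#'
#' @inheritParams generator_config
#' @param tree_fraction Probability a species is a tree (vs shrub).
#' @param seed Optional RNG seed.
#' @return A tibble shaped like [dujiangyan_species()].
#' @export
simulate_taxonomy <- function(n_families = 20, species_per_family = c(1, 7),
                              individuals_per_species = c(1, 16),
                              exception_rate = 0.15, tree_fraction = 0.75,
                              seed = NULL) {
  sample_count <- function(rng, n) {
    if (length(rng) == 1) rep(rng, n) else sample(seq(rng[1], rng[2]), n, replace = TRUE)
  }
  with_seed(seed, {
    n_spec <- sample_count(species_per_family, n_families)
    fam <- sprintf("Fam%02d", rep(seq_len(n_families), n_spec))
    fam_type <- sample(functional_types(), n_families, replace = TRUE)
    flip <- runif(length(fam)) < exception_rate
    ft <- fam_type[rep(seq_len(n_families), n_spec)]
    ft[flip] <- ifelse(ft[flip] == "deciduous", "evergreen", "deciduous")
    n_total <- length(fam)
    tibble::tibble(
      family = fam,
      genus = sprintf("Genus%03d", seq_len(n_total)),
      species = sprintf("sp%03d", seq_len(n_total)),
      functional_type = ft,
      growth_form = ifelse(runif(n_total) < tree_fraction, "tree", "shrub"),
      n_individuals = sample_count(individuals_per_species, n_total)
    )
  })
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' @param n_tips Number of tips.
#' @param tip_labels Optional tip labels (length `n_tips`).
#' @param birth Speciation rate.
#' @param seed Optional RNG seed.
#' @return An [ape::phylo] object.
#' @export
simulate_yule_tree <- function(n_tips, tip_labels = NULL, birth = 1, seed = NULL) {
  with_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = birth, death = 0)
    if (!is.null(tip_labels)) tree$tip.label <- sample(tip_labels)
    tree
  })
}

# Draw n rows from a T-variate normal with SD vector `sds` and correlation
# `R`; eigen square root tolerates semi-definite R (e.g. correlations of 1).
mvn_level_draws <- function(n, sds, R) {
  traits <- names(sds)
  R <- R[traits, traits, drop = FALSE]
  e <- eigen(R, symmetric = TRUE)
  sqrtR <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), length(traits)) %*% t(e$vectors)
  Z <- matrix(rnorm(n * length(traits)), n, length(traits)) %*% sqrtR
  Z <- sweep(Z, 2, sds, `*`)
  colnames(Z) <- traits
  Z
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Each trait evolves independently from `root_state` with increments
#' `N(0, rate * branch length)` along every branch, so tip covariance
#' equals `rate` times shared path length (the phylogenetic
#' variance-covariance matrix).
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param rate Brownian rate (variance per unit branch length), > 0.
#' @param n_traits Number of independent traits.
#' @param root_state Trait value at the root.
#' @param seed Optional RNG seed.
#' @return A tibble with column `species` and one `trait_<j>` column per
#'   trait.
#' @export
simulate_bm_traits <- function(tree, rate = 1, n_traits = 1, root_state = 0,
                               seed = NULL) {
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    abort("rate must be a positive number", class = "traitdecomp_config_error")
  }
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    vals <- matrix(NA_real_, ntip + tree$Nnode, n_traits)
    vals[ntip + 1L, ] <- root_state
    ord <- ape::reorder.phylo(tree, "postorder")
    edge <- ord$edge
    len <- ord$edge.length
    for (k in rev(seq_len(nrow(edge)))) {
      vals[edge[k, 2L], ] <- vals[edge[k, 1L], ] +
        rnorm(n_traits, 0, sqrt(rate * len[k]))
    }
    out <- tibble::tibble(species = tree$tip.label)
    for (j in seq_len(n_traits)) out[[paste0("trait_", j)]] <- vals[seq_len(ntip), j]
    out
  })
}

#' Simulate a leaf-cohort census under exponential abscission
#'
#' Lifetimes of the `n_leaves0` marked leaves are i.i.d. exponential with
#' median `half_life_days`; the live count at each census is the number
#' of lifetimes exceeding the time since marking (the first census).
#'
#' @param n_leaves0 Initial cohort size, >= 1.
#' @param half_life_days Leaf half-life in days (`Inf` allowed: no
#'   abscission).
#' @param census_times Strictly increasing census days; the cohort is
#'   marked at the first one.
#' @param seed Optional RNG seed.
#' @return A tibble with columns `date` and `live_count`.
#' @export
simulate_leaf_census <- function(n_leaves0, half_life_days, census_times,
                                 seed = NULL) {
  if (n_leaves0 < 1) abort("n_leaves0 must be >= 1", class = "traitdecomp_config_error")
  if (!(half_life_days > 0)) abort("half_life_days must be positive",
                                   class = "traitdecomp_config_error")
  tt <- as.numeric(census_times)
  if (length(tt) < 1 || any(diff(tt) <= 0)) {
    abort("census_times must be strictly increasing",
          class = "traitdecomp_validation_error")
  }
  with_seed(seed, {
    lifetimes <- if (is.infinite(half_life_days)) {
      rep(Inf, n_leaves0)
    } else {
      rexp(n_leaves0, rate = log(2) / half_life_days)
    }
    counts <- vapply(tt - tt[1], function(dt) sum(lifetimes > dt), integer(1))
    tibble::tibble(date = census_times, live_count = counts)
  })
}

#' Generate a full synthetic trait dataset with known ground truth
#'
#' Produces a long trait table, a Yule phylogeny over the species, leaf
#' censuses for a subset of individuals, and a `truth` list (config,
#' seed, realized level effects and true per-individual leaf half-lives)
#' sufficient to regenerate every observation deterministically.
#'
#' @param config A [generator_config()].
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @return A list of class `synthetic_traits` with elements `traits`,
#'   `tree`, `censuses`, `truth`.
#' @export
#' @examples
#' d <- generate_trait_dataset(generator_config(), seed = 42)
#' dplyr::count(d$traits, trait)
generate_trait_dataset <- function(config = generator_config(), seed = 1) {
  if (!inherits(config, "trait_generator_config")) {
    abort("config must come from generator_config()",
          class = "traitdecomp_config_error")
  }
  with_seed(seed, {
    tax <- config$taxonomy %||% simulate_taxonomy(
      n_families = config$n_families,
      species_per_family = config$species_per_family,
      individuals_per_species = config$individuals_per_species,
      exception_rate = config$exception_rate
    )
    tax$species_id <- species_label(tax$genus, tax$species)
    traits <- config$traits
    fams <- unique(tax$family)

    inds <- tax[rep(seq_len(nrow(tax)), tax$n_individuals), ]
    inds$individual_id <- unlist(lapply(tax$n_individuals, seq_len))
    inds$individual_id <- sprintf("%s_%02d", inds$species_id, inds$individual_id)

    fam_eff <- mvn_level_draws(length(fams), config$level_sds["family", traits],
                               config$level_correlations$family)
    rownames(fam_eff) <- fams
    spec_eff <- mvn_level_draws(nrow(tax), config$level_sds["species", traits],
                                config$level_correlations$species)
    rownames(spec_eff) <- tax$species_id
    ind_eff <- mvn_level_draws(nrow(inds), config$level_sds["individual", traits],
                               config$level_correlations$individual)
    rownames(ind_eff) <- inds$individual_id

    fe <- config$fixed_effects
    sign_ft <- ifelse(inds$functional_type == "evergreen", 1, -1)
    sign_gf <- ifelse(inds$growth_form == "tree", 1, -1)
    soil_n <- round(exp(rnorm(nrow(inds), config$soil_log_mean, config$soil_log_sd)), 2)

    base_log <- function(trait) unname(
      config$grand_means[[trait]] +
        sign_ft * fe$functional_type[[trait]] +
        sign_gf * fe$growth_form[[trait]] +
        fam_eff[inds$family, trait] +
        spec_eff[inds$species_id, trait] +
        ind_eff[inds$individual_id, trait]
    )

    seasonal <- setdiff(traits, "LHL")
    rows <- list()
    for (season in season_levels()) {
      sign_season <- if (season == "spring") 1 else -1
      res <- mvn_level_draws(nrow(inds), config$level_sds["residual", traits],
                             config$level_correlations$residual)
      for (tr in seasonal) {
        rows[[paste(season, tr)]] <- tibble::tibble(
          individual_id = inds$individual_id,
          family = inds$family, genus = inds$genus, species = inds$species,
          functional_type = inds$functional_type,
          growth_form = inds$growth_form,
          season = season, trait = tr,
          value = exp(base_log(tr) + sign_season * fe$season[[tr]] +
                        res[, tr]),
          soil_n = soil_n
        )
      }
    }
    lhl_true <- exp(base_log("LHL"))
    if ("LHL" %in% traits) {
      rows$LHL <- tibble::tibble(
        individual_id = inds$individual_id,
        family = inds$family, genus = inds$genus, species = inds$species,
        functional_type = inds$functional_type, growth_form = inds$growth_form,
        season = NA_character_, trait = "LHL",
        value = lhl_true, soil_n = soil_n
      )
    }
    trait_table <- dplyr::arrange(dplyr::bind_rows(rows),
                                  .data$individual_id, .data$trait, .data$season)

    tree <- simulate_yule_tree(nrow(tax), tip_labels = tax$species_id)

    censused <- inds$individual_id[runif(nrow(inds)) < config$fraction_censused]
    censuses <- purrr::map_dfr(censused, function(id) {
      purrr::map_dfr(seq_len(config$n_branches), function(b) {
        n0 <- sample(seq(config$cohort_size_range[1], config$cohort_size_range[2]), 1)
        cen <- simulate_leaf_census(n0, lhl_true[match(id, inds$individual_id)],
                                    config$census_times)
        tibble::tibble(individual_id = id, branch_id = sprintf("b%d", b),
                       cohort_id = "c1", date = cen$date,
                       live_count = cen$live_count)
      })
    })

    structure(list(
      traits = trait_table,
      tree = tree,
      censuses = censuses,
      truth = list(
        config = config, seed = seed, taxonomy = tax,
        family_effects = fam_eff, species_effects = spec_eff,
        individual_effects = ind_eff,
        lhl_true = setNames(lhl_true, inds$individual_id)
      )
    ), class = "synthetic_traits")
  })
}

#' @export
print.synthetic_traits <- function(x, ...) {
  cat(sprintf(
    "<synthetic_traits> %d trait records | %d species | %d families | %d censused individuals (seed %s)\n",
    nrow(x$traits),
    nrow(unique(x$traits[c("genus", "species")])),
    length(unique(x$traits$family)),
    length(unique(x$censuses$individual_id)), format(x$truth$seed)))
  invisible(x)
}
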