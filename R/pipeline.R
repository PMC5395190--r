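# One-call orchestration: ingest -> leaf half-life -> per-trait variance
# decomposition -> per-pair covariance partition -> phylogenetic signal
# -> four-level correlation table, with a manifest of seeds and settings.

#' Configuration for a full analysis run
#'
#' Inputs are either file paths / in-memory objects (trait table, census
#' table, tree) or a synthetic-generator config — never neither.
#'
#' @param trait_table A trait table (tibble or CSV path), or `NULL` when
#'   generating.
#' @param census_table Optional census table (tibble or CSV path); when
#'   present, leaf half-lives are estimated from it and appended as LHL
#'   records (replacing any provided LHL rows).
#' @param tree Optional phylogeny ([ape::phylo] or Newick path); without
#'   it the phylogenetic stages are skipped with a notice.
#' @param generator Optional [generator_config()]; used when
#'   `trait_table` is `NULL`.
#' @param seed Global seed (generation, MCMC, permutations,
#'   randomizations).
#' @param mcmc List of [fit_trait_variance()] chain settings.
#' @param n_permutations Permutations per covariance component.
#' @param k_randomizations Randomizations for Blomberg's K.
#' @param term_order Term order for the covariance partition.
#' @return A `trait_run_config` list.
#' @export
trait_analysis_config <- function(trait_table = NULL, census_table = NULL,
                                  tree = NULL, generator = NULL, seed = 1,
                                  mcmc = list(chains = 3, iterations = 20000,
                                              burn_in = 5000, thin = 5),
                                  n_permutations = 199,
                                  k_randomizations = 1000,
                                  term_order = default_term_order()) {
  if (is.null(trait_table) && is.null(generator)) {
    abort("config needs either a trait table or a generator config",
          class = "traitdecomp_config_error")
  }
  structure(list(trait_table = trait_table, census_table = census_table,
                 tree = tree, generator = generator, seed = seed,
                 mcmc = mcmc, n_permutations = n_permutations,
                 k_randomizations = k_randomizations,
                 term_order = term_order),
            class = "trait_run_config")
}

#' Run the full trait variance/covariance analysis
#'
#' Executes every stage on real or generated data and returns all result
#' tables; optionally writes them (CSV) plus a JSON manifest to
#' `out_dir`. Stages: validation, leaf half-life estimation from
#' censuses, the Bayesian variance decomposition per trait, the
#' cross-product partition with permutation tests per trait pair,
#' Blomberg's K with randomization per trait, and the four-level
#' correlation table.
#'
#' @param config A [trait_analysis_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return A `trait_analysis` list: `traits`, `lhl`, `varcomp` (fitted
#'   objects), `varcomp_summary`, `covpart`, `covpart_summary`,
#'   `phylo_signal`, `correlations`, `manifest`.
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "trait_run_config"))
  seed <- config$seed

  if (is.null(config$trait_table)) {
    dataset <- generate_trait_dataset(config$generator, seed = seed)
    records <- dataset$traits
    censuses <- config$census_table %||% dataset$censuses
    tree <- config$tree %||% dataset$tree
  } else {
    records <- if (is.character(config$trait_table)) {
      read_trait_table(config$trait_table)
    } else {
      validate_trait_table(config$trait_table)
    }
    censuses <- config$census_table
    if (is.character(censuses)) censuses <- read_census_table(censuses)
    tree <- config$tree
    if (is.character(tree)) tree <- read_newick_tree(tree)
  }

  lhl <- NULL
  if (!is.null(censuses) && nrow(censuses) > 0) {
    lhl <- lhl_per_individual(censuses)
    meta <- records |>
      dplyr::distinct(.data$individual_id, .data$family, .data$genus,
                      .data$species, .data$functional_type, .data$growth_form)
    lhl_records <- lhl |>
      dplyr::inner_join(meta, by = "individual_id") |>
      dplyr::transmute(.data$individual_id, .data$family, .data$genus,
                       .data$species, .data$functional_type,
                       .data$growth_form, season = NA_character_,
                       trait = "LHL", value = .data$lhl_days)
    records <- dplyr::bind_rows(dplyr::filter(records, .data$trait != "LHL"),
                                lhl_records)
  }

  traits <- intersect(trait_levels(), unique(records$trait))

  varcomp <- lapply(setNames(traits, traits), function(tr) {
    fit_trait_variance(records, tr, chains = config$mcmc$chains,
                       iterations = config$mcmc$iterations,
                       burn_in = config$mcmc$burn_in,
                       thin = config$mcmc$thin, seed = seed)
  })
  varcomp_summary <- purrr::map_dfr(varcomp, tidy)

  tabs <- wide_log_tables(records)
  meta_ind <- records |>
    dplyr::distinct(.data$individual_id, .data$family, .data$functional_type,
                    .data$growth_form)
  pair_list <- utils::combn(traits, 2, simplify = FALSE)
  covpart <- lapply(pair_list, function(p) {
    tab <- if ("LHL" %in% p) tabs$indiv else tabs$obs
    d <- dplyr::inner_join(tab, meta_ind, by = "individual_id")
    d$species <- d$species_id
    terms <- config$term_order
    if (!"season" %in% names(d)) terms <- setdiff(terms, "season")
    partition_cross_products(d, p[1], p[2], terms = terms,
                             n_permutations = config$n_permutations,
                             seed = seed)
  })
  names(covpart) <- vapply(pair_list, paste, character(1), collapse = "-")
  covpart_summary <- purrr::map_dfr(covpart, tidy)

  phylo_signal <- NULL
  correlations <- NULL
  if (is.null(tree)) {
    inform("no tree supplied: skipping phylogenetic signal and PIC correlations")
    correlations <- trait_correlations(records, tree = NULL)
  } else {
    overlap <- species_tree_overlap(records, tree)
    if (length(overlap$missing_from_tree) > 0) {
      inform(sprintf("%d species missing from tree (analysis on intersection): %s",
                     length(overlap$missing_from_tree),
                     paste(overlap$missing_from_tree, collapse = ", ")))
    }
    sm <- species_summary(records) |>
      dplyr::mutate(species_id = species_label(.data$genus, .data$species))
    phylo_signal <- purrr::map_dfr(setNames(traits, traits), function(tr) {
      v <- sm |> dplyr::filter(.data$trait == tr)
      vals <- setNames(log(v$mean), v$species_id)
      vals <- vals[names(vals) %in% tree$tip.label]
      if (length(vals) < 3) return(NULL)
      dplyr::mutate(tidy(k_randomization_test(tree, vals,
                                              n_reps = config$k_randomizations,
                                              seed = seed)),
                    trait = tr, .before = 1)
    })
    correlations <- trait_correlations(records, tree = tree)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("traitdecomp")),
    seed = seed, term_order = config$term_order,
    mcmc = config$mcmc, n_permutations = config$n_permutations,
    k_randomizations = config$k_randomizations,
    n_records = nrow(records), traits = traits
  )

  result <- structure(list(
    traits = records, lhl = lhl, varcomp = varcomp,
    varcomp_summary = varcomp_summary, covpart = covpart,
    covpart_summary = covpart_summary, phylo_signal = phylo_signal,
    correlations = correlations, manifest = manifest
  ), class = "trait_analysis")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(varcomp_summary, file.path(out_dir, "varcomp_summary.csv"),
                     progress = FALSE)
    readr::write_csv(covpart_summary, file.path(out_dir, "covpart_summary.csv"),
                     progress = FALSE)
    if (!is.null(phylo_signal)) {
      readr::write_csv(phylo_signal, file.path(out_dir, "phylo_signal.csv"),
                       progress = FALSE)
    }
    readr::write_csv(correlations, file.path(out_dir, "correlations.csv"),
                     progress = FALSE)
    if (!is.null(lhl)) {
      readr::write_csv(lhl, file.path(out_dir, "lhl.csv"), progress = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}

#' @export
print.trait_analysis <- function(x, ...) {
  cat(sprintf("<trait_analysis> %d records | %d traits | %d pairs | seed %s\n",
              nrow(x$traits), length(x$varcomp), length(x$covpart),
              format(x$manifest$seed)))
  cat("stages: varcomp", if (!is.null(x$covpart)) "+ covpart",
      if (!is.null(x$phylo_signal)) "+ phylo_signal", "+ correlations\n")
  invisible(x)
}

#' Write a synthetic demonstration dataset to disk
#'
#' Generates a dataset with the default generator (the packaged species
#' list: 294 individuals, 45 species, 20 families) and writes
#' `traits.csv`, `censuses.csv`, `tree.nwk` and `truth.json` (the
#' generator settings and seed, sufficient to regenerate the dataset
#' bit-identically via [regenerate_from_truth()]).
#'
#' @param output_dir Writable output directory (created if needed).
#' @param seed RNG seed.
#' @param config A [generator_config()].
#' @return Invisibly, the named vector of file paths.
#' @export
make_demo_data <- function(output_dir, seed = 1, config = generator_config()) {
  dataset <- generate_trait_dataset(config, seed = seed)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) {
    abort(sprintf("cannot create output directory %s", output_dir),
          class = "traitdecomp_io_error")
  }
  paths <- c(traits = file.path(output_dir, "traits.csv"),
             censuses = file.path(output_dir, "censuses.csv"),
             tree = file.path(output_dir, "tree.nwk"),
             truth = file.path(output_dir, "truth.json"))
  write_trait_table(dataset$traits, paths[["traits"]])
  write_census_table(dataset$censuses, paths[["censuses"]])
  write_newick_tree(dataset$tree, paths[["tree"]])
  truth <- list(seed = seed, config = serialize_config(config))
  # I(17) significant digits: doubles survive the JSON round trip exactly
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = I(17))
  invisible(paths)
}

serialize_config <- function(config) {
  out <- unclass(config)
  # named vectors must become JSON objects, arrays drop names
  out$grand_means <- as.list(config$grand_means)
  out$fixed_effects <- lapply(config$fixed_effects, as.list)
  out$level_sds <- list(values = as.vector(config$level_sds),
                        rows = rownames(config$level_sds),
                        cols = colnames(config$level_sds))
  out$level_correlations <- lapply(config$level_correlations, function(R) {
    list(values = as.vector(R), traits = colnames(R))
  })
  out
}

deserialize_config <- function(x) {
  sds <- matrix(unlist(x$level_sds$values), nrow = length(x$level_sds$rows),
                dimnames = list(unlist(x$level_sds$rows),
                                unlist(x$level_sds$cols)))
  cors <- lapply(x$level_correlations, function(R) {
    tr <- unlist(R$traits)
    matrix(unlist(R$values), nrow = length(tr), dimnames = list(tr, tr))
  })
  generator_config(
    taxonomy = if (is.null(x$taxonomy)) NULL else
      tibble::as_tibble(x$taxonomy)[, c("family", "genus", "species",
                                        "functional_type", "growth_form",
                                        "n_individuals")],
    n_families = x$n_families,
    species_per_family = unlist(x$species_per_family),
    individuals_per_species = unlist(x$individuals_per_species),
    exception_rate = x$exception_rate,
    grand_means = unlist(x$grand_means),
    fixed_effects = lapply(x$fixed_effects, unlist),
    level_sds = sds, level_correlations = cors,
    fraction_censused = x$fraction_censused, n_branches = x$n_branches,
    cohort_size_range = unlist(x$cohort_size_range),
    census_times = unlist(x$census_times),
    soil_log_mean = x$soil_log_mean, soil_log_sd = x$soil_log_sd
  )
}

#' Regenerate a synthetic dataset from its truth file
#'
#' @param truth_path Path to a `truth.json` written by [make_demo_data()].
#' @return The regenerated `synthetic_traits` dataset (identical to the
#'   one originally written).
#' @export
regenerate_from_truth <- function(truth_path) {
  truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  config <- deserialize_config(truth$config)
  generate_trait_dataset(config, seed = truth$seed)
}
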