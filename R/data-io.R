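#' Read an individual-level trait table
#'
#' Reads a delimited text file holding one trait observation per row (long
#' format) and validates it. Long format is used because the four traits
#' have different coverage: leaf mass per area and leaf nitrogen are
#' measured once per season, leaf half-life once per individual, and wood
#' density may be missing for some individuals.
#'
#' Required columns: `individual_id`, `family`, `genus`, `species`,
#' `functional_type` (`deciduous`/`evergreen`), `growth_form`
#' (`tree`/`shrub`), `season` (`spring`/`fall`, empty for LHL), `trait`
#' (`LMA`, `Ngreen`, `LHL`, `WD`) and `value` (strictly positive; traits
#' are log-transformed downstream). An optional `soil_n` column carries
#' soil nitrogen (g/kg) under the individual's crown.
#'
#' @param path Path to a CSV (or TSV, by file extension) file with a header.
#' @return A validated tibble of trait records.
#' @seealso [validate_trait_table()], [write_trait_table()]
#' @export
read_trait_table <- function(path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  validate_trait_table(x)
}

#' Validate a trait table against its invariants
#'
#' Checks the schema and the record-level invariants: positive trait
#' values, known trait names, known functional types/growth forms, and
#' season present for seasonal traits only (leaf half-life is a single
#' value per individual and carries no season). Errors cite the offending
#' data row numbers.
#'
#' @param x A data frame of trait records (see [read_trait_table()]).
#' @return `x` as a tibble, invisibly usable in a pipe.
#' @export
validate_trait_table <- function(x) {
  check_columns(x, c("individual_id", "family", "genus", "species",
                     "functional_type", "growth_form", "season",
                     "trait", "value"), what = "trait table")
  x <- tibble::as_tibble(x)
  x$individual_id <- as.character(x$individual_id)
  x$season <- as.character(x$season)

  fail <- function(rows, msg) {
    abort(sprintf("%s (row%s %s)", msg, if (length(rows) > 1) "s" else "",
                  bad_rows_msg(rows)),
          class = "traitdecomp_validation_error")
  }
  bad <- which(!x$trait %in% trait_levels())
  if (length(bad) > 0) fail(bad, "unknown trait name")
  bad <- which(!is.na(x$value) & !(is.finite(x$value) & x$value > 0))
  if (length(bad) > 0) fail(bad, "trait values must be strictly positive")
  bad <- which(!x$functional_type %in% functional_types())
  if (length(bad) > 0) fail(bad, "functional_type must be deciduous or evergreen")
  bad <- which(!x$growth_form %in% growth_forms())
  if (length(bad) > 0) fail(bad, "growth_form must be tree or shrub")
  bad <- which(x$trait != "LHL" & !is.na(x$value) &
                 !x$season %in% season_levels())
  if (length(bad) > 0) fail(bad, "seasonal traits need season spring or fall")
  bad <- which(x$trait == "LHL" & !is.na(x$season))
  if (length(bad) > 0) fail(bad, "LHL records carry no season")
  x
}

#' Write a trait table to CSV
#'
#' @param x A trait table (long format).
#' @param path Output file path.
#' @return `x`, invisibly.
#' @export
write_trait_table <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}

#' Read a leaf-census table
#'
#' One row per census of a marked leaf cohort: columns `individual_id`,
#' `branch_id`, `cohort_id`, `date` (ISO-8601 or days since marking) and
#' `live_count` (non-negative integer). Within each cohort, census dates
#' must be strictly increasing and the first live count at least 1.
#'
#' @param path Path to a CSV file with a header.
#' @return A validated tibble of censuses.
#' @export
read_census_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_census_table(x)
}

#' Validate a leaf-census table
#'
#' @param x A data frame of leaf censuses (see [read_census_table()]).
#' @return `x` as a tibble.
#' @export
validate_census_table <- function(x) {
  check_columns(x, c("individual_id", "branch_id", "cohort_id",
                     "date", "live_count"), what = "census table")
  x <- tibble::as_tibble(x)
  if (any(is.na(x$live_count) | x$live_count < 0 |
            x$live_count != round(x$live_count))) {
    abort("live_count must be a non-negative integer",
          class = "traitdecomp_validation_error")
  }
  chk <- x |>
    dplyr::group_by(.data$individual_id, .data$branch_id, .data$cohort_id) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::summarise(
      increasing = all(diff(as.numeric(.data$date)) > 0) || dplyr::n() == 1,
      first_ok = .data$live_count[1] >= 1,
      .groups = "drop"
    )
  if (any(!chk$increasing)) {
    abort("census dates must be strictly increasing within each cohort",
          class = "traitdecomp_validation_error")
  }
  if (any(!chk$first_ok)) {
    abort("first live_count of each cohort must be >= 1",
          class = "traitdecomp_validation_error")
  }
  x
}

#' @rdname read_census_table
#' @param x A census table.
#' @export
write_census_table <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}

#' Read a phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()] with the validation the downstream comparative
#' methods need: unique tip labels and non-negative branch lengths. Trees
#' without branch lengths get unit lengths with a warning; ultrametricity
#' is not required.
#'
#' @param path Path to a Newick file (or a Newick string via `text`).
#' @param text Optional Newick string, used instead of `path`.
#' @return An [ape::phylo] object.
#' @export
read_newick_tree <- function(path = NULL, text = NULL) {
  nwk <- text %||% paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0
  for (i in seq_len(nchar(nwk))) {
    ch <- substr(nwk, i, i)
    if (ch == "(") depth <- depth + 1
    if (ch == ")") depth <- depth - 1
    if (depth < 0) {
      abort(sprintf("unbalanced parentheses in Newick at character %d", i),
            class = "traitdecomp_parse_error")
    }
  }
  if (depth != 0) {
    abort(sprintf("unbalanced parentheses in Newick: %d '(' left open", depth),
          class = "traitdecomp_parse_error")
  }
  tree <- tryCatch(ape::read.tree(text = nwk), error = function(e) NULL)
  if (is.null(tree)) {
    abort("failed to parse Newick tree", class = "traitdecomp_parse_error")
  }
  validate_phylogeny(tree)
}

#' Validate a phylogeny for comparative analysis
#'
#' @param tree An [ape::phylo] object.
#' @return The tree, with unit branch lengths filled in (and a warning)
#'   when none were supplied.
#' @export
validate_phylogeny <- function(tree) {
  if (anyDuplicated(tree$tip.label) > 0) {
    dups <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(sprintf("duplicate tip names: %s", paste(dups, collapse = ", ")),
          class = "traitdecomp_validation_error")
  }
  if (is.null(tree$edge.length)) {
    warn("tree has no branch lengths; defaulting every branch to 1")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0)) {
    abort("negative branch lengths are not allowed",
          class = "traitdecomp_validation_error")
  }
  tree
}

#' @rdname read_newick_tree
#' @param tree An [ape::phylo] object.
#' @export
write_newick_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(tree)
}

#' Species list of the Dujiangyan subtropical forest community
#'
#' The packaged study community: 45 woody angiosperm species in 20
#' families from a secondary subtropical forest at Dujiangyan (Sichuan,
#' SW China), with functional type (deciduous/evergreen), growth form
#' (tree/shrub) and the number of individuals sampled per species
#' (294 in total, 1 to 16 per species).
#'
#' @return A tibble with columns `family`, `genus`, `species`,
#'   `functional_type`, `growth_form`, `n_individuals`.
#' @export
#' @examples
#' sp <- dujiangyan_species()
#' sum(sp$n_individuals)
dujiangyan_species <- function() {
  path <- system.file("extdata", "dujiangyan_species.csv",
                      package = "traitdecomp", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Per-species trait means and standard deviations
#'
#' Summarises a long trait table on the original (untransformed) scale.
#' The SD is reported as missing for species represented by a single
#' observation.
#'
#' @param records A trait table (see [read_trait_table()]).
#' @return A tibble with one row per species and trait: `family`, `genus`,
#'   `species`, `trait`, `n`, `mean`, `sd`.
#' @export
species_summary <- function(records) {
  records |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$family, .data$genus, .data$species, .data$trait) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = sd(.data$value),
      .groups = "drop"
    )
}

#' Report the overlap between trait-table species and tree tips
#'
#' Species are matched to tips by exact string equality on the
#' `Genus_epithet` label. Supertrees assembled elsewhere rarely match a
#' field table perfectly, so the mismatch report is produced up front and
#' phylogenetic analyses proceed on the intersection.
#'
#' @param records A trait table.
#' @param tree An [ape::phylo] object.
#' @return A list with `matched`, `missing_from_tree` and
#'   `missing_from_table` character vectors of species labels.
#' @export
species_tree_overlap <- function(records, tree) {
  labels <- unique(species_label(records$genus, records$species))
  list(
    matched = intersect(labels, tree$tip.label),
    missing_from_tree = setdiff(labels, tree$tip.label),
    missing_from_table = setdiff(tree$tip.label, labels)
  )
}
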