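# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream; a NULL seed just evaluates `code`.
with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# Canonical trait names, in display order.
trait_levels <- function() c("LMA", "Ngreen", "LHL", "WD")

functional_types <- function() c("deciduous", "evergreen")
growth_forms <- function() c("tree", "shrub")
season_levels <- function() c("spring", "fall")

# "Genus epithet" -> tree tip label ("Genus_epithet"); collapses any
# non-alphanumeric runs so infraspecific ranks survive as single tokens.
species_label <- function(genus, species) {
  gsub("^_|_$", "", gsub("[^A-Za-z0-9]+", "_", paste(genus, species)))
}

# Stop unless `x` has every column in `cols`; names the first offender.
check_columns <- function(x, cols, what = "table") {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ), class = "traitdecomp_schema_error")
  }
  invisible(x)
}

bad_rows_msg <- function(rows, max_show = 5) {
  shown <- paste(head(rows, max_show), collapse = ", ")
  if (length(rows) > max_show) shown <- paste0(shown, ", ...")
  shown
}
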