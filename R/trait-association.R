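# Four-level trait correlations and bivariate log-log slopes.

# Wide observation-level table of log trait values. Seasonal traits keep
# one row per individual x season; LHL (one value per individual) is
# carried in a separate individual-level table together with
# individual-mean values of the seasonal traits.
wide_log_tables <- function(records) {
  base <- records |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::mutate(log_value = log(.data$value),
                  species_id = species_label(.data$genus, .data$species))
  obs <- base |>
    dplyr::filter(.data$trait != "LHL") |>
    dplyr::select("individual_id", "species_id", "season", "trait", "log_value") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "log_value")
  indiv <- base |>
    dplyr::group_by(.data$individual_id, .data$species_id, .data$trait) |>
    dplyr::summarise(log_value = mean(.data$log_value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "log_value")
  list(obs = obs, indiv = indiv)
}

cor_row <- function(x, y, df_penalty = 0) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3 || sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, p_value = NA_real_, n = n))
  }
  r <- cor(x, y)
  df <- n - 2 - df_penalty
  if (df < 1) return(tibble::tibble(r = r, p_value = NA_real_, n = n))
  tstat <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
  tibble::tibble(r = r, p_value = 2 * pt(-abs(tstat), df), n = n)
}

#' Trait correlations at four levels
#'
#' For every trait pair, Pearson correlations of the log-transformed
#' values at four levels: (1) overall, across individual observations;
#' (2) between species means; (3) between phylogenetically independent
#' contrasts of species means (when a tree is supplied); (4) within
#' species, i.e. the pooled correlation of species-mean-centred
#' deviations, with `df = n - n_species - 1`. Pairs involving leaf
#' half-life (one value per individual) use individual-level data, with
#' seasonal traits averaged per individual.
#'
#' @param records A trait table (long format).
#' @param tree Optional [ape::phylo] tree (tips `Genus_epithet`); without
#'   it the PIC level is reported missing.
#' @param pairs Optional list of 2-element character vectors; defaults to
#'   all pairs of traits present.
#' @return A tibble with `trait_x`, `trait_y`, `level` (`overall`,
#'   `species_mean`, `pic`, `within_species`), `r`, `p_value`, `n`.
#' @export
trait_correlations <- function(records, tree = NULL, pairs = NULL) {
  tabs <- wide_log_tables(records)
  traits <- intersect(trait_levels(), unique(records$trait))
  pairs <- pairs %||% utils::combn(traits, 2, simplify = FALSE)

  species_means <- tabs$indiv |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric),
                                   ~ mean(.x, na.rm = TRUE)), .groups = "drop")

  pics <- NULL
  if (!is.null(tree)) {
    pics <- lapply(setNames(traits, traits), function(tr) {
      v <- setNames(species_means[[tr]], species_means$species_id)
      v <- v[is.finite(v)]
      v <- v[names(v) %in% tree$tip.label]
      if (length(v) < 3) return(NULL)
      independent_contrasts(tree, v)
    })
  }

  purrr::map_dfr(pairs, function(p) {
    tab <- if ("LHL" %in% p) tabs$indiv else tabs$obs
    x <- tab[[p[1]]] %||% rep(NA_real_, nrow(tab))
    y <- tab[[p[2]]] %||% rep(NA_real_, nrow(tab))

    overall <- cor_row(x, y)

    sm <- cor_row(species_means[[p[1]]] %||% NA_real_,
                  species_means[[p[2]]] %||% NA_real_)

    pic <- if (!is.null(pics) && !is.null(pics[[p[1]]]) && !is.null(pics[[p[2]]])) {
      # contrasts must come from the shared species set
      v1 <- setNames(species_means[[p[1]]], species_means$species_id)
      v2 <- setNames(species_means[[p[2]]], species_means$species_id)
      shared <- names(v1)[is.finite(v1) & is.finite(v2)]
      shared <- intersect(shared, tree$tip.label)
      if (length(shared) >= 3) {
        c1 <- independent_contrasts(tree, v1[shared])
        c2 <- independent_contrasts(tree, v2[shared])
        pc <- pic_correlation(c1, c2)
        tibble::tibble(r = pc$r, p_value = pc$p_value, n = pc$n_contrasts)
      } else {
        tibble::tibble(r = NA_real_, p_value = NA_real_, n = length(shared))
      }
    } else {
      tibble::tibble(r = NA_real_, p_value = NA_real_, n = NA_integer_)
    }

    cc <- is.finite(x) & is.finite(y)
    sp <- tab$species_id[cc]
    xs <- x[cc] - stats::ave(x[cc], sp)
    ys <- y[cc] - stats::ave(y[cc], sp)
    within <- cor_row(xs, ys, df_penalty = length(unique(sp)) - 1)

    dplyr::bind_rows(
      dplyr::mutate(overall, level = "overall"),
      dplyr::mutate(sm, level = "species_mean"),
      dplyr::mutate(pic, level = "pic"),
      dplyr::mutate(within, level = "within_species")
    ) |>
      dplyr::mutate(trait_x = p[1], trait_y = p[2], .before = 1) |>
      dplyr::select("trait_x", "trait_y", "level", "r", "p_value", "n")
  })
}

#' Bivariate log-log slope (standardized major axis or OLS)
#'
#' The default standardized major axis (SMA) slope is
#' `sign(r) * SD(y) / SD(x)`, the geometric-mean relationship used for
#' allometric trait scaling, with its standard confidence interval;
#' ordinary least squares is available by flag and the method is
#' recorded in the output.
#'
#' @param x,y Paired (log-transformed) numeric vectors, `n >= 3`.
#' @param method `"sma"` (default) or `"ols"`.
#' @param conf_level Confidence level for the interval.
#' @return A one-row tibble: `method`, `slope`, `conf_low`, `conf_high`,
#'   `r`, `n`.
#' @export
#' @examples
#' bivariate_slope(log(1:20), 2 * log(1:20))
bivariate_slope <- function(x, y, method = c("sma", "ols"),
                            conf_level = 0.95) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 paired observations",
                   class = "traitdecomp_validation_error")
  if (sd(x) == 0) abort("zero variance in x", class = "traitdecomp_validation_error")
  r <- cor(x, y)
  if (method == "sma") {
    slope <- (if (r < 0) -1 else 1) * sd(y) / sd(x)
    B <- qf(conf_level, 1, n - 2) * (1 - r^2) / (n - 2)
    lims <- slope * c(sqrt(B + 1) + sqrt(B), sqrt(B + 1) - sqrt(B))
    tibble::tibble(method = "sma", slope = slope,
                   conf_low = min(lims), conf_high = max(lims), r = r, n = n)
  } else {
    fit <- lm(y ~ x)
    ci <- stats::confint(fit, "x", level = conf_level)
    tibble::tibble(method = "ols", slope = unname(stats::coef(fit)[2]),
                   conf_low = ci[1], conf_high = ci[2], r = r, n = n)
  }
}
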