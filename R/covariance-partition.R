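# Sequential (Type-I) ANOVA and decomposition of sums of cross-products.
#
# The covariance between two log traits is partitioned into per-term
# components with the polarization identity
#   SCP_term = (SS_term(x + y) - SS_term(x) - SS_term(y)) / 2
# applied to three sequential ANOVAs sharing one term order, so the
# components sum exactly to the total corrected cross-product. Sequential
# sums of squares are order-dependent in unbalanced data; the term order
# is a recorded, user-overridable setting that defaults to the ecological
# hierarchy functional type -> growth form -> family -> species ->
# individual -> season.

default_term_order <- function() {
  c("functional_type", "growth_form", "family", "species",
    "individual_id", "season")
}

# Error stratum for each term's F test: taxonomic terms are tested
# against the stratum nested below them, season against the
# within-individual residual. ".residual" means the residual mean square.
default_strata <- function() {
  c(functional_type = "family", growth_form = "family",
    family = "species", species = "individual_id",
    individual_id = ".residual", season = ".residual")
}

# Sequential SS per term via stats::anova on a single lm fit; terms
# contributing no estimable columns (or a single level) get df = 0.
seq_ss <- function(data, v, terms) {
  keep <- terms[vapply(terms, function(t) {
    x <- data[[t]]
    length(unique(x[!is.na(x)])) >= 2
  }, logical(1))]
  df <- ss <- setNames(rep(0, length(terms) + 1), c(terms, ".residual"))
  if (length(keep) == 0) {
    ss[".residual"] <- sum((v - mean(v))^2)
    df[".residual"] <- length(v) - 1
    return(list(df = df, ss = ss))
  }
  d <- data[keep]
  for (t in keep) if (!is.numeric(d[[t]])) d[[t]] <- factor(d[[t]])
  d$.y <- v
  f <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", keep), collapse = " + ")))
  a <- anova(lm(f, data = d))
  rn <- rownames(a)
  rn[rn == "Residuals"] <- ".residual"
  rn <- gsub("`", "", rn)
  df[rn] <- a$Df
  ss[rn] <- a$`Sum Sq`
  list(df = df, ss = ss)
}

#' Sequential (Type-I) ANOVA with stratum-aware F tests
#'
#' Decomposes the total corrected sum of squares of a response into
#' sequential contributions of the given terms (incremental least-squares
#' fits, so the decomposition is exact but order-dependent in unbalanced
#' data). Factor terms are tested against the mean square of the error
#' stratum appropriate to the level at which they vary rather than
#' blindly against the residual; numeric columns are treated as 1-df
#' covariates tested against the residual.
#'
#' @param data A data frame with one row per observation, holding the
#'   term columns.
#' @param response Name of the (already log-transformed) response column,
#'   or a numeric vector of length `nrow(data)`.
#' @param terms Term order, a character vector of column names.
#' @param strata Named character vector mapping each term to its error
#'   stratum (a term name or `".residual"`); defaults to
#'   `default_strata()` with unlisted terms tested against the residual.
#' @return A tibble with columns `term`, `df`, `ss`, `pct_ss`, `ms`,
#'   `error_term`, `statistic`, `p_value`; the residual row closes the
#'   decomposition. Total SS is in `attr(, "total_ss")`.
#' @export
sequential_anova <- function(data, response, terms = default_term_order(),
                             strata = NULL) {
  v <- if (is.character(response) && length(response) == 1) {
    data[[response]]
  } else {
    as.numeric(response)
  }
  if (length(v) != nrow(data)) {
    abort("response length must match data", class = "traitdecomp_validation_error")
  }
  res <- seq_ss(data, v, terms)
  df <- res$df
  ss <- res$ss
  dropped <- terms[df[terms] == 0]
  if (length(dropped) > 0) {
    inform(sprintf("term(s) with no estimable contrast (0 df): %s",
                   paste(dropped, collapse = ", ")))
  }
  strata_map <- default_strata()
  strata_map[names(strata %||% character())] <- strata %||% character()
  ms <- ifelse(df > 0, ss / df, NA_real_)
  resolve_stratum <- function(term) {
    nxt <- if (term %in% names(strata_map)) strata_map[[term]] else ".residual"
    while (nxt != ".residual" && (!nxt %in% names(df) || df[[nxt]] == 0)) {
      nxt <- if (nxt %in% names(strata_map)) strata_map[[nxt]] else ".residual"
    }
    nxt
  }
  out <- tibble::tibble(term = c(terms, ".residual"),
                        df = as.integer(df), ss = unname(ss),
                        pct_ss = 100 * unname(ss) / sum(ss))
  out$ms <- unname(ms)
  out$error_term <- c(vapply(terms, resolve_stratum, character(1)), NA)
  out$statistic <- NA_real_
  out$p_value <- NA_real_
  for (i in seq_along(terms)) {
    et <- out$error_term[i]
    if (is.na(et) || out$df[i] == 0) next
    ms_err <- ms[[et]]
    df_err <- df[[et]]
    if (is.na(ms_err) || df_err == 0) next
    out$statistic[i] <- out$ms[i] / ms_err
    out$p_value[i] <- pf(out$statistic[i], out$df[i], df_err, lower.tail = FALSE)
  }
  attr(out, "total_ss") <- sum(ss)
  out
}

#' Partition the sum of cross-products of a trait pair
#'
#' Decomposes the total corrected cross-product of two (log) traits into
#' sequential per-term components via the polarization identity applied
#' to the sequential ANOVAs of `x`, `y` and `x + y` under one shared term
#' order. Component signs are kept: a negative component marks a term
#' whose covariance contribution opposes the overall one. Percentages sum
#' to 100 and components sum to the total corrected cross-product by
#' construction.
#'
#' Rows with a missing value in either trait are dropped (pairwise
#' deletion), so each pair is analysed on its maximal sample.
#'
#' @param data A data frame with one row per observation.
#' @param x,y Names of the two (log-transformed) trait columns.
#' @param terms Term order, as in [sequential_anova()].
#' @param strata Error-stratum map, as in [sequential_anova()].
#' @param n_permutations If > 0, per-term permutation p-values are added
#'   via [component_significance()].
#' @param seed RNG seed for the permutation test.
#' @return A `trait_covpart` tibble: `term`, `df`, `scp`, `pct_scp`,
#'   `sign` (and `p_value` when permutations were run), with the total
#'   corrected cross-product in `attr(, "total_scp")`.
#' @export
partition_cross_products <- function(data, x, y,
                                     terms = default_term_order(),
                                     strata = NULL,
                                     n_permutations = 0, seed = NULL) {
  xv <- data[[x]]
  yv <- data[[y]]
  if (is.null(xv) || is.null(yv)) {
    abort("x and y must name columns of data", class = "traitdecomp_schema_error")
  }
  keep <- !is.na(xv) & !is.na(yv)
  data <- data[keep, , drop = FALSE]
  xv <- xv[keep]
  yv <- yv[keep]
  ss_x <- seq_ss(data, xv, terms)
  ss_y <- seq_ss(data, yv, terms)
  ss_xy <- seq_ss(data, xv + yv, terms)
  scp <- (ss_xy$ss - ss_x$ss - ss_y$ss) / 2
  total <- sum(scp)
  out <- tibble::tibble(
    term = names(scp), df = as.integer(ss_x$df), scp = unname(scp)
  )
  if (abs(total) < 1e-12 * max(1, sum(abs(scp)))) {
    warn("total cross-product is ~0; percentages reported as missing")
    out$pct_scp <- NA_real_
  } else {
    out$pct_scp <- 100 * out$scp / total
  }
  out$sign <- ifelse(out$scp >= 0, "+", "-")
  attr(out, "total_scp") <- total
  attr(out, "pair") <- c(x = x, y = y)
  attr(out, "terms") <- terms
  attr(out, "model_data") <- dplyr::mutate(data[intersect(terms, names(data))],
                                           .x = xv, .y = yv)
  class(out) <- c("trait_covpart", class(out))
  if (n_permutations > 0) {
    out <- component_significance(out, n_permutations = n_permutations,
                                  seed = seed)
  }
  out
}

# Incremental fitted components of v for each term (and the residual),
# via successive QR least-squares fits. Each term's component is the
# change in fitted values when the term enters the model.
incremental_components <- function(data, v, terms) {
  n <- length(v)
  comp <- matrix(0, n, length(terms) + 1,
                 dimnames = list(NULL, c(terms, ".residual")))
  fit_prev <- rep(mean(v), n)
  M <- matrix(1, n, 1)
  for (t in terms) {
    x <- data[[t]]
    if (length(unique(x[!is.na(x)])) < 2) next
    Mt <- if (is.numeric(x)) matrix(x, n, 1) else model.matrix(~ f - 1, data.frame(f = factor(x)))
    M <- cbind(M, Mt)
    fit <- qr.fitted(qr(M), v)
    comp[, t] <- fit - fit_prev
    fit_prev <- fit
  }
  comp[, ".residual"] <- v - fit_prev
  comp
}

#' Permutation significance of covariance components
#'
#' Stratum-restricted permutation test for each term of a cross-product
#' partition. For random terms the first trait's incremental fitted
#' component is permuted among the term's units within the enclosing
#' stratum (species within family, individuals within species, seasons
#' within individual, families globally); the species-level fixed factors
#' (functional type, growth form) are permuted as label reassignments
#' among species. Two-sided p-values come from the permutation
#' distribution of the absolute component.
#'
#' @param partition A `trait_covpart` from [partition_cross_products()].
#' @param n_permutations Number of permutations (0 skips the test).
#' @param seed Optional RNG seed.
#' @return The partition with a `p_value` column added.
#' @export
component_significance <- function(partition, n_permutations = 999,
                                   seed = NULL) {
  if (n_permutations <= 0) return(partition)
  data <- attr(partition, "model_data")
  terms <- attr(partition, "terms")
  xv <- data$.x
  yv <- data$.y
  comp_x <- incremental_components(data, xv, terms)
  comp_y <- incremental_components(data, yv, terms)
  scp_obs <- colSums(comp_x * comp_y)

  # unit/stratum ids per term; NULL stratum = single global stratum
  nesting <- list(
    family = c("family", NA), species = c("species", "family"),
    individual_id = c("individual_id", "species"),
    season = c("season_cell", "individual_id")
  )
  if (!is.null(data$season) && !is.null(data$individual_id)) {
    data$season_cell <- paste(data$individual_id, data$season)
  }
  species_col <- if ("species" %in% names(data)) "species" else NULL

  p <- setNames(rep(NA_real_, nrow(partition)), partition$term)
  with_seed(seed, {
    for (term in terms) {
      if (!term %in% colnames(comp_x) || partition$df[partition$term == term] == 0) next
      if (term %in% c("functional_type", "growth_form") && !is.null(species_col)) {
        # reassign the species-level label among species, refit this
        # term's increment for x given the preceding terms
        idx <- match(term, terms)
        prev <- terms[seq_len(idx - 1)][terms[seq_len(idx - 1)] %in% colnames(comp_x)]
        sp_tab <- dplyr::distinct(data[c(species_col, term)])
        base_fit <- rep(mean(xv), length(xv)) +
          if (idx > 1) rowSums(comp_x[, prev, drop = FALSE]) else 0
        stat <- numeric(n_permutations)
        for (b in seq_len(n_permutations)) {
          perm_lab <- sp_tab[[term]][sample.int(nrow(sp_tab))]
          lab <- perm_lab[match(data[[species_col]], sp_tab[[species_col]])]
          Mp <- cbind(1, if (idx > 1) comp_x[, prev, drop = FALSE],
                      model.matrix(~ f - 1, data.frame(f = factor(lab))))
          fitp <- qr.fitted(qr(Mp), xv)
          stat[b] <- sum((fitp - base_fit) * comp_y[, term])
        }
        p[term] <- (1 + sum(abs(stat) >= abs(scp_obs[[term]]) - 1e-12)) /
          (n_permutations + 1)
      } else if (term %in% names(nesting)) {
        unit_col <- nesting[[term]][1]
        strat_col <- nesting[[term]][2]
        if (!unit_col %in% names(data)) next
        units <- data[[unit_col]]
        uu <- unique(units)
        strat <- if (!is.na(strat_col) && strat_col %in% names(data)) {
          data[[strat_col]][match(uu, units)]
        } else {
          rep("all", length(uu))
        }
        unit_val <- comp_x[match(uu, units), term]
        obs_unit <- match(units, uu)
        stat <- numeric(n_permutations)
        for (b in seq_len(n_permutations)) {
          perm <- seq_along(uu)
          for (s in unique(strat)) {
            i <- which(strat == s)
            perm[i] <- i[sample.int(length(i))]
          }
          stat[b] <- sum(unit_val[perm][obs_unit] * comp_y[, term])
        }
        p[term] <- (1 + sum(abs(stat) >= abs(scp_obs[[term]]) - 1e-12)) /
          (n_permutations + 1)
      }
    }
  })
  floor_p <- 1 / (n_permutations + 1)
  if (any(!is.na(p) & p <= floor_p & floor_p > 0.05)) {
    warn("too few permutations to resolve p < 0.05; p floored at attainable resolution")
  }
  partition$p_value <- unname(p[partition$term])
  partition
}

#' @export
print.trait_covpart <- function(x, ...) {
  pair <- attr(x, "pair")
  cat(sprintf("<trait_covpart> %s x %s | total corrected SCP %.4f\n",
              pair[["x"]], pair[["y"]], attr(x, "total_scp")))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @rdname partition_cross_products
#' @param x A `trait_covpart` object.
#' @param ... Unused.
#' @export
tidy.trait_covpart <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$trait_x <- attr(x, "pair")[["x"]]
  out$trait_y <- attr(x, "pair")[["y"]]
  out
}
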