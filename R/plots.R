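# ggplot2 views of the three main result types.

#' Plot effect sizes of a fitted variance decomposition
#'
#' Dot-and-interval display of the posterior effect-size SD of every
#' model term: posterior mean, thick 50% and thin 95% credible
#' intervals, random terms (family, species, individual, residual) above
#' the fixed ones (functional type, growth form, season).
#'
#' @param object A `trait_varcomp` from [fit_trait_variance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trait_varcomp <- function(object, ...) {
  s <- object$summary[object$summary$term != "grand_mean", ]
  order <- c("season", "growth_form", "functional_type",
             "residual", "individual", "species", "family")
  s$term <- factor(s$term, levels = intersect(order, s$term))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$q2.5, xmax = .data$q97.5),
                            linewidth = 0.3) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$q25, xmax = .data$q75),
                            linewidth = 1.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "effect size (SD, log scale)", y = NULL,
                  title = object$trait) +
    ggplot2::theme_minimal()
}

#' Plot a covariance partition as a signed stacked bar
#'
#' Per-term percent of the total corrected cross-product, with negative
#' components (terms opposing the overall covariance) below zero and
#' significance stars when a permutation test was run.
#'
#' @param object A `trait_covpart` from [partition_cross_products()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trait_covpart <- function(object, ...) {
  d <- tibble::as_tibble(object)
  pair <- attr(object, "pair")
  d$label <- if ("p_value" %in% names(d)) {
    dplyr::case_when(is.na(d$p_value) ~ "", d$p_value < 0.001 ~ "***",
                     d$p_value < 0.01 ~ "**", d$p_value < 0.05 ~ "*",
                     .default = "")
  } else {
    ""
  }
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pct_scp, y = .data$term)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$scp >= 0), show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), hjust = -0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "% of total covariance", y = NULL,
                  title = sprintf("%s × %s", pair[["x"]], pair[["y"]])) +
    ggplot2::theme_minimal()
}

#' Plot a Blomberg's K randomization test
#'
#' Histogram of the randomized K distribution with the 95% bounds and
#' the observed K marked.
#'
#' @param object A `phylo_signal` from [k_randomization_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phylo_signal <- function(object, ...) {
  d <- tibble::tibble(k_rand = object$k_rand)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k_rand)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = c(object$ci_lower, object$ci_upper),
                        linetype = 2) +
    ggplot2::geom_vline(xintercept = object$k, colour = "red") +
    ggplot2::labs(x = "K under randomization", y = "count",
                  subtitle = sprintf("K = %.3f, randomization mean %.3f",
                                     object$k, object$k_rand_mean)) +
    ggplot2::theme_minimal()
}
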