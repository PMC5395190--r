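# Blomberg's K and phylogenetically independent contrasts.

match_tip_values <- function(tree, tip_values) {
  if (is.null(names(tip_values))) {
    abort("tip_values must be named by species", class = "traitdecomp_validation_error")
  }
  tip_values <- tip_values[!is.na(tip_values)]
  extra <- setdiff(names(tip_values), tree$tip.label)
  if (length(extra) > 0) {
    abort(sprintf("trait species absent from tree: %s",
                  paste(extra, collapse = ", ")),
          class = "traitdecomp_validation_error")
  }
  drop <- setdiff(tree$tip.label, names(tip_values))
  if (length(drop) > 0) tree <- ape::drop.tip(tree, drop)
  list(tree = tree, x = tip_values[tree$tip.label])
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' The ratio of the mean squared error of the tip data (around the
#' phylogenetically GLS-estimated mean) to the GLS mean squared error
#' under the tree's variance-covariance matrix, standardised by the same
#' ratio expected under Brownian motion. K is about 1 when trait
#' variation tracks the phylogeny as Brownian motion predicts and falls
#' towards 0 when trait values are independent of phylogeny.
#'
#' Species with missing values are pruned, so each trait is analysed on
#' its maximal species set.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param tip_values Named numeric vector of species (tip) trait values.
#' @return The K statistic (a single non-negative number).
#' @export
blomberg_k <- function(tree, tip_values) {
  m <- match_tip_values(tree, tip_values)
  x <- m$x
  n <- length(x)
  if (n < 3) abort("need at least 3 species", class = "traitdecomp_validation_error")
  if (var(x) == 0) abort("zero trait variance", class = "traitdecomp_validation_error")
  C <- ape::vcv(m$tree)
  Ci <- solve(C)
  k_from_parts(x, Ci, sum(diag(C)))
}

# K given the inverse VCV and trace; shared with the randomization loop
# (the tree, hence Ci and the Brownian expectation, is permutation-fixed).
k_from_parts <- function(x, Ci, trC) {
  n <- length(x)
  denom_gls <- sum(Ci)
  ahat <- sum(Ci %*% x) / denom_gls
  d <- x - ahat
  mse0 <- sum(d^2) / (n - 1)
  mse <- drop(t(d) %*% Ci %*% d) / (n - 1)
  expected <- (trC - n / denom_gls) / (n - 1)
  (mse0 / mse) / expected
}

#' Randomization test for Blomberg's K
#'
#' Permutes trait values among species `n_reps` times, recomputes K for
#' every randomization, and reports the 95% interval (2.5th to 97.5th
#' percentiles) of the randomized K values. The observed signal is
#' called significant when K exceeds the upper bound; a percentile
#' p-value is reported alongside.
#'
#' @inheritParams blomberg_k
#' @param n_reps Number of randomizations (values below 100 give
#'   unstable intervals and trigger a warning).
#' @param seed Optional RNG seed.
#' @return A `phylo_signal` object with `k`, the `k_rand` distribution
#'   and its mean and 95% bounds, `significant`, a percentile `p_value`,
#'   and `n_species`.
#' @export
k_randomization_test <- function(tree, tip_values, n_reps = 1000, seed = NULL) {
  if (n_reps < 100) warn("fewer than 100 randomizations: unstable CI")
  m <- match_tip_values(tree, tip_values)
  x <- m$x
  n <- length(x)
  if (n < 3) abort("need at least 3 species", class = "traitdecomp_validation_error")
  if (var(x) == 0) abort("zero trait variance", class = "traitdecomp_validation_error")
  C <- ape::vcv(m$tree)
  Ci <- solve(C)
  trC <- sum(diag(C))
  k_obs <- k_from_parts(x, Ci, trC)
  k_rand <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) k_from_parts(sample(x), Ci, trC),
           numeric(1))
  })
  ci <- unname(quantile(k_rand, c(0.025, 0.975)))
  structure(list(
    k = k_obs, k_rand = k_rand, k_rand_mean = mean(k_rand),
    ci_lower = ci[1], ci_upper = ci[2],
    significant = k_obs > ci[2],
    p_value = (1 + sum(k_rand >= k_obs)) / (n_reps + 1),
    n_species = n, n_reps = n_reps
  ), class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat(sprintf(
    "<phylo_signal> K = %.3f | K_rand = %.3f (95%% CI %.3f-%.3f, %d reps) | %s (p = %.3g, n = %d)\n",
    x$k, x$k_rand_mean, x$ci_lower, x$ci_upper, x$n_reps,
    if (x$significant) "significant" else "not significant",
    x$p_value, x$n_species))
  invisible(x)
}

#' @rdname k_randomization_test
#' @param x A `phylo_signal` object.
#' @param ... Unused.
#' @export
tidy.phylo_signal <- function(x, ...) {
  tibble::tibble(k = x$k, k_rand_mean = x$k_rand_mean,
                 ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                 significant = x$significant, p_value = x$p_value,
                 n_species = x$n_species, n_reps = x$n_reps)
}

#' @rdname k_randomization_test
#' @export
glance.phylo_signal <- function(x, ...) tidy(x)

#' Resolve polytomies for contrast analysis
#'
#' Multifurcations are resolved to arbitrary bifurcations and the newly
#' created zero-length internal branches set to a small epsilon (default
#' 1e-8 times the tree depth), since supertrees are typically
#' polytomy-rich and the contrast recursion needs strictly bifurcating
#' trees.
#'
#' @param tree An [ape::phylo] tree.
#' @param epsilon Length assigned to created zero-length internal
#'   branches; default `1e-8 * max tip depth`.
#' @return A bifurcating [ape::phylo] tree.
#' @export
resolve_polytomies <- function(tree, epsilon = NULL) {
  if (ape::is.binary(tree)) return(tree)
  epsilon <- epsilon %||% (1e-8 * max(ape::node.depth.edgelength(tree)))
  tree2 <- ape::multi2di(tree, random = FALSE)
  internal <- tree2$edge[, 2] > length(tree2$tip.label)
  zero <- internal & tree2$edge.length == 0
  tree2$edge.length[zero] <- epsilon
  tree2
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's pruning recursion: at each internal node the contrast is
#' the difference of the two daughter values divided by the square root
#' of the sum of their (adjusted) branch lengths; the ancestral value is
#' the branch-length-weighted average and the parent branch is lengthened
#' by `v1 * v2 / (v1 + v2)`. A tree with n species yields n - 1
#' standardized contrasts, mutually independent under Brownian motion.
#'
#' Polytomies are resolved first via [resolve_polytomies()] (with a
#' message); species with missing values are pruned.
#'
#' @inheritParams blomberg_k
#' @return A tibble with one row per internal node: `node`, `contrast`
#'   (standardized), `expected_variance` (sum of adjusted branch
#'   lengths).
#' @export
independent_contrasts <- function(tree, tip_values) {
  m <- match_tip_values(tree, tip_values)
  tree <- m$tree
  x <- m$x
  if (!ape::is.binary(tree)) {
    inform("resolving polytomies to bifurcations with epsilon-length branches")
    tree <- resolve_polytomies(tree)
  }
  ntip <- length(tree$tip.label)
  vals <- c(unname(x), rep(NA_real_, tree$Nnode))
  ord <- ape::reorder.phylo(tree, "postorder")
  vlen <- numeric(ntip + tree$Nnode)
  vlen[ord$edge[, 2]] <- ord$edge.length
  contrast <- exp_var <- setNames(rep(NA_real_, tree$Nnode),
                                  ntip + seq_len(tree$Nnode))
  # a node is reduced once its second daughter edge appears; postorder
  # guarantees both daughter subtrees are complete by then
  first_child <- integer(ntip + tree$Nnode)
  for (k in seq_len(nrow(ord$edge))) {
    node <- ord$edge[k, 1]
    ch <- ord$edge[k, 2]
    if (first_child[node] == 0L) {
      first_child[node] <- ch
      next
    }
    c1 <- first_child[node]
    c2 <- ch
    v1 <- vlen[c1]
    v2 <- vlen[c2]
    if (v1 + v2 <= 0) {
      abort("zero-length daughter branch pair; resolve with a minimum branch length",
            class = "traitdecomp_validation_error")
    }
    contrast[as.character(node)] <- (vals[c1] - vals[c2]) / sqrt(v1 + v2)
    exp_var[as.character(node)] <- v1 + v2
    vals[node] <- (vals[c1] / v1 + vals[c2] / v2) / (1 / v1 + 1 / v2)
    vlen[node] <- vlen[node] + v1 * v2 / (v1 + v2)
  }
  tibble::tibble(node = as.integer(names(contrast)),
                 contrast = unname(contrast),
                 expected_variance = unname(exp_var))
}

#' Correlation of independent contrasts
#'
#' Pearson correlation forced through the origin (contrast signs are
#' arbitrary), with `df = n_contrasts - 1`. Reported missing for fewer
#' than 3 contrasts.
#'
#' @param contrasts_x,contrasts_y Contrast tables from
#'   [independent_contrasts()] (aligned by node) or numeric vectors.
#' @return A tibble with `r`, `p_value`, `n_contrasts`.
#' @export
pic_correlation <- function(contrasts_x, contrasts_y) {
  cx <- if (is.data.frame(contrasts_x)) contrasts_x$contrast else contrasts_x
  cy <- if (is.data.frame(contrasts_y)) contrasts_y$contrast else contrasts_y
  if (is.data.frame(contrasts_x) && is.data.frame(contrasts_y)) {
    cy <- cy[match(contrasts_x$node, contrasts_y$node)]
  }
  ok <- !is.na(cx) & !is.na(cy)
  cx <- cx[ok]
  cy <- cy[ok]
  n <- length(cx)
  if (n < 3) {
    return(tibble::tibble(r = NA_real_, p_value = NA_real_, n_contrasts = n))
  }
  r <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  df <- n - 1
  tstat <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
  tibble::tibble(r = r, p_value = 2 * pt(-abs(tstat), df), n_contrasts = n)
}
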