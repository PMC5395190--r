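test_that("Blomberg's K matches the dense-matrix oracle on a toy tree", {
  tree <- read_newick_tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  x <- c(A = 1, B = 2, C = 4, D = 8)
  # independent oracle: explicit GLS with the full VCV inverse
  C <- ape::vcv(tree)[names(x), names(x)]
  Ci <- solve(C)
  ahat <- sum(Ci %*% x) / sum(Ci)
  d <- x - ahat
  obs <- (sum(d^2) / 3) / (drop(t(d) %*% Ci %*% d) / 3)
  expected <- (sum(diag(C)) - 4 / sum(Ci)) / 3
  expect_equal(blomberg_k(tree, x), obs / expected, tolerance = 1e-10)
  skip_if_not_installed("picante")
  expect_equal(blomberg_k(tree, x),
               as.numeric(picante::Kcalc(x[tree$tip.label], tree)),
               tolerance = 1e-10)
})

test_that("K is near 1 under Brownian motion and depressed after shuffling", {
  res <- withr::with_seed(10, {
    t(vapply(1:50, function(i) {
      tree <- simulate_yule_tree(45)
      x <- simulate_bm_traits(tree)
      v <- setNames(x$trait_1, x$species)
      c(bm = blomberg_k(tree, v),
        shuf = blomberg_k(tree, setNames(sample(v), names(v))))
    }, numeric(2)))
  })
  expect_equal(mean(res[, "bm"]), 1, tolerance = 0.2)
  expect_lt(mean(res[, "shuf"]), 0.5)
})

test_that("K is invariant to affine transformation of tip values", {
  tree <- simulate_yule_tree(20, seed = 2)
  v <- setNames(simulate_bm_traits(tree, seed = 3)$trait_1, tree$tip.label)
  k0 <- blomberg_k(tree, v)
  expect_equal(blomberg_k(tree, 5 + 2.5 * v), k0, tolerance = 1e-12)
  expect_equal(blomberg_k(tree, -v), k0, tolerance = 1e-12)
})

test_that("K validates its inputs", {
  tree <- simulate_yule_tree(10, seed = 4)
  v <- setNames(rep(1, 10), tree$tip.label)
  expect_error(blomberg_k(tree, v), "zero trait variance",
               class = "traitdecomp_validation_error")
  v2 <- c(setNames(rnorm(3), tree$tip.label[1:3]), bogus_species = 1)
  expect_error(blomberg_k(tree, v2), "bogus_species",
               class = "traitdecomp_validation_error")
  # species missing a value are pruned
  v3 <- setNames(rnorm(10), tree$tip.label)
  v3[1] <- NA
  expect_silent(blomberg_k(tree, v3))
})

test_that("the K randomization test is reproducible and detects strong signal", {
  tree <- simulate_yule_tree(45, seed = 6)
  v <- setNames(simulate_bm_traits(tree, seed = 7)$trait_1, tree$tip.label)
  r1 <- k_randomization_test(tree, v, n_reps = 300, seed = 5)
  r2 <- k_randomization_test(tree, v, n_reps = 300, seed = 5)
  expect_identical(r1$k_rand, r2$k_rand)
  expect_identical(c(r1$ci_lower, r1$ci_upper), c(r2$ci_lower, r2$ci_upper))
  expect_true(r1$significant)
  expect_lt(r1$p_value, 0.05)
  expect_lte(r1$ci_lower, r1$k_rand_mean)
  expect_lte(r1$k_rand_mean, r1$ci_upper)
  expect_warning(k_randomization_test(tree, v, n_reps = 50, seed = 1),
                 "unstable CI")
  expect_s3_class(autoplot(r1), "ggplot")
  expect_equal(nrow(tidy(r1)), 1)
})

test_that("label-shuffled traits are rarely called significant", {
  hits <- withr::with_seed(30, {
    tree <- simulate_yule_tree(45)
    x <- setNames(simulate_bm_traits(tree)$trait_1, tree$tip.label)
    vapply(1:25, function(i) {
      v <- setNames(sample(x), names(x))
      k_randomization_test(tree, v, n_reps = 199, seed = i)$significant
    }, logical(1))
  })
  # nominal 2.5% upper-tail rule: expect almost all FALSE
  expect_lte(sum(hits), 3)
})

test_that("contrasts match the closed form on a two-tip tree", {
  tree <- read_newick_tree(text = "(A:2,B:2);")
  ct <- independent_contrasts(tree, c(A = 3, B = 1))
  expect_equal(nrow(ct), 1)
  expect_equal(abs(ct$contrast), 1) # (3-1)/sqrt(2+2)
  expect_equal(ct$expected_variance, 4)
})

test_that("a constant trait yields all-zero contrasts", {
  tree <- simulate_yule_tree(12, seed = 8)
  ct <- independent_contrasts(tree, setNames(rep(2, 12), tree$tip.label))
  expect_equal(ct$contrast, rep(0, 11))
})

test_that("contrasts equal the reference implementation on random trees", {
  for (seed in 1:20) {
    tree <- withr::with_seed(seed, ape::rtree(8))
    v <- withr::with_seed(seed + 100, setNames(rnorm(8), tree$tip.label))
    mine <- independent_contrasts(tree, v)
    ref <- ape::pic(v, tree, var.contrasts = TRUE)
    idx <- match(as.integer(rownames(ref)), mine$node)
    expect_equal(abs(mine$contrast[idx]), unname(abs(ref[, 1])),
                 tolerance = 1e-10)
    expect_equal(mine$expected_variance[idx], unname(ref[, 2]),
                 tolerance = 1e-10)
  }
})

test_that("polytomies are resolved with epsilon branches before contrasts", {
  star <- read_newick_tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  expect_message(ct <- independent_contrasts(star, c(A = 1, B = 2, C = 3,
                                                     D = 4, E = 5)),
                 "polytomies")
  expect_equal(nrow(ct), 4)
  expect_true(all(is.finite(ct$contrast)))
})

test_that("PIC correlations are through the origin with reduced df", {
  cx <- c(1, -2, 3, 0.5, -1)
  expect_equal(pic_correlation(cx, 2 * cx)$r, 1)
  expect_equal(pic_correlation(cx, -cx)$r, -1)
  expect_true(is.na(pic_correlation(cx[1:2], cx[1:2])$r))
  # through-origin: an offset changes r, unlike ordinary Pearson
  r_off <- pic_correlation(cx, cx + 10)$r
  expect_lt(r_off, 1)
})

test_that("correlated Brownian traits recover the generating correlation", {
  rs <- withr::with_seed(12, {
    vapply(1:25, function(i) {
      tree <- simulate_yule_tree(100)
      z <- simulate_bm_traits(tree, n_traits = 2)
      x <- z$trait_1
      y <- 0.7 * z$trait_1 + sqrt(1 - 0.7^2) * z$trait_2
      cx <- independent_contrasts(tree, setNames(x, z$species))
      cy <- independent_contrasts(tree, setNames(y, z$species))
      pic_correlation(cx, cy)$r
    }, numeric(1))
  })
  expect_equal(mean(rs), 0.7, tolerance = 0.1)
})
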