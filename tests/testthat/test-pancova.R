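test_that("the ANCOVA F-test matches its classical oracle and edge cases", {
  # noiseless data with no group effect: F = 0, p = 1
  x <- seq(0, 2, length.out = 12)
  y <- 0.2 + 0.9 * x
  g <- rep(c(0, 1), 6)
  res <- pancova_f_test(y, x, NULL, g)
  expect_equal(res$F, 0, tolerance = 1e-20)
  expect_equal(res$p, 1)

  # identity covariance: equals classical ANCOVA computed via lm/anova
  set.seed(61)
  for (i in 1:10) {
    n <- 40
    x <- rnorm(n)
    g <- as.numeric(seq_len(n) <= 15)
    y <- 0.1 + 0.8 * x + 0.15 * g + 0.1 * g * x + rnorm(n, sd = 0.3)
    mine <- pancova_f_test(y, x, NULL, g)
    ref <- anova(lm(y ~ x), lm(y ~ x + g + g:x))
    expect_equal(mine$F, ref$F[2], tolerance = 1e-8)
    expect_equal(mine$p, ref$`Pr(>F)`[2], tolerance = 1e-8)
    expect_equal(mine$df_num, 2)
  }

  # intercept-only and slope-only variants have q = 1
  one <- pancova_f_test(y, x, NULL, g, terms = "intercept")
  expect_equal(one$df_num, 1)
  ref1 <- anova(lm(y ~ x), lm(y ~ x + g))
  expect_equal(one$F, ref1$F[2], tolerance = 1e-8)

  expect_error(pancova_f_test(y, x, NULL, rep(1, n)), "members")
  expect_error(pancova_f_test(y, x, NULL, rep(0, n)), "members")
})

test_that("the F-test respects a phylogenetic covariance", {
  set.seed(62)
  tr <- make_test_tree(40, depth = 100)
  V <- unclass(bm_covariance(tr))
  x <- rnorm(40)
  g <- as.numeric(seq_len(40) <= 12)
  y <- 0.1 + 0.9 * x + 0.2 * as.numeric(t(chol(V / mean(diag(V)))) %*% rnorm(40))
  mine <- pancova_f_test(y, x, V, g)
  # whitening oracle: transform and run the classical test
  Li <- solve(t(chol(V)))
  yw <- as.numeric(Li %*% y)
  X0 <- Li %*% cbind(1, x)
  X1 <- Li %*% cbind(1, x, g, g * x)
  rss0 <- sum(stats::lm.fit(X0, yw)$residuals^2)
  rss1 <- sum(stats::lm.fit(X1, yw)$residuals^2)
  Fo <- ((rss0 - rss1) / 2) / (rss1 / (40 - 4))
  expect_equal(mine$F, Fo, tolerance = 1e-8)
})

test_that("dependent p-value pooling obeys its limits and monotonicity", {
  # perfectly dependent identical tests add no evidence
  expect_equal(pool_dependent_pvalues(rep(0.05, 6), rho = 1), 0.05,
               tolerance = 1e-10)
  # independent replication strengthens evidence
  expect_lt(pool_dependent_pvalues(rep(0.05, 4), rho = 0), 0.05)
  # worked example: m = 2, both p = 0.05, independent
  z <- qnorm(0.95)
  expect_equal(pool_dependent_pvalues(c(0.05, 0.05), rho = 0),
               pnorm(2 * z / sqrt(2), lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(pool_dependent_pvalues(c(0.05, 0.05), rho = 0), 0.0100,
               tolerance = 1e-3)

  # permutation invariance and monotonicity
  set.seed(63)
  p <- runif(10, 0.01, 0.9)
  expect_equal(pool_dependent_pvalues(p, 0.4),
               pool_dependent_pvalues(sample(p), 0.4))
  p2 <- p
  p2[3] <- p2[3] / 2
  expect_lt(pool_dependent_pvalues(p2, 0.4), pool_dependent_pvalues(p, 0.4))

  # zero p-values are clipped with a warning, not fatal
  expect_warning(out <- pool_dependent_pvalues(c(0, 0.2), 0.5), "clipped")
  expect_true(out > 0 && out < 1)

  # harmonic-mean alternative is sane
  expect_lt(pool_dependent_pvalues(rep(0.01, 5), method = "harmonic"), 0.05)
  expect_equal(pool_dependent_pvalues(rep(0.5, 5), method = "harmonic"), 0.5)
})

test_that("between-tree dependence is estimated from replicate z-scores", {
  set.seed(64)
  shared <- rnorm(8)
  zmat <- matrix(rep(shared, each = 30), 30, 8, byrow = FALSE) # rows identical
  zmat <- t(replicate(30, shared))
  expect_equal(estimate_tree_dependence(zmat), 1)
  znoise <- matrix(rnorm(30 * 8), 30, 8)
  expect_lt(estimate_tree_dependence(znoise), 0.35)
  expect_true(is.na(estimate_tree_dependence(matrix(rnorm(5), 5, 1))))
})

test_that("the type-I error of the deviation test is nominal under the null", {
  set.seed(65)
  tr <- make_test_tree(60, depth = 100)
  V <- unclass(lambda_transform(bm_covariance(tr), 0.93))
  Vn <- V / mean(diag(V))
  L <- t(chol(Vn))
  g <- as.numeric(seq_len(60) <= 20)
  x <- rnorm(60)
  rej <- replicate(400, {
    y <- 0.1 + 0.9 * x + 0.1 * as.numeric(L %*% rnorm(60))
    pancova_f_test(y, x, Vn, g)$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.035)
})

test_that("the iterative loop excludes a deviant clade and stops cleanly", {
  set.seed(66)
  syn <- suppressWarnings(make_synthetic_dataset(
    sim_config(n_species = 60, frac_multi = 0.2,
               clade_effects = list(Deviant = list(size = 18,
                                                   delta_slope = 0.25))),
    seed = 8))
  cp <- calibration_params(0.1, 0.05)
  ens <- generate_tree_ensemble(syn$base_topology, 8,
                                syn$age_ranges, cp,
                                syn$species_to_specimens, seed = 9)
  res <- iterative_exclusion(syn$specimens, ens,
                             c("Deviant", "NullClade1", "NullClade2"),
                             subset_size = 8)
  expect_s3_class(res, "exclusion_result")
  expect_true("Deviant" %in% res$excluded_clades)
  expect_lte(length(res$rounds), 3)
  # last round excludes nothing (that's the stopping rule)
  expect_length(res$rounds[[length(res$rounds)]]$excluded, 0)
  expect_false(any(in_clade(res$kept, "Deviant")))
  expect_s3_class(res$final_pool, "pooled_table")

  # a dataset with no deviating clade stops after one round, unchanged
  syn0 <- suppressWarnings(make_synthetic_dataset(
    sim_config(n_species = 40, frac_multi = 0.2), seed = 10))
  ens0 <- generate_tree_ensemble(syn0$base_topology, 6, syn0$age_ranges, cp,
                                 syn0$species_to_specimens, seed = 11)
  res0 <- iterative_exclusion(syn0$specimens, ens0,
                              c("NullClade1", "NullClade2"), subset_size = 6)
  expect_length(res0$rounds, 1)
  expect_length(res0$excluded_clades, 0)
  expect_equal(nrow(res0$kept), nrow(syn0$specimens))

  # forced exclusions are honored without testing
  resf <- iterative_exclusion(syn0$specimens, ens0, c("NullClade1"),
                              subset_size = 4,
                              forced_exclusions = syn0$specimens$species[1])
  expect_false(syn0$specimens$species[1] %in% resf$kept$species)
})

test_that("per-clade regressions pool subtree fits and bracket tiny clades", {
  set.seed(67)
  syn <- suppressWarnings(make_synthetic_dataset(
    sim_config(n_species = 50, frac_multi = 0.2, n_null_clades = 1,
               null_clade_size = 15), seed = 12))
  cp <- calibration_params(0.1, 0.05)
  ens <- generate_tree_ensemble(syn$base_topology, 6, syn$age_ranges, cp,
                                syn$species_to_specimens, seed = 13)
  # add a clade too small to analyse
  sp <- syn$specimens
  sp$clades[[1]] <- c(sp$clades[[1]], "Tiny")
  sp$clades[[2]] <- c(sp$clades[[2]], "Tiny")
  out <- per_clade_regressions(sp, ens, c("NullClade1", "Tiny"))
  expect_true("skipped" %in% out$fit[out$clade == "Tiny"])
  nc <- out[out$clade == "NullClade1", ]
  expect_true(all(nc$fit %in% c("estimated_lambda", "fixed_lambda_1",
                                "fixed_lambda_0")))
  expect_true(all(is.finite(nc$slope)))
  # bracketing rows, when present, come in the 1-and-0 pair
  if (any(nc$fit == "fixed_lambda_1")) {
    expect_true(any(nc$fit == "fixed_lambda_0"))
  }
})
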