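test_that("identity-covariance GLS is exact on a perfect line and equals OLS", {
  f <- gls_fit(c(0, 1, 2), c(0, 1, 2))
  expect_equal(unname(coef(f)), c(0, 1), tolerance = 1e-12)

  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    x <- rnorm(n)
    y <- 0.3 + 0.8 * x + rnorm(n, sd = 0.2)
    mine <- gls_fit(y, x)
    ref <- lm(y ~ x)
    expect_equal(unname(coef(mine)), unname(coef(ref)), tolerance = 1e-10)
    expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-10)
  }
})

test_that("GLS equals the whitened-OLS oracle on random phylogenetic data", {
  set.seed(32)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    tr <- ape::rtree(n)
    V <- unclass(bm_covariance(tr))
    x <- rnorm(n)
    y <- 0.2 + 0.9 * x + as.numeric(t(chol(V)) %*% rnorm(n)) * 0.3
    mine <- gls_fit(y, x, V)
    expect_equal(unname(coef(mine)), unname(whitened_ols_oracle(y, x, V)),
                 tolerance = 1e-8)
  }
})

test_that("PGLS with lambda = 0 is ordinary least squares", {
  set.seed(33)
  tr <- make_test_tree(30)
  d <- draw_traits(tr)
  rownames(d) <- d$tip
  f0 <- pgls_allom(log_hl ~ log_fl, d, tr, model = "lambda", signal = 0)
  fo <- pgls_allom(log_hl ~ log_fl, d, model = "OLS")
  expect_equal(coef(f0), coef(fo), tolerance = 1e-10)
  expect_equal(f0$se, fo$se, tolerance = 1e-10)
})

test_that("fixed-lambda fits agree with nlme::gls + corPagel", {
  skip_if_not_installed("nlme")
  set.seed(34)
  tr <- ape::rcoal(40)  # ultrametric: correlation and covariance coincide
  V <- unclass(bm_covariance(tr))
  x <- 2 + as.numeric(t(chol(V)) %*% rnorm(40)) * 0.3
  y <- 0.1 + 0.9 * x + as.numeric(t(chol(V)) %*% rnorm(40)) * 0.1
  d <- data.frame(x = x, y = y, sp = tr$tip.label, row.names = tr$tip.label)
  for (lam in c(0.25, 0.6, 1)) {
    mine <- pgls_allom(y ~ x, d[, c("x", "y")], tr, model = "lambda",
                       signal = lam)
    ref <- nlme::gls(y ~ x, data = d, method = "REML",
                     correlation = ape::corPagel(lam, tr, fixed = TRUE,
                                                 form = ~sp))
    expect_equal(unname(coef(mine)), unname(coef(ref)), tolerance = 1e-8)
    expect_equal(unname(mine$se[2]), sqrt(vcov(ref)[2, 2]), tolerance = 1e-8)
    expect_equal(mine$loglik, as.numeric(ref$logLik), tolerance = 1e-6)
  }
})

test_that("the lambda optimizer beats a grid and recovers extreme signal", {
  set.seed(35)
  tr <- make_test_tree(60, depth = 150)
  d <- draw_traits(tr, lambda0 = 0.8)
  rownames(d) <- d$tip
  fit <- pgls_allom(log_hl ~ log_fl, d, tr, model = "lambda")
  expect_true(fit$converged)
  expect_false(fit$signal$fixed)
  # profile likelihood at the optimum dominates a fine grid
  X <- cbind(1, d$log_fl[match(tr$tip.label, d$tip)])
  yv <- d$log_hl[match(tr$tip.label, d$tip)]
  Vbm <- bm_covariance(tr)
  grid_ll <- vapply(seq(0, 1, length.out = 101), function(l) {
    phylallom:::gls_engine(yv, X, lambda_transform(Vbm, l), "REML")$loglik
  }, numeric(1))
  expect_gte(fit$loglik, max(grid_ll) - 1e-6)

  # independent residuals on a deep tree push lambda-hat to ~0
  tr2 <- make_test_tree(300, depth = 150)
  d2 <- draw_traits(tr2, lambda0 = 0)
  rownames(d2) <- d2$tip
  f2 <- pgls_allom(log_hl ~ log_fl, d2, tr2, model = "lambda")
  expect_lt(f2$signal$value, 0.1)
})

test_that("non-identifiable lambda falls back to fixed 1 plus an OLS fit", {
  # a star phylogeny has no shared history: the lambda transform has no
  # effect and the profile likelihood is exactly flat
  set.seed(36)
  star <- read_topology(paste0("(", paste0("t", 1:12, ":5", collapse = ","), ");"))
  d <- data.frame(x = rnorm(12), row.names = star$tip.label)
  d$y <- 0.2 + 0.9 * d$x + rnorm(12, sd = 0.1)
  fit <- pgls_allom(y ~ x, d, star, model = "lambda")
  expect_false(fit$converged)
  expect_true(fit$signal$fixed)
  expect_equal(fit$signal$value, 1)
  expect_s3_class(fit$fallback_ols, "pgls_allom")
  expect_equal(fit$fallback_ols$model, "OLS")
  # on a star tree the lambda = 1 fit and OLS coincide
  expect_equal(coef(fit), coef(fit$fallback_ols), tolerance = 1e-8)
})

test_that("OU nests BM at small alpha and flags unreliable regimes", {
  set.seed(37)
  tr <- make_test_tree(50, depth = 120)
  d <- draw_traits(tr, lambda0 = 1)
  rownames(d) <- d$tip
  fbm <- pgls_allom(log_hl ~ log_fl, d, tr, model = "BM")
  fou <- pgls_allom(log_hl ~ log_fl, d, tr, model = "OU", signal = 1e-6)
  expect_lt(abs(fou$loglik - fbm$loglik), 0.01)
  expect_true(fou$caution)  # alpha below the reliability threshold

  small <- d[seq_len(20), ]
  tr_small <- ape::keep.tip(tr, small$tip)
  fsmall <- pgls_allom(log_hl ~ log_fl, small, tr_small, model = "OU")
  expect_true(fsmall$caution)  # n < 50
})

test_that("OU recovers a moderate attraction strength", {
  set.seed(38)
  tr <- make_test_tree(200, depth = 60)
  geom <- phylallom:::tree_geometry(tr)
  Vou <- unclass(phylallom:::ou_cov_from_geometry(geom, 0.5))
  x <- rnorm(200)
  y <- 0.1 + 0.9 * x + 0.15 * as.numeric(t(chol(Vou / mean(diag(Vou)))) %*%
                                           rnorm(200))
  d <- data.frame(x = x, y = y, row.names = tr$tip.label)
  f <- pgls_allom(y ~ x, d, tr, model = "OU")
  expect_gt(f$signal$value, 0.1)
  expect_lt(f$signal$value, 2.5)
})

test_that("observations are matched to tips exactly, never fuzzily", {
  set.seed(39)
  tr <- make_test_tree(10)
  d <- draw_traits(tr)
  rownames(d) <- d$tip
  # scrambled rows still fit identically (exact-name reorder)
  shuf <- d[sample(nrow(d)), ]
  f1 <- pgls_allom(log_hl ~ log_fl, d, tr, model = "lambda", signal = 0.7)
  f2 <- pgls_allom(log_hl ~ log_fl, shuf, tr, model = "lambda", signal = 0.7)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
  # a renamed observation is an error
  bad <- d
  rownames(bad)[1] <- "not_a_tip"
  expect_error(pgls_allom(log_hl ~ log_fl, bad, tr, model = "lambda"),
               "do not match")
})

test_that("within-taxon regressions handle exact, noisy and tiny taxa", {
  # three collinear specimens: exact slope, zero-width CI
  sp <- as_specimen_table(data.frame(
    specimen_id = paste0("c", 1:3), species = "s", genus = "g", clades = "",
    fl_mm = c(100, 200, 400), hl_mm = c(50, 100, 200),
    age_min_ma = 1, age_max_ma = 2, onto_status = "adult"))
  out <- within_taxon_fits(sp, by = "genus")
  expect_equal(out$slope, 1, tolerance = 1e-10)
  expect_equal(out$ci_hi - out$ci_lo, 0, tolerance = 1e-8)

  # two specimens: reported as insufficient, not an error
  sp2 <- sp[1:2, ]
  out2 <- within_taxon_fits(sp2, by = "genus")
  expect_equal(out2$note, "insufficient_data")
  expect_true(is.na(out2$slope))

  # a synthetic ontogenetic series is recovered within its CI
  set.seed(40)
  hits <- replicate(60, {
    lfl <- runif(12, 1.8, 2.6)
    lhl <- -0.5 + 1.2 * lfl + rnorm(12, sd = 0.02)
    d <- as_specimen_table(data.frame(
      specimen_id = paste0("o", 1:12), species = "s", genus = "g", clades = "",
      fl_mm = 10^lfl, hl_mm = 10^lhl, age_min_ma = 1, age_max_ma = 2,
      onto_status = "adult"))
    w <- within_taxon_fits(d, by = "genus")
    w$ci_lo <= 1.2 && 1.2 <= w$ci_hi
  })
  expect_gte(mean(hits), 0.9)
})

test_that("model objects support the standard S3 verbs", {
  set.seed(41)
  tr <- make_test_tree(30)
  d <- draw_traits(tr)
  rownames(d) <- d$tip
  f <- pgls_allom(log_hl ~ log_fl, d, tr, model = "lambda")
  expect_output(print(f), "slope")
  s <- summary(f)
  expect_output(print(s), "isometry")
  expect_equal(nrow(s$coefficients), 2)
  expect_equal(unname(confint(f)["slope", ]), unname(f$ci[2, ]))
  expect_length(fitted(f), 30)
  expect_length(residuals(f), 30)
  expect_equal(fitted(f) + residuals(f), f$y, tolerance = 1e-12)
  # normalized residuals are decorrelated: unit-ish variance
  rn <- residuals(f, type = "normalized")
  expect_equal(length(rn), 30)
  expect_equal(predict(f, data.frame(x = c(2, 3))),
               unname(coef(f)[1] + coef(f)[2] * c(2, 3)))
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(30, 3))
  expect_s3_class(logLik(f), "logLik")
})
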