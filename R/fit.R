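# Core generalized least squares machinery. V is always handled through its
# Cholesky factor (whitening); it is never inverted explicitly.

gls_engine <- function(y, X, V, method = "REML") {
  n <- length(y)
  p <- ncol(X)
  if (n < p + 1) stop("need at least ", p + 1, " observations")
  U <- chol_or_fail(V)
  yw <- backsolve(U, y, transpose = TRUE)
  Xw <- backsolve(U, X, transpose = TRUE)
  qrX <- qr(Xw)
  if (qrX$rank < p) stop("design matrix is rank deficient")
  beta <- qr.coef(qrX, yw)
  res_w <- yw - Xw %*% beta
  rss <- sum(res_w^2)
  logdetV <- 2 * sum(log(diag(U)))
  XtX <- crossprod(Xw)
  ll_ml <- -0.5 * (n * log(2 * pi * rss / n) + logdetV + n)
  ll_reml <- -0.5 * ((n - p) * log(2 * pi * rss / (n - p)) + logdetV +
                       determinant(XtX, logarithm = TRUE)$modulus + (n - p))
  sigma2 <- rss / (n - p)
  cov_beta <- sigma2 * chol2inv(qr.R(qrX))
  list(beta = as.numeric(beta), se = sqrt(diag(cov_beta)), cov_beta = cov_beta,
       rss = rss, sigma2 = sigma2, logdetV = logdetV,
       loglik = if (method == "REML") as.numeric(ll_reml) else ll_ml,
       loglik_ml = ll_ml, loglik_reml = as.numeric(ll_reml),
       n = n, p = p, df_residual = n - p,
       fitted = as.numeric(X %*% beta), residuals = as.numeric(y - X %*% beta))
}

make_allom_fit <- function(eng, model, signal, y, x, tip_labels, V, method,
                           converged = TRUE, caution = FALSE,
                           fallback_ols = NULL, call = NULL) {
  est <- eng$beta
  names(est) <- c("(Intercept)", "slope")[seq_along(est)]
  tq <- stats::qt(0.975, eng$df_residual)
  ci <- cbind(est - tq * eng$se, est + tq * eng$se)
  colnames(ci) <- c("2.5 %", "97.5 %")
  rownames(ci) <- names(est)
  fitted <- eng$fitted
  resid <- eng$residuals
  if (!is.null(tip_labels)) {
    names(fitted) <- tip_labels
    names(resid) <- tip_labels
  }
  structure(list(
    coefficients = est, se = stats::setNames(eng$se, names(est)),
    ci = ci, vcov = eng$cov_beta, sigma2 = eng$sigma2,
    loglik = eng$loglik, method = method, model = model, signal = signal,
    n = eng$n, df.residual = eng$df_residual,
    fitted.values = fitted, residuals = resid,
    y = y, x = x, tip_labels = tip_labels, V = V,
    converged = converged, caution = caution, fallback_ols = fallback_ols,
    call = call
  ), class = "pgls_allom")
}

#' Generalized least squares fit with a fixed covariance structure
#'
#' Fits `y = a + b x + e` with `e ~ N(0, sigma^2 V)` for a known covariance
#' structure `V` (up to scale); with `V` the identity this is ordinary least
#' squares. Standard errors use `sigma^2` estimated from the whitened
#' residual sum of squares on `n - 2` degrees of freedom, and the 95%
#' confidence intervals are Student-t based.
#'
#' @param y Response vector.
#' @param x Predictor vector.
#' @param V Covariance matrix (e.g. a [bm_covariance()]), or `NULL` for the
#'   identity.
#' @param method Label for the stored log-likelihood, `"REML"` (default)
#'   or `"ML"`; the point estimates are identical.
#' @return A `pgls_allom` model object.
#' @export
gls_fit <- function(y, x, V = NULL, method = c("REML", "ML")) {
  method <- match.arg(method)
  stopifnot(length(y) == length(x))
  if (is.null(V)) V <- diag(length(y))
  stopifnot(nrow(V) == length(y))
  X <- cbind(1, x)
  eng <- gls_engine(y, X, V, method)
  model <- if (attr(V, "model") %||% "" == "OU") "OU" else "GLS"
  make_allom_fit(eng, model = model,
                 signal = list(name = attr(V, "model") %||% NA_character_,
                               value = attr(V, "parameter") %||% NA_real_,
                               fixed = TRUE),
                 y = y, x = x, tip_labels = rownames(V), V = V, method = method,
                 call = match.call())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# match observation ids against tree tips; exact names only, never fuzzy
order_to_tree <- function(ids, tree) {
  if (!setequal(ids, tree$tip.label) || length(ids) != length(tree$tip.label)) {
    stop("observation ids and tree tips do not match exactly; ",
         "missing from data: ",
         paste(utils::head(setdiff(tree$tip.label, ids), 5), collapse = ", "),
         "; missing from tree: ",
         paste(utils::head(setdiff(ids, tree$tip.label), 5), collapse = ", "))
  }
  match(tree$tip.label, ids)
}

profile_lambda <- function(y, X, Vbm, method) {
  function(lam) {
    tryCatch(gls_engine(y, X, lambda_transform(Vbm, lam), method)$loglik,
             error = function(e) -Inf)
  }
}

#' Phylogenetic allometric regression on a time-calibrated tree
#'
#' The workhorse fitter: regresses one log-measurement on another by
#' generalized least squares with residual covariance derived from a
#' phylogeny. Supported covariance models:
#' \describe{
#'   \item{`"lambda"`}{Brownian motion with simultaneous estimation of
#'     Pagel's lambda by bounded likelihood maximization over \[0, 1\]
#'     (tolerance 1e-6). If the likelihood is flat or non-finite across the
#'     range (lambda not identifiable), the fit falls back to fixed
#'     `lambda = 1` with an ordinary least squares fit attached as
#'     `$fallback_ols`, and `converged` is `FALSE`.}
#'   \item{`"OU"`}{Ornstein-Uhlenbeck with attraction strength alpha
#'     maximized over a log-spaced interval (default \eqn{[10^{-6}, 10^2]}
#'     per My). A `caution` flag is set when `alpha < 0.05` or `n < 50`,
#'     where OU estimates are known to be unreliable.}
#'   \item{`"BM"`}{Brownian motion with lambda fixed at 1.}
#'   \item{`"OLS"`}{ordinary least squares (equivalently lambda fixed at 0).}
#' }
#' Signal parameters are estimated by REML by default; `method = "ML"` is
#' available. Observations are matched to tree tips by exact label and
#' reordered to tip order; any mismatch is an error.
#'
#' @param formula Model formula, e.g. `log_hl ~ log_fl`.
#' @param data A data frame (e.g. a `specimen_table`); tip labels are taken
#'   from its `specimen_id` column if present, else from row names.
#' @param tree A rooted, calibrated `phylo` (not needed for `"OLS"`).
#' @param model Covariance model, see above.
#' @param method `"REML"` (default) or `"ML"` for signal estimation.
#' @param signal Optional fixed value for lambda/alpha, skipping estimation.
#' @param eps Duration given to zero-length terminal branches before
#'   building covariances (see [apply_branch_epsilon()]).
#' @return A `pgls_allom` object; see [summary.pgls_allom()].
#' @examples
#' tr <- ape::rcoal(40)
#' x <- as.numeric(ape::vcv(tr) %*% rnorm(40)) # BM-ish predictor
#' d <- data.frame(xf = x, yh = 0.1 + 0.9 * x + rnorm(40, sd = 0.1),
#'                 row.names = tr$tip.label)
#' fit <- pgls_allom(yh ~ xf, d, tr, model = "lambda")
#' coef(fit)
#' @export
pgls_allom <- function(formula, data, tree = NULL,
                       model = c("lambda", "OU", "BM", "OLS"),
                       method = c("REML", "ML"), signal = NULL, eps = 1e-6) {
  model <- match.arg(model)
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  ids <- if ("specimen_id" %in% names(data)) data$specimen_id else rownames(data)

  if (model == "OLS") {
    eng <- gls_engine(y, X, diag(length(y)), method)
    return(make_allom_fit(eng, model = "OLS",
                          signal = list(name = "lambda", value = 0, fixed = TRUE),
                          y = y, x = X[, 2], tip_labels = ids,
                          V = NULL, method = method, call = match.call()))
  }

  if (is.null(tree)) stop("a tree is required for model '", model, "'")
  tree <- apply_branch_epsilon(tree, eps)
  ord <- order_to_tree(ids, tree)
  y <- y[ord]; X <- X[ord, , drop = FALSE]; ids <- ids[ord]
  Vbm <- bm_covariance(tree)

  if (model == "BM") signal_fixed <- 1
  fit <- switch(
    model,
    BM = {
      eng <- gls_engine(y, X, Vbm, method)
      make_allom_fit(eng, "BM+lambda",
                     list(name = "lambda", value = 1, fixed = TRUE),
                     y, X[, 2], ids, Vbm, method)
    },
    lambda = fit_lambda_internal(y, X, Vbm, method, signal),
    OU = fit_ou_internal(y, X, tree, method, signal)
  )
  fit$call <- match.call()
  fit
}

fit_lambda_internal <- function(y, X, Vbm, method, signal = NULL) {
  if (!is.null(signal)) {
    V <- lambda_transform(Vbm, signal)
    eng <- gls_engine(y, X, V, method)
    return(make_allom_fit(eng, "BM+lambda",
                          list(name = "lambda", value = signal, fixed = TRUE),
                          y, X[, 2], rownames(Vbm), V, method))
  }
  obj <- profile_lambda(y, X, Vbm, method)
  opt <- tryCatch(stats::optimize(obj, c(0, 1), maximum = TRUE, tol = 1e-6),
                  error = function(e) NULL)
  cand <- c(if (!is.null(opt)) opt$maximum, 0, 1)
  vals <- vapply(cand, obj, numeric(1))
  lam_hat <- cand[which.max(vals)]
  ll_hat <- max(vals)

  failed <- !is.finite(ll_hat)
  if (!failed) {
    # non-identifiable: likelihood flat across the whole range
    probe <- vapply(c(0, 0.25, 0.5, 0.75, 1), obj, numeric(1))
    if (all(is.finite(probe)) &&
        diff(range(c(probe, ll_hat))) < 1e-8 * max(1, abs(ll_hat))) failed <- TRUE
    # bound hit with non-finite or flat interior slope
    if (!failed && (lam_hat < 1e-6 || lam_hat > 1 - 1e-6)) {
      h <- 1e-3
      inward <- if (lam_hat < 0.5) obj(h) else obj(1 - h)
      g <- (ll_hat - inward) / h
      if (!is.finite(g) || abs(g) < 1e-8 * max(1, abs(ll_hat))) failed <- TRUE
    }
  }

  if (failed) {
    V1 <- Vbm
    eng <- gls_engine(y, X, V1, method)
    ols_eng <- gls_engine(y, X, diag(length(y)), method)
    ols_fit <- make_allom_fit(ols_eng, "OLS",
                              list(name = "lambda", value = 0, fixed = TRUE),
                              y, X[, 2], rownames(Vbm), NULL, method)
    return(make_allom_fit(eng, "BM+lambda",
                          list(name = "lambda", value = 1, fixed = TRUE),
                          y, X[, 2], rownames(Vbm), V1, method,
                          converged = FALSE, fallback_ols = ols_fit))
  }

  V <- lambda_transform(Vbm, lam_hat)
  eng <- gls_engine(y, X, V, method)
  make_allom_fit(eng, "BM+lambda",
                 list(name = "lambda", value = lam_hat, fixed = FALSE),
                 y, X[, 2], rownames(Vbm), V, method)
}

fit_ou_internal <- function(y, X, tree, method, signal = NULL,
                            alpha_range = c(1e-6, 100)) {
  geom <- tree_geometry(tree)
  if (!is.null(signal)) {
    V <- ou_cov_from_geometry(geom, signal)
    eng <- gls_engine(y, X, V, method)
    fit <- make_allom_fit(eng, "OU",
                          list(name = "alpha", value = signal, fixed = TRUE),
                          y, X[, 2], tree$tip.label, V, method)
    fit$caution <- signal < 0.05 || length(y) < 50
    return(fit)
  }
  obj <- function(la) {
    tryCatch(gls_engine(y, X, ou_cov_from_geometry(geom, exp(la)),
                        method)$loglik,
             error = function(e) -Inf)
  }
  lr <- log(alpha_range)
  opt <- tryCatch(stats::optimize(obj, lr, maximum = TRUE, tol = 1e-6),
                  error = function(e) NULL)
  cand <- c(if (!is.null(opt)) opt$maximum, lr)
  vals <- vapply(cand, obj, numeric(1))
  la_hat <- cand[which.max(vals)]
  converged <- is.finite(max(vals))
  alpha_hat <- exp(la_hat)
  V <- ou_cov_from_geometry(geom, alpha_hat)
  eng <- gls_engine(y, X, V, method)
  fit <- make_allom_fit(eng, "OU",
                        list(name = "alpha", value = alpha_hat, fixed = FALSE),
                        y, X[, 2], tree$tip.label, V, method,
                        converged = converged)
  fit$caution <- alpha_hat < 0.05 || length(y) < 50
  fit
}

#' @rdname pgls_allom
#' @param y,x Named numeric vectors (names = tip labels) for the
#'   vector-interface wrappers.
#' @export
fit_pgls_bm_lambda <- function(y, x, tree, method = c("REML", "ML"), eps = 1e-6) {
  d <- data.frame(.y = y, .x = x, row.names = names(y))
  pgls_allom(.y ~ .x, d, tree, model = "lambda", method = match.arg(method),
             eps = eps)
}

#' @rdname pgls_allom
#' @export
fit_pgls_ou <- function(y, x, tree, method = c("REML", "ML"), eps = 1e-6) {
  d <- data.frame(.y = y, .x = x, row.names = names(y))
  pgls_allom(.y ~ .x, d, tree, model = "OU", method = match.arg(method),
             eps = eps)
}

#' @rdname pgls_allom
#' @export
fit_ols <- function(y, x) {
  d <- data.frame(.y = y, .x = x,
                  row.names = names(y) %||% paste0("obs", seq_along(y)))
  pgls_allom(.y ~ .x, d, model = "OLS")
}

#' Ordinary least squares allometry within single genera or species
#'
#' A preliminary look at ontogenetic trends: for every taxon with at least
#' `min_n` specimens, fits log humerus on log femur by OLS with no
#' phylogenetic correction (conspecific/congeneric specimens share no
#' usable tree structure). Taxa below the threshold are reported, not
#' dropped silently.
#'
#' @param specimens A `specimen_table`.
#' @param by `"genus"` or `"species"`.
#' @param min_n Minimum specimens per taxon (default 3).
#' @return Data frame: taxon, n, intercept, slope, se_slope, ci bounds,
#'   and a `note` column (`"ok"` or `"insufficient_data"`).
#' @export
within_taxon_fits <- function(specimens, by = c("genus", "species"), min_n = 3) {
  by <- match.arg(by)
  groups <- split(specimens, specimens[[by]])
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    if (nrow(d) < min_n) {
      return(data.frame(taxon = g, n = nrow(d), intercept = NA_real_,
                        slope = NA_real_, se_slope = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_,
                        note = "insufficient_data"))
    }
    f <- fit_ols(stats::setNames(d$log_hl, d$specimen_id), d$log_fl)
    data.frame(taxon = g, n = nrow(d), intercept = coef(f)[1],
               slope = coef(f)[2], se_slope = f$se[2],
               ci_lo = f$ci[2, 1], ci_hi = f$ci[2, 2], note = "ok")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- S3 methods -----------------------------------------------------------

#' @export
print.pgls_allom <- function(x, ...) {
  cat("Phylogenetic allometric regression (", x$model, ", ", x$method, ")\n",
      sep = "")
  cat(sprintf("n = %d, slope = %.4f [%.4f, %.4f], intercept = %.4f\n",
              x$n, x$coefficients[2], x$ci[2, 1], x$ci[2, 2],
              x$coefficients[1]))
  if (!is.na(x$signal$value)) {
    cat(sprintf("%s = %.4f (%s)\n", x$signal$name, x$signal$value,
                if (x$signal$fixed) "fixed" else "estimated"))
  }
  if (!x$converged) cat("note: signal estimation failed; fixed-signal fit",
                        "returned (see $fallback_ols)\n")
  invisible(x)
}

#' Summarize a phylogenetic allometric regression
#'
#' Reports the coefficient table and, for the slope, tests against 0 and
#' against isometry (slope = 1) — the scientifically relevant null for a
#' log-log scaling of two lengths.
#'
#' @param object A `pgls_allom` fit.
#' @param ... Unused.
#' @export
summary.pgls_allom <- function(object, ...) {
  est <- object$coefficients
  se <- object$se
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), object$df.residual)
  tab <- cbind(Estimate = est, `Std. Error` = se, `t value` = tval,
               `Pr(>|t|)` = pval)
  t_iso <- (est[2] - 1) / se[2]
  p_iso <- 2 * stats::pt(-abs(t_iso), object$df.residual)
  out <- list(fit = object, coefficients = tab,
              isometry = c(t = t_iso, p = p_iso),
              sigma2 = object$sigma2, loglik = object$loglik)
  class(out) <- "summary.pgls_allom"
  out
}

#' @export
print.summary.pgls_allom <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  cat(sprintf("\nTest of isometry (slope = 1): t = %.3f, p = %.4g\n",
              x$isometry[1], x$isometry[2]))
  cat(sprintf("residual scale sigma^2 = %.5g, logLik (%s) = %.3f\n",
              x$sigma2, x$fit$method, x$loglik))
  if (isTRUE(x$fit$caution)) {
    cat("caution: low attraction strength and/or small sample;",
        "OU estimates may be unreliable\n")
  }
  invisible(x)
}

#' @export
coef.pgls_allom <- function(object, ...) object$coefficients

#' @export
vcov.pgls_allom <- function(object, ...) object$vcov

#' @export
nobs.pgls_allom <- function(object, ...) object$n

#' @export
logLik.pgls_allom <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1 +
              !object$signal$fixed, class = "logLik")
}

#' @export
confint.pgls_allom <- function(object, parm, level = 0.95, ...) {
  tq <- stats::qt(1 - (1 - level) / 2, object$df.residual)
  ci <- cbind(object$coefficients - tq * object$se,
              object$coefficients + tq * object$se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2)), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
fitted.pgls_allom <- function(object, ...) object$fitted.values

#' @export
residuals.pgls_allom <- function(object, type = c("response", "normalized"), ...) {
  type <- match.arg(type)
  r <- object$residuals
  if (type == "response" || is.null(object$V)) return(r)
  U <- chol(object$V)
  as.numeric(backsolve(U, r, transpose = TRUE)) / sqrt(object$sigma2)
}

#' @export
predict.pgls_allom <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  x <- if (is.data.frame(newdata)) newdata[[1]] else newdata
  object$coefficients[1] + object$coefficients[2] * x
}

#' @export
simulate.pgls_allom <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  L <- if (is.null(object$V)) diag(n) else t(chol(object$V))
  sims <- replicate(nsim,
    object$fitted.values + sqrt(object$sigma2) * as.numeric(L %*% stats::rnorm(n)))
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$tip_labels
  out
}

#' @export
plot.pgls_allom <- function(x, xlab = "log10 femur length",
                            ylab = "log10 humerus length", ...) {
  graphics::plot(x$x, x$y, xlab = xlab, ylab = ylab, pch = 19,
                 col = grDevices::grey(0.3), ...)
  graphics::abline(x$coefficients[1], x$coefficients[2], lwd = 2)
  graphics::abline(x$coefficients[1], 1, lty = 3)
  graphics::legend("topleft", bty = "n",
                   legend = c(sprintf("fit (b = %.3f)", x$coefficients[2]),
                              "isometry"),
                   lty = c(1, 3), lwd = c(2, 1))
  invisible(x)
}
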