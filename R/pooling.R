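#' Pool estimates across an ensemble by Rubin's rules
#'
#' Treats each tree's fit as one imputation of the unknowable true
#' phylogeny. For estimates \eqn{Q_i} with squared standard errors
#' \eqn{W_i}, the pooled estimate is \eqn{\bar Q = m^{-1}\sum Q_i}, the
#' within variance \eqn{\bar W = m^{-1}\sum W_i}, the between variance
#' \eqn{B} the sample variance of the \eqn{Q_i}, the total variance
#' \eqn{T = \bar W + (1 + 1/m) B}, and the degrees of freedom
#' \eqn{(m-1)\,[1 + \bar W / ((1+1/m)B)]^2} (classic large-m form; the
#' Barnard-Rubin small-sample correction can be requested). When \eqn{B =
#' 0} the fits are identical and \eqn{T = \bar W} with infinite df.
#'
#' @param estimates Numeric vector of per-fit estimates \eqn{Q_i}.
#' @param variances Numeric vector of per-fit variances (se squared), > 0.
#' @param small_sample Apply the Barnard-Rubin adjustment with
#'   `com_df` complete-data degrees of freedom. Default off: ensembles of
#'   1000+ trees gain nothing from it.
#' @param com_df Complete-data residual df, required if `small_sample`.
#' @return A list of class `pooled_fit`: `m`, `qbar`, `wbar`, `between`,
#'   `total_var`, `df`, `ci` (95%), `se`.
#' @export
rubin_pool <- function(estimates, variances, small_sample = FALSE, com_df = NULL) {
  m <- length(estimates)
  if (m < 2) stop("pooling requires at least 2 fits")
  if (length(variances) != m) stop("estimates and variances differ in length")
  if (any(variances <= 0)) stop("all variances must be > 0")
  qbar <- mean(estimates)
  wbar <- mean(variances)
  B <- stats::var(estimates)
  if (B <= 0) {
    total <- wbar
    df <- Inf
  } else {
    total <- wbar + (1 + 1 / m) * B
    df <- (m - 1) * (1 + wbar / ((1 + 1 / m) * B))^2
    if (small_sample) {
      if (is.null(com_df)) stop("com_df required for the small-sample correction")
      lam <- (1 + 1 / m) * B / total
      df_obs <- (com_df + 1) / (com_df + 3) * com_df * (1 - lam)
      df <- 1 / (1 / df + 1 / df_obs)
    }
  }
  tq <- stats::qt(0.975, df)
  structure(list(m = m, qbar = qbar, wbar = wbar, between = B,
                 total_var = total, df = df, se = sqrt(total),
                 ci = c(qbar - tq * sqrt(total), qbar + tq * sqrt(total))),
            class = "pooled_fit")
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat(sprintf("pooled estimate over m = %d fits: %.4f [%.4f, %.4f]\n",
              x$m, x$qbar, x$ci[1], x$ci[2]))
  cat(sprintf("  within var %.4g, between var %.4g, total %.4g, df %.1f\n",
              x$wbar, x$between, x$total_var, x$df))
  invisible(x)
}

#' Fit the allometric regression on every tree of an ensemble
#'
#' @param specimens A `specimen_table` (one row per tree tip).
#' @param ensemble A `tree_ensemble` whose tips are specimen ids.
#' @param model Covariance model passed to [pgls_allom()].
#' @param method `"REML"` or `"ML"`.
#' @param formula Regression formula; defaults to humerus on femur.
#' @return Data frame of per-tree results (class `ensemble_fits`):
#'   topology, tree, intercept, slope, their standard errors, signal value
#'   and fixed flag, loglik, converged.
#' @export
fit_ensemble <- function(specimens, ensemble,
                         model = c("lambda", "OU", "BM", "OLS"),
                         method = c("REML", "ML"),
                         formula = log_hl ~ log_fl) {
  model <- match.arg(model)
  method <- match.arg(method)
  rows <- list()
  for (ti in seq_along(ensemble)) {
    for (k in seq_along(ensemble[[ti]])) {
      fit <- pgls_allom(formula, specimens, ensemble[[ti]][[k]],
                        model = model, method = method)
      rows[[length(rows) + 1L]] <- data.frame(
        topology = ti, tree = k,
        intercept = fit$coefficients[1], slope = fit$coefficients[2],
        se_intercept = fit$se[1], se_slope = fit$se[2],
        signal = fit$signal$value, signal_fixed = fit$signal$fixed,
        loglik = fit$loglik, converged = fit$converged)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "model") <- model
  class(out) <- c("ensemble_fits", "data.frame")
  out
}

#' Pool per-tree fits per topology and overall
#'
#' Applies [rubin_pool()] to intercept and slope, per topology and for the
#' grand pool over all trees; the signal parameter (lambda or alpha) is
#' pooled as a simple arithmetic mean. Fits whose signal optimization did
#' not converge are excluded from pooling and reported as an attrition
#' rate: a failed optimum is not a valid imputation draw.
#'
#' @param fits An `ensemble_fits` data frame from [fit_ensemble()].
#' @param small_sample Passed to [rubin_pool()].
#' @return Data frame (class `pooled_table`): one row per topology plus a
#'   `"all"` row, with m, pooled intercept and slope, slope CI, mean
#'   signal; the attrition rate is attached as an attribute.
#' @export
pool_by_topology <- function(fits, small_sample = FALSE) {
  used <- fits[fits$converged, , drop = FALSE]
  attrition <- 1 - nrow(used) / nrow(fits)
  groups <- c(split(used, used$topology), list(all = used))
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    if (nrow(d) < 2) stop("topology '", g, "' has fewer than 2 converged fits")
    ps <- rubin_pool(d$slope, d$se_slope^2, small_sample = small_sample)
    pa <- rubin_pool(d$intercept, d$se_intercept^2, small_sample = small_sample)
    data.frame(topology = g, m = ps$m,
               intercept = pa$qbar, intercept_lo = pa$ci[1], intercept_hi = pa$ci[2],
               slope = ps$qbar, slope_lo = ps$ci[1], slope_hi = ps$ci[2],
               slope_se = ps$se, signal_mean = mean(d$signal))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "attrition") <- attrition
  attr(out, "model") <- attr(fits, "model")
  class(out) <- c("pooled_table", "data.frame")
  out
}

#' @export
print.pooled_table <- function(x, digits = 4, ...) {
  cat("Pooled allometric regression (", attr(x, "model") %||% "?", " model)\n",
      sep = "")
  df <- as.data.frame(x)
  df$slope_ci <- sprintf("(%.3f, %.3f)", x$slope_lo, x$slope_hi)
  print(format(df[, c("topology", "m", "intercept", "slope", "slope_ci",
                      "signal_mean")], digits = digits), row.names = FALSE)
  if ((attr(x, "attrition") %||% 0) > 0) {
    cat(sprintf("attrition: %.1f%% of fits excluded (signal estimation failed)\n",
                100 * attr(x, "attrition")))
  }
  invisible(x)
}
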