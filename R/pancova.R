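#' Phylogenetic ANCOVA F-test for a clade's deviation from the main trend
#'
#' Compares nested generalized least squares mean structures sharing one
#' covariance matrix: the null design `[1, x]` against the full design
#' adding a clade indicator and its interaction with the predictor
#' (`terms = "both"`, q = 2), or only the intercept / only the slope term.
#' The statistic is computed in the whitened space,
#' \deqn{F = \frac{(RSS_0 - RSS_1)/q}{RSS_1/(n - p_1)},}
#' and referred to the F distribution with (q, n - p1) df. With the
#' identity covariance this is the classical ANCOVA group test.
#'
#' @param y Response vector.
#' @param x Predictor vector.
#' @param V Covariance matrix shared by both models (`NULL` = identity).
#' @param group Logical or 0/1 vector: clade membership per observation.
#' @param terms Which group terms to test: `"both"` (default),
#'   `"intercept"`, `"slope"`.
#' @return List with `F`, `p`, `df_num`, `df_den`, `rss0`, `rss1`.
#' @export
pancova_f_test <- function(y, x, V = NULL, group,
                           terms = c("both", "intercept", "slope")) {
  terms <- match.arg(terms)
  g <- as.numeric(group)
  n <- length(y)
  if (sum(g) < 2 || sum(g) > n - 2) {
    stop("group must have at least 2 members and 2 non-members")
  }
  if (is.null(V)) V <- diag(n)
  X0 <- cbind(1, x)
  X1 <- switch(terms,
               both = cbind(1, x, g, g * x),
               intercept = cbind(1, x, g),
               slope = cbind(1, x, g * x))
  e0 <- gls_engine(y, X0, V)
  e1 <- gls_engine(y, X1, V)
  q <- ncol(X1) - ncol(X0)
  diff <- e0$rss - e1$rss
  # numerically-zero improvements (noiseless data) must give F = 0, p = 1
  if (!is.finite(diff) || diff < 1e-10 * max(e0$rss, .Machine$double.eps)) {
    diff <- 0
  }
  Fstat <- if (e1$rss <= 0) {
    if (diff > 0) Inf else 0
  } else {
    (diff / q) / (e1$rss / (n - ncol(X1)))
  }
  p <- stats::pf(Fstat, q, n - ncol(X1), lower.tail = FALSE)
  list(F = Fstat, p = p, df_num = q, df_den = n - ncol(X1),
       rss0 = e0$rss, rss1 = e1$rss)
}

#' Combine dependent p-values from tests on alternative trees
#'
#' The same data tested on many candidate trees yields strongly dependent
#' p-values; naive combination overstates the evidence. The default is a
#' dependence-corrected Stouffer combination: with \eqn{z_i =
#' \Phi^{-1}(1-p_i)} and mean pairwise correlation \eqn{\bar\rho} of the
#' z-scores,
#' \deqn{\bar z = \frac{\sum z_i}{\sqrt{m + m(m-1)\bar\rho}},}
#' referred to the standard normal. At \eqn{\bar\rho = 1} (perfect
#' dependence) identical p-values pass through unchanged; at
#' \eqn{\bar\rho = 0} the combination reduces to the classical independent
#' Stouffer rule. The harmonic-mean p-value is offered as a
#' dependence-robust alternative for sensitivity analysis.
#'
#' @param pvals Vector of p-values in (0, 1]; exact zeros are clipped to
#'   the smallest positive double with a warning.
#' @param rho Mean pairwise z-score correlation in \[0, 1\]. Estimate it
#'   with [estimate_tree_dependence()] when replicate tests are available;
#'   the default 0.5 is a deliberately middle-of-the-road value for trees
#'   that share most of their structure.
#' @param method `"stouffer"` (default) or `"harmonic"`.
#' @return A single pooled p-value.
#' @export
pool_dependent_pvalues <- function(pvals, rho = 0.5,
                                   method = c("stouffer", "harmonic")) {
  method <- match.arg(method)
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  if (any(pvals == 0)) {
    warning("p-value of 0 clipped to the smallest positive double")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  m <- length(pvals)
  if (m == 1) return(pvals)
  if (method == "harmonic") return(min(1, m / sum(1 / pvals)))
  rho <- min(1, max(0, rho))
  z <- stats::qnorm(pmin(pvals, 1 - 1e-16), lower.tail = FALSE)
  zbar <- sum(z) / sqrt(m + m * (m - 1) * rho)
  stats::pnorm(zbar, lower.tail = FALSE)
}

#' Estimate the mean between-tree dependence of test z-scores
#'
#' Given a matrix of z-scores with one row per tree and one column per
#' replicate test (e.g. the candidate clades tested on that tree), returns
#' the mean pairwise correlation between trees, computed across the
#' replicates and clipped to \[0, 1\].
#'
#' @param zmat Numeric matrix, trees x replicate tests (needs >= 2 columns).
#' @return Scalar mean correlation, or `NA` if not estimable.
#' @export
estimate_tree_dependence <- function(zmat) {
  if (is.null(dim(zmat)) || ncol(zmat) < 2 || nrow(zmat) < 2) return(NA_real_)
  keep <- apply(zmat, 1, function(r) all(is.finite(r)) && stats::sd(r) > 0)
  if (sum(keep) < 2) return(NA_real_)
  cc <- stats::cor(t(zmat[keep, , drop = FALSE]))
  min(1, max(0, mean(cc[lower.tri(cc)])))
}

# Fit the null allometry once per tree (shared across candidate clades) and
# return, per topology, the per-tree p-values of every clade's F-test.
pancova_over_ensemble <- function(specimens, ensemble, clades,
                                  subset_size = 200, terms = "both",
                                  method = "REML", eps = 1e-6,
                                  model = c("lambda", "OU")) {
  model <- match.arg(model)
  lapply(seq_along(ensemble), function(ti) {
    trees <- ensemble[[ti]][seq_len(min(subset_size, length(ensemble[[ti]])))]
    pm <- matrix(NA_real_, length(trees), length(clades),
                 dimnames = list(NULL, clades))
    fm <- pm
    for (k in seq_along(trees)) {
      tr <- apply_branch_epsilon(ape::keep.tip(trees[[k]], specimens$specimen_id),
                                 eps)
      ord <- match(tr$tip.label, specimens$specimen_id)
      y <- specimens$log_hl[ord]
      x <- specimens$log_fl[ord]
      null_fit <- if (model == "lambda") {
        fit_lambda_internal(y, cbind(1, x), bm_covariance(tr), method)
      } else {
        fit_ou_internal(y, cbind(1, x), tr, method)
      }
      V <- null_fit$V
      for (cl in clades) {
        g <- in_clade(specimens, cl)[ord]
        if (sum(g) < 2 || sum(g) > length(g) - 2) next
        ft <- tryCatch(pancova_f_test(y, x, V, g, terms = terms),
                       error = function(e) NULL)
        if (!is.null(ft)) {
          pm[k, cl] <- ft$p
          fm[k, cl] <- ft$F
        }
      }
    }
    list(p = pm, F = fm)
  })
}

#' Test candidate clades for deviation from the main allometric trend
#'
#' For each topology, runs the phylogenetic ANCOVA of [pancova_f_test()] on
#' a deterministic subset of trees (the first `subset_size` per topology),
#' sharing per tree a single null-model signal estimate across all
#' candidate clades, then pools the per-tree p-values per clade and
#' topology with [pool_dependent_pvalues()]. The between-tree dependence is
#' estimated empirically from the z-scores across candidate clades when
#' at least two clades are testable.
#'
#' @param specimens A `specimen_table`.
#' @param ensemble A `tree_ensemble` with specimen-level tips (supersets of
#'   the specimen table are pruned per tree).
#' @param clades Character vector of candidate clade labels.
#' @param subset_size Trees used per topology (default 200).
#' @param threshold Significance level for the `consistent` call.
#' @param terms,method,eps,model Passed to the underlying fits.
#' @return Data frame (class `deviation_tests`): clade, topology, m_trees,
#'   median F, pooled_p, plus a `consistent` logical per clade (significant
#'   in every topology) in attribute and merged column.
#' @export
clade_deviation_tests <- function(specimens, ensemble, clades,
                                  subset_size = 200, threshold = 0.05,
                                  terms = "both", method = "REML",
                                  eps = 1e-6, model = "lambda") {
  res <- pancova_over_ensemble(specimens, ensemble, clades, subset_size,
                               terms, method, eps, model)
  rows <- list()
  for (ti in seq_along(res)) {
    pm <- res[[ti]]$p
    zm <- stats::qnorm(pmin(pmax(pm, .Machine$double.xmin), 1 - 1e-16),
                       lower.tail = FALSE)
    rho <- estimate_tree_dependence(zm)
    if (is.na(rho)) rho <- 0.5
    for (cl in clades) {
      pv <- pm[, cl]
      pv <- pv[!is.na(pv)]
      rows[[length(rows) + 1L]] <- data.frame(
        clade = cl, topology = ti, m_trees = length(pv),
        median_F = if (length(pv)) stats::median(res[[ti]]$F[, cl], na.rm = TRUE)
                   else NA_real_,
        rho = rho,
        pooled_p = if (length(pv) >= 1) pool_dependent_pvalues(pv, rho)
                   else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  cons <- tapply(out$pooled_p < threshold, out$clade,
                 function(v) all(!is.na(v)) && all(v))
  out$consistent <- as.logical(cons[out$clade])
  rownames(out) <- NULL
  class(out) <- c("deviation_tests", "data.frame")
  out
}

#' Iteratively exclude clades deviating from the main allometric trend
#'
#' Each round tests every remaining candidate clade with
#' [clade_deviation_tests()]; clades significant consistently across all
#' topologies are removed from the dataset, the main regression is
#' refitted on the remainder, and the procedure repeats until a round
#' excludes nothing. Clades reduced to fewer than 2 testable members are
#' skipped (a single data point cannot be tested and must be handled as a
#' forced exclusion if deemed aberrant, as with highly specialized
#' single-specimen taxa).
#'
#' @inheritParams clade_deviation_tests
#' @param forced_exclusions Species names removed before round 1 without
#'   testing (e.g. single-specimen taxa with extreme specialization).
#' @param min_remaining Abort if an exclusion would leave fewer specimens
#'   than this (default 10).
#' @return List of class `exclusion_result`: `kept` (final specimen
#'   table), `rounds` (per round: the `deviation_tests` table and the
#'   clades excluded), `excluded_clades`, `final_fits` (per-tree fits on
#'   the kept set over the subset trees), `final_pool` (pooled table).
#' @export
iterative_exclusion <- function(specimens, ensemble, clades,
                                threshold = 0.05, subset_size = 200,
                                terms = "both", method = "REML", eps = 1e-6,
                                model = "lambda", forced_exclusions = NULL,
                                min_remaining = 10) {
  if (length(clades) == 0) stop("clade list must be non-empty")
  current <- specimens
  if (!is.null(forced_exclusions)) {
    current <- current[!current$species %in% forced_exclusions, , drop = FALSE]
  }
  remaining <- clades
  rounds <- list()
  excluded <- character(0)
  repeat {
    testable <- remaining[vapply(remaining, function(cl) {
      k <- sum(in_clade(current, cl))
      k >= 2 && k <= nrow(current) - 2
    }, logical(1))]
    if (length(testable) == 0) break
    tests <- clade_deviation_tests(current, ensemble, testable,
                                   subset_size = subset_size,
                                   threshold = threshold, terms = terms,
                                   method = method, eps = eps, model = model)
    hits <- unique(tests$clade[tests$consistent])
    rounds[[length(rounds) + 1L]] <- list(tests = tests, excluded = hits)
    if (length(hits) == 0) break
    drop_rows <- Reduce(`|`, lapply(hits, in_clade, specimens = current))
    if (nrow(current) - sum(drop_rows) < min_remaining) {
      stop("excluding ", paste(hits, collapse = ", "), " would leave only ",
           nrow(current) - sum(drop_rows), " specimens (< ", min_remaining, ")")
    }
    current <- current[!drop_rows, , drop = FALSE]
    excluded <- c(excluded, hits)
    remaining <- setdiff(remaining, hits)
  }
  sub_ens <- lapply(ensemble, function(trs) {
    lapply(trs[seq_len(min(subset_size, length(trs)))],
           function(tr) ape::keep.tip(tr, current$specimen_id))
  })
  class(sub_ens) <- "tree_ensemble"
  fits <- fit_ensemble(current, sub_ens, model = if (model == "lambda") "lambda"
                       else "OU", method = method)
  structure(list(kept = current, rounds = rounds, excluded_clades = excluded,
                 forced_exclusions = forced_exclusions,
                 final_fits = fits, final_pool = pool_by_topology(fits)),
            class = "exclusion_result")
}

#' @export
print.exclusion_result <- function(x, ...) {
  cat("Iterative clade exclusion:", length(x$rounds), "round(s)\n")
  if (length(x$forced_exclusions)) {
    cat("forced exclusions:", paste(x$forced_exclusions, collapse = ", "), "\n")
  }
  if (length(x$excluded_clades)) {
    cat("excluded clades:", paste(x$excluded_clades, collapse = ", "), "\n")
  } else cat("no clade consistently deviated from the main trend\n")
  cat("kept specimens:", nrow(x$kept), "\n\nfinal pooled regression:\n")
  print(x$final_pool)
  invisible(x)
}

#' Pooled PGLS regressions within each candidate clade
#'
#' Fits the allometry separately inside every clade on its induced subtree
#' ensemble and pools across trees. Small clades rarely support lambda
#' estimation: when fewer than half of a clade's per-tree fits yield an
#' interior, converged lambda estimate, the clade is instead reported with
#' the two bracketing fixed-signal fits — lambda = 1 (pure Brownian) and
#' lambda = 0 (ordinary least squares) — covering the full range of
#' possible phylogenetic weighting.
#'
#' @param specimens A `specimen_table`.
#' @param ensemble A `tree_ensemble` with specimen-level tips.
#' @param clades Candidate clade labels.
#' @param min_n Minimum specimens per clade (default 3); smaller clades
#'   produce a `skipped` row.
#' @param subset_size Trees per topology to fit (default all).
#' @param method `"REML"` or `"ML"`.
#' @return Data frame: clade, n, fit type (`estimated_lambda`,
#'   `fixed_lambda_1`, `fixed_lambda_0`, or `skipped`), pooled intercept
#'   and slope with CI, mean signal.
#' @export
per_clade_regressions <- function(specimens, ensemble, clades, min_n = 3,
                                  subset_size = Inf, method = "REML") {
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  for (cl in clades) {
    members <- specimens[in_clade(specimens, cl), , drop = FALSE]
    if (nrow(members) < min_n) {
      add(data.frame(clade = cl, n = nrow(members), fit = "skipped",
                     intercept = NA_real_, slope = NA_real_,
                     slope_lo = NA_real_, slope_hi = NA_real_,
                     signal_mean = NA_real_))
      next
    }
    sub_ens <- lapply(ensemble, function(trs) {
      lapply(trs[seq_len(min(subset_size, length(trs)))],
             function(tr) ape::keep.tip(tr, members$specimen_id))
    })
    class(sub_ens) <- "tree_ensemble"
    fits <- fit_ensemble(members, sub_ens, model = "lambda", method = method)
    interior <- fits$converged & !fits$signal_fixed &
      fits$signal > 1e-6 & fits$signal < 1 - 1e-6
    if (mean(interior) >= 0.5) {
      pool <- pool_by_topology(fits[interior, , drop = FALSE])
      tot <- pool[pool$topology == "all", ]
      add(data.frame(clade = cl, n = nrow(members), fit = "estimated_lambda",
                     intercept = tot$intercept, slope = tot$slope,
                     slope_lo = tot$slope_lo, slope_hi = tot$slope_hi,
                     signal_mean = tot$signal_mean))
    } else {
      bm_fits <- fit_ensemble(members, sub_ens, model = "BM", method = method)
      pool1 <- pool_by_topology(bm_fits)
      tot1 <- pool1[pool1$topology == "all", ]
      add(data.frame(clade = cl, n = nrow(members), fit = "fixed_lambda_1",
                     intercept = tot1$intercept, slope = tot1$slope,
                     slope_lo = tot1$slope_lo, slope_hi = tot1$slope_hi,
                     signal_mean = 1))
      f0 <- pgls_allom(log_hl ~ log_fl, members, model = "OLS")
      add(data.frame(clade = cl, n = nrow(members), fit = "fixed_lambda_0",
                     intercept = f0$coefficients[1], slope = f0$coefficients[2],
                     slope_lo = f0$ci[2, 1], slope_hi = f0$ci[2, 2],
                     signal_mean = 0))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
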