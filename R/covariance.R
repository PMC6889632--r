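#' Brownian-motion covariance of tip values on a time tree
#'
#' Under Brownian motion the covariance between two tips is the total path
#' length shared on their way from the root, i.e. the depth (below the
#' root) of their most recent common ancestor; the diagonal holds each
#' tip's root-to-tip depth. The matrix is returned up to the profiled
#' Brownian rate \eqn{\sigma^2}, which is estimated by the regression.
#'
#' @param tree A rooted `phylo` with branch lengths (My).
#' @return A `phylo_cov` object: the tip-by-tip matrix with attributes
#'   `model = "BM"` and `tip_order`.
#' @export
bm_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  n <- length(tree$tip.label)
  ntot <- n + tree$Nnode
  depth <- numeric(ntot)           # path length from root
  # cladewise (preorder) walk: parent depth known before child
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    depth[ord$edge[e, 2]] <- depth[ord$edge[e, 1]] + ord$edge.length[e]
  }
  mrca <- ape::mrca(tree)
  V <- matrix(depth[mrca], n, n)
  diag(V) <- depth[seq_len(n)]
  dimnames(V) <- list(tree$tip.label, tree$tip.label)
  new_phylo_cov(V, model = "BM", parameter = NA_real_)
}

new_phylo_cov <- function(V, model, parameter) {
  structure(V, model = model, parameter = parameter,
            class = c("phylo_cov", "matrix", "array"))
}

#' Pagel's lambda transform of a Brownian-motion covariance
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged: `lambda = 1` returns the pure Brownian structure, `lambda =
#' 0` an independent (diagonal) one, intermediate values down-weight the
#' phylogenetic covariance.
#'
#' @param cov A `phylo_cov` from [bm_covariance()].
#' @param lambda Signal multiplier in \[0, 1\].
#' @return A `phylo_cov` with `model = "lambda"`.
#' @export
lambda_transform <- function(cov, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]")
  }
  d <- diag(cov)
  V <- unclass(cov) * lambda
  diag(V) <- d
  new_phylo_cov(V, model = "lambda", parameter = lambda)
}

#' Ornstein-Uhlenbeck covariance on a (possibly non-ultrametric) time tree
#'
#' Assumes the process is at stationarity at the root. With \eqn{s_{ij}}
#' the root-to-MRCA depth and \eqn{d_{ij}} the patristic distance between
#' tips \eqn{i} and \eqn{j}, the covariance is
#' \deqn{V_{ij} = \frac{1}{2\alpha} e^{-\alpha d_{ij}}
#'       \left(1 - e^{-2\alpha s_{ij}}\right),}
#' which converges entrywise to the Brownian covariance \eqn{s_{ij}} as
#' \eqn{\alpha \to 0} and decorrelates tips at rate \eqn{\alpha} with
#' patristic distance. The scale \eqn{\sigma^2} is profiled out downstream.
#'
#' @param tree A rooted `phylo` with branch lengths (My).
#' @param alpha Attraction strength (> 0), per My.
#' @return A `phylo_cov` with `model = "OU"`.
#' @export
ou_covariance <- function(tree, alpha) {
  ou_cov_from_geometry(tree_geometry(tree), alpha)
}

# shared-depth and patristic-distance matrices, computed once per tree so
# that repeated OU evaluations during alpha optimization stay cheap
tree_geometry <- function(tree) {
  s <- unclass(bm_covariance(tree))
  depths <- diag(s)
  list(s = s, d = outer(depths, depths, "+") - 2 * s)
}

ou_cov_from_geometry <- function(geom, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) {
    stop("alpha must be a single value > 0")
  }
  V <- exp(-alpha * geom$d) * (1 - exp(-2 * alpha * geom$s)) / (2 * alpha)
  dimnames(V) <- dimnames(geom$s)
  new_phylo_cov(V, model = "OU", parameter = alpha)
}

#' Cholesky factor of a phylogenetic covariance, with a clear failure mode
#'
#' @param V A covariance matrix.
#' @return Upper-triangular Cholesky factor.
#' @keywords internal
chol_or_fail <- function(V) {
  U <- tryCatch(chol(V), error = function(e) {
    stop("covariance matrix is not positive definite (zero-length ",
         "conspecific branches? see apply_branch_epsilon): ",
         conditionMessage(e), call. = FALSE)
  })
  # base chol can "succeed" on an exactly singular matrix through a
  # rounding-noise pivot; refuse rather than silently regularize
  tol <- nrow(V) * .Machine$double.eps * max(diag(V))
  if (any(diag(U)^2 < tol)) {
    stop("covariance matrix is numerically singular (zero-length ",
         "conspecific branches? see apply_branch_epsilon)", call. = FALSE)
  }
  U
}

#' @export
print.phylo_cov <- function(x, ...) {
  cat(sprintf("phylogenetic covariance (%s%s), %d tips\n",
              attr(x, "model"),
              if (!is.na(attr(x, "parameter")))
                paste0(", parameter = ", signif(attr(x, "parameter"), 4)) else "",
              nrow(x)))
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x))), drop = FALSE])
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}
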