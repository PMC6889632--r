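# Small programmatic fixtures shared across test files.

# hand-built specimen table: 3 species, one with 3 specimens incl. a juvenile
make_test_specimens <- function() {
  as_specimen_table(data.frame(
    specimen_id = c("Aa_1", "Aa_2", "Aa_3", "Bb_1", "Cc_1"),
    species = c("Allo_alpha", "Allo_alpha", "Allo_alpha", "Beta_beta", "Gamma_c"),
    genus = c("Allo", "Allo", "Allo", "Beta", "Gamma"),
    clades = c("CladeX", "CladeX", "CladeX", "CladeX;CladeY", ""),
    fl_mm = c(150, 120, 90, 300, 45),
    hl_mm = c(100, 85, 70, 180, 40),
    age_min_ma = c(150, 150, 148, 120, 200),
    age_max_ma = c(155, 155, 152, 125, 205),
    onto_status = c("adult", "subadult", "juvenile", "adult", "unknown"),
    stringsAsFactors = FALSE))
}

# a calibrated random tree with total depth scaled to `depth` My
make_test_tree <- function(n, depth = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * depth
  tr
}

# species-level traits drawn under the fitted model's exact generative twin
draw_traits <- function(tree, a0 = 0.1, b0 = 0.9, lambda0 = 0.93,
                        sigma0 = 0.1, x_root = 2.5, x_rate = 0.001) {
  cfg <- sim_config(a0 = a0, b0 = b0, lambda0 = lambda0, sigma0 = sigma0,
                    x_root = x_root, x_rate = x_rate)
  simulate_traits(tree, cfg)
}

# independent brute-force oracle: BM covariance entry = summed length of the
# shared root-to-tip path prefix, via ape::nodepath (never used by the
# implementation, which works from MRCA depths)
bm_oracle <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  elen <- numeric(n + tree$Nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(n), function(i) ape::nodepath(tree, root, i))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      pi <- paths[[i]][-1]
      pj <- paths[[j]][-1]
      k <- 0
      while (k < min(length(pi), length(pj)) && pi[k + 1] == pj[k + 1]) k <- k + 1
      if (k > 0) V[i, j] <- sum(elen[pi[seq_len(k)]])
    }
  }
  V
}

# whitened-OLS oracle for GLS estimates
whitened_ols_oracle <- function(y, x, V) {
  Linv <- solve(t(chol(V)))
  fit <- stats::lm.fit(Linv %*% cbind(1, x), as.numeric(Linv %*% y))
  fit$coefficients
}

# canonical signature of a rooted topology: sorted set of tip-sets per clade
topology_signature <- function(tree) {
  n <- length(tree$tip.label)
  clades <- vapply((n + 1L):(n + tree$Nnode), function(node) {
    tips <- tree$tip.label[phylallom:::descendant_tips(tree, node)]
    paste(sort(tips), collapse = "|")
  }, character(1))
  paste(sort(clades), collapse = ";")
}
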