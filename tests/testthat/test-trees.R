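test_that("Newick parsing and writing behave and round-trip", {
  tr <- read_topology("((A,B),C);")
  expect_equal(length(tr$tip.label), 3)
  expect_true(ape::is.binary(tr))

  poly <- read_topology("(A,B,C);")
  expect_equal(sum(tabulate(poly$edge[, 1]) == 3), 1)  # one degree-3 node

  expect_error(read_topology("((A,B,C;"), "malformed")

  tr2 <- read_topology("((A:1,B:1):1,C:2);")
  back <- read_topology(write_topology(tr2))
  expect_equal(ape::dist.nodes(back), ape::dist.nodes(tr2))
  expect_equal(sort(back$tip.label), sort(tr2$tip.label))
})

test_that("polytomy resolution is binary, tip- and bipartition-preserving", {
  set.seed(1)
  tr <- read_topology("((A,B,C,D),(E,F,G),H);")
  for (i in 1:20) {
    res <- resolve_polytomies(tr)
    expect_true(ape::is.binary(res))
    expect_setequal(res$tip.label, tr$tip.label)
    # every input clade survives as a clade
    expect_true(ape::is.monophyletic(res, c("A", "B", "C", "D")))
    expect_true(ape::is.monophyletic(res, c("E", "F", "G")))
  }
  # binary input is returned with identical topology
  bin <- read_topology("((A:1,B:1):1,C:2);")
  res <- resolve_polytomies(bin)
  expect_true(ape::all.equal.phylo(bin, res, use.edge.length = FALSE))
})

test_that("a 5-tip star resolves uniformly over all 105 rooted topologies", {
  set.seed(99)
  star <- read_topology("(A,B,C,D,E);")
  n_draws <- 10000
  sig <- character(n_draws)
  for (i in seq_len(n_draws)) {
    sig[i] <- topology_signature(resolve_polytomies(star))
  }
  counts <- table(sig)
  expect_equal(length(counts), 105)
  p <- 1 / 105
  band <- 3 * sqrt(p * (1 - p) / n_draws)
  expect_true(all(abs(counts / n_draws - p) < band + 1e-12))
})

test_that("calibration respects ages, ranges and the branch constant", {
  set.seed(3)
  tr <- resolve_polytomies(read_topology("(A,B,C,(D,E));"))
  ages <- data.frame(tip = c("A", "B", "C", "D", "E"),
                     age_min_ma = c(100, 95, 90, 80, 70),
                     age_max_ma = c(105, 99, 95, 85, 75))
  cp <- calibration_params(0.1, 0.05)
  for (i in 1:20) {
    ct <- calibrate_tree(resolve_polytomies(read_topology("(A,B,C,(D,E));")),
                         ages, cp)
    na <- attr(ct, "node_ages")
    n <- length(ct$tip.label)
    # tip ages inside their stratigraphic windows
    idx <- match(ages$tip, ct$tip.label)
    expect_true(all(na[idx] >= ages$age_min_ma & na[idx] <= ages$age_max_ma))
    # every parent older than its child, every branch >= the +1 constant
    expect_true(all(na[ct$edge[, 1]] > na[ct$edge[, 2]]))
    expect_true(all(ct$edge.length >= cp$branch_constant))
    expect_gt(na[n + 1], 100)  # root older than the oldest tip
  }

  # two point-age tips: root age exceeds the older tip
  cherry <- read_topology("(X,Y);")
  a2 <- data.frame(tip = c("X", "Y"), age_min_ma = c(100, 90),
                   age_max_ma = c(100, 90))
  ct2 <- calibrate_tree(cherry, a2, cp)
  expect_gt(attr(ct2, "node_ages")[3], 100)
  expect_true(all(ct2$edge.length > 0))

  # uniform null mode: every branch length exactly 1
  cu <- calibrate_tree(cherry, a2, calibration_params(0.1, 0.05, mode = "uniform"))
  expect_equal(cu$edge.length, c(1, 1))

  # errors: no usable ages at all; bad rates
  expect_error(calibration_params(-1, 0.05), "rates")
})

test_that("node-age offsets are exponential with the combined rate", {
  set.seed(11)
  cp <- calibration_params(sampling_rate = 0.08, extinction_rate = 0.05,
                           birth_rate = 0.05)
  r <- with(cp, sampling_rate + extinction_rate + birth_rate)
  cherry <- read_topology("(X,Y);")
  a2 <- data.frame(tip = c("X", "Y"), age_min_ma = c(100, 100),
                   age_max_ma = c(100, 100))
  n_rep <- 4000
  deltas <- vapply(seq_len(n_rep), function(i) {
    attr(calibrate_tree(cherry, a2, cp), "node_ages")[3] - 100
  }, numeric(1))
  # mean of Exp(r) is 1/r; allow 3 standard errors
  expect_lt(abs(mean(deltas) - 1 / r), 3 * (1 / r) / sqrt(n_rep))
  expect_true(all(deltas > 0))
})

test_that("missing tip ages fall back to sisters, then the whole tree", {
  set.seed(5)
  tr <- resolve_polytomies(read_topology("((A,B),C);"))
  ages <- data.frame(tip = c("A", "C"), age_min_ma = c(100, 90),
                     age_max_ma = c(100, 90))
  cp <- calibration_params(0.1, 0.05)
  expect_message(ct <- calibrate_tree(tr, ages, cp), "sister")
  expect_true(all(ct$edge.length > 0))
})

test_that("conspecific expansion creates zero-length specimen polytomies", {
  set.seed(7)
  tr <- calibrate_tree(
    resolve_polytomies(read_topology("((A,B),C);")),
    data.frame(tip = c("A", "B", "C"), age_min_ma = c(90, 85, 80),
               age_max_ma = c(95, 90, 85)),
    calibration_params(0.1, 0.05))
  ex <- expand_conspecific_tips(tr, list(A = c("A_s1", "A_s2", "A_s3"),
                                         B = "B_s1"))
  expect_equal(length(ex$tip.label), 5)  # 3 + 1 + unmapped C
  expect_setequal(ex$tip.label, c("A_s1", "A_s2", "A_s3", "B_s1", "C"))
  d <- ape::cophenetic.phylo(ex)
  expect_equal(d["A_s1", "A_s2"], 0)
  expect_equal(d["A_s1", "A_s3"], 0)
  # single-specimen species only relabeled; patristic structure unchanged
  expect_equal(d["B_s1", "C"], ape::cophenetic.phylo(tr)["B", "C"])

  # all species single-specimen: topology unchanged
  ex1 <- expand_conspecific_tips(tr, list(A = "a1", B = "b1", C = "c1"))
  expect_equal(ape::cophenetic.phylo(ex1)[c("a1","b1","c1"), c("a1","b1","c1")],
               ape::cophenetic.phylo(tr)[c("A","B","C"), c("A","B","C")],
               ignore_attr = TRUE)

  expect_error(expand_conspecific_tips(tr, list(Zz = "z1")), "absent")
})

test_that("epsilon policy nudges only zero-length terminal branches", {
  tr <- read_topology("((A:0,B:0):1,C:2);")
  out <- apply_branch_epsilon(tr, 1e-6)
  n <- length(tr$tip.label)
  term <- out$edge[, 2] <= n
  expect_true(all(out$edge.length[term] > 0))
  expect_equal(sort(out$edge.length), sort(c(1e-6, 1e-6, 1, 2)))
})

test_that("ensemble generation is seeded, sized and topology-preserving", {
  sp <- make_test_specimens()
  ages <- species_age_ranges(sp)
  base <- read_topology("(Allo_alpha,Beta_beta,Gamma_c);")
  cp <- calibration_params(0.1, 0.05)
  smap <- split(sp$specimen_id, sp$species)

  e1 <- generate_tree_ensemble(list(base, base), 4, ages, cp, smap, seed = 42)
  e2 <- generate_tree_ensemble(list(base, base), 4, ages, cp, smap, seed = 42)
  expect_length(e1, 2)
  expect_length(e1[[1]], 4)
  expect_equal(lapply(e1, function(l) lapply(l, write_topology)),
               lapply(e2, function(l) lapply(l, write_topology)))
  # specimen-level tips, all branches positive path to root
  tr <- e1[[1]][[1]]
  expect_setequal(tr$tip.label, sp$specimen_id)
  expect_true(all(ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)] > 0))
})
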