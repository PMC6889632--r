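#' Read and write tree topologies
#'
#' Thin validated wrappers around [ape::read.tree()] / [ape::write.tree()].
#' Input may contain polytomies and need not have branch lengths.
#'
#' @param text A Newick string, or `NULL` if `file` is given.
#' @param file Path to a Newick file (one or more trees).
#' @return A `phylo` object (or `multiPhylo` when the file holds several).
#' @export
read_topology <- function(text = NULL, file = NULL) {
  tr <- tryCatch(
    if (!is.null(file)) ape::read.tree(file) else ape::read.tree(text = text),
    error = function(e) stop("malformed Newick: ", conditionMessage(e)),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w))
  )
  if (is.null(tr)) stop("malformed Newick: parser returned no tree")
  tr
}

#' @rdname read_topology
#' @param tree A `phylo` object.
#' @export
write_topology <- function(tree, file = NULL) {
  if (is.null(file)) ape::write.tree(tree) else ape::write.tree(tree, file = file)
}

#' Randomly resolve all polytomies of a rooted tree
#'
#' Every polytomy is dichotomized stochastically: the subtrees hanging off a
#' degree-\eqn{c} node are reassembled into a rooted binary arrangement drawn
#' uniformly at random among all \eqn{(2c-3)!!} labeled resolutions, by
#' stepwise insertion onto a uniformly chosen branch. Newly created internal
#' branches get length 0 (they acquire positive duration later, during
#' calibration); existing branch lengths and all input bipartitions are
#' preserved, as is the tip set. Binary input is returned unchanged.
#'
#' Uses the R random number generator; seed with [set.seed()] for
#' reproducibility.
#'
#' @param tree A rooted `phylo` object, possibly with polytomies.
#' @return A strictly binary `phylo`.
#' @export
resolve_polytomies <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  # the Newick hierarchy defines the root; a basal polytomy is legitimate
  has_len <- !is.null(tree$edge.length)
  nodes <- as_node_list(tree)
  resolved <- resolve_node(nodes, has_len)
  txt <- paste0(deparse_node(resolved, has_len), ";")
  out <- ape::read.tree(text = txt)
  out
}

# phylo -> nested list(label|children, length)
as_node_list <- function(tree) {
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(n + tree$Nnode)))
  elen <- if (!is.null(tree$edge.length)) tree$edge.length else rep(NA_real_, nrow(tree$edge))
  len_of <- numeric(n + tree$Nnode)
  len_of[tree$edge[, 2]] <- elen
  build <- function(node) {
    if (node <= n) {
      list(label = tree$tip.label[node], length = len_of[node])
    } else {
      list(children = lapply(kids[[node]], build), length = len_of[node])
    }
  }
  root <- n + 1L
  b <- build(root)
  b$length <- NA_real_
  b
}

# uniform rooted binary arrangement of k subtrees via stepwise insertion.
# The arrangement is grown over atomic placeholder leaves so that insertion
# never descends into (and never breaks) the subtrees themselves; the
# placeholders are substituted at the end.
combine_uniform <- function(items) {
  k <- length(items)
  cur <- list(children = list(list(leaf = 1L), list(leaf = 2L)), length = 0)
  if (k > 2) {
    for (m in 3:k) {
      # sister positions: every existing node (2(m-1)-1 of them incl. root)
      pos <- sample.int(2L * (m - 1L) - 1L, 1L)
      cur <- insert_leaf(cur, m, pos)$tree
    }
  }
  substitute_leaves(cur, items)
}

# insert placeholder `idx` as sister to the `pos`-th node in preorder;
# pos == 1 at the root means "above the root"
insert_leaf <- function(node, idx, pos) {
  if (pos == 1L) {
    return(list(tree = list(children = list(node, list(leaf = idx)),
                            length = 0), pos = 0L))
  }
  pos <- pos - 1L
  if (!is.null(node$children)) {
    for (i in seq_along(node$children)) {
      res <- insert_leaf(node$children[[i]], idx, pos)
      pos <- res$pos
      if (pos == 0L) {
        node$children[[i]] <- res$tree
        return(list(tree = node, pos = 0L))
      }
    }
  }
  list(tree = node, pos = pos)
}

substitute_leaves <- function(node, items) {
  if (!is.null(node$leaf)) return(items[[node$leaf]])
  node$children <- lapply(node$children, substitute_leaves, items = items)
  node
}

resolve_node <- function(node, has_len) {
  if (is.null(node$children)) return(node)
  node$children <- lapply(node$children, resolve_node, has_len = has_len)
  while (length(node$children) > 2) {
    sub <- combine_uniform(node$children)
    # sub is a binary arrangement rooted where the polytomy was
    sub$length <- node$length
    node <- sub
  }
  node
}

deparse_node <- function(node, has_len) {
  if (is.null(node$children)) {
    core <- node$label
  } else {
    core <- paste0("(", paste(vapply(node$children, deparse_node, character(1),
                                     has_len = has_len), collapse = ","), ")")
  }
  if (has_len && !is.na(node$length)) paste0(core, ":", format(node$length, digits = 15))
  else core
}

#' Calibration parameters for birth-death-sampling time-scaling
#'
#' Bundles the per-lineage rates (events per lineage per My) used when
#' drawing node ages. Following the common assumption for wholly extinct
#' clades, the diversification (birth) rate defaults to the extinction rate.
#' The sampling rate is a required input: it is clade- and study-specific
#' and must be supplied from the literature or estimated externally.
#'
#' @param sampling_rate Fossil sampling rate \eqn{\psi} (> 0).
#' @param extinction_rate Extinction rate \eqn{\mu} (> 0).
#' @param birth_rate Birth rate; defaults to `extinction_rate`.
#' @param branch_constant Constant (My) added to every branch after
#'   calibration so that zero-length branches created by polytomy
#'   resolution keep the base topology's node structure. Default 1.
#' @param mode `"stochastic"` for the birth-death-sampling draw or
#'   `"uniform"` for the null model in which every branch has length 1.
#' @return A list of class `calibration_params`.
#' @export
calibration_params <- function(sampling_rate, extinction_rate,
                               birth_rate = extinction_rate,
                               branch_constant = 1,
                               mode = c("stochastic", "uniform")) {
  mode <- match.arg(mode)
  if (mode == "stochastic") {
    if (any(c(sampling_rate, extinction_rate, birth_rate) <= 0)) {
      stop("all rates must be > 0 in stochastic mode")
    }
  }
  structure(list(sampling_rate = sampling_rate,
                 extinction_rate = extinction_rate,
                 birth_rate = birth_rate,
                 branch_constant = branch_constant,
                 mode = mode),
            class = "calibration_params")
}

#' Time-calibrate a binary tree from stratigraphic tip age ranges
#'
#' Draws each tip age uniformly within its stratigraphic range, then assigns
#' node ages from the tips towards the root: a node's age is the maximum of
#' its children's ages plus an offset drawn from an exponential distribution
#' with rate \eqn{b + \mu + \psi} (the combined birth, extinction and
#' sampling rate), so waiting times shrink when lineages are born, die or
#' are sampled frequently. Branch lengths become parent age minus child age
#' (guaranteed non-negative) and the branch constant is then added to every
#' branch. In `"uniform"` mode every branch is simply set to length 1.
#'
#' Tips missing from `age_ranges` fall back to the age range of their
#' sister tips, or failing that the whole-tree range, with a message.
#'
#' @param tree A binary rooted `phylo` (tips named as in `age_ranges$tip`).
#' @param age_ranges Data frame with columns `tip`, `age_min_ma`,
#'   `age_max_ma` (Ma).
#' @param params A [calibration_params()] object.
#' @return The tree with branch lengths in My; node ages (Ma) are attached
#'   as attribute `node_ages` (tips first, then internal nodes).
#' @export
calibrate_tree <- function(tree, age_ranges, params) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "calibration_params"))
  if (!ape::is.binary(tree)) stop("tree must be binary; resolve polytomies first")
  n <- length(tree$tip.label)

  if (params$mode == "uniform") {
    tree$edge.length <- rep(1, nrow(tree$edge))
    return(tree)
  }

  amin <- stats::setNames(age_ranges$age_min_ma, age_ranges$tip)
  amax <- stats::setNames(age_ranges$age_max_ma, age_ranges$tip)
  missing_tips <- setdiff(tree$tip.label, age_ranges$tip)
  if (length(missing_tips) > 0) {
    filled <- fill_missing_ages(tree, missing_tips, amin, amax)
    amin <- filled$amin
    amax <- filled$amax
  }
  if (any(is.na(amin[tree$tip.label])) || any(is.na(amax[tree$tip.label]))) {
    stop("no age range for tip(s): ",
         paste(tree$tip.label[is.na(amin[tree$tip.label])], collapse = ", "))
  }

  rate <- params$birth_rate + params$extinction_rate + params$sampling_rate
  ntot <- n + tree$Nnode
  kids <- split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(ntot)))
  age <- numeric(ntot)
  age[seq_len(n)] <- stats::runif(n, amin[tree$tip.label], amax[tree$tip.label])
  assign_age <- function(node) {
    if (node <= n) return(age[node])
    oldest_child <- max(vapply(kids[[node]], assign_age, numeric(1)))
    age[node] <<- oldest_child + stats::rexp(1, rate)
    age[node]
  }
  assign_age(n + 1L)
  tree$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]] + params$branch_constant
  attr(tree, "node_ages") <- age
  tree
}

fill_missing_ages <- function(tree, missing_tips, amin, amax) {
  for (tp in missing_tips) {
    i <- match(tp, tree$tip.label)
    parent <- tree$edge[tree$edge[, 2] == i, 1]
    sisters <- setdiff(tree$tip.label[unlist(descendant_tips(tree, parent))], tp)
    sisters <- sisters[sisters %in% names(amin)]
    if (length(sisters) > 0) {
      amin[tp] <- min(amin[sisters])
      amax[tp] <- max(amax[sisters])
      message("tip '", tp, "': age range taken from sister taxa")
    } else {
      known <- names(amin)[!is.na(amin)]
      if (length(known) == 0) stop("no age information available for tip '", tp, "'")
      amin[tp] <- min(amin[known])
      amax[tp] <- max(amax[known])
      message("tip '", tp, "': age range taken from the whole tree")
    }
  }
  list(amin = amin, amax = amax)
}

descendant_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, descendant_tips, tree = tree))
}

#' Replace multi-specimen species tips by zero-length polytomies
#'
#' Species represented by several specimens are attached to the tree as a
#' polytomy of specimen tips with branch length 0 hanging off the species'
#' terminal branch, so conspecific specimens share their full evolutionary
#' history and are down-weighted accordingly in generalized least squares.
#' Single-specimen species tips are relabeled to their specimen id.
#'
#' @param tree A calibrated `phylo` whose tips are species names.
#' @param species_to_specimens Named list: species name -> character vector
#'   of specimen ids. Species in the tree but absent from the map keep
#'   their label; mapped species missing from the tree are an error.
#' @return A `phylo` whose tips are specimen ids.
#' @export
expand_conspecific_tips <- function(tree, species_to_specimens) {
  stopifnot(inherits(tree, "phylo"))
  absent <- setdiff(names(species_to_specimens), tree$tip.label)
  if (length(absent) > 0) {
    stop("specimens mapped to species absent from the tree: ",
         paste(absent, collapse = ", "))
  }
  all_ids <- unlist(species_to_specimens, use.names = FALSE)
  bad <- grepl("[,();:\\[\\]' ]", c(all_ids, tree$tip.label))
  if (any(bad)) stop("labels must not contain Newick metacharacters or spaces")

  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(n + tree$Nnode)))
  elen <- if (!is.null(tree$edge.length)) tree$edge.length else rep(NA_real_, nrow(tree$edge))
  len_of <- numeric(n + tree$Nnode)
  len_of[tree$edge[, 2]] <- elen
  fmt <- function(x) format(x, digits = 15)
  dep <- function(node) {
    if (node <= n) {
      sp <- tree$tip.label[node]
      ids <- species_to_specimens[[sp]]
      if (is.null(ids) || length(ids) == 0) {
        paste0(sp, ":", fmt(len_of[node]))
      } else if (length(ids) == 1) {
        paste0(ids, ":", fmt(len_of[node]))
      } else {
        paste0("(", paste0(ids, ":0", collapse = ","), "):", fmt(len_of[node]))
      }
    } else {
      body <- paste(vapply(kids[[node]], dep, character(1)), collapse = ",")
      if (node == n + 1L) paste0("(", body, ")")
      else paste0("(", body, "):", fmt(len_of[node]))
    }
  }
  ape::read.tree(text = paste0(dep(n + 1L), ";"))
}

#' Nudge zero-length terminal branches for invertibility
#'
#' Zero-length conspecific branches make the Brownian-motion covariance
#' singular when the signal parameter does not shrink off-diagonal entries
#' (lambda fixed at 1, or two specimens at zero patristic distance under an
#' Ornstein-Uhlenbeck model). Adding a tiny duration to those branches
#' restores positive definiteness without materially changing covariances.
#'
#' @param tree A `phylo`.
#' @param eps Duration (My) given to zero-length terminal branches;
#'   default `1e-6`.
#' @return The adjusted tree.
#' @export
apply_branch_epsilon <- function(tree, eps = 1e-6) {
  if (is.null(tree$edge.length)) return(tree)
  n <- length(tree$tip.label)
  zero_term <- tree$edge[, 2] <= n & tree$edge.length <= 0
  tree$edge.length[zero_term] <- eps
  tree
}

#' Generate an ensemble of resolved, calibrated trees
#'
#' For each base topology, repeatedly (i) resolves polytomies at random,
#' (ii) time-calibrates from the tip age ranges, and (iii) optionally
#' expands multi-specimen species into zero-length conspecific polytomies.
#' The whole procedure is deterministic given `seed`.
#'
#' @param base_topologies A list of rooted `phylo` objects (or a single
#'   `phylo`), tips named as species.
#' @param n_per_topology Number of trees to draw per base topology.
#' @param age_ranges Species age ranges, as from [species_age_ranges()].
#' @param params A [calibration_params()] object.
#' @param species_to_specimens Optional map for
#'   [expand_conspecific_tips()]; `NULL` keeps species-level tips.
#' @param seed Optional integer seed.
#' @return A list of class `tree_ensemble`: one element per topology, each
#'   a list of `phylo` objects of length `n_per_topology`.
#' @export
generate_tree_ensemble <- function(base_topologies, n_per_topology, age_ranges,
                                   params, species_to_specimens = NULL,
                                   seed = NULL) {
  if (inherits(base_topologies, "phylo")) base_topologies <- list(base_topologies)
  stopifnot(n_per_topology >= 1)
  if (!is.null(seed)) set.seed(seed)
  ens <- lapply(base_topologies, function(topo) {
    lapply(seq_len(n_per_topology), function(i) {
      tr <- resolve_polytomies(topo)
      tr <- calibrate_tree(tr, age_ranges, params)
      if (!is.null(species_to_specimens)) {
        tr <- expand_conspecific_tips(tr, species_to_specimens)
      }
      tr
    })
  })
  names(ens) <- paste0("topology_", seq_along(ens))
  class(ens) <- "tree_ensemble"
  ens
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat("Tree ensemble:", length(x), "topolog", if (length(x) == 1) "y" else "ies",
      "x", length(x[[1]]), "trees each\n")
  cat("tips per tree:", length(x[[1]][[1]]$tip.label), "\n")
  invisible(x)
}

#' Write a tree ensemble to multi-tree Newick files
#'
#' One file per topology, each holding all its trees.
#'
#' @param ensemble A `tree_ensemble`.
#' @param dir Output directory (created if needed).
#' @return The written file paths, invisibly.
#' @export
write_tree_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(ensemble), function(i) {
    p <- file.path(dir, paste0(names(ensemble)[i], ".nwk"))
    cls <- ensemble[[i]]
    class(cls) <- "multiPhylo"
    ape::write.tree(cls, file = p)
    p
  }, character(1))
  invisible(paths)
}
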