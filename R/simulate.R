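#' Configuration for the synthetic fossil-allometry generator
#'
#' Bundles, with defaults chosen to emulate a theropod-like study system,
#' every parameter of the synthetic data generator: a clade of around a
#' hundred fossil species spanning the Mesozoic, femur lengths spread over
#' roughly 1.5 orders of magnitude, a main allometric trend of mild
#' negative allometry with strong phylogenetic signal, a modest fraction
#' of species known from several specimens, and stratigraphic age ranges
#' a few My wide.
#'
#' @param n_species Number of species tips (default 110).
#' @param birth,death Per-lineage-My rates of the generating birth-death
#'   process (defaults 0.06 and 0.03).
#' @param root_age Age of the root, Ma (default 230).
#' @param frac_multi Fraction of species with more than one specimen
#'   (default 0.3).
#' @param max_specimens Maximum specimens per multi-specimen species
#'   (default 3; the count is drawn uniformly from 2..max).
#' @param a0,b0 True intercept and slope of log10 humerus on log10 femur
#'   (defaults 0.1 and 0.9).
#' @param lambda0 True phylogenetic signal of the residuals (default 0.93).
#' @param sigma0 Residual standard deviation on the log10 scale
#'   (default 0.1).
#' @param x_root Root state of log10 femur length (default 2.5, i.e. a
#'   316 mm femur).
#' @param x_rate Brownian rate of log10 femur length per My
#'   (default 0.0015).
#' @param onto_spread Width of the (negative) uniform ontogenetic offset
#'   in log10 femur length for non-largest conspecific specimens
#'   (default 0.25).
#' @param onto_noise_sd Individual scatter (log10 scale) of non-largest
#'   conspecific specimens around their species' allometric trajectory
#'   (default 0.03, a few percent in linear measurement terms). Without
#'   it, zero-length conspecific branches would pin the regression to the
#'   noise-free within-species contrasts.
#' @param measurement_sd Independent per-specimen noise on both log
#'   measurements; 0 (default) keeps the generative model identical to
#'   the fitted one.
#' @param age_slack Half-width (My) of the stratigraphic age range around
#'   the true tip age (default 2).
#' @param polytomy_frac Fraction of internal branches of the base
#'   topology collapsed into polytomies (default 0.3).
#' @param clade_effects Named list of deviating clades:
#'   `list(CladeA = list(size = 25, delta_slope = 0.2, delta_intercept = 0))`.
#'   Clades are carved out of the simulated tree as the monophyletic group
#'   whose size is closest to `size`.
#' @param n_null_clades Additional no-effect clades to label (default 2),
#'   useful as negative controls for the deviation tests.
#' @param null_clade_size Target tip count of the null clades (default 15).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 110, birth = 0.06, death = 0.03,
                       root_age = 230, frac_multi = 0.3, max_specimens = 3,
                       a0 = 0.1, b0 = 0.9, lambda0 = 0.93, sigma0 = 0.1,
                       x_root = 2.5, x_rate = 0.001, onto_spread = 0.25,
                       onto_noise_sd = 0.03,
                       measurement_sd = 0, age_slack = 2,
                       polytomy_frac = 0.3, clade_effects = list(),
                       n_null_clades = 2, null_clade_size = 15) {
  stopifnot(lambda0 >= 0, lambda0 <= 1, sigma0 > 0, birth > 0, death >= 0,
            n_species >= 5)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a birth-death tree with fossil tips
#'
#' Forward simulation from a single root lineage: lineages split at the
#' birth rate and die at the death rate; the process stops once the tree
#' holds `n_species` tips (or at the present). Lineages dead at the stop
#' time are fossil tips at their extinction age; lineages still alive
#' become tips at the stop age — the generator's stand-in for taxa whose
#' record ends at the study's sampling horizon. With `death = 0` the tree
#' is ultrametric (all tips extant at the stop time). A run that dies out
#' or hits the `root_age` horizon before reaching `n_species` is discarded
#' and re-simulated, up to 100 attempts.
#'
#' @param config A [sim_config()].
#' @return A binary `phylo`; true tip ages (Ma) in attribute `tip_ages`.
#' @export
simulate_birth_death_tree <- function(config) {
  for (attempt in 1:100) {
    tr <- sim_bd_once(config)
    if (!is.null(tr) && length(tr$tip.label) >= config$n_species) return(tr)
  }
  stop("birth-death simulation failed to reach ", config$n_species,
       " species in 100 attempts; increase birth rate, decrease death ",
       "rate, or extend root_age")
}

sim_bd_once <- function(cfg) {
  # lineage records: parent id, start time (My after root), end time, children
  parent <- c(NA_integer_)
  t_start <- c(0)
  t_end <- c(NA_real_)
  alive <- c(TRUE)
  n_lin <- 1L
  t_now <- 0
  t_max <- cfg$root_age
  repeat {
    # tips = lineages that never split: dead-without-children + alive ones
    n_children <- tabulate(parent[!is.na(parent)], nbins = n_lin)
    tip_count <- sum(n_children == 0)
    if (tip_count >= cfg$n_species || t_now >= t_max) break
    idx_alive <- which(alive)
    n_alive <- length(idx_alive)
    if (n_alive == 0) return(NULL)
    rate_total <- n_alive * (cfg$birth + cfg$death)
    t_now <- t_now + stats::rexp(1, rate_total)
    if (t_now >= t_max) { t_now <- t_max; break }
    lin <- idx_alive[sample.int(n_alive, 1)]
    if (stats::runif(1) < cfg$birth / (cfg$birth + cfg$death)) {
      # split: two children
      t_end[lin] <- t_now
      alive[lin] <- FALSE
      for (j in 1:2) {
        n_lin <- n_lin + 1L
        parent[n_lin] <- lin
        t_start[n_lin] <- t_now
        t_end[n_lin] <- NA_real_
        alive[n_lin] <- TRUE
      }
    } else {
      t_end[lin] <- t_now
      alive[lin] <- FALSE
    }
  }
  t_end[alive] <- t_now
  n_children <- tabulate(parent[!is.na(parent)], nbins = n_lin)
  is_tip <- n_children == 0
  # reaching the time horizon below the species cap is legitimate; only
  # unusably small trees are rejected (extinction already returned NULL)
  if (sum(is_tip) < 3) return(NULL)

  kids_of <- split(seq_len(n_lin)[-1], parent[-1])
  tip_no <- 0L
  labels <- character(0)
  tip_age <- numeric(0)
  dep <- function(lin) {
    if (is_tip[lin]) {
      tip_no <<- tip_no + 1L
      lab <- sprintf("sp_%03d", tip_no)
      labels <<- c(labels, lab)
      tip_age <<- c(tip_age, cfg$root_age - t_end[lin])
      paste0(lab, ":", format(t_end[lin] - t_start[lin], digits = 12))
    } else {
      ch <- kids_of[[as.character(lin)]]
      paste0("(", paste(vapply(ch, dep, character(1)), collapse = ","),
             "):", format(t_end[lin] - t_start[lin], digits = 12))
    }
  }
  root_lin <- 1L
  # the root lineage's children define the crown; keep its stem as root edge 0
  if (is_tip[root_lin]) return(NULL)
  txt <- paste0(dep(root_lin), ";")
  tr <- ape::read.tree(text = txt)
  attr(tr, "tip_ages") <- stats::setNames(tip_age, labels)[tr$tip.label]
  tr
}

#' Simulate paired log-scale traits on a calibrated tree
#'
#' The predictor (log10 femur length) evolves by Brownian motion from
#' `x_root` at rate `x_rate`; the response is `a0 + b0 * x` plus residuals
#' drawn from a multivariate normal with covariance
#' `sigma0^2 * V(lambda0)`, the exact generative twin of the fitted
#' regression model. Tips belonging to a clade listed in `clade_effects`
#' (matched against the `tip_clades` argument) get the shifted intercept
#' and slope.
#'
#' @param tree A calibrated `phylo`.
#' @param config A [sim_config()].
#' @param tip_clades Optional named list: clade label -> tip labels, used
#'   to apply `clade_effects`.
#' @return Data frame: tip, log_fl, log_hl.
#' @export
simulate_traits <- function(tree, config, tip_clades = NULL) {
  n <- length(tree$tip.label)
  Vbm <- unclass(bm_covariance(apply_branch_epsilon(tree, 1e-8)))
  Lx <- t(chol(Vbm))
  x <- config$x_root + sqrt(config$x_rate) * as.numeric(Lx %*% stats::rnorm(n))
  Vr <- unclass(lambda_transform(new_phylo_cov(Vbm, "BM", NA_real_),
                                 config$lambda0))
  # normalize to unit mean diagonal so sigma0 is the residual standard
  # deviation on the log10 scale at the average tip depth
  Le <- t(chol(Vr / mean(diag(Vbm))))
  e <- config$sigma0 * as.numeric(Le %*% stats::rnorm(n))
  a <- rep(config$a0, n)
  b <- rep(config$b0, n)
  if (length(config$clade_effects) > 0 && !is.null(tip_clades)) {
    for (cl in names(config$clade_effects)) {
      eff <- config$clade_effects[[cl]]
      hit <- tree$tip.label %in% tip_clades[[cl]]
      a[hit] <- a[hit] + (eff$delta_intercept %||% 0)
      b[hit] <- b[hit] + (eff$delta_slope %||% 0)
    }
  }
  y <- a + b * x + e
  if (config$measurement_sd > 0) {
    x <- x + stats::rnorm(n, sd = config$measurement_sd)
    y <- y + stats::rnorm(n, sd = config$measurement_sd)
  }
  data.frame(tip = tree$tip.label, log_fl = x, log_hl = y,
             a = a, b = b, e = e, stringsAsFactors = FALSE)
}

# pick the monophyletic group whose tip count is closest to `size`,
# avoiding tips already claimed
pick_clade <- function(tree, size, taken) {
  n <- length(tree$tip.label)
  best <- NULL
  best_score <- Inf
  for (node in (n + 2L):(n + tree$Nnode)) {
    tips <- tree$tip.label[descendant_tips(tree, node)]
    if (any(tips %in% taken)) next
    score <- abs(length(tips) - size)
    if (score < best_score) {
      best <- tips
      best_score <- score
    }
  }
  best
}

#' Generate a complete synthetic study dataset with known truth
#'
#' Runs the whole generative chain: birth-death species tree, clade
#' labelling (deviating clades plus null controls), conspecific specimen
#' structure with ontogenetically smaller extra individuals, bivariate
#' log traits under the allometric model, stratigraphic age ranges, and a
#' polytomized base topology — everything in exactly the shapes the
#' analysis pipeline consumes, plus the full generative truth.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @param dir Optional directory; when given, writes `specimens.csv`,
#'   `base_topology.nwk`, `age_ranges.csv` and `truth.json` there.
#' @return List: `specimens` (a `specimen_table`), `base_topology`
#'   (multifurcating species-level `phylo`, no branch lengths),
#'   `species_tree` (the true calibrated tree), `age_ranges`,
#'   `species_to_specimens`, `clade_table`, `truth` (generative
#'   parameters, incl. clade assignments).
#' @export
make_synthetic_dataset <- function(config = sim_config(), seed = NULL,
                                   dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- simulate_birth_death_tree(config)
  tip_ages <- attr(tree, "tip_ages")

  # carve out deviating and null clades
  wanted <- c(lapply(config$clade_effects, `[[`, "size"),
              stats::setNames(rep(list(config$null_clade_size),
                                  config$n_null_clades),
                              paste0("NullClade", seq_len(config$n_null_clades))))
  taken <- character(0)
  tip_clades <- list()
  for (cl in names(wanted)) {
    tips <- pick_clade(tree, wanted[[cl]], taken)
    if (is.null(tips)) {
      warning("could not carve out clade '", cl, "'; skipped")
      next
    }
    tip_clades[[cl]] <- tips
    taken <- c(taken, tips)
  }

  traits <- simulate_traits(tree, config, tip_clades)

  # conspecific specimen structure
  n <- length(tree$tip.label)
  multi <- stats::runif(n) < config$frac_multi
  ks <- if (config$max_specimens <= 2) rep(2L, n)
        else sample(2:config$max_specimens, n, replace = TRUE)
  n_spec <- ifelse(multi, ks, 1L)
  rows <- list()
  for (i in seq_len(n)) {
    sp <- tree$tip.label[i]
    for (k in seq_len(n_spec[i])) {
      # extra conspecifics are ontogenetically smaller individuals following
      # the species' own allometric trajectory, with individual scatter
      off <- if (k == 1) 0 else -stats::runif(1, 0, config$onto_spread)
      scatter <- if (k == 1) 0 else stats::rnorm(1, sd = config$onto_noise_sd)
      lfl <- traits$log_fl[i] + off
      lhl <- traits$a[i] + traits$b[i] * lfl + traits$e[i] + scatter
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = sprintf("%s_s%d", sp, k),
        species = sp,
        genus = sub("_.*", "", sp),
        fl_mm = 10^lfl,
        hl_mm = 10^lhl,
        age_min_ma = max(0, tip_ages[i] - config$age_slack),
        age_max_ma = tip_ages[i] + config$age_slack,
        onto_status = if (off < -0.15) "juvenile"
                      else sample(c("adult", "subadult", "unknown"), 1,
                                  prob = c(0.6, 0.2, 0.2)),
        stringsAsFactors = FALSE)
    }
  }
  spec_df <- do.call(rbind, rows)
  clade_of <- stats::setNames(rep("", n), tree$tip.label)
  for (cl in names(tip_clades)) clade_of[tip_clades[[cl]]] <- cl
  spec_df$clades <- clade_of[spec_df$species]
  specimens <- as_specimen_table(spec_df)

  species_map <- split(specimens$specimen_id, specimens$species)
  age_ranges <- species_age_ranges(specimens)

  # base topology: collapse a fraction of internal branches into polytomies
  base <- tree
  n_edges <- nrow(base$edge)
  internal <- which(base$edge[, 2] > n)
  collapse <- internal[stats::runif(length(internal)) < config$polytomy_frac]
  base$edge.length[collapse] <- 0
  base <- ape::di2multi(base, tol = 1e-12)
  base$edge.length <- NULL

  clade_table <- stats::setNames(
    lapply(tree$tip.label, function(sp) {
      cl <- clade_of[[sp]]
      if (nzchar(cl)) cl else character(0)
    }), tree$tip.label)

  truth <- list(a0 = config$a0, b0 = config$b0, lambda0 = config$lambda0,
                sigma0 = config$sigma0, x_root = config$x_root,
                x_rate = config$x_rate, n_species = n,
                n_specimens = nrow(specimens),
                clade_effects = config$clade_effects,
                tip_clades = tip_clades, seed = seed)

  out <- list(specimens = specimens, base_topology = base,
              species_tree = tree, age_ranges = age_ranges,
              species_to_specimens = species_map, clade_table = clade_table,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_specimens(specimens, file.path(dir, "specimens.csv"))
    ape::write.tree(base, file.path(dir, "base_topology.nwk"))
    utils::write.csv(age_ranges, file.path(dir, "age_ranges.csv"),
                     row.names = FALSE)
    jsonlite::write_json(truth[setdiff(names(truth), "tip_clades")],
                         file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  out
}
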