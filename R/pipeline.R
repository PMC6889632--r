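#' Assemble a run configuration for the full analysis
#'
#' @param specimens Path to a specimen CSV or a `specimen_table`.
#' @param topologies Paths to Newick files, a single `phylo`, or a list of
#'   `phylo` base topologies.
#' @param variant Dataset variant, see [make_variant()].
#' @param n_trees Trees per topology (default 1000).
#' @param sampling_rate,extinction_rate,birth_rate,branch_constant,calibration_mode
#'   Passed to [calibration_params()].
#' @param models Which regressions to fit: subset of
#'   `c("lambda", "OU", "OLS")`.
#' @param clades Candidate clade labels for the deviation tests; defaults
#'   to every label present in the data.
#' @param pancova_subset Trees per topology used by the deviation tests
#'   (default 200).
#' @param threshold Significance threshold for consistent deviation
#'   (default 0.05).
#' @param forced_exclusions Species excluded without testing.
#' @param seed Integer seed for the whole run.
#' @param out_dir Output directory, or `NULL` for no files.
#' @param run_exclusion Run the iterative PANCOVA exclusion loop
#'   (default TRUE).
#' @param run_per_clade Run per-clade pooled regressions (default TRUE).
#' @param per_clade_subset Trees per topology for per-clade regressions
#'   (default 200).
#' @return A list of class `run_config`.
#' @export
run_config <- function(specimens, topologies, variant = "complete",
                       n_trees = 1000, sampling_rate = 0.1,
                       extinction_rate = 0.05, birth_rate = extinction_rate,
                       branch_constant = 1,
                       calibration_mode = "stochastic",
                       models = c("lambda", "OU"), clades = NULL,
                       pancova_subset = 200, threshold = 0.05,
                       forced_exclusions = NULL, seed = 1L, out_dir = NULL,
                       run_exclusion = TRUE, run_per_clade = TRUE,
                       per_clade_subset = 200) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Any field of [run_config()] may appear in the file; missing fields take
#' the defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}

#' Run the complete ensemble allometry analysis
#'
#' Orchestrates the full workflow: load and subset the specimen table,
#' generate the resolved and calibrated tree ensemble with conspecific
#' expansion, fit the allometric regression on every tree under each
#' requested model, pool per topology and overall by Rubin's rules, run
#' per-clade regressions, and run the iterative PANCOVA exclusion loop.
#' With `out_dir` set, writes the pooled tables and per-tree fits as TSV,
#' the exclusion log as JSON, and a manifest (seed, package version,
#' config hash) that makes the run reproducible.
#'
#' @param config A [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return A list of class `allom_run`: `specimens`, `ensemble`, `fits`
#'   (per model), `pooled` (per model), `per_clade`, `exclusion`,
#'   `manifest`.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)

  specimens <- config$specimens
  if (is.character(specimens)) specimens <- read_specimens(specimens)
  specimens <- make_variant(specimens, config$variant)

  topologies <- config$topologies
  if (is.character(topologies)) {
    topologies <- lapply(topologies, function(p) read_topology(file = p))
  }
  if (inherits(topologies, "phylo")) topologies <- list(topologies)

  params <- calibration_params(config$sampling_rate, config$extinction_rate,
                               config$birth_rate, config$branch_constant,
                               config$calibration_mode)
  species_map <- split(specimens$specimen_id, specimens$species)
  ages <- species_age_ranges(specimens)
  # the base topologies may carry species without measurements; prune
  topologies <- lapply(topologies, function(tp) {
    extra <- setdiff(tp$tip.label, names(species_map))
    if (length(extra) > 0) tp <- ape::drop.tip(tp, extra)
    tp
  })
  ensemble <- generate_tree_ensemble(topologies, config$n_trees, ages, params,
                                     species_to_specimens = species_map)

  models <- intersect(config$models, c("lambda", "OU", "OLS"))
  fits <- list()
  pooled <- list()
  for (mod in models) {
    fits[[mod]] <- fit_ensemble(specimens, ensemble, model = mod)
    pooled[[mod]] <- if (mod == "OLS") NULL else pool_by_topology(fits[[mod]])
  }

  clades <- config$clades %||% sort(unique(unlist(specimens$clades)))

  per_clade <- NULL
  if (isTRUE(config$run_per_clade) && length(clades) > 0) {
    per_clade <- per_clade_regressions(specimens, ensemble, clades,
                                       subset_size = config$per_clade_subset)
  }

  exclusion <- NULL
  if (isTRUE(config$run_exclusion) && length(clades) > 0) {
    exclusion <- iterative_exclusion(
      specimens, ensemble, clades, threshold = config$threshold,
      subset_size = config$pancova_subset,
      model = if ("lambda" %in% models) "lambda" else "OU",
      forced_exclusions = config$forced_exclusions)
  }

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("phylallom")),
    r_version = as.character(getRversion()),
    n_topologies = length(topologies),
    n_trees = config$n_trees,
    n_specimens = nrow(specimens),
    variant = config$variant,
    models = models,
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  out <- structure(list(specimens = specimens, ensemble = ensemble,
                        fits = fits, pooled = pooled, per_clade = per_clade,
                        exclusion = exclusion, manifest = manifest),
                   class = "allom_run")
  if (!is.null(config$out_dir)) write_run_outputs(out, config$out_dir)
  out
}

config_hash <- function(config) {
  flat <- config[!vapply(config, is.object, logical(1))]
  flat <- flat[vapply(flat, function(x) is.atomic(x) || is.null(x), logical(1))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(vapply(seq_along(flat), function(i) {
    paste0(names(flat)[i], "=", paste(flat[[i]], collapse = ","))
  }, character(1)), tmp)
  unname(tools::md5sum(tmp))
}

write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (mod in names(run$fits)) {
    utils::write.table(run$fits[[mod]],
                       file.path(dir, paste0("fits_", mod, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(run$pooled[[mod]])) {
      utils::write.table(as.data.frame(run$pooled[[mod]]),
                         file.path(dir, paste0("pooled_", mod, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  if (!is.null(run$per_clade)) {
    utils::write.table(run$per_clade, file.path(dir, "per_clade.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(run$exclusion)) {
    log <- list(
      forced = run$exclusion$forced_exclusions,
      rounds = lapply(seq_along(run$exclusion$rounds), function(i) {
        r <- run$exclusion$rounds[[i]]
        list(round = i, excluded = r$excluded,
             tests = r$tests[, c("clade", "topology", "m_trees", "pooled_p",
                                 "consistent")])
      }),
      excluded_clades = run$exclusion$excluded_clades,
      kept_specimens = nrow(run$exclusion$kept))
    jsonlite::write_json(log, file.path(dir, "exclusion_log.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    utils::write.table(as.data.frame(run$exclusion$final_pool),
                       file.path(dir, "pooled_post_exclusion.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.allom_run <- function(x, ...) {
  cat("Ensemble allometry analysis\n")
  cat(sprintf("  %d specimens (%s variant), %d topolog%s x %d trees\n",
              nrow(x$specimens), x$manifest$variant, x$manifest$n_topologies,
              if (x$manifest$n_topologies == 1) "y" else "ies",
              x$manifest$n_trees))
  for (mod in names(x$pooled)) {
    if (is.null(x$pooled[[mod]])) next
    tot <- x$pooled[[mod]]
    tot <- tot[tot$topology == "all", ]
    cat(sprintf("  %s: slope %.3f [%.3f, %.3f], signal %.3f\n", mod,
                tot$slope, tot$slope_lo, tot$slope_hi, tot$signal_mean))
  }
  if (!is.null(x$exclusion)) {
    cat("  excluded clades:",
        if (length(x$exclusion$excluded_clades))
          paste(x$exclusion$excluded_clades, collapse = ", ") else "none",
        "\n")
  }
  invisible(x)
}
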