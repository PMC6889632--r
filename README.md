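# phylallom

Evolutionary allometry on ensembles of time-calibrated fossil trees.

`phylallom` estimates log-log scaling relations between skeletal
measurements of fossil taxa — the motivating case is humerus length
against femur length (a body-size proxy) across non-avian theropod
dinosaurs — while propagating the two dominant sources of uncertainty in
fossil comparative data: unresolved phylogenetic relationships and
uncertain divergence times.

The allometric model is the standard power law, fitted on the log scale:

    log10(HL) = a + b * log10(FL) + e,      e ~ N(0, sigma^2 * V)

where `b` is the allometric coefficient (`b < 1`: negative allometry,
larger animals have relatively shorter forelimbs; `b = 1`: isometry) and
`V` is the among-tip covariance implied by a phylogeny under Brownian
motion (BM), Pagel's-lambda-scaled BM, or an Ornstein-Uhlenbeck (OU)
process with attraction strength `alpha`. Because no single correct tree
exists for a fossil supertree with polytomies, the package:

1. stochastically resolves every polytomy (uniformly over all labeled
   resolutions) and time-calibrates each resolved tree from stratigraphic
   tip age ranges under a birth-death-sampling model, adding a +1 My
   branch constant and replacing multi-specimen species tips by
   zero-branch-length conspecific polytomies;
2. fits the regression on every tree of the resulting ensemble by
   generalized least squares, with maximum (restricted) likelihood
   estimation of `lambda` in [0, 1] or `alpha`;
3. pools estimates across trees by Rubin's multiple-imputation rules
   (between-tree variance widens the confidence intervals);
4. tests named subclades for deviation from the main trend by
   phylogenetic ANCOVA, pools the dependent per-tree p-values, and
   iteratively excludes clades that deviate consistently across all base
   topologies.

A synthetic-data generator (`make_synthetic_dataset()`) emulates the full
study design — fossil birth-death trees, polytomous base topologies,
conspecific specimen structure, clade-level deviations — with known truth,
so every stage is testable without external data.

## Worked example

A small synthetic dataset (24 species, 41 specimens, one clade with an
injected +0.2 slope deviation) ships with the package:

```r
library(phylallom)

csv <- system.file("extdata", "synthetic_specimens.csv", package = "phylallom")
nwk <- system.file("extdata", "synthetic_topology.nwk", package = "phylallom")
specimens <- read_specimens(csv)
topology  <- read_topology(file = nwk)

cal <- calibration_params(sampling_rate = 0.1, extinction_rate = 0.05)
ensemble <- generate_tree_ensemble(
  topology, n_per_topology = 50, species_age_ranges(specimens), cal,
  species_to_specimens = split(specimens$specimen_id, specimens$species),
  seed = 1)

summary(pgls_allom(log_hl ~ log_fl, specimens, ensemble[[1]][[1]],
                   model = "lambda"))
#> Phylogenetic allometric regression (BM+lambda, REML)
#> n = 41, slope = 0.9112 [0.8009, 1.0215], intercept = 0.1234
#> lambda = 0.9957 (estimated)
#> ...
#> Test of isometry (slope = 1): t = -1.628, p = 0.1115

fits <- fit_ensemble(specimens, ensemble, model = "lambda")
pool_by_topology(fits)
#> Pooled allometric regression (lambda model)
#>  topology  m intercept  slope       slope_ci signal_mean
#>         1 50    0.1165 0.9218 (0.817, 1.027)      0.9943
#>       all 50    0.1165 0.9218 (0.817, 1.027)      0.9943

iterative_exclusion(specimens, ensemble,
                    c("LongarmClade", "NullClade1"), subset_size = 50)
#> Iterative clade exclusion: 2 round(s)
#> excluded clades: LongarmClade
#> kept specimens: 30
#> final pooled regression:
#>  topology  m intercept  slope       slope_ci signal_mean
#>       all 50   0.07994 0.9274 (0.806, 1.049)      0.9732
```

The single-tree fit recovers the generating slope of 0.9 within its CI;
the pooled CI additionally reflects between-tree disagreement; and the
exclusion loop flags exactly the clade whose slope was shifted, leaving
the null clade alone. `run_full_analysis()` wraps the whole workflow
(dataset variants, multiple models, per-clade regressions, report files)
behind a single YAML-configurable call.

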