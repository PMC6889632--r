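---
title: "Ensemble phylogenetic allometry: models, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble phylogenetic allometry: models, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylallom)
```

## The problem

Evolutionary allometry asks how one body part scales with body size
across species. On the log scale the power law becomes linear,

$$\log_{10}(\mathrm{HL}) = a + b\,\log_{10}(\mathrm{FL}) + e,$$

with femur length FL standing in for body size and humerus length HL for
forelimb size. The coefficient $b$ separates negative allometry
($b < 1$), isometry ($b = 1$) and positive allometry ($b > 1$). Related
species are not independent draws: residuals covary through shared
ancestry, and ignoring that covariance biases estimates and inflates
type-I error. `phylallom` therefore fits the regression by generalized
least squares with residual covariance $\sigma^2 V$ derived from a
phylogeny — and, because fossil phylogenies are themselves uncertain,
repeats the fit over an ensemble of candidate trees and pools.

## Covariance models

Three structures are supported, all up to the profiled scale $\sigma^2$:

* **Brownian motion.** $V_{ij}$ is the depth below the root of the most
  recent common ancestor of tips $i$ and $j$ (their shared path length);
  the diagonal is each tip's root-to-tip depth. Fossil trees are not
  ultrametric, so the diagonal is not constant.
* **Pagel's lambda.** Off-diagonal entries of the BM matrix are
  multiplied by $\lambda \in [0, 1]$: $\lambda = 0$ removes the
  phylogeny, $\lambda = 1$ is pure BM, intermediate values measure the
  phylogenetic signal of the residuals. $\lambda$ is estimated jointly
  with the regression by bounded likelihood maximization.
* **Ornstein–Uhlenbeck.** A mean-reverting process with attraction
  strength $\alpha$ (per My). We adopt the stationary-root form for
  non-ultrametric trees,
  $$V_{ij} = \frac{1}{2\alpha} e^{-\alpha d_{ij}}
  \bigl(1 - e^{-2\alpha s_{ij}}\bigr),$$
  with $s_{ij}$ the root-to-MRCA depth and $d_{ij}$ the patristic
  distance. As $\alpha \to 0$ this converges entrywise to BM; at large
  $\alpha$ tips decorrelate. The literature also contains a
  non-stationary variant; which of the two any given earlier analysis
  used is often unrecoverable, so the choice here is fixed, documented,
  and testable (the test suite checks both limits and the closed form).

Numerics: $V$ is always handled through its Cholesky factor (whitening);
nothing is ever explicitly inverted. A factorization that encounters a
numerically zero pivot **raises an error rather than regularizing** —
silent repair would change the model. The one sanctioned adjustment is
`apply_branch_epsilon()`, which gives zero-length terminal branches a
tiny duration (default $10^{-6}$ My) so that conspecific specimens (below)
do not make $V$ exactly singular; at the default it changes covariances
by parts in $10^{8}$.

## The tree ensemble

Base topologies are informal supertrees with unresolved polytomies and no
usable branch lengths. For each of `n_per_topology` draws:

1. **Resolution.** Every polytomy of degree $c$ is replaced by a rooted
   binary arrangement drawn *uniformly* over all $(2c-3)!!$ labeled
   resolutions, by stepwise insertion over placeholder leaves. Uniformity
   matters: sequential random joining schemes oversample balanced shapes.
   A property test checks all 105 resolutions of a 5-star appear at
   frequency $1/105$ within three standard errors.
2. **Calibration.** Tip ages are drawn uniformly within each species'
   stratigraphic range (Ma). Node ages follow tips-to-root: a node is as
   old as its oldest child plus an exponential offset with rate
   $b_{bd} + \mu + \psi$ — the combined birth, extinction and fossil
   sampling rate, so richer sampling and faster turnover pull nodes
   closer to their children. This is a deliberate simplification of the
   full three-rate cal3 sampler, which conditions each offset on the
   subtree's sampled descendants; the simplified version preserves the
   qualitative behaviour (stochastic, rate-controlled node ages
   respecting stratigraphic order) without reimplementing the published
   algorithm. The `uniform` mode (every branch length 1) provides the
   robustness check of a branch-length-free null.
3. **The +1 constant.** After calibration, 1 My is added to every branch
   so that the zero-length branches created by resolution keep the base
   topology's node structure. We interpret the constant in My (it is
   applied to branch durations, the only scale present at that stage).
4. **Conspecific expansion.** Species with several specimens become
   zero-branch-length polytomies of specimen tips, so conspecifics share
   their full evolutionary history and are strongly down-weighted rather
   than counted as independent. All specimens of a species share its
   pooled age range. Missing tip ages fall back to sister-taxon ages,
   then the whole-tree range, with a message.

Diversification is assumed equal to extinction when only a sampling and
extinction rate are supplied — the standard assumption for wholly extinct
clades. The numeric rates are study inputs, not package constants: the
sampling rate in particular must come from the literature for the clade
at hand.

## Estimation details

* **REML by default.** The signal parameters ($\lambda$, $\alpha$) are
  estimated by restricted maximum likelihood, which corrects the scale
  estimate for the two estimated mean parameters; plain ML is available
  via `method = "ML"`. Fixed-signal fits match `nlme::gls` with
  `ape::corPagel` to machine precision on ultrametric trees (test suite).
* **Bounds and tolerance.** $\lambda$ is maximized over $[0,1]$ with a
  scalar search at tolerance $10^{-6}$, with the endpoints checked
  explicitly; $\alpha$ over a log-spaced $[10^{-6}, 10^{2}]$ per My.
* **Failure and fallback.** Signal estimation is declared impossible
  when the likelihood is non-finite everywhere, flat across the whole
  range (e.g. a star phylogeny, where $\lambda$ has no effect), or flat
  at a boundary optimum. The fit then falls back to fixed $\lambda = 1$
  with an additional OLS fit attached ($\lambda = 0$), bracketing the
  full range of phylogenetic weighting. Per-clade analyses apply a
  stricter version: clades whose per-tree estimates are mostly boundary
  values are reported with the two bracketing fixed fits, because small
  subtrees rarely carry usable information about $\lambda$.
* **Confidence intervals** use Student-t quantiles on $n - 2$ degrees of
  freedom, uncorrected for the estimated signal parameter — the standard
  practice, slightly anti-conservative in principle; empirical coverage
  under the generative model is checked in the acceptance tests
  (93–95% at the study scale).
* **Observation matching.** Data rows are matched to tree tips by exact
  label and reordered; any mismatch is an error. Nothing is ever matched
  by name similarity.

## Pooling across trees

Each tree is treated as one imputation of the unknowable true phylogeny
and the per-tree estimates are pooled by Rubin's rules: pooled estimate
$\bar Q$, within variance $\bar W$, between variance $B$, total
$T = \bar W + (1 + 1/m)B$, and degrees of freedom
$(m-1)[1 + \bar W/((1+1/m)B)]^2$. The Barnard–Rubin small-sample
correction is off by default (ensembles of hundreds to thousands of trees
gain nothing) but available. Both intercept and slope are pooled by
Rubin's rules; $\lambda$ and $\alpha$ are summarized as simple means, the
convention used in published tables of this kind. Fits whose signal
optimization failed are excluded from pooling and reported as an
attrition rate: a failed optimum is not a valid imputation draw.

## Deviation testing and the exclusion loop

Whether a subclade deviates from the main trend is a nested-model
question: the null design $[1, x]$ against the full design
$[1, x, g, g\!\cdot\!x]$ with $g$ the clade indicator, sharing one
covariance matrix, compared by an F-test on $q = 2$ numerator degrees of
freedom computed in the whitened space. Intercept-only and slope-only
variants ($q = 1$) are exposed because the published description of the
test does not pin down the tested terms; the joint test is the default as
the most complete. $\lambda$ is estimated once per tree under the null
design and shared by both models, so the test compares mean structures
under a common covariance.

P-values from the same data on many trees are strongly dependent. The
default combination is a dependence-corrected Stouffer rule,
$\bar z = \sum z_i / \sqrt{m + m(m-1)\bar\rho}$, where $\bar\rho$ is the
mean between-tree correlation of the z-scores, estimated empirically
across the candidate clades tested on the same trees (clipped to
$[0,1]$; default 0.5 when only one clade is testable). At $\bar\rho = 1$
identical p-values pass through unchanged; at $\bar\rho = 0$ the rule is
the classical independent Stouffer combination. The harmonic-mean
p-value is available as a dependence-robust sensitivity check. The exact
meta-analytic method used in earlier work of this kind is not described
in enough detail to replicate, so this explicit, testable default stands
in its place.

The iterative loop tests every candidate clade on a deterministic subset
of trees (the first 200 per topology by default — deviation testing is
the expensive stage), excludes clades significant at 0.05 *in every
topology*, refits on the remainder, and repeats until a round excludes
nothing; it terminates in at most as many rounds as there are candidate
clades. Clades reduced to a single specimen cannot be tested and are
handled as forced exclusions (the package takes a species list to remove
up front). The 0.05 threshold is a convention, not derived from data.

## The synthetic-data generator

`make_synthetic_dataset()` emulates the study design the pipeline
expects: a fossil birth-death tree (default 110 species, birth 0.06 and
death 0.03 per lineage-My from a root at 230 Ma — rates chosen so a
theropod-scale clade accumulates that diversity over the available time);
log femur length evolving by BM (root $2.5 = 316$ mm, rate $10^{-3}$ per
My, giving roughly 1.5 orders of magnitude of body size); residuals drawn
from $\sigma_0^2 V(\lambda_0)$ with $V$ normalized to unit mean diagonal
so $\sigma_0 = 0.1$ is the residual scatter in log units; true slope 0.9
and $\lambda_0 = 0.93$; 30% of species with 2–3 specimens, extra
specimens ontogenetically smaller (uniform offset up to $-0.25$ log
units) and scattered around their species' trajectory with sd 0.03;
stratigraphic ranges of $\pm 2$ My; 30% of internal branches collapsed
into polytomies for the base topology. Deviating clades are carved out of
the simulated tree as monophyletic groups of a requested size with slope
and/or intercept shifts; additional no-effect clades serve as negative
controls.

What the generator does **not** emulate: taphonomic and geographic
sampling biases, measurement-protocol heterogeneity between publications
(a `measurement_sd` option exists but is off by default), body-mass
estimation error in the size proxy, and realistic diversification
dynamics (the process is stopped at a species quota, not conditioned on
survival shapes). Passing tests therefore demonstrate that the
*estimators* are correct and well calibrated under the model's own
assumptions — not that any real dataset satisfies those assumptions.

One limitation surfaced by the generator deserves emphasis: with
conspecific specimens on zero-length branches, the OU covariance cannot
discount their near-perfect correlation (unlike $\lambda$, which scales
all off-diagonals), so any intraspecific scatter pushes $\hat\alpha$
toward its decorrelation bound on specimen-expanded data. OU results are
therefore best interpreted on the reduced (one specimen per species)
variant, and OU estimates from low attraction strengths or small samples
carry a `caution` flag in any case.

## Problem sizes used in validation

The acceptance tests run 200 parameter-recovery replicates on 150-tip
fossil trees, 1000 null simulations of the deviation test at $n = 80$,
and 100 end-to-end power runs with a 25-species deviant clade at
$+0.2$ slope on 70-species datasets; the acceptance script analyses a
110-species/160-specimen synthetic study over 100 trees (50 for the
PANCOVA loop). These sizes were chosen to match the scale of the fossil
datasets this package targets while keeping a full validation run in the
minutes range on a single core; all of them are parameters, not
constants, and scale up directly.

## Known limitations

* The calibration sampler is a documented simplification of cal3, not a
  reimplementation; absolute node ages are stochastic stand-ins, and
  analyses that depend on precise divergence times should use externally
  calibrated trees (the pipeline accepts any calibrated `phylo`).
* CI degrees of freedom ignore the estimated signal parameter.
* The dependence correction for pooled p-values estimates a single mean
  correlation; strongly heterogeneous dependence between trees is
  averaged over.
* No phylogenetic reduced-major-axis option and no measurement-error
  model: the regression is asymmetric in its variables by design.
* No multiple-testing correction across candidate clades (the
  all-topologies consistency requirement is the only guard), matching
  the practice this pipeline formalizes.
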