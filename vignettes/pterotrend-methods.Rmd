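---
title: "Modelling wingspan macroevolution in fossil flying reptiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling wingspan macroevolution in fossil flying reptiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pterosaurs span roughly 160 million years of the Mesozoic and reached
wingspans above 10 m, an order of magnitude beyond the largest flying birds.
A long-standing question is whether that gigantism reflects Cope's rule —
active, sustained selection for larger size along lineages — or passive
processes such as the selective loss of small species. Answering it requires
(i) wingspans for as many species as the fossil record allows, although most
specimens are incomplete; (ii) a time-calibrated phylogeny, although
cladograms of fossils carry no branch durations and species' ages are only
known to stage-level windows; and (iii) trait models rich enough to separate
a drifting mean from attraction toward clade- or era-specific optima.

`pterotrend` implements that whole chain as composable, tested pieces:
stochastic time-calibration, phylogenetic imputation of missing measurements,
multi-regime Ornstein–Uhlenbeck (OU) model fitting with measurement error,
AICc-weight comparison aggregated over replicate calibrations, and
non-phylogenetic era-split trend regressions. A synthetic-data generator
produces complete study-like data sets (tree, measurement table,
stratigraphic ages) so every stage can be validated against known truth.

## Time calibration

Ages are measured in Ma before present, depths forward from the root; a
calibrated tree is an `ape::phylo` with branch lengths in Ma plus a
`root.time`, and all conversions go through `node_depths()` / `tip_ages()`
so the two conventions cannot be mixed accidentally.

Polytomies are resolved by seeded sequential random pairing of child
subtrees (`resolve_polytomies()`): uniform over the three resolutions of a
trichotomy, and able to reach all $(2k-3)!!$ resolutions of a $k$-tomy.
Tip ages are drawn uniformly within each taxon's stratigraphic window
(`sample_tip_ages()`). Node ages are then initialised at their minima (each
node as young as its oldest descendant) and repaired by one of two
procedures:

* **mbl** (`calibrate_mbl()`): a tips-to-root pass enforcing
  `parent_age >= child_age + min_bl`. Default `min_bl` is 2 Ma, with 1 Ma as
  the standard sensitivity variant.
* **equal** (`calibrate_equal()`): each maximal run of zero-duration
  branches, together with the positive-duration branch immediately above it,
  has that duration shared equally across the run by raising intermediate
  node ages. Because the run containing the globally oldest tip always
  reaches the root under minimum node ages, a `root_buffer` (extra root age)
  is required whenever that happens; with `root_buffer = 0` the situation is
  reported as an error naming the path.

The root receives no extra duration under `mbl` (root buffer 0); this is a
deliberate default and easy to vary for sensitivity analysis. Era paintings
(`paint_eras()`) split branches exactly at the boundary ages rather than
classifying whole branches by midpoint — exact splitting makes painted
durations tile the tree, which the likelihood code then verifies. Clade
paintings (`paint_clades()`) are stem-inclusive by default (`stem = FALSE`
flips to crown-only), matching common practice for multi-regime paintings.

## Trait assembly

A wingspan is the summed length of one wing's skeletal elements — humerus,
ulna, metacarpal IV and wing-finger phalanges 1–4 — times the taxon's
adult-rescaling factor, converted to metres and log10-transformed. The
radius is excluded from the sum as anatomically parallel to the ulna; the
element set is a configuration argument, not a constant.

Missing data are estimated in two stages, both by GLS regression under
Pagel's $\lambda$ (`pgls_fit()`):

1. Taxa missing only the terminal wing phalanx get it predicted from
   phalanx IV-3 under $\lambda = 1$ (`estimate_phalanx4()`); observed values
   are never altered and the operation is idempotent.
2. Remaining taxa receive a wingspan from the first available predictor in
   a preference cascade (`estimate_wingspan_cascade()`), default
   phalanx IV-2, then IV-1, then humerus, then mandible. Each predictor's
   regression is fitted on the directly computable subset, with $\lambda$
   chosen per predictor by AICc between the $\lambda = 0$ and $\lambda = 1$
   fits (`select_predictor()`), the ML $\lambda$ reported alongside.

$\lambda$ scales the off-diagonal entries of the Brownian *correlation*
matrix (the `corPagel` formulation), so $\lambda = 0$ is exactly ordinary
least squares on any tree — the natural reading on non-ultrametric fossil
trees, and the one under which the two fixed-$\lambda$ fits mean what their
names say. The ML search runs over $[-0.2, 1.3]$ (restricted to
positive-definite structures), wide enough to expose mildly negative or
above-1 signal estimates rather than silently clipping them.

Cascade estimates carry the predictor's *mean standard estimate error* (the
standard deviation of predicted-minus-known wingspans on the training taxa)
as their `se`; direct sums have `se = 0`, or a delta-method propagation of
the phalanx-IV-4 prediction error where that bone was imputed. These `se`
values become the measurement-error diagonal (`mserr`) of the trait models.
Outlier taxa (argument `exclude`) are dropped from regression *fitting*
only, never from the output. Juvenile- and subadult-only taxa are removed
before analysis (`filter_adults()`).

## The multi-regime OU model

Along each branch segment with regime $r$ the trait follows
$dX = \alpha_r(\theta_r - X)\,dt + \sqrt{\beta_r}\,dW$, with the root state
fixed. Families: `BM1`, `OU1`, and multi-regime `OUM` (regime optima),
`OUMV` (+ regime rates), `OUMA` (+ regime attractions), `OUMVA`. The root
is either aliased to the basal regime's optimum (`root_mode = "theta"`) or
estimated separately (`"separate"`, the "+ root" variants).

All moments come from one root-to-tips pass over painted segments: the
cumulative attraction load $\Lambda$ and accumulated variance per node give
$\mathrm{Cov}(X_i, X_j) = V_{\mathrm{mrca}}
e^{-(\Lambda_i-\Lambda_m)}e^{-(\Lambda_j-\Lambda_m)}$, and tip expectations
are convex combinations of $Z_0$ and the $\theta_r$ whose weights sum to 1
(`ou_covariance()`, `ou_mean_weights()`). Per-tip `se²` is added to the
covariance diagonal. The same transition densities drive the exact
simulator (`simulate_trait()`), so the analytic and Monte-Carlo routes are
coupled only through the mathematics — the test suite exploits this, and
retains a fine-step Euler–Maruyama integrator purely as an independent
oracle.

Fitting (`fit_model()`) optimises $\log\alpha$, $\log\beta$ by L-BFGS-B
from 8 seeded starts whose half-lives span 1 Ma to ten times the tree
depth; $\alpha$ is bounded below at $10^{-6}$/Ma inside OU families for the
stability of $1/\alpha$ terms, with Brownian motion its own family.
Conditional on $(\alpha, \beta)$ the optima are solved by GLS. Two
standard errors are reported for each optimum: `se_theta`, from the
observed information (numerical Hessian over all free parameters), and
`se_theta_conditional`, from the conditional GLS covariance. The
conditional value is what multi-regime OU software conventionally tabulates,
but recovery simulations here showed it undercovers — across 100 replicate
OUM fits the derived-regime optimum fell within ±2 conditional s.e. of
truth only ~85% of the time, because $\hat\alpha$ and $\hat\theta$ covary —
so the observed-information value is the primary reported uncertainty and
the conditional one is kept for comparability with published tables.

Parameter counts for AICc (`aicc()`, weights via `akaike_weights()`) are
explicit in code: BM1 = 2, OU1 = 3, and with $r$ regimes OUM = $2+r$,
OUMV = OUMA = $1+2r$, OUMVA = $3r$, plus 1 whenever the root is separate.
Derived quantities (`derived_quantities()`): phylogenetic half-life
$\ln 2/\alpha$ (infinite at $\alpha = 0$), the equivalent trend coefficient
$\mu = \alpha\theta$ with bounds $\alpha(\theta \pm 2\,\mathrm{se})$, and
optima back-transformed to metres.

## Trend regressions

`trend_regressions()` splits taxa at a boundary age (ties go to the older
interval) and fits both ordinary least squares and major-axis lines of
log10 wingspan on age; both are reported because published figures and
methods sections disagree about which was used, and their slopes agree in
sign whenever the correlation is appreciable. Ages enter as stratigraphic
midpoints by default (an option reuses sampled calibration ages). Slopes
are in log10(m)/Ma against age *before present*, so increasing size toward
the present is a negative slope; reversing the axis flips the sign exactly.
Major-axis confidence intervals come from a seeded 2000-resample bootstrap.

## Pipeline and aggregation

`run_pipeline()` repeats, for each of `n_replicate_trees` (default 25)
replicate calibrations: resolve → sample ages → calibrate → assemble traits
(regressions refitted on that tree) → paint configured schemes → fit all
models → AICc weights. Every random stage draws a child seed from the
master seed via `derive_seed(master, stage, replicate)`, so any stage is
independently reproducible and a fixed configuration yields byte-identical
outputs. Models that fail to converge are dropped for that replicate with
success counts reported. `aggregate_fits()` gives medians and absolute
ranges per parameter, median/IQR AICc weights, and filters models to those
with at least half the best median weight; half-lives are aggregated both
as median-of-derived and derived-of-median since the two orders differ.

## The synthetic generator

`sim_scenario()` fixes the study conditions the generator emulates: a
109-tip cladogram inside a 168-taxon measurement compilation, a ~160 Ma
span ending 66 Ma before present, stage-level age windows of 2–10 Ma, and a
two-era trait history — a constrained basal regime
($\alpha = 0.02$/Ma, $\theta = 0$ log10 m) switching at 145 Ma to a
weakly-attracted large optimum ($\alpha = 0.0056$, $\theta = 1.35$,
equivalent drift $\mu \approx 0.0076$ log10(m)/Ma), root at 0, per-tip
observation error 0.06 log10 m. Trees come from a high-turnover birth–death
simulation (birth 0.12, death 0.09 per Ma) retaining extinct tips, pruned
with stratified sampling over depth bins because fossil compilations sample
more evenly through time than a supercritical birth–death process does.
Element tables decompose each true wingspan into the seven wing elements
with noisy proportions that sum exactly, Brownian-structured for phalanges
and humerus but independent for ulna and radius (a functional, not
phylogenetic, correlation — so predictor selection faces the same
$\lambda$ contrast the real elements show). Missingness follows a
preservational gradient, heaviest distally and cranially, tuned once so
that the expected number of complete forelimbs is ~34 of 168.

What the generator does *not* emulate: correlated (block) loss of adjacent
elements within a specimen, heterogeneous sampling between marine and
terrestrial facies, taxonomic over-splitting, or body-plan covariation
beyond the single wingspan axis. Passing tests therefore demonstrate that
the machinery recovers what it assumes, under realistic sizes and noise —
not that the biological conclusions are insensitive to those unmodelled
features.

## Problem sizes and numerical choices

The test suite uses 4–6-tip fixed trees for closed-form and Monte-Carlo
oracle checks ($10^5$ exact-transition replicates), 100-tip trees for
parameter-recovery (100 replicates) and $\lambda$-recovery (100
replicates), 72-tip trees for the model-selection experiment (50
replicates, matching the study's adult sample size), and 40-tip studies for
end-to-end pipeline checks — sizes chosen to make each experiment's
sampling error small relative to the property being asserted. Convergence
tolerance is ~$10^{-8}$ on the log-likelihood (`factr = 1e7`); regime maps
are validated to tile branches within $10^{-8}$ Ma; mean-weight rows are
asserted to sum to 1 within $10^{-12}$.

## Known limitations

* The observed-information standard errors are asymptotic; very small trees
  or optima estimated from few effective observations (e.g. a separate root
  state on a shallow tree) can still be over-confident.
* `OUMA`/`OUMVA` likelihood surfaces are multimodal in earnest; 8 starts
  catch the common cases but a failure flag, not a guarantee, is what the
  pipeline propagates.
* The 'equal' calibration redistributes along a single descending chain per
  run; trees with many exactly tied tip ages can depend on edge order for
  which chain is processed first (the result is deterministic, but not
  unique mathematically).
* Imputation standard errors are per-predictor constants (mean standard
  estimate error), not pointwise prediction intervals — the convention the
  downstream measurement-error model expects.
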