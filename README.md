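# pterotrend

Macroevolutionary analysis of body size in fossil clades, built around the
pterosaur wingspan problem: did 160 million years of flying-reptile
evolution follow Cope's rule — sustained, active selection toward larger
size — or something more passive?

The package implements the full analytical chain needed to ask that
question of a fossil compilation:

* **Stochastic time-calibration** of a cladogram against stratigraphic age
  ranges: random polytomy resolution, uniform tip-age draws within each
  taxon's window, and either minimum-branch-length (`mbl`, default 2 Ma) or
  duration-sharing (`equal`) node-age repair, replicated over seeds.
* **Phylogenetic imputation** of missing measurements by GLS under Pagel's
  λ (the corPagel convention, so λ = 0 is exactly OLS): the terminal wing
  phalanx is predicted from its neighbour, then wingspans are estimated
  through a predictor cascade (phalanx IV-2, IV-1, humerus, mandible),
  with per-predictor λ chosen by AICc and a mean standard estimate error
  attached to every imputed value.
* **Multi-regime Ornstein–Uhlenbeck models** on non-ultrametric calibrated
  trees with per-tip measurement error: `BM1`, `OU1`, `OUM`, `OUMV`,
  `OUMA`, `OUMVA`, with regimes painted by clade (stem-inclusive) or by
  time slice (branches split exactly at era boundaries), and the root state
  either aliased to the basal optimum or estimated separately. Along each
  branch segment `dX = α_r(θ_r − X)dt + √β_r dW`; tip means and covariances
  are assembled analytically in one root-to-tips pass, and fits are
  compared by AICc weights.
* **Era-split trend regressions** (OLS and major axis) of log10 wingspan
  on geological age, the non-phylogenetic view of the same history.
* **A synthetic-data generator** that emulates the study conditions — a
  109-tip fossil cladogram inside a 168-taxon measurement table, 2–10 Ma
  age windows, a constrained-then-trending two-era trait history, and a
  preservational missingness gradient leaving ~34 taxa with complete
  forelimbs — so the whole pipeline is testable against known truth.

Derived quantities follow the field's conventions: phylogenetic half-life
`ln(2)/α` (Ma), the equivalent trend coefficient `μ = α·θ` with bounds
`α(θ ± 2 se)` (log10(m)/Ma), and optima back-transformed to metres.

## Worked example

Generate a synthetic study, run three replicate calibrations through the
full pipeline, and compare single- against two-era models:

```r
library(pterotrend)

study <- simulate_study(sim_scenario(seed = 7), dir = "study")
cfg <- pipeline_config(
  tree = "study/tree.nwk", measurements = "study/measurements.csv",
  ages = "study/ages.csv",
  n_replicate_trees = 3, calibration = "mbl", min_bl = 2,
  era_schemes = list(time2 = 145),
  families = c("OUM", "OUMV"), single_families = c("BM1", "OU1"),
  seed = 1)
res <- run_pipeline(cfg)
agg <- aggregate_fits(res)

agg$model_weights
#>        model n_success weight_median weight_q1 weight_q3
#> 4 OUMV_time2         3         0.958     0.934     0.959

agg$params[agg$params$model == "OUM_time2", ]
#>       model regime alpha_median half_life_median theta_median theta_m_median mu_median
#> 3 OUM_time2   era1      0.00824             84.1       0.0173           1.04  0.000145
#> 5 OUM_time2   era2      0.00824             84.1       0.8917           7.79  0.007347

res$trend[res$trend$method == "ols", c("label","n","slope","slope_lo","slope_hi","p_value")]
#>     label  n     slope slope_lo slope_hi  p_value
#> 1   older 16  0.000435 -0.00201  0.00289 7.09e-01
#> 3 younger 75 -0.004461 -0.00645 -0.00247 2.84e-05
```

Reading the output: the two-era models absorb essentially all AICc weight
(0.96 to the regime-rate variant), and the two views of the history agree —
before 145 Ma the size-vs-age regression is flat (slope ≈ 0.0004, CI
spanning zero, n = 16), while afterwards sizes climb toward the present
(slope −0.0045 log10(m)/Ma, p < 10⁻⁴, n = 75). The fitted era-2 optimum
(0.89 log10 m ≈ 7.8 m) lies above the observed size range with weak
attraction: a sustained directional trend, whose equivalent drift rate
`μ = α·θ ≈ 0.0073` log10(m)/Ma matches the generating value (0.0076) and
the absolute regression slope — the signature of along-lineage, Cope's-rule
evolution rather than species sorting.

A thin command-line wrapper lives at `inst/cli/pterotrend.R`
(`run --config config.yaml`, `calibrate --tree t.nwk --ages a.csv ...`).

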