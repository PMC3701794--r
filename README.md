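# ssysnet — S-system network inference from metabolite time courses

`ssysnet` is for researchers who have longitudinal concentration profiles —
for example weekly plasma amino-acid measurements from healthy and diseased
animals — and want to move beyond per-metabolite comparisons to the
*interactive* structure behind them: which metabolite influences which,
in which direction, and which of those influences dominates, and how the
network rewires between conditions.

## The model and method

Dynamics are modeled as an S-system, the canonical power-law ODE formalism
with one synthesis and one degradation term per component:

    dXi/dt = alpha_i * prod_j Xj^g_ij  -  beta_i * prod_j Xj^h_ij

The signed exponents `g_ij`/`h_ij` (interrelated coefficients) are the
directed network: `g_ij > 0` means component *j* activates the synthesis of
component *i*. The package provides:

* **Forward simulation** (`ssys_integrate`, compiled right-hand side,
  stiff-capable adaptive solver) and log-linear **steady states**
  (`steady_state`).
* **Inference** (`ssys_fit`): a real-coded genetic algorithm (UNDX
  crossover under minimal-generation-gap alternation, multi-start,
  fully seeded) minimizing the average relative error per sampling point
  `E = 100/(N T) * sum |X_cal - X_exp| / X_exp` (percent). Returns a classed
  fit object with `print`, `summary`, `coef`, `fitted`, `residuals`,
  `predict`, `plot` and `simulate` methods.
* **Sensitivity ranking** (`sensitivity_analysis`): each nonzero coefficient
  perturbed by +5%, trajectory deviation summarized as mean squared relative
  deviation, scaled so the top path scores exactly 100.
* **Condition comparison** (`compare_networks`): edge-by-edge pairing of two
  fitted networks with sign-reversal flags; SIF/GraphML export
  (`export_network`).
* **Variable selection** (`rank_by_correlation`, `select_top`): Pearson
  correlation of candidate variables against a reference series (e.g. blood
  sugar), ranked by |r|.
* **Synthetic data** (`generate_dataset`, `make_recovery_problem`):
  seeded generation of weekly time courses with multiplicative lognormal
  noise at a configurable coefficient of variation (default 10.07%), and
  random sparse stable recovery problems with known ground truth.
* **Fixtures**: the published 5-amino-acid network parameter sets for
  healthy (`Ins2+/+`) and hyperglycemic (`Ins2+/-`) mice
  (`load_fixture_model`), plus the blood-sugar correlation table
  (`load_fixture_correlations`).
* **Pipeline** (`run_pipeline` and `inst/scripts/ssysnet.R`): select → fit
  per condition → sensitivity → compare, with a manifest that reproduces
  every number.

## Worked example

Recover a known sparse 3-variable network from its own noiseless weekly
course, then rank and compare:

```r
library(ssysnet)

prob <- make_recovery_problem(n = 3, sparsity = 0.5, seed = 42)
fit <- ssys_fit(prob$data, mask_g = prob$model$mask_g,
                mask_h = prob$model$mask_h,
                control = ssys_control(profile = "desk"), seed = 1)
fit
#> S-system network fit (3 variables, 3 trial(s), profile 'desk')
#> Selected trial: 3
#> Average relative error per sampling point: 0.04168 %

rank_paths(sensitivity_analysis(fit$model, prob$x0, prob$data$times), top_k = 3)
#>   matrix  i  j       raw scaled rank
#> 1      h X1 X1 1.551e-05 100.00    1
#> 2      h X2 X2 1.108e-05  71.44    2
#> 3      g X2 X1 9.575e-06  61.73    3

cmp <- compare_networks(load_fixture_model("Ins2+/+"),
                        load_fixture_model("Ins2+/-"))
subset(cmp, status == "sign-reversal")[, c("matrix", "i", "j", "coeff_a", "coeff_b")]
#>    matrix   i   j coeff_a coeff_b
#> 5       g Val Gly    -1.8     0.1
#> 14      g Ile Ala    -2.3     0.4
#> 16      g Ala Val     0.8    -0.6
#> 17      g Ala Leu    -1.7     1.0
```

The fit error of 0.04% is far inside the 10% acceptance allowance (the
analytical measurement error of the underlying assay is about 10%, so a
model reproducing the data more closely than that is as good as the data
can distinguish). The sensitivity table says the self-degradation of X1 is
the most rigidly constrained path in the recovered network. The comparison
shows the four coefficient positions at which the two packaged condition
networks carry opposite signs — the rewiring signature between health and
hyperglycemia.

The methods vignette (`vignettes/ssystem-network-inference.Rmd`) documents
the model, the optimizer, all tunable parameters and the numerical-design
choices in detail.

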