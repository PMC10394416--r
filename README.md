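# spinedyn

Analysis and modelling of the right-skewed, lognormal-like distribution of
dendritic spine head sizes.

Spine head area is a morphological proxy for synaptic strength, and across
preparations its distribution is heavy-tailed and close to lognormal:

```
f(x) = 1/(x σ √(2π)) · exp(−(ln x − μ)² / 2σ²)
```

The striking experimental facts are that this shape survives the induction
of long-term potentiation/depression and persists even with presynaptic
transmitter release completely blocked. `spinedyn` implements the full
computational chain behind that observation, for neuroscientists analysing
spine-size tables and for modellers studying synaptic weight dynamics:

* **Distribution fitting** — integral-normalised histograms, nonlinear
  least-squares lognormal fits with r² goodness of fit, Gaussian fits to
  log-transformed sizes, skewness and log-sd ("sigma") diagnostics, and AIC
  comparison against gamma and Weibull (`fit_condition()`,
  `fit_lognormal()`, `compare_aic()`, ...).
* **Nonparametric group statistics** — Mann–Whitney, Friedman
  (repeated-measures across dendritic layers), Kruskal–Wallis, and
  Holm-corrected post hoc rank tests over per-cell fit metrics
  (`run_comparison_suite()`).
* **A weight-dynamics simulator** — populations of leaky integrate-and-fire
  neurons whose synapses evolve under intrinsic Kesten-type
  multiplicative/additive noise, exponential-window STDP
  (w → w + c_p·e^(−|Δt|/τ) for pre-before-post, w → w(1 − c_d·e^(−|Δt|/τ))
  for post-before-pre), and uniform heterosynaptic scaling that holds each
  neuron's total conductance constant (`run_simulation()`,
  `run_protocol_suite()`).
* **Simulation-based inference** — sequential rejection-ABC with importance
  weights, recovering six plasticity parameters from the lognormal (μ, σ)
  features of the silent / 10 Hz control / 200 Hz HFS protocols
  (`sequential_infer()`, `map_estimate()`).
* **Synthetic data** — seeded generators emulating the condition structure
  of the two experimental designs (dentate adult-born granule cells:
  3 layers × 3 cell ages × 2 hemispheres; CA1 cultures: 2 genotype groups ×
  3 ages × spine types with fixed proportions and a mushroom/thin size
  cutoff), so the entire pipeline runs without any data download
  (`generate_spine_table()`).

See the vignette `vignettes/spine-size-dynamics.Rmd` for the models,
assumptions, parameter defaults and known limitations.

## Worked example

Generate a synthetic granule-cell spine table, fit every condition, and run
the uniform-to-lognormal generation experiment:

```r
library(spinedyn)

tab <- generate_spine_table(generator_config("abGC", seed = 1))
nrow(tab)
#> [1] 17631

pooled <- fit_condition(tab, "pooled")
head(pooled[, c("layer", "age", "side_or_group", "n", "mu", "sigma",
                "r2", "skewness", "best_model")], 4)
#>   layer age side_or_group    n     mu sigma    r2 skewness best_model
#> 1   IML  21        contra  933 -0.968 0.511 0.984     1.45  lognormal
#> 2   IML  21          ipsi  943 -0.995 0.523 0.977     1.91  lognormal
#> 3   IML  28        contra  951 -1.010 0.494 0.986     1.97  lognormal
#> 4   IML  28          ipsi 1002 -0.994 0.423 0.988     1.14  lognormal

demo <- run_generation_demo(n_synapses = 1e4, mult_strength = 0.2,
                            duration = 100, seed = 1)
w <- as.numeric(demo$final_weights); w <- w[w > 0]
fit <- fit_lognormal_sample(w, 30)
c(r2 = fit$r2, skewness = sample_skewness(w))
#>        r2  skewness
#>     1.000      24.8
```

Each pooled row is one experimental condition: `mu`/`sigma` are the fitted
lognormal parameters of the head-area density (log-µm² units), `r2` how well
the lognormal reproduces the binned data, `skewness` the right-asymmetry of
the raw sizes, and `best_model` the AIC winner among lognormal, gamma and
Weibull — here lognormal throughout, with r² ≈ 0.98 matching the quality of
fit reported for pooled experimental conditions. The generation demo starts
from uniformly distributed weights and applies only multiplicative noise;
the final distribution is lognormal to r² ≈ 1.0 with strongly positive
skewness, the signature that intrinsic noise alone generates the shape.

A thin command-line front end over the same functions lives at
`inst/scripts/spinedyn.R` (subcommands `synth`, `fit`, `stats`, `simulate`,
`study`).

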