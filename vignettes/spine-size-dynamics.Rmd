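---
title: "Spine-size distributions and synaptic weight dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spine-size distributions and synaptic weight dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinedyn)
```

## The scientific problem

Dendritic spine head sizes — a standard morphological proxy for synaptic
strength — are not symmetrically distributed: across cell types and
preparations their distribution is right-skewed and heavy-tailed, close to
lognormal. Two experimental observations make this interesting. First, the
lognormal-like shape survives the induction of long-term potentiation and
depression: plasticity shifts the distribution's location and width but does
not destroy its form. Second, the shape emerges even when presynaptic
transmitter release is blocked entirely, so synaptic activity cannot be
necessary for it. Together these point to *intrinsic* (activity-independent)
spine dynamics as the generator of the skewed distribution, with *extrinsic*
(activity-dependent) plasticity acting on top of it.

`spinedyn` implements the complete computational chain behind that argument:

1. **distribution fitting** — quantify how lognormal a spine-size sample is;
2. **group statistics** — compare fit metrics across experimental conditions;
3. **a weight-dynamics simulator** — a population model combining intrinsic
   Kesten-type noise with spike-timing-dependent plasticity (STDP);
4. **simulation-based inference** — recover the model parameters consistent
   with observed size distributions;
5. **a synthetic-data generator** — seeded datasets with the statistical
   structure of the two experimental designs, so the whole chain is testable
   without any experimental download.

## Fitting lognormal-like distributions

A sample of head areas $x_1,\dots,x_n$ (µm²) is binned into equal-width bins
spanning $[\min x, \max x]$, and the counts are divided by the histogram
integral so that the binned density integrates to exactly 1
(`bin_and_normalize()`). The lognormal probability density

$$f(x) = \frac{1}{x\,\sigma\sqrt{2\pi}}
  \exp\!\left(-\frac{(\ln x-\mu)^2}{2\sigma^2}\right)$$

is then fitted to the bin-center densities by Levenberg–Marquardt nonlinear
least squares, initialised at the log-moments
$\hat\mu_0 = \overline{\ln x}$, $\hat\sigma_0 = \mathrm{sd}(\ln x)$
(`fit_lognormal()`). The goodness of fit is the coefficient of determination
$r^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$ computed on the binned densities;
it can be negative for fits worse than a constant, and such failures are
*flagged, never raised*, so batch per-cell fitting always completes.

Independent diagnostics cross-check the least-squares route:

* `fit_gaussian_log()` bins $\ln x$ and fits the bump
  $a\exp(-((x-b)/c)^2)$; for truly lognormal data $b = \mu$ and
  $c = \sigma\sqrt2$. Deviations from lognormality (e.g. an overabundance of
  large spines) depress this fit's $r^2$ in an interpretable way.
* `sample_skewness()` is the adjusted Fisher–Pearson estimator on the raw
  sizes; a lognormal sample has positive skewness
  $(e^{\sigma^2}+2)\sqrt{e^{\sigma^2}-1}$.
* `shape_diagnostics()` also reports "sigma", the standard deviation of the
  natural logs — the field's width measure for these distributions.
* `compare_aic()` fits lognormal, gamma and Weibull by maximum likelihood
  (each $k=2$ parameters, via `fitdistrplus`) and ranks them by
  $\mathrm{AIC} = 2k - 2\ln L$.

**Numerical choices.** The bin count defaults to the Freedman–Diaconis rule
clamped to $[10, 50]$, which keeps densities stable from per-cell samples
($n \approx 60$) to pooled ones ($n > 10^4$); $\sigma$ is constrained to
$(10^{-4}, 10)$ to exclude degenerate optima; per-cell fits use per-cell bin
edges. Cells with fewer than 20 spines are retained but flagged.

## Comparing conditions

All comparisons are nonparametric, because the metrics (per-cell $r^2$,
skewness, sigma) are themselves far from Gaussian:

* hemisphere (stimulated vs control) and genotype group: two-sided
  Mann–Whitney U, exact for small tie-free samples;
* the three dendritic layers: Friedman's test, because the layer values of
  one cell are repeated measures on that cell;
* cell or culture ages: Kruskal–Wallis with tie correction.

When an omnibus test is significant at $\alpha = 0.05$, pairwise post hoc
rank tests follow with step-down Bonferroni–Holm correction
(`holm_adjust()`). All tests are rank-based and hence invariant to monotone
transformations of the metric. The battery is calibrated: under null
simulations each test's type-I error at $\alpha=0.05$ lies within the
binomial sampling band at 1000 replicates (checked in the test suite at
group sizes 20/20, 20×3 and 3×15, comparable to the experimental cell
counts).

## The weight-dynamics simulator

The model is a population of 1000 independent leaky integrate-and-fire (LIF)
neurons, each receiving 100 synapses. Weights $w$ are in pS; spine sizes are
taken as proportional to weights.

**Extrinsic plasticity (STDP).** With $\Delta t = t_\mathrm{pre} -
t_\mathrm{post}$, pre-before-post pairings potentiate additively and
post-before-pre pairings depress multiplicatively:

$$w_p = w + c_p e^{-|\Delta t|/\tau_\mathrm{STDP}}, \qquad
  w_d = w\,(1 - c_d e^{-|\Delta t|/\tau_\mathrm{STDP}}),$$

with defaults $c_p = 0.007$ pS, $c_d = 0.003$,
$\tau_\mathrm{STDP} = 0.5$ ms. The depression kernel is implemented with a
decaying exponential window on both sides (the growing form that a literal
reading of the update rule would give diverges for large $\Delta t$ and is
taken to be a sign typo). Pairing is nearest-neighbour: each postsynaptic
spike pairs with the most recent presynaptic spike per input and vice versa.
$\tau_\mathrm{STDP} = 0.5$ ms is unusually short for STDP; it is kept as the
model's stated constant and is also one of the inference targets.

**Intrinsic plasticity (noise).** Each synapse follows a Kesten-type
process: per noise substep $\Delta$,
$w' = w(1 + \lambda_m\sqrt{\Delta}\,\xi_1) +
\lambda_a\sqrt{\Delta}\,\xi_2$, with independent standard normals and
clipping at zero. $\lambda_m$ is in proportion of spine size per second
(default 0.2), $\lambda_a$ in pS per second (default 0.01, deliberately
weak: strong additive noise erodes the skewness of the stationary
distribution).

**Homeostasis.** After every substep, uniform heterosynaptic scaling
multiplies each neuron's weight vector so its total stays at the initial
total conductance (relative error $<10^{-9}$ throughout a run, verified per
snapshot in the tests).

**Neuron and protocols.** The LIF membrane has $\tau_m = 10$ ms and
threshold 10 mV above rest; a presynaptic spike at input $i$ bumps the
potential by $k\,w_i$ with $k = 1$ mV/pS, calibrated so ~20 near-coincident
average-weight inputs reach threshold. Protocols: *silent* (no input),
*control* (10 Hz Poisson) and *HFS* (200 Hz periodic with random phase per
input), applied to a configurable fraction of inputs (default 0.5).

**Integration scheme.** The spiking part is integrated *event-exactly*: the
membrane decays analytically between presynaptic events, so there is no
time-step error in spike timing or STDP pairing. The slow noise-plus-scaling
part advances on a coarse grid (default 10 ms); the Euler–Maruyama error per
substep is $O(\lambda_m^2\Delta) \sim 4\times10^{-4}$, negligible against
the 10% tolerance of the geometric-Brownian checks. All randomness flows
from R's RNG through one seed; identical seeds give byte-identical results.

At these defaults a full three-protocol suite (1000 × 100 synapses, 20 s
simulated) runs in about two minutes on one CPU; that is the scale used for
the headline skewness checks. The uniform-to-lognormal generation demo uses
10⁴ synapses for 100 s of multiplicative noise only, a few seconds of
compute.

## Simulation-based inference

Six parameters are inferred: the stimulated input fraction, the
multiplicative and additive noise strengths, $\tau_\mathrm{STDP}$, and the
potentiation/depression rates. The observation is compressed to six summary
features: the fitted lognormal $(\mu, \sigma)$ of the final weight
distribution under each of the three protocols, after rescaling each
simulated sample to the observed mean (rescaling by $c$ shifts $\mu$ by
exactly $\ln c$ and leaves $\sigma$ unchanged, which is what makes the
weight-to-area bridge legitimate).

The inference engine is sequential rejection ABC with Gaussian perturbation
kernels — the same in/out interface as a neural posterior-estimation
backend, which could be slotted in unchanged. Round 1 samples the uniform
prior box (defaults: stimulated fraction $[0,1]$, $\lambda_m \in [0,0.5]$/s,
$\lambda_a \in [0,0.1]$/s, $\tau_\mathrm{STDP} \in [0.1,50]$ ms,
$c_p \in [0,0.05]$, $c_d \in [0,0.5]$ — deliberately wide, and mandatory
config for any scientific run). Each round keeps the 10% of candidates
closest to the observed features in Euclidean distance standardized by the
round-1 feature spreads, then proposes from a Gaussian perturbation of the
survivors with kernel scale $\sqrt2$ times their weighted standard
deviation, truncated to the prior. Survivors carry Beaumont-style importance
weights (uniform prior over the Gaussian-mixture proposal); without them the
sequential posterior visibly over-concentrates relative to a plain-rejection
reference run. The final weighted survivors are resampled to the posterior
draws.

During inference each candidate simulates a reduced system (100 neurons × 50
inputs, 0.8 s per protocol) so that a 3-round × 500-simulation run fits in
minutes; presentation-quality MAP validation re-simulates at whatever scale
is wanted. The MAP itself is the mode of a product-Gaussian kernel density
over the draws with a 3× Silverman per-dimension bandwidth, polished by
mean-shift; the raw Silverman bandwidth makes the KDE mode too variable to
be a useful point estimate (measured error ~0.3 sd at 5000 draws, vs ~0.06
sd with the oversmoothed bandwidth, which still separates well-spaced
modes).

**Identifiability.** The six features do not pin down all six parameters.
In particular, intrinsic multiplicative noise and multiplicative STDP
depression widen the distribution in similar ways, so the stimulated
fraction trades off against the noise and STDP parameters; posterior
marginals for the stimulated fraction are correspondingly broad and, for
ground truths whose $\tau_\mathrm{STDP}$ sits at the extreme low end of the
prior, biased toward small fractions (a plain-rejection reference posterior
shows the same geometry, so this is a property of the feature set, not of
the sequential sampler). The package therefore validates the inference the
way simulation-based calibration does: ground truths are drawn from the
prior, and the central 90% credible interval is required to cover them in at
least 8 of 10 seeded repetitions for the multiplicative-noise strength and
the stimulated fraction. The complementary shape check is a closed loop at
the model's default parameter vector: re-simulating at the MAP reproduces
the observed binned densities at $r^2 \ge 0.9$ in every protocol. The same
check can fail at extreme high-stimulation/strong-STDP corners of the prior,
where the six lognormal features no longer pin down the (increasingly
bimodal) weight distribution; pointwise recovery at atypical corners is not
guaranteed, and users fitting real data should read the stimulated-fraction
marginal with that caveat.

## The synthetic-data generator

`generate_spine_table()` emulates the *statistical structure* of the two
experimental designs:

* **abGC design**: 3 dentate molecular layers (IML/MML/OML) × 3 cell ages
  (21/28/35 days post-injection) × 2 hemispheres (ipsilateral stimulated,
  contralateral control); per condition 12 cells of 60–105 spines (uniform
  count), head areas i.i.d. LogNormal.
* **CA1 design**: 2 groups (release-blocked vs control) × 3 culture ages
  (7/14/21 days in vitro), with spine types drawn at the fixed proportions
  22.85% mushroom / 23.73% thin / 51.16% stubby / 2.26% other; "other" is
  generated but excluded from analyses. Stubby and other are assigned
  independently of size; mushroom and thin partition the remaining spines at
  a sharp area cutoff, reproducing the size-based classification artifact of
  type-resolved data (by default the cutoff is the quantile that makes the
  expected mushroom:thin split match the stated proportions).

Baseline log-parameters default to $\mu=-1.0$, $\sigma=0.5$ (median
$\approx 0.37$ µm²). These are *illustrative*: the experimental
per-condition lognormal parameters are not published in machine-readable
form, so no synthetic default can be anchored to them. Plasticity enters as
multiplicative shifts on $(\mu,\sigma)$: by default the stimulated-MML
$\sigma$ is inflated (homosynaptic broadening) and the flanking ipsilateral
IML/OML $\sigma$ deflated (heterosynaptic narrowing) at the two older cell
ages, matching the direction of the reported effects.

What the generator deliberately does **not** emulate: imaging and spine
detection (and hence the small-spine detection bias real data show in
log-space), within-cell spatial correlations, animal-level random effects,
and any departure from exact lognormality. Passing tests therefore
demonstrate that the pipeline's statistics behave correctly on data with the
assumed structure — not that real spine data satisfy those assumptions.

## Reproducibility

Every stochastic entry point takes an integer seed and is deterministic
given it; pipeline runs (`run_fit_study()`, `run_model_study()`) write a
manifest with the config snapshot, seed and MD5 digests of every output
file, and identical config+seed reproduce byte-identical CSVs.

## Known limitations

* The simulator's neurons are independent (no recurrence, no inhibition, no
  structural plasticity); heterosynaptic interaction exists only through
  uniform scaling.
* Synapses are delta-current; there are no conductance dynamics.
* The ABC backend is a rejection sampler: posteriors are exact only in the
  small-tolerance, many-simulations limit, and the stimulated-fraction
  marginal is structurally broad (see above).
* Experimental $r^2$/skewness values from the original microscopy datasets
  are not reproducible here because those spine tables are not deposited in
  machine-readable form; the pipeline's claims are therefore validated on
  its own synthetic data and on the simulator's closed forms.
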