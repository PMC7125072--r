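---
title: "Threshold kinetics for hydrogen-limited acetogen growth: models, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold kinetics for hydrogen-limited acetogen growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetokin)
```

## The biological problem

Reductive acetogens such as *Blautia hydrogenotrophica* grow by converting
hydrogen and carbon dioxide to acetate along the Wood–Ljungdahl pathway,

$$4\,\mathrm{H_2} + 2\,\mathrm{CO_2} \rightarrow
  \mathrm{CH_3COO^-} + \mathrm{H^+} + 2\,\mathrm{H_2O},$$

a metabolism relevant both to the gut microbiome (hydrogen cross-feeding)
and to syngas fermentation in bioreactors.  A robust empirical observation
for this organism is a *hydrogen uptake threshold*: below a hydrogen
concentration of roughly 70–90 mM, net uptake essentially stops.  Plain
Monod kinetics cannot produce such a plateau — uptake only vanishes as
$H \to 0$ — so batch cultures that level off near 90 mM hydrogen are fit
poorly by the textbook model.

`acetokin` implements a family of batch-culture models spanning the
standard and threshold formulations, the machinery to calibrate them
against time-course data by MCMC, a synthetic-data generator for recovery
studies, and the closed-form analyses (stoichiometric bounds, steady
states, unit conversions) that go with them.

## Model family

All structures track hydrogen $H$ (mM), acetate $P$ (mM) and cell dry
weight $X$ (g L$^{-1}$), and share two equations that follow from pathway
stoichiometry and a constant specific death rate $k_d$:

$$\frac{dP}{dt} = -\frac14 \frac{dH}{dt}, \qquad
  \frac{dX}{dt} = -Y \frac{dH}{dt} - k_d X .$$

The structures differ only in the hydrogen uptake law:

| structure | $dH/dt$ | parameters |
|---|---|---|
| `monod` | $-\dfrac{\mu_{max} X}{Y}\dfrac{H}{K_H + H}$ | $\mu_{max}, K_H, Y, k_d$ |
| `first_order` | $-\dfrac{\eta X H}{Y}$ | $\eta \simeq \mu_{max}/K_H$ |
| `t1` | $-\dfrac{\eta X H^{*}}{Y}$, $H^{*} = \max(H - H_t, 0)$ | adds $H_t$ |
| `t2` | $-\dfrac{\eta X H}{Y} F(H)$, $F = \dfrac{1}{1+e^{A(T-H)}}$ | adds $A, T$ |
| `t3` | $-\dfrac{X}{Y}\dfrac{\mu_{max,H} H/K_H - \mu_{max,R} P/K_R}{1 + H/K_H + P/K_R}$ | $\mu_{max,H}, \mu_{max,R}, K_H, K_R$ |

The first-order law is the small-$H$ linearisation of Monod: a single
batch time course informs only the *ratio* $\mu_{max}/K_H$, not the two
parameters separately (see "non-identifiability" below), which is why the
threshold variants T1 and T2 are built on the linearised law.  T1 imposes
a hard cutoff — simple, but with a derivative kink at $H_t$.  T2 (after
Ribes et al.) gates uptake with a smooth sigmoid; $A$ and $T$ are tuning
parameters with only indirect biological meaning.  T3 treats the pathway
as a reversible Michaelis–Menten reaction; the "threshold" emerges as the
hydrogen level at which forward and reverse fluxes balance, and all four
kinetic parameters have direct reaction interpretations.

Two non-linearised variants (`t1_nonlinear`, `t2_nonlinear`: the hard
cutoff and double-sigmoid constructions inside a full Monod term) are
provided as derivative functions for completeness but are excluded from
default fitting, since their $\mu_{max}/K_H$ pair inherits the Monod
non-identifiability.  On the printed form of the double-sigmoid
construction: the source literature defines the pair $f, F$ with a
duplicated label in print; only $F$ enters the linearised T2 equation, and
we take $f = 1/(1+\exp(A(H_t - H)))$ (the form that rises with $H$
towards 1 above the threshold) for the non-linearised variant, flagging
rather than guessing any further role for it.

A two-substrate extension adds a pooled yeast-extract substrate $E$ (mM)
consumed with first-order kinetics,

$$\frac{dE}{dt} = -\frac{\eta_E X E}{Y_E}, \qquad
  \frac{dP}{dt} = -\frac14\frac{dH}{dt} - b_{EP}\frac{dE}{dt}, \qquad
  \frac{dX}{dt} = -Y\frac{dH}{dt} - Y_E\frac{dE}{dt} - k_d X,$$

leaving the hydrogen equation untouched.  $b_{EP}$ is the moles of
acetate produced per mole of yeast extract consumed.  The extension is
attached to the T2 and T3 structures, the setting in which it is normally
used.  The packaged extension values (`dsmz_extension_params()`) are
explicitly hypothetical demonstration values, not fitted estimates.

Out of scope by design: gas–liquid mass transfer (dissolved-phase data
are unavailable for the motivating experiments, and under batch
conditions threshold estimates are only weakly affected — though growth
rates may be underestimated), maintenance-energy substrate use, and pH or
CO$_2$ dynamics.

## Simulation

`simulate_model()` integrates any structure with `deSolve::lsoda`
(adaptive, stiff-capable) at `rtol = 1e-8`, `atol = 1e-10` by default.
The T1 kink and steep T2 gates can make the system locally stiff; lsoda's
method switching absorbs this, and the kinked RHS is continuous (though
not differentiable) at $H_t$, which an adaptive solver tolerates without
event detection.  Derivatives are evaluated in compiled C for speed; the
pure-R derivative functions are the reference implementation and the test
suite asserts both backends agree.  Output states are clipped at zero
(integrator overshoot is cosmetic at these tolerances; the clip magnitude
is retained on the trajectory).  The exact conservation law
$P(t) - P(0) = (H(0) - H(t))/4$ of the single-substrate models is used
throughout the tests as an integration-quality probe
(`conservation_residual()`), and holds below $10^{-6}$ mM at default
tolerances.

```{r}
tr <- simulate_model(reference_params("t1"),
                     culture_state(H = 400, P = 0, X = 0.01),
                     times = seq(0, 80, by = 16))
as.data.frame(tr)
```

Hydrogen plateaus at the threshold (86.2 mM) rather than at zero — the
qualitative signature that motivates the threshold family.

## Calibration

`mcmc_fit()` samples the parameters of any structure against the
objective of `fit_objective()`: the sum of squared residuals, each
normalised by a per-observation scale.  Design choices, and why:

* **Normalisation.**  Three policies are available.  `"sd"` (default)
  divides by the observation's replicate standard deviation where
  available, falling back to the variable's mean level — this uses the
  dispersion information that published figures provide as error bars.
  `"mean"` always uses the variable's mean level.  `"value"` divides by
  the observation itself (floored at 10% of the variable mean), i.e.
  relative residuals.  For data whose noise is multiplicative with a
  constant coefficient of variation — which is what the synthetic
  generator produces and what signal-proportional error bars suggest —
  `"value"` matches the true error structure.  In our recovery studies
  the `"sd"` policy with triplicate-based SDs gave poorly calibrated
  intervals: an empirical SD from $n=3$ is so noisy that its reciprocal
  square is a heavy-tailed (F-distributed) weight, and interval coverage
  dropped well below nominal.  Recovery experiments in the test suite
  therefore fit with `normalisation = "value"`.
* **Sampler.**  Adaptive random-walk Metropolis on log-parameters (all
  parameters are positive and span orders of magnitude).  The proposal
  covariance is learned during burn-in from the running sample
  covariance (scaled by $2.38^2/d$, the classic optimal-scaling factor)
  and frozen afterwards, so the post-burn-in chain is a valid Markov
  chain.  Covariance adaptation matters here: several parameter pairs
  (notably $\mu_{max}$–$K_H$) are strongly ridge-correlated and a
  diagonal proposal mixes hopelessly slowly along the ridge.
* **Target density.**  The fitting literature behind this model family
  specifies only "minimise the sum of normalised squared differences".
  We give the objective a probabilistic reading: Gaussian errors with the
  stated per-point scales and an unknown global variance factor, which is
  marginalised under a Jeffreys prior, yielding
  $\log p(\theta \mid y) = -(n/2)\log Q(\theta)$ for objective $Q$ and
  $n$ observations.  This keeps credible intervals calibrated against
  the actual scatter of the data (a fixed $e^{-Q/2}$ target would make
  interval widths depend on an arbitrary overall scaling of the weights)
  and concentrates on the exact optimum for noiseless self-fits.
* **Priors and initialisation.**  Flat priors on log-parameters within
  bounds defaulting to $\pm 3$ decades around the starting values; chains
  start at the supplied parameter record (jittered for chains 2+).
  Initial *states* are taken from the first observation of each variable,
  not fitted.
* **Summaries.**  `best_fit` is the minimum-objective sample (the
  posterior mode proxy; the posterior median is also reported — the two
  can differ and the mode may sit outside the central interval); `ci95`
  is the central 2.5–97.5% posterior interval; convergence is flagged by
  split-$\widehat R < 1.05$; pairwise Pearson correlations of the pooled
  samples expose identifiability structure.
* **Degenerate cases.**  Integration failures make the objective $+\infty$
  (proposal rejected).  A run in which no proposal is ever accepted stops
  with a diagnostic error — unless the chain started at an essentially
  perfect fit, where rejecting everything is the correct behaviour.

### Non-identifiability of the Monod pair

On a single batch curve with $H \ll K_H$ throughout (or with $K_H$ large),
the likelihood depends on $\mu_{max}$ and $K_H$ almost solely through
$\mu_{max}/K_H$.  The posterior is then a ridge: marginal intervals for
both parameters are enormous (the $K_H$ interval is wider than the value
itself), while their correlation approaches 1.  The test suite reproduces
this qualitatively on synthetic single-batch Monod fits
($|\rho(\mu_{max}, K_H)| > 0.9$).  This is the practical reason the
linearised (first-order) law and its threshold variants are the preferred
fitting structures.

## Synthetic data

`generate_dataset()` draws replicate observations as
$y = \text{truth}\cdot(1+\varepsilon)$, $\varepsilon \sim
\mathcal N(0, \text{cv})$, truncated at zero, and stores replicate means
and SDs — the structure of figure-derived triplicate data.  For
$\text{cv} \le 0.2$ truncation is a $<5\sigma$ event, so the mean bias is
far below 1% (checked by simulation in the tests).

Two packaged scenarios fix the study conditions:

* `bernalier_like_scenario()` — calibration-style monoculture: T1
  kinetics at the packaged reference estimates
  ($\eta = 0.0008$, $Y = 0.0014$, $k_d = 0.014$, $H_t = 86.2$),
  $H(0) = 400$ mM, $P(0) = 0$, $X(0) = 0.01$ g L$^{-1}$, 8 samples over
  0–80 h, cv 10%, triplicates.  Everything except the kinetic parameters
  is an invented default emulating the *layout* of such experiments; the
  scenario is not a reproduction of any measured dataset.
* `dsmz_like_scenario()` — validation-style culture on a yeast-extract
  rich medium: T2 or T3 base plus the hypothetical extension values, with
  $H(0) = 200$ mM chosen so the dissolved hydrogen supply equals the
  0.02 mol-in-0.1 L headspace inventory of the serum-bottle experiments
  (hence a 50 mM stoichiometric acetate ceiling), and a nominal
  $E(0) = 200$ mM.  10 samples over 0–100 h.

What passing recovery tests on these scenarios shows — and does not
show: they demonstrate that the estimation machinery is unbiased and
calibrated *when the model class is correct and noise is multiplicative
i.i.d.*  Real figure-digitised data add digitisation error, correlated
replicate structure, gas–liquid transfer effects and model misfit, none
of which the generator emulates; recovery results should be read as a
floor on method quality, not a guarantee about any published estimate.

## Closed-form analyses

* `t3_steady_state_ratio()`: the P/H ray where T3's net flux vanishes,
  $(\mu_{max,H} K_R)/(\mu_{max,R} K_H)$; at the packaged estimates
  $\approx 3.43$.  Because this point attracts trajectories, the T3
  structure predicts acetate *consumption* and hydrogen *accumulation* in
  high-acetate/low-hydrogen environments — a regime in which it should
  not be used for this organism (no supporting culture data; conflicts
  with direct threshold measurements; the model would also need a
  reverse-reaction yield).
* `ribes_default_tuning()`: $A = 100/H_t$, $T = 1.1 H_t$; at
  $H_t = 86.2$, $A \approx 1.16$ and $T = 94.82$.  Fitted T2 values for
  this organism differ strongly from these defaults (the fitted gate is
  far shallower), so the defaults effect an abrupt shutdown that fits
  poorly — the relationship between tuning and threshold is case
  dependent.  (The published prose compares the two parameterisations
  with percentages — "773% and 30%" — that do not follow from the printed
  numbers, $100/86.2 \div 0.015 \approx 7734\%$; we document the
  discrepancy rather than reproduce either figure.)
* `headspace_h2_moles()` / `max_acetate_mM()`: ideal-gas hydrogen
  inventory of a closed bottle and the resulting acetate ceiling;
  0.4 L at 200 kPa and 66% H$_2$ holds $\approx 0.02$ mol (at any
  temperature between 25 and 37 °C to the printed precision — the
  operation takes temperature explicitly, defaulting to the 310.15 K
  culture temperature), giving at most 50 mM acetate in 0.1 L of medium.
  `compare_media()` turns this into a flag for acetate of
  non-hydrogen origin.
* Unit conversions: `od_to_cdw()` ($0.37\,$g L$^{-1}$ per OD unit, an
  organism-specific factor), `gram_per_litre_to_mM()` (molar masses
  2.016 and 59.044 g mol$^{-1}$).  The literature threshold of
  $70 \pm 12.7$ mM (from a 1100 ppm gas-phase measurement) is stored as
  a constant with citation metadata only, since its phase-conversion
  basis is not published.

```{r}
t3_steady_state_ratio(reference_params("t3")$params)
ribes_default_tuning(86.2)
max_acetate_mM(headspace_h2_moles(headspace_spec()), 0.1)
```

## Numerical choices and problem sizes

Default tolerances (`rtol = 1e-8`, `atol = 1e-10`) keep the conservation
residual below $10^{-6}$ mM over 100 h horizons for all structures.
Ties and degenerate inputs: the T1 ramp uses `max(H - H_t, 0)` exactly
(continuous, kinked); sigmoid gates are evaluated through `plogis` and
saturate cleanly at $\pm\infty$ arguments; infinitesimally negative
states from solver overshoot are treated as zero inside every derivative;
an objective of exactly zero is floored at $10^{-12}$ before taking logs.

The packaged recovery studies use 20 replicates per structure at
$2\times 10^4$ MCMC iterations per fit (4 chains × 5000, half burn-in) —
enough for split-$\widehat R$ near 1 on all well-identified parameters —
and judge interval calibration per parameter: each parameter's 95%
interval should cover its generating value in at least 80% of
replicates.  A *joint* all-parameters-at-once reading of that criterion
is not statistically meaningful at these dimensions: six perfectly
calibrated independent 95% marginals have joint coverage
$0.95^6 \approx 0.74$, below the threshold by construction.  Full
calibration-grade runs would use the same machinery at $10^6$ iterations
(`fit_config()`'s default).

## Known limitations

* The sampler is a single-site random-walk family; heavily multimodal
  posteriors (not observed in this model family) would need tempering.
* Initial conditions are treated as known (from first observations);
  with noisy first observations this propagates a small bias into the
  kinetic parameters rather than widening the intervals.
* The yeast-extract pool is a single lumped substrate in nominal mM; its
  parameters are demonstration values and `E` is not identified without
  time-course measurements of the extract itself.
* No gas–liquid transfer: growth rates may be underestimated relative to
  a transfer-limited reality, and threshold estimates apply to dissolved
  concentrations only insofar as equilibrium held in the source
  experiments.
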