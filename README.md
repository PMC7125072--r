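# acetokin

Batch-culture kinetic models for reductive acetogens — bacteria such as
*Blautia hydrogenotrophica* that grow by converting hydrogen and CO₂ to
acetate along the Wood–Ljungdahl pathway
(4 H₂ + 2 CO₂ → CH₃COO⁻ + H⁺ + 2 H₂O).  The package is aimed at
microbiologists and bioprocess modellers who need to fit, simulate and
stress-test growth models for hydrogenotrophic organisms, in particular
models that capture the **hydrogen uptake threshold**: the empirical
observation that net hydrogen consumption stops below roughly 70–90 mM,
which plain Monod kinetics cannot reproduce.

## Models

All structures track hydrogen H (mM), acetate P (mM) and cell dry weight
X (g L⁻¹), sharing the stoichiometric coupling dP/dt = −¼ dH/dt and the
biomass balance dX/dt = −Y dH/dt − k_d X.  They differ in the hydrogen
uptake law:

* **`monod`** — dH/dt = −(μ_max X / Y) · H/(K_H + H)
* **`first_order`** — dH/dt = −η X H / Y, the small-H linearisation
  (η ≃ μ_max/K_H); preferred because a single batch curve identifies only
  the ratio μ_max/K_H
* **`t1`** — first-order in H* = max(H − H_t, 0): hard threshold at H_t
* **`t2`** — first-order gated by the sigmoid F(H) = 1/(1 + e^{A(T−H)})
  (after Ribes et al.)
* **`t3`** — reversible Michaelis–Menten:
  dH/dt = −(X/Y) (μ_max,H H/K_H − μ_max,R P/K_R)/(1 + H/K_H + P/K_R);
  the threshold emerges where forward and reverse fluxes balance
* a **yeast-extract extension** (for `t2`/`t3`) adding a second substrate
  E with dE/dt = −η_E X E / Y_E, extra acetate b_EP per mole of E, and
  extra biomass yield Y_E

On top of the model family the package provides stiff ODE simulation
(compiled derivatives via `deSolve`), calibration by adaptive-Metropolis
MCMC with credible intervals, split-R̂ diagnostics and parameter
correlations, a synthetic time-course generator for parameter-recovery
studies, and closed-form analyses (steady-state metabolite ratio,
headspace stoichiometry bounds, unit conversions).

## Worked example

Simulate the hard-threshold model at the packaged reference estimates
(η = 0.0008 h⁻¹ mM⁻¹, Y = 0.0014 g L⁻¹ mM⁻¹, k_d = 0.014 h⁻¹,
H_t = 86.2 mM) from 400 mM hydrogen:

```r
library(acetokin)
tr <- simulate_model(reference_params("t1"),
                     culture_state(H = 400, P = 0, X = 0.01),
                     times = seq(0, 80, by = 16))
as.data.frame(tr)
#>   time_h      H_mM     P_mM      X_gL
#> 1      0 400.00000  0.00000 0.0100000
#> 2     16 236.01345 40.99664 0.2214667
#> 3     32  93.99743 76.50064 0.3478770
#> 4     48  86.62374 78.34407 0.2868455
#> 5     64  86.24030 78.43992 0.2297399
#> 6     80  86.20614 78.44847 0.1836758
```

Hydrogen plateaus at the 86.2 mM threshold instead of falling to zero;
acetate rises by exactly a quarter of the hydrogen consumed; biomass
peaks and then decays at the death rate.  Generate a noisy triplicate
dataset from that scenario and refit it:

```r
scen <- bernalier_like_scenario(seed = 42)
gen <- generate_dataset(scen)
fit <- mcmc_fit(scen$spec, gen$dataset,
                fit_config(n_iterations = 5000, n_chains = 4,
                           burn_in_fraction = 0.5, seed = 42),
                normalisation = "value")
fit
#> <fit_result> t1 model, 4 free parameter(s), 24 observations
#>   objective at best fit: 0.128514   acceptance rate: 0.28
#>      best fit          95% interval  Rhat converged
#> eta 7.405e-04 (0.0006952-0.0007865) 1.004      TRUE
#> Y   1.376e-03   (0.001172-0.001541) 1.002      TRUE
#> k_d 1.448e-02     (0.01033-0.01798) 1.006      TRUE
#> H_t 8.624e+01         (79.86-92.21) 1.002      TRUE
#>   R^2: H = 0.998, P = 0.945, X = 0.977
```

Every 95% credible interval covers the generating value (e.g. H_t = 86.2
inside 79.9–92.2), R̂ ≈ 1 signals converged chains, and the per-variable
R² quantify goodness of fit.  The closed-form analyses:

```r
t3_steady_state_ratio(reference_params("t3")$params)  # 3.430527
ribes_default_tuning(86.2)                            # A = 1.16, T = 94.82
max_acetate_mM(headspace_h2_moles(headspace_spec()), 0.1)  # 51.2 mM
```

The first number is the acetate-to-hydrogen ratio (P ≈ 3.43 H) at which
the reversible model's net flux vanishes; the last is the stoichiometric
acetate ceiling implied by a 0.4 L serum-bottle headspace of 66% H₂ at
200 kPa over 0.1 L of medium (≈ 0.02 mol H₂ → ≈ 50 mM acetate) —
observed acetate beyond it must come from other carbon sources, such as
yeast extract in rich media.

Command-style runners (`run_simulate()`, `run_generate()`, `run_fit()`,
`run_analyze()`) bind these steps into reproducible runs with metadata
sidecars; `inst/cli/acetokin.R` is a thin Rscript wrapper over them.

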