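# atpasekin

Steady-state kinetic analysis of substrate-stimulated ABC-transporter
ATPase activity, built around the **nonessential activator model**. The
package targets assays like the colorimetric phosphate-release
measurements for the bacterial exporter NaAtm1, whose basal ATP
hydrolysis is stimulated several-fold by its transported substrate,
oxidized glutathione (GSSG).

## The model

GSSG (`S`) acts as a nonessential activator: the transporter turns over
on MgATP (`T`) alone with basal rate constant *k*, while bound activator
rescales the MgATP binding constant *K<sub>T</sub>* by the interaction
factor *α* and the hydrolysis rate constant by the acceleration factor
*β*:

$$v = E_T\,k\,\frac{T/K_T + \beta S T/(\alpha K_S K_T)}
{1 + T/K_T + S/K_S + S T/(\alpha K_S K_T)}$$

At fixed `S` this is a hyperbola in `T` with apparent constants

$$k_{\mathrm{obs}}(S) = k\,\frac{1+\beta S/(\alpha K_S)}{1+S/(\alpha K_S)},
\qquad
K_T^{\mathrm{app}}(S) = K_T\,\frac{1+S/K_S}{1+S/(\alpha K_S)} .$$

The package provides:

* closed-form evaluation of these rate laws and derived quantities
  (`activator_velocity()`, `kobs()`, `kt_app()`, `fold_stimulation()`);
* a seeded synthetic assay generator with the standard experimental
  design — 8 MgATP × 6 GSSG concentrations, timed phosphate readings,
  replicate structure per reconstitution condition
  (`paper_design()`, `simulate_dataset()`);
* rate extraction, per-GSSG Michaelis–Menten fits, and the global
  five-parameter fit with multi-start Levenberg–Marquardt in log-space,
  asymptotic and bootstrap uncertainties (`extract_rate()`,
  `fit_michaelis()`, `fit_activator_global()`,
  `bootstrap_uncertainty()`);
* parameter-recovery experiments scoring the whole simulate-and-fit
  pipeline (`recovery_experiment()`), and a reproducible file pipeline
  (`run_simulate()`, `run_fit()`, `run_recover()`).

The numbered scripts under `analysis/` walk through the full study:
simulate the three reconstitution conditions, fit per-GSSG hyperbolas,
fit the global activator model, and score parameter recovery. Outputs
land under `results/`.

## Worked example

```r
library(atpasekin)

# published NaAtm1 parameter sets for the three reconstitution conditions
p <- naatm1_params("detergent")
fold_stimulation(p, 20)
#> [1] 5.327182        # ~5-fold stimulation of kobs at 20 mM GSSG

# simulate a full assay (noise-free here) and refit it
ctx <- reconstitution_context("detergent")
obs <- simulate_dataset(p, ctx, paper_design("detergent"),
                        noise = noise_spec(0, 0), seed = 1)
fit <- fit_activator_global(obs)
round(fit$estimates, 2)
#>     k   K_T   K_S alpha  beta
#> 17.58  0.82 13.34  1.03  8.30
```

The five parameters come back exactly: *k* = 17.58 min⁻¹ is the basal
turnover per transporter homodimer, *K<sub>T</sub>* = 0.82 mM the MgATP
Michaelis constant, *K<sub>S</sub>* = 13.34 mM the GSSG binding
constant, *α* = 1.03 (essentially no MgATP–GSSG cooperativity in
detergent) and *β* = 8.30 (8-fold acceleration with GSSG bound). At the
realistic noise level (`noise_spec()` defaults: 5% per phosphate reading
plus a 0.5 µM floor) the same fit returns estimates within a few percent
for the well-identified parameters and wider scatter for *α* and *β*
when their saturation lies above the sampled GSSG range — see the
vignette and `analysis/04_recovery.R`.

Rounding the fold stimulation at 20 mM GSSG with the published parameter
sets reproduces the canonical factors for the three conditions:

```r
sapply(c("detergent", "nanodiscs", "proteoliposomes"),
       function(cond) round(fold_stimulation(naatm1_params(cond), 20)))
#>       detergent       nanodiscs proteoliposomes
#>               5              14              11
```

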