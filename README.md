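# drypom

Kinetic and quality analysis of convective drying for fruit pomace and
similar thin-bed agricultural by-products.

Drying a wet press residue into a fiber-rich powder ingredient forces a
temperature trade-off: hotter air shortens the run but degrades
anthocyanins and phenolics and compacts the fiber matrix. `drypom`
implements the full analysis chain a process study needs to choose a
temperature defensibly, with a seeded synthetic-data generator so every
stage is testable end to end without laboratory data.

## What it computes

**Drying kinetics.** Weighing series become moisture-ratio curves
MR(t) = (M_t − M_e)/(M_0 − M_e) and per-interval drying rates, with the
equilibrium endpoint detected by the operational stop rule (relative
change below 0.01 % over three consecutive measurements).

**Thin-layer model selection.** The five classical models —
Page exp(−k tⁿ), Modified Page [exp(−k t)]ⁿ, Henderson–Pabis a exp(−k t),
Logarithmic a exp(−k t) + c, Midilli a exp(−k tⁿ) + b t — are fitted by
bounded multi-start Levenberg–Marquardt least squares, scored with the
seven-statistic battery (R², χ², MSE, SSE, RMSE, AIC, AICc) and ranked by
AICc.

**Moisture transport.** Effective diffusivity by the Fick slab slope
method, D_cal = −slope·4L²/π² from the regression of ln MR on time, a
geometric correction D_eff = D_cal/R_g (R_g = 13.1 for the flat tray-bed
geometry), and activation energy from the Arrhenius regression of
ln D_eff on 1/(T + 273.15), E_a = −slope·R in kJ·mol⁻¹.

**Antioxidant potency.** Percent inhibition from control/sample
absorbances and IC50 by four-parameter logistic regression
inh(c) = lower + (upper − lower)/(1 + (IC50/c)^hill), asymptotes fixed at
0/100 by default.

**Treatment comparison.** One-way ANOVA with Tukey HSD compact letter
displays (highest mean lettered "a"), pooled-mean percent-change
contrasts, and advisory Shapiro–Wilk/Levene screens.

## Worked example

Simulate a five-temperature drying study, fit the model bank at 70 °C,
then run the diffusivity/Arrhenius chain and an IC50 fit:

```r
library(drypom)

dir <- tempfile()
paths <- run_simulate(dir, seed = 42)      # writes drying_50C.csv ... drying_90C.csv

res <- run_fit(paths["70"], seed = 42)
res$fits[["70"]][[1]]
#> Thin-layer fit: page (N = 18, K = 2, k in h^-n scale)
#>      k      n
#> 0.6803 1.0970
#> R2 = 0.9998  RMSE = 0.003735  AICc = -196.4442

dif <- run_diffusivity(paths)
dif$arrhenius
#> Arrhenius fit over 5 temperatures:
#>   E_a = 28.03 kJ/mol, D_0 = 3.059e-06 m^2/s, R^2 = 0.9169

dr <- simulate_dose_response(0.016, hill = 1, noise_sd_pct = 2, seed = 42)
fit_ic50(dr)
#> IC50 = 0.0153 mg/mL (hill = 1, R^2 = 0.9977)
```

The 70 °C run was generated from Page constants k = 0.6635 h⁻ⁿ,
n = 1.0826 with 0.005 moisture-ratio noise; the fit recovers them to a
few percent and ranks the stretched-exponential family first. The
Arrhenius fit summarizes how strongly temperature accelerates internal
moisture transport across the five simulated runs, and the IC50 lands
within 5 % of the generating 0.016 mg·mL⁻¹ midpoint under 2 % assay
noise.

A thin command-line wrapper over the same runners is installed at
`inst/cli/drypom.R` (`Rscript drypom.R <simulate|fit|diffusivity|ic50|compare> ...`).

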