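---
title: "Methods: drying kinetics, diffusivity, and quality comparison of fruit pomace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drying kinetics, diffusivity, and quality comparison of fruit pomace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drypom)
```

## The problem

Convective drying turns wet fruit pomace — the fiber-rich press residue of
juice extraction — into a shelf-stable powder ingredient. Choosing a
drying-air temperature is a trade-off: hotter air removes water faster but
degrades anthocyanins and phenolics and compacts the fiber matrix, changing
its techno-functional behavior (water/oil holding, swelling, solubility).
`drypom` implements the complete analysis chain used to make that choice
quantitatively: kinetic curve modeling, moisture-transport physics,
antioxidant dose-response potency, and treatment-comparison statistics, plus
a seeded generator that emulates the whole experimental protocol so every
stage can be validated by parameter recovery.

## Drying kinetics

A run is a weighing series at fixed air temperature: dry-basis moisture
$M_t$ (kg water per kg bone-dry solid) every 30 min. The run ends at
equilibrium, defined operationally as the first reading where the relative
change between consecutive readings has stayed below 0.01 % over three
consecutive measurements (two consecutive inter-reading changes). Because
the criterion is relative it is insensitive to whether raw mass or dry-basis
moisture is monitored — the two differ by the bone-dry offset and scale.
Boundary handling: a change *equal* to the threshold does not count as
"less than"; the comparison carries a tiny relative guard so floating-point
rounding cannot flip exact-boundary cases.

Curves are normalized to the moisture ratio

$$MR(t) = \frac{M_t - M_e}{M_0 - M_e},$$

which decays from 1 toward 0, and differentiated into the per-interval
drying rate $DR = (M_{t_1} - M_{t_2})/(t_2 - t_1)$. We report $DR$ as a
positive magnitude for a drying series (the sign convention that matches
reported tables); intervals where moisture rises are kept with their
negative sign and flagged as rewetting. The `mr_series` container requires
$MR(0) = 1$ and tolerates small negative excursions (to $-0.05$): balance
noise around the equilibrium plateau routinely pushes the renormalized
ratio slightly below zero and rejecting such series would make the
container unusable on real data.

## The thin-layer model bank and its time scale

Five semi-empirical models describe $MR(t)$: Page $e^{-kt^n}$, Modified
Page $[e^{-kt}]^n$, Henderson–Pabis $a\,e^{-kt}$, Logarithmic
$a\,e^{-kt}+c$, and Midilli $a\,e^{-kt^n}+bt$. Two structural facts matter
for interpretation:

* Modified Page as written collapses to $\exp(-nkt)$ — a pure exponential
  in which $k$ and $n$ enter only through their product and are not
  separately identifiable. Fits report *a* valid $(k, n)$ pair, not a
  unique one.
* Midilli nests Page ($a = 1$, $b = 0$), so on Page-generated data with
  small noise either may win an information-criterion comparison; the
  meaningful statement is that the stretched-exponential family wins.

Rate constants carry units of (time unit)$^{-n}$, so the time base is part
of the model definition. The package evaluates models on whatever grid it
is given, but the fitting pipeline converts the minute grid to **hours** by
default. This is the scale on which literature constants for berry-pomace
drying live (k of order 0.2–1 h$^{-n}$): a per-minute reading of such
constants would finish drying in about two minutes, contradicting the
multi-hour drying windows the same sources report, whereas on the hour
scale the implied equilibrium ratios ($e^{-0.93 \cdot 3.5^{1.19}} \approx
0.016$ after a 3.5-h run) match the observed plateau range. This choice is
also what makes noiseless parameter recovery well-posed: on a per-minute
reading the curve is 1 followed by values near $10^{-23}$ and the
least-squares surface is flat at double precision.

Parameter bounds — $k \in (10^{-6}, 50)$, $n \in (0.1, 5)$,
$a \in (0.5, 1.5)$, $b \in (-0.01, 0.01)$, $c \in (-0.5, 0.5)$ — enclose
all plausible constants with a wide margin; they exist to keep the
multi-start box sane, not to regularize.

## Fitting, the statistic battery, and ranking

`fit_drying_model()` minimizes $\sum_i (MR_{\mathrm{exp},i} -
MR_{\mathrm{pre},i})^2$ with bounded Levenberg–Marquardt least squares
(`minpack.lm`), launched from a seeded 5-point Latin-hypercube over the
bounds ($k$ sampled log-uniformly since its box spans seven decades) plus
one heuristic start taken from the early log-linear decay. The best start
wins; given the seed the whole procedure is deterministic, and refitting
from a returned optimum improves the SSE by less than $10^{-10}$
(idempotence, asserted in the tests).

The battery: $R^2$, $\chi^2 = \sum (MR_\mathrm{exp} -
MR_\mathrm{pre})^2 / MR_\mathrm{pre}$, MSE, SSE, RMSE, $AIC = N \ln(SSE/N)
+ 2K$, and $AIC_c = AIC + 2K(K+1)/(N-K-1)$. Numerical policy:

* $\chi^2$ divides by the predicted ratio as defined, which blows up as
  predictions approach zero at long times; points with $MR_\mathrm{pre}
  \le 10^{-6}$ are excluded from the sum and counted, with a warning.
* A perfect fit ($SSE = 0$, routine on noiseless synthetic data) reports
  $AIC$ and $AIC_c$ as $-\infty$ with a `perfect_fit` flag instead of
  erroring, so ranking still works (perfect fits sort first).
* With $N \le K + 1$ the small-sample correction is undefined; $AIC_c$ is
  `NaN` with a warning.
* A constant observed series has zero total sum of squares and no defined
  $R^2$; that is an error, not an `NA`.

`rank_models()` orders by $AIC_c$ — the small-sample criterion, the right
one at $N \approx 8$–28 points per run — with ties broken by RMSE and then
by fewer parameters. Comparing fits with different $N$ is refused.

## Diffusivity and activation energy

The one-term Fick slab solution $MR = \frac{8}{\pi^2} \exp\!\big(
-\frac{\pi^2 D_{cal}}{4L^2} t \big)$ is log-linear in $t$, so $D_{cal}$
comes from the OLS slope of $\ln MR$ on $t$ (seconds; the module converts
from the minute grid so diffusivities are m² s⁻¹). $L$ is the slab
*half*-thickness — 0.005 m for the standard 0.01-m tray bed — configurable
for single-face drying. Points with $MR \le 10^{-4}$ are excluded from the
regression (the equilibrium plateau is noise in log space); the $t = 0$
point is kept because it lies on the line under the slab solution. The
effective diffusivity applies a dimensionless geometric factor,
$D_{eff} = D_{cal} / R_g$ with $R_g = 13.1$ for this flat-bed geometry;
the factor is empirical and exposed as a plain argument.

Activation energy comes from the Arrhenius relation $D_{eff} = D_0
\exp\!\big(-\frac{E_a}{R(T + 273.15)}\big)$, fitted as OLS of
$\ln D_{eff}$ on $1/(T+273.15)$: $E_a = -\mathrm{slope} \cdot R$ reported
in kJ mol⁻¹ with $R = 8.314$ J mol⁻¹ K⁻¹ (the J-based constant is the one
consistent with activation energies of tens of kJ mol⁻¹). A
temperature-independent diffusivity set short-circuits to $E_a = 0$,
$D_0 = D_{eff}$.

## IC50 estimation

Percent inhibition defaults to the standard scavenging form
$100\,(A_c - A_s)/A_c$; the algebraic complement $100\,A_s/A_c$ is
available as `convention = "as_printed"` because some sources print the
complemented formula. The two conventions sum to 100; the standard form is
the one under which IC50 magnitudes of hundredths of mg mL⁻¹ make sense
for berry extracts.

`fit_ic50()` fits the four-parameter logistic
$\mathrm{inh}(c) = \mathrm{lower} + (\mathrm{upper} -
\mathrm{lower})/(1 + (IC_{50}/c)^{h})$ with asymptotes fixed at 0/100 by
default (free with `fix_asymptotes = FALSE`). The published analyses state
only "non-linear regression"; the 4PL is the field-standard choice for
serial-dilution inhibition data and is the one functional form we commit
to. $IC_{50}$ and the Hill slope are optimized on the log scale — serial
dilutions are geometric, so this is the natural, well-conditioned axis —
and reported on the linear scale. A response that never crosses 50 % still
returns an estimate but is flagged as an extrapolation; a response that
*decreases* with dose beyond noise is a fit error.

## Treatment comparison

Replicated property tables (dietary-fiber fractions, techno-functional
attributes, bioactive contents; $n = 3$ in the emulated design) are
compared by classical one-way ANOVA followed by Tukey's HSD at
$\alpha = 0.05$, condensed into a compact letter display by
insert-and-absorb over the significant pairs. Letters are assigned in
descending-mean order so the highest mean is always "a" — the convention
used in published treatment tables. Two treatments share a letter exactly
when their difference is below the HSD critical range (asserted as a
property test, and the sharing structure is cross-checked against
`multcomp::cld`). Shapiro–Wilk and Levene screens are computed as advisory
flags only; they never gate or modify the analysis, matching how such
screens are reported in practice. Zero within-group variance everywhere is
a degenerate input and an error.

Pooled contrasts of the form "property averaged over the 50–80 °C
treatments vs the freeze-dried control" average the *treatment means*
(identical to pooling replicates under balanced replication) before the
signed percent change $100\,(x - x_{ref})/x_{ref}$, reported rounded to
two decimals.

## What the synthetic generator emulates — and what it does not

`simulate_drying_experiment()` reproduces the protocol's statistical
structure: a thin-layer (or Fick-slab) decay on a 30-min grid, an
equilibrium plateau, conversion to dry-basis moisture, and additive
Gaussian noise on the moisture ratio (default sd 0.005, roughly the
relative scatter a ±0.001-g balance induces at these sample masses), with
optional quantization at the balance resolution. Defaults encode the study
conditions: Page kinetics with per-temperature constants on the hour
scale; drying windows shrinking from 810 min at 50 °C to 210 min at 90 °C
(endpoints as reported; intermediate windows interpolated, as only the
extremes are published); an equilibrium-ratio floor interpolating from
3.5 × 10⁻³ at 50 °C to 1.54 × 10⁻² at 90 °C (the reported plateau range —
hotter air hardens the surface and traps moisture); initial moisture 4.0
kg kg⁻¹ db (a typical fresh-pomace value; the source protocol does not
print one) and equilibrium moisture 0.05 kg kg⁻¹ db.

The generator does **not** emulate heteroscedastic noise, shrinkage,
case-hardening dynamics, or any heat/mass-transfer physics beyond the
closed-form curves. Passing recovery tests therefore demonstrates that the
estimators are correct and well-conditioned under the stated noise model —
not that the thin-layer models are adequate for any particular real
material. Every generator attaches its ground truth as an attribute (and a
key-value sidecar on disk) so recovery tests never re-enter truth by hand,
and all randomness flows through an explicit seed with the caller's RNG
state restored.

Companion generators produce Arrhenius diffusivity sets (lognormal noise
on $\ln D_{eff}$), serial-dilution inhibition curves (Gaussian noise in
percent units, clipped to the measurable $[-5, 105]$ window, on an 8-point
two-fold dilution series from 0.13 mg mL⁻¹ — the top of the ascorbic-acid
standard window), and replicated property tables (normal, $n = 3$). The
property-table route regenerates pseudo-replicates from printed mean ± SD
values; this is an approximation used for validating the letter-display
machinery, not a reconstruction of the unpublished raw replicates.

## Problem sizes and determinism

The validation suite runs Monte-Carlo studies at 100–200 seeded replicates
(bias of the recovered rate constant, model-recovery win rates, IC50
median recovery, letter-display stability), with curve fits on 8–28-point
grids — the sizes at which these experiments are actually conducted. All
stochastic tests fix seeds, and the multi-start optimizer is deterministic
given its control seed, so reruns are byte-identical (asserted for the
pipeline reports).

## Known limitations

* Only the one-term Fick slab solution is implemented; no multi-term
  series, shrinkage correction, or temperature-dependent half-thickness.
* No weighted or Bayesian fitting and no parameter confidence intervals;
  the multi-start least-squares point estimate is the deliverable.
* The 4PL is the only dose-response form; data generated by a different
  mechanism will be summarized, not diagnosed.
* Tukey letters assume the comparison is run jointly across all treatments
  of a property; subset-wise lettering is not supported.
* The geometric factor $R_g$ is taken as a given constant of the drying
  geometry; the package does not derive it.
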