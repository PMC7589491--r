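# franzpampa

Permeability analysis for PAMPA (parallel artificial membrane permeability
assay) experiments run on Franz vertical diffusion cells. The package takes
receiver-compartment concentration–time data from a two-chamber diffusion
cell, estimates the apparent permeability coefficient *P*app two ways —
under the classical sink assumption and with a non-sink two-compartment
model — classifies drugs as high/low BCS permeability against a metoprolol
internal reference, and correlates permeability against the human fraction
absorbed (Fa%). A mass-conserving Franz-cell simulator with known
ground-truth permeability makes every stage testable without laboratory
data. It is written for formulation and ADME scientists who run
Franz-cell PAMPA assays and for method developers validating
permeability-based BCS classification.

## The model

A Franz cell has a donor chamber (volume *V*d, initial concentration
*C*0) and a stirred receiver chamber (*V*r) separated by a
lipid-impregnated membrane of area *S*. At steady state, flux follows
Fick's first law,

    J = dQ/dt / S            (µg cm⁻² s⁻¹)

where *Q*(t) is the cumulative mass transported. Because each sampling
event withdraws a volume *V*s of receiver medium (replaced with fresh
buffer), *Q* is reconstructed with the replacement correction
*Q*(t_k) = *C*_k·*V*r + Σ_{i<k} *C*_i·*V*s. The slope d*Q*/dt is read from
the best-fitting linear window of the cumulative curve (highest OLS R²
among all contiguous windows of ≥ 4 points), and the sink-condition
apparent permeability is

    Papp = J / C0            (cm/s)

When the receiver concentration approaches the donor's — high-permeability
drugs, long runs — the sink assumption fails and Papp underestimates the
true coefficient. The non-sink model propagates the receiver concentration
interval by interval:

    C_r,t = Qtot/(Vr+Vd) + (C_r,t−1·f − Qtot/(Vr+Vd)) · exp(−Peff·S·(1/Vr+1/Vd)·Δt)

with dilution factor f = (Vr − Vs)/Vr, and *P*eff is fitted by minimising
the sum of squared residuals against the observed series (deterministic
log-grid search plus Brent refinement — no random starts). A drug is
classified highly permeable when its Papp exceeds 0.8 × the metoprolol
value measured by the same method.

## Worked example

Simulate a triplicate 12-hour run at true *P*eff = 1 × 10⁻⁵ cm/s with 5%
analytic noise, then estimate permeability both ways:

```r
library(franzpampa)
exp <- simulate_permeation(simulation_config(true_peff = 1e-5, seed = 42))
res <- estimate_papp(exp, papp_reference = 15.8e-6)
print(res)
#> Papp estimate: sink = 9.396e-06 cm/s, non-sink = 9.975e-06 cm/s (SSR 625.1, mass_conserving)
#>   classification: low
print(res$flux)
#> Flux: J = 0.09396 ug/cm2/s (CV 5.9%), window [1, 4], R2 = 0.9999
```

The non-sink fit recovers the simulated 1 × 10⁻⁵ cm/s within 0.3%, while
the sink estimate sits ~6% low — donor depletion over 12 h flattens the
cumulative curve, biasing the slope-based estimate. The linear window
[1, 4] shows the flux was read from the early, still-linear portion; the
CV is the across-replicate spread of the flux.

Correlating the packaged drug reference table (20 BCS model drugs) against
human fraction absorbed:

```r
fit_fa_correlation(drug_reference_table(), "papp_corti", "linear")
#> Fa% ~ papp_corti [linear], n = 14
#>   Fa% = 19.537 +1.742 * x,  r = 0.9510,  R2 = 0.9043
```

`ivivc_report()` runs the full correlation battery (Fa% vs each membrane
system, cross-membrane comparisons on both log10 and raw scales) and
states, per row, the statistic, the scale, and the exact drug subset used
alongside the published reference value.

A thin command-line front end over the same functions lives at
`inst/cli/franz_pampa.R` (subcommands `simulate`, `fit`, `classify`,
`correlate`, `report`; flags override the YAML config in
`inst/extdata/demo_config.yaml`).

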