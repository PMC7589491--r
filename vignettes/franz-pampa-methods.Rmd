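---
title: "Estimating apparent permeability from Franz-cell PAMPA data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating apparent permeability from Franz-cell PAMPA data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(franzpampa)
```

## The measurement and its two models

A Franz vertical diffusion cell holds a donor chamber (volume $V_d$,
loaded at concentration $C_0$) above a stirred receiver chamber ($V_r$),
separated by a membrane of diffusion area $S$. An autosampler withdraws a
volume $V_s$ from the receiver at each scheduled time and replaces it with
fresh buffer. The quantity of interest is the permeability coefficient of
the membrane for the drug, in cm/s.

**Sink-condition estimate.** While the receiver concentration is
negligible against the donor's and donor depletion is small, transport is
zero-order and Fick's first law applies at steady state:
$J = (dQ/dt)/S$, with $Q(t)$ the cumulative transported mass. Each
sampling event removes drug, so $Q$ is reconstructed with the replacement
correction

$$Q(t_k) = C_k V_r + \sum_{i<k} C_i V_s,$$

where $C_i$ are the measured (pre-replacement) receiver concentrations.
The apparent permeability is $P_\mathrm{app} = J / C_0$. The slope is
taken from the *best-fitting linear window* of the cumulative curve:
among all contiguous windows of at least `min_window` points, the one with
the highest ordinary-least-squares $R^2$ wins. `find_linear_portion()`
breaks ties (within $10^{-9}$) toward the longer window, then the later
start, on the reasoning that a longer fit is statistically stronger and a
later window is closer to steady state.

**Non-sink estimate.** When permeability is high, the receiver
concentration becomes comparable to the donor's within the run, the
driving gradient decays, and the slope-based estimate is biased low. The
two-compartment model drops both sink assumptions. Within one sampling
interval the pair of chambers is a closed linear system whose receiver
concentration relaxes exponentially toward the well-mixed equilibrium
$Q_\mathrm{tot}/(V_r + V_d)$:

$$C_{r,t} = \frac{Q_\mathrm{tot}}{V_r+V_d} +
  \left(C_{r,t-1} f - \frac{Q_\mathrm{tot}}{V_r+V_d}\right)
  e^{-P_\mathrm{eff}\, S\, (1/V_r + 1/V_d)\, \Delta t},$$

with dilution factor $f = (V_r - V_s)/V_r$ applied to the previous
recorded concentration at the start of each interval. This is the exact
closed-form solution of the interval ODE, so no step-size error enters;
the test suite checks it against adaptive numerical integration (deSolve)
to $10^{-6}$ relative over $P_\mathrm{eff} \in [10^{-7}, 10^{-4}]$ cm/s
and $\Delta t \in [900, 14400]$ s. `fit_peff()` minimises the sum of
squared residuals between this prediction and the replicate-mean observed
series.

## Parameters that matter

| Parameter | Unit | Default | Rationale |
|---|---|---|---|
| `area` | cm² | 1.77 | diffusion area of the standard cell radius |
| `donor_volume` | mL | 1 | donor chamber of the reference setup |
| `receiver_volume` | mL | 7 | receiver chamber of the reference setup |
| `sample_volume` | mL | none — required | an autosampler setting, not a cell constant; the demo config uses 1.0 mL and documents it as an assumption |
| schedule | h | 0.25–12 h, 10 points | the 12-hour autosampler program of the reference assay |
| `donor_concentration_0` | µg/mL | 10000 | 10 mg/mL donor load |
| `min_window` | points | 4 | on a 10-point schedule, keeps ≥ 2 residual degrees of freedom in the straight-line fit |
| `noise_cv` | fraction | 0.05 | typical HPLC assay imprecision |
| Peff search range | cm/s | $[10^{-9}, 10^{-2}]$ | brackets every pharmaceutically relevant permeability by ≥ 2 decades |

Time is carried in hours at all interfaces (matching assay practice) and
converted to seconds only inside the flux and permeability arithmetic, so
$P_\mathrm{app}$ comes out in cm/s. All mass bookkeeping is in µg; since
$P_\mathrm{app} = J/C_0$ divides two quantities in the same mass unit, no
molar conversion is needed.

## The simulator and what passing tests mean

`simulate_permeation()` emulates passive two-compartment diffusion with
donor depletion, discrete sampling with buffer replacement, and
multiplicative Gaussian measurement noise (mean 1, sd `noise_cv`,
truncated at zero) applied to recorded values only — analytic error does
not feed back into the physics. Bookkeeping is always mass-conserving:
donor + receiver + withdrawn mass equals the loaded dose to $10^{-9}$
relative at every step. Recorded concentrations are the pre-replacement
values, the usual autosampler convention.

The simulator deliberately omits: an unstirred water layer (the stirred
receiver minimises it, but it is not zero in reality), pH- and
ionisation-dependent permeability, membrane retention and lag time, and
solid excess in the donor (the "infinite dose" regime is modelled as a
fully dissolved, well-mixed donor). Parameter-recovery results therefore
show that the estimators are correct *for the stated transport model*;
they do not certify accuracy against real membranes, where those omitted
effects bias low-permeability measurements in particular.

## Numerical choices

- **Optimisation.** The non-sink objective has one parameter, so a
  deterministic coarse log-grid (60 points over $[10^{-9}, 10^{-2}]$ cm/s)
  followed by Brent refinement on the $\log_{10}$ scale replaces generic
  nonlinear least squares: identical inputs give identical fits, and the
  grid stage is immune to local minima. On noise-free data the result
  matches a $10^4$-point brute-force grid argmin within one grid step.
- **Total-mass convention.** The recursion above leaves open whether
  $Q_\mathrm{tot}$ is decremented by withdrawn mass. The default
  (`qtotal_mode = "mass_conserving"`) decrements it, matching physical
  reality and the simulator; `"constant"` keeps $Q_\mathrm{tot} = V_d C_0$
  throughout, for reproducing analyses that treat the load as fixed. The
  first interval has no preceding withdrawal, so $f = 1$ there.
- **Degenerate inputs.** An all-zero observed series is reported as
  $P_\mathrm{eff} = 0$ with a degenerate-fit flag rather than an error;
  an all-flat cumulative curve yields zero flux with $R^2$ reported as
  missing.
- **Fitting target.** The non-sink fit uses the replicate-mean series;
  the sink route fits each replicate separately and averages the fluxes,
  so the across-replicate CV of the flux is well defined.

## Classification and correlation

`classify_permeability()` implements the metoprolol internal-reference
rule: *high* iff $P_\mathrm{app} > 0.8 \times P_\mathrm{app}$(metoprolol),
strictly — a drug at exactly the threshold is *low*. The published
analyses never exercise the exact tie, so the strictness is a documented
package choice. `dose_number()` uses the standard BCS definition
$D_0 = (\mathrm{dose}/250\,\mathrm{mL})/\mathrm{solubility}$; the 250 mL
reference gastric volume is likewise a convention the source data do not
spell out.

"Log-linear" IVIVC is ordinary least squares of Fa% on
$\log_{10} P_\mathrm{app}$ — the conventional choice when permeabilities
span three orders of magnitude; a sigmoidal alternative is out of scope.
Cross-membrane comparisons default to the $\log_{10}$ scale for the same
reason, but `ivivc_report()` emits both scales because the published
reference statistics do not state which was used.

## Known limitations

The packaged reference table aggregates one permeability value per drug
per membrane system. The reference correlation statistics distributed
with it for the Fa% vs Franz-PAMPA comparisons (and Fa% vs Caco-2) cannot
be reproduced from the aggregated table under any defensible drug subset
or axis scale — the per-experiment concentration series behind them were
never published, and the drug subsets entering each regression are not
enumerated. `ivivc_report()` therefore prints, for every row, the
statistic, scale, size and exact drug set used next to the reference
value, making the discrepancy visible rather than silent. The Fa% vs
Corti comparisons *do* reproduce (recomputed 0.9043 and 0.8934 vs
reference 0.904 and 0.890), as does the direction of every qualitative
claim: removing the actively transported trio (ranitidine, trimethoprim,
verapamil) improves the Fa% correlation, and sink estimates sit below
non-sink estimates for high-permeability drugs.

Problem sizes used by the tests and the acceptance script: the 10-point,
12-hour schedule with the 1.77 cm²/1 mL/7 mL geometry throughout;
noise-free recovery on a four-decade permeability grid; noisy recovery as
the median over 100 seeded triplicate simulations at 5% noise — enough
replication for a stable median while keeping the whole battery in the
seconds range.
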