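---
title: "Multiresponse kinetic modelling of the Maillard reaction in UHT-heated milk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiresponse kinetic modelling of the Maillard reaction in UHT-heated milk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maillardkin)
```

## The model

When milk is heated at ultra-high temperature (110–140 °C), lactose
condenses with the ε-amino group of (free and protein-bound) lysine and the
resulting Amadori compound, lactulosyllysine (LacLys), degrades into the
α-dicarbonyls 3-deoxyglucosone (3-DG), 1-deoxyglucosone (1-DG), glucosone
(G), diacetyl (DA), methylglyoxal (MGO) and glyoxal (GO), and ultimately
into the advanced glycation end-products
N<sup>ε</sup>-carboxymethyllysine (CML) and
N<sup>ε</sup>-carboxyethyllysine (CEL). `maillardkin` implements this
chemistry as a mass-action reaction network of 24 elementary steps over 22
species, 11 of which are measurable; the lactose-isomerization
intermediate (Int) and the product sinks P1–P10 are simulated but never
compared with data.

Every step is first order in each of its reactants and all stoichiometric
coefficients are one, so the ODE system is

$$\dot y = S\,v(k, y), \qquad
  v_i = k_i \prod_{r \in \mathrm{reactants}(i)} y_r ,$$

with $S$ the signed stoichiometry matrix. Three steps are bimolecular
(Lac + Lys → LacLys, GO + Lys → CML, MGO + Lys → CEL; units
kg µmol⁻¹ min⁻¹); the rest are unimolecular (min⁻¹). Concentrations are
µmol per kg of dry matter throughout. `mr_network()` builds the network;
`variant = "comprehensive"` adds the candidate routes that model
discrimination examined and rejected (lactulose enolization, the
lactosone/1-deoxylactosone route, a free-glucose intermediate, an explicit
Heyns intermediate, diacetyl degradation), each toggleable one at a time
through `include =`.

Temperature dependence uses the reparametrized Arrhenius form

$$k(T) = k_\mathrm{ref}\,
  \exp\!\left[\frac{E_a}{R}\left(\frac{1}{T_\mathrm{ref}} -
  \frac{1}{T}\right)\right],$$

with the reference temperature fixed at 393.15 K (120 °C), the midpoint of
the studied range. Estimating $k_\mathrm{ref}$ instead of a pre-exponential
factor decorrelates the two parameters over a narrow temperature window.
$E_a$ (kJ/mol) is not sign-constrained: weakly identified steps can and do
take negative fitted values.

```{r network}
net <- mr_network()
net
```

## Design, initial state and the synthetic-data generator

The generator reproduces the statistical structure of the laboratory
experiment so that every downstream stage is testable without laboratory
data. The default `mr_design()` heats at 110 and 120 °C for 1–5 min, at
130 °C for 1–3 min in half-minute steps and at 140 °C for 0.5–2.5 min, in
triplicate. The default initial state is the measured composition of
pasteurized milk: Lac 939 150, total Lys 194 670, 3-DG 17.19, 1-DG 2.43,
CML 0.14, CEL 0.24 µmol/kg dm. Species whose pasteurized-milk level is not
known on this basis start at zero: LacLys is detectable in pasteurized milk
(as furosine after hydrolysis), but converting it to a dry-matter molar
concentration needs a protein fraction that is not available, so its
default is zero with an override hook (`mr_initial_state(LacLys = ...)`);
zero initial MGO/GO/G/DA is likewise a stated model assumption, not a
measurement.

Replicate noise is proportional Gaussian with an absolute floor:
$\sigma = \max(\mathrm{cv}\cdot\mu, \sigma_0)$ with cv = 0.07 and
$\sigma_0$ = 0.05 µmol/kg by default, resampled to non-negativity. A
proportional model is the natural choice when the responses span seven
orders of magnitude and triplicate scatter grows with the signal; the
floor keeps trace-level species from becoming noise-free. What the
generator does **not** emulate: analytical recovery biases, LOD/LOQ
censoring, species-specific error structure, pH drift, or non-isothermal
heating profiles. Passing recovery tests therefore demonstrate that the
estimator inverts the model under the study design — not that the model is
correct for real milk.

```{r generate}
ds <- mr_generate_dataset(params = mr_reference_arrhenius_params(), seed = 1)
dplyr::glimpse(ds)
```

## The determinant criterion

With 11 responses of wildly different magnitude, per-response weighting
would be arbitrary. The Box–Draper determinant criterion avoids it: with
$Z$ the matrix of residuals (one row per temperature–time–replicate
observation vector, one column per measured species), the estimator
minimizes $\lvert Z^\top Z\rvert$, which is invariant to rescaling any
response. For a single response it reduces to least squares. 95% highest
posterior density (HPD) halfwidths come from a Laplace approximation of
the Box–Draper posterior $p(\theta \mid Y) \propto \lvert Z^\top Z
\rvert^{-n/2}$: the covariance is $\tfrac{2}{n-p} H^{-1}$ with $H$ the
Gauss–Newton Hessian of $\log\lvert Z^\top Z\rvert$
($H_{ij} = 2\,\mathrm{tr}\,[(Z^\top Z)^{-1} J_i^\top J_j]$, $J_i$ the
residual-matrix sensitivity to parameter $i$), which reduces to the
classical $t$-based interval in the single-response linear case. The
normalized parameter covariance (correlation) matrix and the report of
strongly correlated pairs ($\lvert r\rvert \ge 0.95$) come from the same
covariance.

A parameter is reported

* **boundary** when the optimizer pins it at zero and a profile
  comparison at exactly $k = 0$ does not degrade the objective
  (reported as 0 ± 0);
* **indeterminate** when the relative-scaled information matrix has
  condition number above 10⁸ and the parameter loads on a near-null
  eigendirection, or when its halfwidth exceeds ten times its magnitude —
  mirroring the "ind" mechanism of the reference estimates;
* **determinate** otherwise.

## Numerical choices

* **Stiffness.** Rate constants span 10⁻⁹ to 10² min⁻¹, so the system is
  integrated with `lsoda` through a compiled mass-action right-hand side.
  Simulation defaults are rtol 10⁻⁸ and atol 10⁻⁶ µmol/kg; fitting uses
  rtol 10⁻¹⁰ / atol 10⁻⁸ because the criterion differentiates the solution
  and the forward model must be resolved below the residual scale.
  Integration-noise negatives smaller than the absolute tolerance are
  clamped to zero; anything larger is a hard error.
* **Regularized log-determinant.** Noise-free triplicates produce fewer
  distinct residual rows than responses, making $\lvert Z^\top Z\rvert$
  identically zero. Internally the fit therefore minimizes
  $\sum_j \log(\lambda_j + \varepsilon)$ over the eigenvalues of the
  column-rescaled $Z^\top Z$ with $\varepsilon = n \cdot 10^{-8}$: equal to
  the log-determinant (plus a constant) for well-conditioned residual
  matrices, and a smooth pseudo-determinant on the degenerate corner. The
  exported `mr_determinant_objective()` is the raw determinant.
* **Isothermal assumption.** Heating lag is ignored; time zero is the
  instant the sample reaches the set temperature. Temperatures are kelvin
  internally, degrees Celsius at every interface.

## Why the optimizer is staged

This network is a *sloppy* model: combinations such as the production and
consumption rates of a fast or unmeasured intermediate (1-DG → MGO versus
MGO → P6, or Lac ⇌ Int) move trajectories by fractions of a percent along
long curved valleys, and plain local optimization (quasi-Newton or a
single Levenberg–Marquardt run) reliably stalls in them. `mr_fit_rates()`
and `mr_fit_arrhenius()` therefore run a staged engine:

1. **Quasi-linearization warm start.** Mass-action dynamics are linear in
   $k$ given the trajectories:
   $y_s(t) - y_s(0) = \sum_i k_i S_{si} \int_0^{t}\!\prod_r y_r\,d\tau$.
   The fit simulates at the current parameters, corrects each measured
   species' trajectory multiplicatively toward the observed replicate
   means, and solves the resulting non-negative linear system, iterating
   to a fixed point. This crosses the curved valleys that defeat local
   steps, at negligible cost. The global fit warm-starts per temperature
   and then line-fits $\log k(T)$ against $1/T_\mathrm{ref} - 1/T$ per
   step to seed $(k_\mathrm{ref}, E_a)$.
2. **Multistart Levenberg–Marquardt**, first on log-concentration
   residuals, then on linearly rescaled residuals; the first start is the
   warm start itself, the rest are seeded log-normal perturbations around
   it.
3. **Sloppy-valley continuation:** random long-range probes in the
   subspace of the smallest singular vectors of the residual Jacobian,
   each polished by LM and accepted when the deviance improves.
4. **Determinant polish:** a short quasi-Newton run on the regularized
   log-determinant itself, so the reported optimum is a stationary point
   of the multiresponse criterion proper (this is where the estimator
   departs from least squares on noisy data).

All randomness is seeded; `starts`, the continuation budget and the polish
length are exposed through `control =`.

## Moiety accounting

`mr_moiety_totals()` tracks two conserved pools: everything downstream of
lactose carries the *sugar* tag, everything downstream of lysine the
*lysine* tag, propagated as a closure (a product inherits the union of its
reactants' moieties; a co-product that already carries a moiety — the
regenerated lysine in the regenerating variant — absorbs it instead). The
sugar total is an exact stoichiometric invariant of the proposed network:
it spans the one-dimensional left null space of $S$. The lysine total is
exact for every unimolecular step and for the condensation
Lac + Lys → LacLys, but the two AGE condensations (GO + Lys → CML,
MGO + Lys → CEL) consume *two* lysine-tagged reactants into one
lysine-tagged product, so the lysine total drifts downward by exactly the
integrated AGE-condensation flux — about 10⁻⁵ relative under the study
conditions. No static tagging can avoid this: the network's stoichiometric
left null space is one-dimensional, so no second exact linear invariant
exists. With `regenerate_lysine = TRUE` (Amadori breakdown to a dicarbonyl
releases the amino acid, as the degradation chemistry suggests) both
totals become exact invariants; the default remains non-regenerating,
consistent with the observed net lysine loss.

## Model discrimination

`mr_compare_models()` fits every candidate network with identical seeds
and starts and ranks them: lower determinant objective wins; objectives
within 5% of each other count as a tie resolved by parsimony (fewer free
parameters, then fewer indeterminate intervals). The 5% tie factor is this
package's operationalization of judging "goodness of fit together with the
interval quality" — no quantitative rule is standard — and is
configurable. Candidates that fail to fit are reported with a failure
status and excluded from the ranking; residual exact ties are reported as
ties rather than silently broken.

## What the recovery experiments show

The test suite and the acceptance script use the published per-temperature
rate constants and activation energies as generating truth, simulate the
study design with the package's own generator, and require the estimator
to return the generating values:

* noise-free per-temperature recovery at 110, 130 and 140 °C from
  3×-perturbed starts reproduces every constant whose reference interval
  is determinate to well within 10% (in practice < 1%); the constants that
  are *not* recovered are precisely those flagged indeterminate in the
  reference table;
* the global Arrhenius fit on the noise-free four-temperature design
  recovers the activation energies of the well-determined steps to within
  a few percent;
* under 7% proportional noise (five seeds), the medians of the parameters
  that the fit itself flags determinate fall within twice the reference
  HPD halfwidths. The steps coupled by fast-intermediate quasi-steady
  states (LacLys → 1-DG, LacLys → G, 1-DG → MGO) are flagged
  indeterminate at noisy optima: at this noise level the determinant
  criterion's own optimum wanders their sloppy valley (the fitted
  objective is strictly better than at the generating values), so their
  reference halfwidths are narrower than the information actually present
  under this noise model — an honest limit of the study design, not an
  optimizer artifact.

Problem sizes were chosen to keep the default test run comfortably
interactive: recovery fits use two multistart launches around the
perturbed truth, the noisy-recovery experiment uses five seeds at one
temperature (140 °C), and the discrimination and oracle tests run on
reduced subnetworks (single decays, the reversible isomerization pair)
where closed forms exist.

## Known limitations

* HPD intervals are a local Laplace approximation; for strongly sloppy
  directions they understate the true posterior width, which is why the
  condition-number flag exists.
* The generator's noise model is a deliberate simplification; real
  chromatographic errors are censored, heteroscedastic per species, and
  correlated within an analytical batch.
* Non-isothermal time–temperature profiles are out of scope; the heating
  lag of the laboratory protocol (< 5 s) is ignored.
* The unit of the LacLys → CML step is read as first order (min⁻¹),
  matching the reference table's unit column over a conflicting restated
  unit elsewhere; the step is unimolecular in this network either way.
* DA is modelled as terminal in the proposed network (its degradation step
  is available as the `da_degradation` toggle); lysine regeneration from
  Amadori breakdown is off by default.
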