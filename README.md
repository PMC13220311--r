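# maillardkin

Multiresponse kinetic modelling of the Maillard reaction in milk during
ultra-high-temperature (UHT) heating.

When milk is heated at 110–140 °C, lactose condenses with the ε-amino
group of lysine; the Amadori compound lactulosyllysine (LacLys) then
degrades into the α-dicarbonyls 3-DG, 1-DG, glucosone, diacetyl,
methylglyoxal and glyoxal, and finally into the advanced glycation
end-products CML and CEL. `maillardkin` is for food chemists and kinetic
modellers who want to simulate this reaction network, fit its rate
constants to multi-species concentration data, and judge which reaction
steps the data can actually support.

The package provides:

* a 24-step mass-action network over 22 species (11 measured), with the
  candidate routes examined during model discrimination (lactulose
  enolization, lactosone/1-deoxylactosone, free glucose, an explicit Heyns
  intermediate, diacetyl degradation) available as toggles
  (`mr_network()`);
* a stiff ODE simulator with a compiled right-hand side
  (`mr_simulate()`, `mr_simulate_design()`) and conserved-moiety
  accounting (`mr_moiety_totals()`);
* a replicate-level synthetic-data generator reproducing the study design
  — 110/120 °C × 1–5 min, 130 °C × 1–3 min, 140 °C × 0.5–2.5 min,
  triplicate — from the measured pasteurized-milk initial state
  (`mr_design()`, `mr_initial_state()`, `mr_generate_dataset()`);
* estimation by the Box–Draper determinant criterion: per-temperature rate
  constants (`mr_fit_rates()`) and global reparametrized-Arrhenius
  parameters `(k_ref, Ea)` with `T_ref` = 393.15 K
  (`mr_fit_arrhenius()`), with 95% HPD intervals, boundary/indeterminate
  identifiability flags and the normalized parameter covariance
  (correlation) matrix (`mr_hpd_intervals()`,
  `mr_parameter_correlation()`);
* model discrimination between candidate networks with a
  parsimony-resolved ranking (`mr_compare_models()`);
* the published per-temperature rate constants and activation energies as
  reference tables (`mr_reference_rates()`, `mr_reference_arrhenius()`),
  and an end-to-end recovery experiment (`mr_recover()`).

The estimator minimizes the multiresponse objective

```
|Z'Z|,   Z[i, j] = observed_ij − predicted_ij(k)
```

over non-negative rate constants, where the rows of `Z` are
(temperature, time, replicate) observation vectors and the columns the 11
measured species. The determinant criterion is invariant to per-response
rescaling, which is what makes a joint fit across species spanning seven
orders of magnitude possible without arbitrary weights. Uncertainty comes
from a Laplace approximation of the Box–Draper posterior
`p(θ|Y) ∝ |Z'Z|^(−n/2)`.

## Worked example

Simulate the proposed network at 140 °C from the pasteurized-milk state,
then recover the generating rate constants from synthetic triplicate data
starting at 3× perturbed values:

```r
library(maillardkin)

net <- mr_network()
sim <- mr_simulate(net, mr_rate_constants(140),
                   times = c(0, 0.5, 1, 1.5, 2, 2.5), temperature_C = 140)
tidyr::pivot_wider(sim, names_from = species, values_from = concentration)
#>   time_min     Lac     Lys LacLys `3DG`   MGO   CML   CEL
#> 1      0   939150  194670      0   17.2  0    0.14  0.24
#> 2      0.5 808607. 175163.  1664.  20.7  7.01 0.428 0.460
#> 3      1   799436. 157699.  2628.  29.1 11.4  1.05  0.880
#> 4      1.5 797701. 141982.  3180.  40.4 14.0  1.65  1.14
#> 5      2   796534. 127834.  3451.  53.3 15.2  2.11  1.28
#> 6      2.5 795508. 115096.  3532.  66.8 15.6  2.42  1.34
```

Lactose drops sharply in the first half minute (the reversible
isomerization equilibrating), lysine decays by ~40% over 2.5 min, and the
AGEs climb from their pasteurized-milk baselines.

```r
ds  <- mr_generate_dataset(mr_design(140),
                           list(`140` = mr_rate_constants(140)), seed = 1)
fit <- mr_fit_rates(ds, net, 140, init = mr_rate_constants(140) * 3,
                    starts = 2, seed = 1)
tidy(fit)
#>   step reaction                estimate       hpd flag
#> 1    1 Lac + Lys -> LacLys 0.0000000245   4.88e-8 determinate
#> 2    2 LacLys -> 3DG       0.00768        1.23e-2 determinate
#> 3    3 LacLys -> 1DG       0.135         NA       indeterminate
#> ...
glance(fit)
#>   objective log_objective n_obs n_responses n_parameters n_boundary ...
#> 1   1.77e24         -32.6    18          11           24          2

mr_parameter_correlation(fit)$pairs
#>   par1  par2       r
#> 1 k4    k19    1.000
#> 2 k7    k10   -1.000
#> 3 k9    k20    0.999
#> 4 k13   k14    0.991
#> ...
```

Under 7% replicate noise the fit recovers the well-determined constants
(here k1 within a few percent of the generating 2.5 × 10⁻⁸
kg µmol⁻¹ min⁻¹) and flags the rest: the strongly correlated pairs are
exactly the production/consumption rates of fast or unmeasured
intermediates (G with its sink k19, MGO with k20, the Lac ⇌ Int
isomerization pair) — the chemically expected couplings through shared
intermediates.

Plotting and reporting: `autoplot(sim)` and `autoplot(fit, data = ds)`
draw trajectory and fit panels per species, `plot_correlation(fit)` the
correlation heatmap; `mr_write_dataset()`, `mr_write_trajectories()`,
`mr_write_fit()` and `mr_write_network()` export CSV/JSON/YAML artifacts.

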