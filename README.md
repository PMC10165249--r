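# mabrtemp

Temperature dependence of nitrification in membrane-aerated biofilm
reactors (MABRs), as a tested R package.

In an MABR the nitrifying biofilm grows on gas-permeable hollow fibres:
oxygen enters at the biofilm base through the membrane while ammonium
diffuses in from the bulk through a liquid boundary layer — a
counter-diffusional geometry.  Because diffusivities vary with temperature
far more weakly (~2-3 %/degC) than nitrifier growth rates (~6-10 %/degC),
the apparent temperature sensitivity of the reactor tells you how much of
the rate is controlled by mass transfer.  This package provides the three
computational pieces needed to study that question:

* **A 1D two-guild biofilm model** (ammonia oxidisers, nitrite oxidisers,
  inerts; four solutes) with Monod kinetics, exact nitrogen-conserving
  stoichiometry, a membrane-side oxygen source, a stagnant-film boundary
  layer, growth-induced advection and a constant-thickness detachment
  closure.  Solved by finite volumes + damped Newton; planar or cylindrical.
* **Scenario experiments**: steady-state simulation matrices over
  temperature x film thickness x boundary-layer thickness, removal rates at
  non-limiting (35 mg N/L) and strongly limiting (0.1-1.0 mg N/L) ammonium,
  two-point %/degC temperature sensitivity, +/-25 % diffusivity sensitivity
  analysis, and bounded least-squares calibration against published rates.
* **Batch-test analysis + synthetic campaigns**: windowed linear drawdown
  rates with areal conversion, duplicate-run averaging, Arrhenius-type
  fitting `R(T) = R_T0 * theta^(T-T0)` (Levenberg-Marquardt), nitrite
  accumulation fractions, and a seeded generator of realistic batch
  campaigns for parameter-recovery studies.

## Worked example

Steady state of a calibrated scenario — 30 degC, 50 um film, 50 um boundary
layer, 35 mg N/L bulk ammonium:

```r
library(mabrtemp)

sc  <- scenario(temperature = 30, Lf = 50e-6, L_LBL = 50e-6, bulk_NH4 = 35)
res <- run_to_steady_state(sc, calibrated_params(), calibrated_rules())
res
#> Steady-state biofilm (cylindrical): T = 30 degC, Lf = 50 um, LBL = 50 um, bulk NH4 = 35 g/m3
#>   NH4 removal rate: 5.687 g N/m2(membrane)/d
#>   reached at t = 42 d; max solute imbalance 1.3e-13; N balance 8.9e-10
```

The printed rate is the ammonium flux into the biofilm referenced to the
membrane outer area — the number an MABR operator would quote.  The
imbalance diagnostics confirm the discrete mass balances close.  The same
scenario at 8 degC gives 1.77 g N m-2 d-1, i.e. a two-point sensitivity of
`temperature_sensitivity(5.69, 1.77, 30, 8)` ~ 10 %/degC for the thin film,
against ~4 %/degC for a 150 um film — thick films are more
transport-controlled, hence less temperature sensitive.

Batch-side, a synthetic campaign and its full analysis:

```r
spec <- campaign_spec(theta = 1.026, seed = 42)   # 5 temperatures x 2 runs
camp <- generate_campaign(spec)
ana  <- analyze_campaign(camp, c_lo = 10, c_hi = 20, T0 = 20)
ana$fit
#> Arrhenius-type fit R(T) = R_T0 * theta^(T - 20)
#>   R_T0 = 3.703 (+/- 0.017), theta = 1.0270 (+/- 0.0006)
```

The fitted `theta` recovers the generator's 1.026; over 200 replicate
campaigns the mean estimate lands within 0.002.

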