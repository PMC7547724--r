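# lovfret

Kinetic analysis of LOV2-based optogenetic actuators whose switching
state is read out in living cells by resonance energy transfer (RET)
with a fused fluorescent protein.

LOV2 actuators (caged nuclear export signals, caged kinase inhibitors)
cycle between a dark ground state (LOV-445) and a lit cysteine-adduct
state (LOV-390). A cyan donor fused to LOV2 is partially quenched by RET
to the flavin and *dequenches* as the domain switches; yellow/red
acceptors are sensitised and *quench*. `lovfret` turns those
fluorescence traces into the constants that characterise a construct,
and turns the constants into illumination protocols. It is written for
the experimenter running plate-reader or imaging photocycle assays and
for anyone designing minimal-light optogenetic stimulation.

## The model

A first-order reversible photocycle:

* forward (activation) rate `k_f = flux / sens`, with `sens` the
  **sensitivity** — the photon dose (µmol m⁻²) giving unit forward
  drive;
* reverse (thermal relaxation) rate `k_r = 1 / r`, with `r` the dark
  **relaxation time constant** (s);
* apparent rate during illumination `k_app = k_f + k_r`, equilibrium
  adduct fraction `k_f / (k_f + k_r)`;
* maximal fractional RET change, the **transfer limit** (quench or
  dequench limit);
* per-flash **ED50** `= sens / (flash_rate × r)`, the dose at which
  forward drive equals relaxation, so equilibrium switching is half the
  transfer limit.

The package provides: closed-form dequench/quench cycle-trace equations;
shared-parameter global nonlinear least squares with standard errors
(`fit_global_switch`, `fit_cycle_exponentials` + `fit_dark_relaxation`,
`fit_reversible_dose_series`, `fit_single_site`); model comparison
(`nested_f_test`, `holm_sidak`); an exact piecewise-exponential
adduct-state simulator with a closed-form periodic steady state and
minimal-light protocol design (`simulate_adduct`,
`periodic_steady_state`, `design_min_rate`); translocation and
kinase-reporter analyses (`export_rate`, `dose_response`,
`fit_reporter_phases`); photon-flux/irradiance conversions and Förster
sixth-power arithmetic; and seeded synthetic-data generators
(`gen_cycle_traces` and friends) that make the whole pipeline testable
without imaging data.

## Worked example

Simulate a cycling experiment (13 activation cycles of 20 flashes of
14 µmol m⁻² at 4 Hz, dark periods 1–180 s, 3 replicates, 0.5% noise,
ground truth: sensitivity 162 µmol m⁻², r = 6.8 s, dequench limit
18.9%), normalise to the matched LOV2-free control, and recover the
constants with the global fit:

```r
library(lovfret)

truth  <- photocycle_params(sensitivity = 162, relaxation_s = 6.8,
                            transfer_limit = 0.189, mode = "donor")
spec   <- generator_spec(truth, noise_sd = 0.005, seed = 42)
traces <- normalize_to_control(gen_cycle_traces(spec))
fit    <- fit_global_switch(traces, mode = "donor")
print(fit)
#> <fit_result> model=global_switch  ssr=0.00569217  dof=256  converged=TRUE
#>                  best_fit       se
#> offset           1.221715 0.004655
#> transfer_limit   0.189648 0.002672
#> sensitivity    170.046425 5.620497
#> r                6.784050 0.183406
#> derived:
#>   ed50_umol_m2_per_flash = 6.26641 (se 0.35)
#>   apparent_sensitivity_umol_m2 = 117.468
#>   max_dequench_pct = 13.917
```

The fit recovers the generating sensitivity within 5%, the relaxation
time within 0.3%, and the transfer limit within 0.4%; the derived ED50
(~6.3 µmol m⁻² per flash at 4 Hz) is the per-flash dose for
half-maximal equilibrium switching, and the apparent sensitivity
(~117 µmol m⁻²) is the smaller, relaxation-contaminated dose scale an
activation curve alone would suggest.

Protocol design: the steady-state adduct fraction of a caged JNK
inhibitor (sensitivity 206 µmol m⁻², r = 13.7 s) under 1 s flashes of
2.3 µmol m⁻² s⁻¹ (= 60 µW cm⁻² at 465 nm) every 7.5 s:

```r
ss <- periodic_steady_state(2.3, 1, 7.5, photocycle_params(206, 13.7, 0.17))
sprintf("peak %.3f%%  trough %.3f%%  mean %.3f%%",
        100 * ss$peak, 100 * ss$trough, 100 * ss$mean)
#> "peak 2.502%  trough 1.557%  mean 1.998%"
```

— under 3% of the actuator is in the adduct state at any time, yet this
is sufficient for pathway inhibition; `design_min_rate()` finds the
longest flash period that still sustains a target mean fraction. Unit
bookkeeping: `flux_to_irradiance(photon_flux(1, 438))` → `27.3`
µW cm⁻².

## Command line

An installed script (`system.file("cli", "lovfret", package =
"lovfret")`, or the exported `lovfret_cli()`) wraps the main workflows:

```sh
lovfret units convert --from uW_cm2 --to umol_m2_s --wavelength-nm 465 60
lovfret generate cycles --seed 7 --out traces.csv
lovfret fit-cycles --in traces.csv --mode donor --out fit.json
lovfret simulate --params params.json --train train.json --dt 0.05 --out trace.csv
lovfret compare --restricted a.json --full b.json
```

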