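---
title: "Quantifying LOV2 actuator switching from RET trace kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying LOV2 actuator switching from RET trace kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(lovfret)
```

## The model

LOV2-based optogenetic actuators switch between a dark ground state
(LOV-445) and a lit cysteine-adduct state (LOV-390). `lovfret` treats
this photocycle as a first-order reversible reaction:

* blue light drives the forward reaction at rate
  $k_f = \phi / \mathrm{sens}$, where $\phi$ is the photon flux
  (µmol m⁻² s⁻¹) and `sens` — the *sensitivity* — is the photon dose
  producing unit forward drive;
* thermal relaxation reverses it at $k_r = 1/r$, with $r$ the dark
  relaxation time constant in seconds.

Under constant flux the adduct fraction relaxes exponentially at the
apparent rate $k_\mathrm{app} = k_f + k_r$ toward the equilibrium
$k_f/(k_f + k_r)$. Everything else in the package — trace equations,
fitting, protocol design — is a consequence of this two-state picture.
The µs-scale photochemistry (triplet intermediate, Jα undocking) is
deliberately not modelled; those steps are far faster than any reading
interval used here. The photochemical back-reaction of the lit state
under blue light is likewise not modelled separately: it is absorbed
into the fitted lit-state constants, which is also why relaxation
estimated during illumination can be faster than in darkness.

The switching state is read out in situ by resonance energy transfer
(RET) between a fused fluorescent protein and the LOV2 flavin. A cyan
donor is *quenched* by dark-state LOV2 and dequenches on activation
(traces rise); yellow/red acceptors are *sensitised* by LOV2 and quench
on activation (traces fall). The maximal fractional change attributable
to RET is the *transfer limit* (`D_limit` for donors, `Q_limit` for
acceptors), stored as a fraction in [0, 1]; percentages appear only at
I/O. One published transcription of the donor trace equation is written
as a decaying exponential; taken literally it would make a donor trace
fall during illumination, contradicting dequenching, so the package
parameterises direction explicitly by `mode` and treats the rising form
as canonical (a unit test proves the printed alternative differs only
by a constant that re-absorbs into the offset).

## Trace equations and the two fitting routes

A cycling experiment delivers, per cycle, a burst of flashes (default
20 flashes of 14 µmol m⁻² at 4 Hz) preceded by a dark period between
1 and 180 s. For a cycle preceded by dark time $t$, reading $x$ of a
donor trace follows

$$Y = \mathrm{Offset}\,\bigl(1 - D_\mathrm{limit} + D_\mathrm{max}
  \,[1 - (1 - e^{-t/r})\,e^{-k_\mathrm{app} x / \mathrm{rate}}]\bigr),
  \qquad D_\mathrm{max} = \frac{D_\mathrm{limit}}{1 + k_r/k_f},$$

with the acceptor form its mirror image. The hard-coded flux constants
of the original plate protocols (56 and 560 µmol m⁻² s⁻¹) are
generalised to `flash_rate_hz * dose_per_flash`, with 4 Hz the default.
Flashes (10–300 ms) are treated as instantaneous doses at the reading
timestamp, since they are far shorter than any fitted $r$; the
simulator additionally supports finite-duration flashes.

Two routes recover the constants, and their agreement is itself a
tested invariant:

1. **Two-stage.** Each cycle is fitted to
   $F[x] = F_\mathrm{limit} - A[t]\,e^{-x/\tau}$ with one shared
   activation constant $\tau$ (in flashes) and per-cycle amplitudes
   (`fit_cycle_exponentials`); the amplitudes are then fitted against
   dark time as $A[t] = A_0(1 - e^{-t/r})$ (`fit_dark_relaxation`),
   yielding $r$ and the maximal dequench percentage
   $100\,A_0/(1+A_0)$.
2. **Global.** All readings of all cycles are fitted jointly to the
   closed-form trace equation (`fit_global_switch`), returning
   `offset`, `transfer_limit`, `sensitivity` and `r` directly, plus the
   derived per-flash $ED_{50} = \mathrm{sens}/(\mathrm{rate}\cdot r)$
   — the dose at which forward drive equals relaxation, so equilibrium
   switching is half the transfer limit — and the apparent
   (relaxation-contaminated) sensitivity $\phi/k_\mathrm{app}$.

A dose series across several per-flash doses is fitted jointly the same
way (`fit_reversible_dose_series`), and saturating responses (export
rates, photoswitching) use the single-site form $y = a/(1 + b/x)$
(`fit_single_site`, `dose_response`).

## Numerical choices

All fits minimise unweighted squared residuals with a compact
Levenberg–Marquardt (damped Gauss–Newton) driver: forward-difference
Jacobians, box constraints by projection with bound hits reported in
`flags` (never silently clipped), multi-start from a small grid of
heuristic initialisations (limit from the trace span, activation
constant from a log-linear regression of the largest cycle, relaxation
from a coarse grid), an iteration cap of 200, and convergence on
relative SSR change below 1e-14 or a vanishing gradient. Standard
errors are symmetric, from the inverse Gauss–Newton curvature at the
optimum scaled by `ssr/dof`; derived quantities (ED50, maximal
dequench) carry delta-method errors. Replicates of the same protocol
are averaged per reading before fitting by default, with joint fitting
available (`average = FALSE`) and an automatic, flagged fallback to the
replicate mean when a replicate-wise fit fails — the documented
low-signal behaviour. The first reading of a session can be discarded
with an explicit `drop_first` flag (a known systematic artefact of
imperfect control correction); nothing is ever removed automatically.

Degenerate inputs fail loudly: all-equal amplitudes return a
`non_identifiable` flag rather than an arbitrary $r$; a missing or zero
control, mismatched protocols, fewer than 3 dark times or doses, and
unlabelled reporter phases are errors.

## The adduct simulator and protocol design

`simulate_adduct` propagates the two-state ODE
$\mathrm{d}A/\mathrm{d}t = k_f(t)(1-A) - A/r$ piecewise-exponentially:
because illumination trains are piecewise-constant in flux, each
segment has an exact propagator, so the simulation is exact regardless
of the output step. A fixed-step RK4 integrator (`ode_oracle`) provides
the independent cross-check in tests (agreement ≤ 1e-6). For periodic
trains, `periodic_steady_state` gives the closed-form fixed point
(peak, trough, exact cycle mean), and `design_min_rate` inverts it by
bisection to find the longest flash period sustaining a target mean
adduct fraction — the minimal-light protocol for a construct. Slow
relaxation mutants admit proportionally longer periods, which is the
quantitative basis for tenfold light-dose reductions.

Unit conversions between photon flux and irradiance use the per-mole
photon energy $N_A h c/\lambda$ from CODATA constants (438 nm for
microscope excitation, 465 nm for LED-array illumination; at 438 nm,
1 µmol m⁻² s⁻¹ ≈ 27.3 µW cm⁻²). Doses are stored in µmol m⁻²
throughout; irradiance is presentation-layer only. The spacer
calculation uses the random-coil end-to-end estimate $b\sqrt{N}$ with
$b = 0.38$ nm (an extended-chain option $bN$ exists but is not the
default, since the random coil reproduces the reported 1.9 nm for 24
residues); RET-rate fold changes follow the sixth-power law
$(R_\mathrm{far}/R_\mathrm{near})^6$. For the "sevenfold" figure the
package computes whatever its inputs give: with the rounded 1.9 nm
added to a 5 nm separation, $(6.9/5)^6 \approx 6.9$; with the unrounded
1.86 nm, ≈ 6.7. Both orderings of rounding are documented; none is
silently preferred.

## Reporter kinetics

Reporter (kinase translocation) series under alternating lit/dark
phases are fitted as exponential approaches between a lower level $L$
and upper level $L + S$, with one time constant per phase class and the
span shared between reduction and recovery by default — the shared-span
construction that makes the equal-versus-distinct time-constant
comparison a clean extra-sum-of-squares F test. The slow relaxation of
the optogenetic inhibitor can be folded into the recovery phases by
replacing $k_f$ with $(1 - A\,e^{-t/\rho})k_f$, which has the closed
form exponent $-( (k_f+k_r)t - k_f A \rho (1 - e^{-t/\rho}) )$. Three
constants are fixed rather than fitted, to keep the unknown count down:
$\rho = 120$ s (the inhibitor relaxation time), $A = 0.5$ (half-maximal
inhibition — reporter responses to these inhibitors are clearly
partial, and complete shutdown would contradict the observed residual
activity) and a forward-rate share $k_f/(k_f+k_r) = 0.5$ (neutral in
the absence of information separating the two rates). With recovery
time constants in the 8–16 min range observed for these reporters, the
correction moves fitted time constants by under ~10%, which is why it
is not applied routinely.

## What the synthetic generators emulate — and what they do not

The generators produce every input the pipeline consumes, determined
entirely by their seed (they save and restore the session RNG state):

* `gen_cycle_traces`: closed-form cycle traces times a per-reading
  multiplicative bleach factor *shared* with a matched LOV2-free
  control trace, plus independent homoscedastic Gaussian noise on both
  (default sd 0.3% of the normalised signal, matching the visual
  scatter of the published traces; 0.5% in the recovery harnesses). An
  optional control-only fast-quench term exercises imperfect
  correction; it is off by default.
* `gen_dark_recovery_plate`: lysate recovery-from-dequench traces, 20
  reader cycles at 3 s.
* `gen_translocation_ratios`: nuclear:cytoplasmic ratios starting at
  the nuclear-biased baseline 2.37, falling linearly during flash
  trains at the saturating per-flash rate
  $\mathrm{Max}\cdot d/(ED_{50}+d)$, fully recovering between cycles.
* `gen_reporter_series`: piecewise reporter curves over labelled
  lit/dark phases, with the relaxing-inhibitor variant available.

The dark-time schedule is nowhere enumerated in the source protocols;
the default is the 600 s sentinel (first dark period of a session,
effectively infinite — all fitted time constants are far below it)
followed by 12 log-spaced values between 1 and 180 s. Noise is
Gaussian and homoscedastic on the normalised scale: there is no shot
noise, no cell-to-cell variability, no segmentation error, no
field-to-field structure. A green parameter-recovery test therefore
establishes that the estimators are consistent and correctly calibrated
*under the stated noise model at the stated protocol scale* — not that
the published table values would be reproduced from real imaging data,
which are fits to experimental traces this package does not ship.

## Known limitations

* Uncertainties are symmetric curvature-based standard errors; no
  profile likelihood or resampling.
* No heteroscedastic weighting; the unweighted default mirrors the
  original fitting workflow.
* The adduct fraction underestimates the pool of inhibitor still bound
  to targets after relaxation of the LOV2 domain; no target-occupancy
  model is provided.
* $R_0$ is always a user input; no spectral-overlap integral.
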