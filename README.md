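# kndysim

Arcuate kisspeptin (Kiss1/KNDy) neurons generate the pulsatile drive for
GnRH release, and estradiol switches their firing from NKB/TRPC5-driven
sustained synchronous activity to short burst firing that favors glutamate
release. `kndysim` implements a conductance-based single-neuron model of
this cell together with the quantitative electrophysiology and qPCR
analysis used to calibrate and interrogate it. It is aimed at
computational neuroscientists and electrophysiologists who want a tested,
scriptable version of the model and its analysis pipeline.

## The model

The membrane equation is the Hodgkin–Huxley form

```
Cm dVm/dt = −(I_NaT + I_NaP + I_A + I_BK + I_h + I_SK + I_M + I_T
              + I_Ca + I_TRPC5 + I_GIRK + I_leak) + I_inj
```

with twelve ionic currents: transient and persistent Na⁺, A-type K⁺, large-
and small-conductance Ca²⁺-activated K⁺ (BK, SK), HCN (h), M (KCNQ),
T-type and high-voltage-activated (HVA) Ca²⁺, the NKB/Ca²⁺-activated
TRPC5 cation current, the dynorphin-activated GIRK K⁺ current, and leak.
Gating follows first-order Boltzmann kinetics; calcium is tracked in two
pools (a fast submembrane pool fed by the HVA current that drives SK, BK
and Ca-dependent inactivation, and a slower bulk pool that drives TRPC5
autocatalysis); NKB and dynorphin receptor drives are first-order states
that gate TRPC5 and GIRK, with Gq/PIP2 depletion attenuating M and GIRK
during NKB signaling. Units are fixed package-wide (mV, ms, nS, pA, pF,
µM), under which `nS·mV = pA` and `pA/pF = mV/ms`.

Two presets describe the ovariectomized (`ovx`) and estradiol-treated
(`ovx_e2`) states; they share all kinetics and differ only in the
conductances the physiology reports as estradiol-sensitive (HVA Ca, T, h,
TRPC5, GIRK, BK, M). The right-hand side is compiled C integrated through
`deSolve`.

## Worked example

```r
library(kndysim)

# estradiol-treated preset fires in spontaneous phasic bursts
e2 <- kndy_params("ovx_e2")
trace <- simulate_neuron(e2, spontaneous_protocol(20))
classify_firing(trace)$label
#> [1] "phasic_burst"

# calibrate the SK conductance against the measured apamin-sensitive
# density (60.2 pA/pF at +40 mV, untreated state)
fit <- calibrate_conductance("SK", data.frame(v = 40, density = 60.2),
                             kndy_params("ovx"))
round(fit$gbar_ns, 1)
#> [1] 28.1

# pooled t-test from printed group summaries (Ca2+ current density)
t_from_summary(7.2, 0.5, 40, 13.4, 0.9, 11)
#> # A tibble: 1 x 3
#>       t    df    p_value
#>   <dbl> <dbl>      <dbl>
#> 1 -5.82    49 0.000000437

# qPCR standard-curve efficiency, integer percent, capped at 100
primer_efficiency(-3.352)
#> [1] 99
```

The classification means the simulated estradiol-treated cell shows
spike ensembles riding on depolarized up-states separated by quiescent
down-states; the calibration returns the maximal SK conductance whose
modeled apamin-subtraction density matches the recorded one; the t value
reproduces the printed comparison of calcium current densities between
treatment groups.

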