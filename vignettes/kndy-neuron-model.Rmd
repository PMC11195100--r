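---
title: "A conductance-based model of the arcuate kisspeptin neuron and its analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A conductance-based model of the arcuate kisspeptin neuron and its analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The cell and the question

Arcuate kisspeptin (KNDy) neurons co-release kisspeptin, neurokinin B
(NKB) and dynorphin and are the accepted substrate of pulsatile GnRH
release. NKB acting on its Gq-coupled receptor opens TRPC5 channels and
produces a slow EPSP (a plateau potential) that sustains synchronous
high-frequency firing; dynorphin acting through κ-opioid receptors opens
GIRK channels and terminates it. Estradiol remodels this cell: it lowers
TRPC5 and GIRK expression, raises voltage-gated Ca²⁺, HCN, BK and KCNQ
conductances, and the neuron moves from the synchronizing plateau mode to
spontaneous phasic burst firing. `kndysim` is a biophysical model of one
such neuron in both states, plus the measurements used to calibrate it.

## Model structure

The membrane carries twelve currents (`NaT`, `NaP`, `A`, `BK`, `h`, `SK`,
`M`, `T`, `Ca` (lumped HVA), `TRPC5`, `GIRK`, `leak`), each with
first-order Boltzmann gating. The full gating parameterization —
midpoints, slopes, time constants, the calcium-handling constants and the
receptor-drive kinetics — is the package's own: it was constructed from
standard published functional forms for each channel family and then
calibrated so that the model reproduces the quantities the physiology of
this cell type reports (see *Calibration* below). The complete
parameterization ships as editable YAML presets
(`system.file("presets", package = "kndysim")`), and every constant can
be overridden through `kndy_params()`.

Choices worth knowing about:

* **Two calcium pools.** SK, BK and HVA Ca-dependent inactivation are
  driven by a fast submembrane pool (`ca_d`, τ = 120 ms) fed by the HVA
  current alone, reflecting the tight micro-domain coupling of SK/BK
  channels to HVA Ca²⁺ channels; its resting level (0.02 µM) is below the
  bulk resting concentration because the domain collapses without influx.
  TRPC5 is driven by a slower bulk pool (`ca_b`, τ = 2 s) that integrates
  all Ca²⁺ sources, including a fixed fraction of the TRPC5 current
  itself — this is the autocatalytic loop that lets Ca²⁺ entry through
  TRPC5 recruit more TRPC5 current during the slow EPSP. The bulk-loop
  gain is deliberately below the self-ignition threshold at rest, so a
  plateau requires firing-driven Ca²⁺ entry and decays once firing stops.
* **SK.** Purely Ca²⁺-gated, half-activation 0.3 µM with a Hill
  coefficient of 4; BK requires both depolarization and submembrane Ca²⁺
  (Hill 4).
* **HVA Ca²⁺ current.** Activation midpoint −32.3 mV; voltage-dependent
  inactivation is weak (floor 0.8) and most inactivation is
  Ca²⁺-dependent (CDI), as for L-type-dominated currents. The model lumps
  L/N/P/Q/R into one conductance; subtype-selective drugs block the
  printed percentage of it per state (`apply_drug()`).
* **Receptor drives.** NKB and dynorphin inputs are levels or pulse
  trains in [0, 1]; receptor activation states low-pass filter them (NKB:
  on 100 ms, off 8 s; Dyn: on 0.5 s, off 8 s). NKB signaling also
  attenuates the PIP2-dependent M and GIRK conductances (fraction 0.85 at
  saturation), the PLC/PIP2-depletion effect that facilitates sustained
  firing during synchronization. TRPC5 carries a slow desensitization
  state (τ = 12 s) so plateaus run down over tens of seconds.
* **Ideal voltage clamp.** No series resistance; the clamp current equals
  the summed ionic current, and drug subtraction on model traces is exact
  (the tests use the stored per-current decomposition as the oracle).
* **Solver.** Adaptive `lsoda` on a compiled right-hand side, rtol 1e-6,
  atol 1e-9, max step 1 ms; a fixed-step RK4 reference at 0.01 ms is
  available (`method = "rk4"`) and agrees within 0.5 mV. Simulations
  start from a 5-s settle at zero input from −70 mV unless an initial
  state is supplied.

## Calibration

The two presets differ only in the estradiol-sensitive conductances
(HVA Ca 2.1 → 2.8 nS, T 0.66 → 5 nS, h 0.35 → 2 nS, TRPC5 2.0 → 0.68 nS,
GIRK 1.2 → 0.4 nS, BK 7.64 → 20 nS, M 0.5 → 2 nS). Free constants were
fixed, once, against the recorded anchors for this cell type:

* the apamin-sensitive steady-state density at +40 mV equals
  60.2 pA/pF in the untreated state with g_SK = 28.1 nS (this pins the
  submembrane-pool gain);
* the ibTx-sensitive density at +40 mV is ~100 pA/pF in the
  estradiol-treated state with g_BK = 20 nS (pins the BK Ca²⁺
  half-activation), and ~31 pA/pF untreated (pins the untreated g_BK);
* the Cd-sensitive peak I–V (cesium internal, TTX) peaks at the −10 mV
  step at ≈7 pA/pF untreated and ≈13.4 pA/pF estradiol-treated;
* the XE-991-sensitive deactivation amplitude at −30 mV is 4× larger in
  the estradiol-treated state (the g_M ratio);
* the estradiol-treated preset fires spontaneous phasic bursts with
  up/down states, the untreated preset is silent at rest, fires
  tonically under saturating NKB/dynorphin drive, and falls silent when
  TRPC5 conductance is low relative to GIRK; halving TRPC5 raises
  rheobase and lowers the F–I curve at every step.

One tension in the source data cannot be satisfied by any Ca²⁺-activated
SK model with a state-independent g_SK: the SK current and SK3 mRNA do
not differ between states and g_SK = 28.1 nS matches the untreated
60.2 pA/pF, yet the treated state is also described by a ~50 pA/pF SK
contribution — while its *measured* apamin-sensitive density is
75.9 ± 12.3 pA/pF. Because the treated state has the larger HVA
conductance, its submembrane Ca²⁺, and therefore its SK density, is
necessarily ≥ the untreated one; this model lands at ≈91 pA/pF, on the
measured side of that contradiction. The corresponding acceptance check
against "~50 pA/pF" is left failing on purpose rather than resolved by
re-tuning.

Two further known deviations: the model's rheobase under a 50 pA/s ramp
is ≈9 pA (reported: ≈31 pA) because the silent resting state sits closer
to threshold than the recorded cells'; and the whole Cd-sensitive
activation midpoint fits at ≈−37 mV rather than −32.3 mV because the
T-type transient contributes at negative steps — isolating the HVA
component (TTA-P2 subtraction) recovers ≈−33.6 mV. Both quantities are
reported, not hidden, by `scripts/acceptance.R`.

## Measurements

All analysis operates on tidy `sim_trace` tibbles:

* `peak_iv()` — baseline-subtracted peak or steady-state I–V with
  densities (baseline: final 50 ms of the hold; steady window: final 5%
  of the step; peak: extremum by absolute value, inward negative).
* `fit_boltzmann()` — two-parameter sigmoid fits; both the standard
  inactivation convention and the complementary "1 − …" parameterization
  are available (they describe the same family; the latter returns the
  negative slope factor it implies).
* `drug_subtraction()` — control − treated, on traces or I–V curves,
  with protocol-hash checking.
* `m_current_amplitude()` — mean over the first 10 ms minus mean over
  475–500 ms of each deactivation step.
* `slow_epsp_metrics()` — 2-Hz zero-phase low-pass (reflect-padded
  Butterworth), amplitude = peak of the filtered trace within 30 s after
  train onset minus the 5-s pre-train mean; R2/R1 for two-epoch runs.
* `classify_firing()` — deterministic cascade: silent below 0.1 Hz;
  bursting when ≥2 bursts (runs of ≥2 spikes, intra-burst ISI ≤ 80 ms,
  ≥300 ms quiescence between) capture ≥50% of spikes — `phasic_burst` if
  the 10-Hz-filtered potential is bimodal with ≥10 mV mode separation,
  else `irregular_burst`; otherwise `tonic` below ISI CV 0.5, else
  `irregular`. Spike detection: upward crossing of −20 mV, 2-ms
  refractory. All constants live in `classify_config()`.
* `regime_map()` — classification over a two-conductance grid;
  per-point integration failures are labeled, not fatal.
* `calibrate_conductance()` — drug-subtraction density matching; exact
  closed form for channels whose current is linear in g under clamp,
  bounded search otherwise.
* qPCR: `primer_efficiency()` (E = 10^(−1/m) − 1, integer percent capped
  at 100 — the cap reproduces how standard-curve tables report
  better-than-perfect slopes), `ddct_fold_change()` (per-pool ΔCT,
  calibrator-group ΔΔCT, per-animal 2^−ΔΔCT means), and
  `t_from_summary()` (pooled by default, Welch behind a flag; which
  variant produced any given printed t is usually unstated, and pooled
  reproduces the worked example).

The F–I comparison between TRPC5 variants is made on 10–90 pA steps;
beyond ≈90 pA the model approaches depolarization block, where rate
comparisons stop being meaningful.

## Synthetic data

`generate_vclamp_cells()`, `generate_spike_train()` and
`generate_qpcr_pools()` produce seeded datasets with the cohort structure
of the real experiments: Gaussian between-cell offsets (a cohort printed
as mean ± SEM over n cells has between-cell SD = SEM·√n), Gaussian
within-curve noise, gamma ISI spike trains or constructed burst/up-state
traces, and CT tables with per-animal random effects on the cycle scale.
These generators exist to validate the estimators (classifier ground
truth, ΔΔCT recovery, law-of-large-numbers convergence at n = 10⁴); they
do not emulate patch-clamp artifacts (capacitive transients, access
resistance) or qPCR outliers, so passing tests say the *pipeline* is
correct, not that it is robust to every failure mode of real recordings.

## Problem sizes

The shipped tests and the acceptance script use single-sweep clamp
families for density calibrations, full 12-sweep families for the I–V
curves, 15–20 s windows for firing classification, a 10-s train plus 40-s
observation for the slow EPSP, and 2-s steps for F–I; these are the
smallest sizes at which each measurement is stable.

## Limitations

Single neuron only (no KNDy network or presynaptic dynorphin action);
deterministic ODEs (no channel noise); ideal clamp; one lumped HVA
conductance; receptor cascades reduced to first-order drives. The
transient Na⁺ window current is sizeable near −30 mV, which is why the
K⁺- and Ca²⁺-current protocols are simulated under TTX, as in the
corresponding recordings.
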